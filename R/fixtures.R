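# Fixtures: the bundled RPV study inputs reconstructed from the published
# values, plus analytic toy cases with closed-form answers.

# Frozen FNV-1a checksum over the canonical fixture values; guards the
# packaged data files against silent drift. Regenerate with
# alaradose:::kori_checksum() after a deliberate data change.
.KORI_CHECKSUM <- 3661993496

kori_checksum <- function(fix) {
  inv_str <- paste(unlist(lapply(fix$inventories, function(iv)
    c(iv$part_name, iv$entries$nuclide, sprintf("%.10g", iv$entries$activity_bq)))),
    collapse = "|")
  wp_str <- paste(unlist(lapply(fix$work_plans, function(p)
    c(p$label, p$repetitions, sprintf("%.10g", p$uncertainty_fraction),
      unlist(lapply(p$tasks, function(t)
        c(t$label, t$role, sprintf("%.10g", c(t$duration_min, t$dose_rate_msv_h)))))))),
    collapse = "|")
  cut_str <- paste(sprintf("%.10g", unlist(c(
    fix$cut$rpv[names(fix$cut$rpv) != "class"], fix$cut$drum$height_m,
    fix$cut$drum$diameter_m, fix$cut$counts, fix$cut$cut_lengths_m))),
    collapse = "|")
  fnv1a32(paste(inv_str, wp_str, cut_str, sep = "||"))
}

#' Reconstruct the bundled Kori-1 RPV fixture
#'
#' Scene (RPV shells), radionuclide inventories for the upper/active/lower
#' parts, the six work plans (fragmentation and segmentation of each part,
#' repetitions upper 6 / active 6 / lower 8), the cutting-scenario
#' parameters and the technology presets — all read from packaged
#' plain-text data files whose values are the published ones. A checksum
#' over the values guards against drift.
#'
#' @param verify_checksum error if the packaged values do not match the
#'   frozen checksum.
#' @return object of class `kori_fixture` with elements `scene`,
#'   `inventories` (named list), `work_plans` (named list), `cut` (rpv,
#'   drum, counts, cut lengths, technologies), `worker_distance_m`.
#' @export
build_kori_fixture <- function(verify_checksum = TRUE) {
  scene <- read_scene_json(pkg_extdata("kori_scene.json"))
  inventories <- read_inventory_csv(pkg_extdata("kori_inventories.csv"))
  work_plans <- read_work_plans(pkg_extdata("kori_workplans.json"))
  j <- jsonlite::fromJSON(pkg_extdata("kori_cutting.json"))
  rpv <- rpv_spec(j$rpv$total_height_m, j$rpv$body_length_m,
                  j$rpv$inside_diameter_m, j$rpv$shell_thickness_m,
                  j$rpv$cap_length_m, j$rpv$leg_fragment_height_m,
                  j$rpv$outside_diameter_m)
  fix <- structure(list(
    scene = scene,
    inventories = inventories,
    work_plans = work_plans,
    cut = list(rpv = rpv, drum = drum_spec(j$drum$height_m, j$drum$diameter_m),
               counts = as.list(j$counts), cut_lengths_m = as.list(j$cut_lengths_m),
               scenario_speed_mm_min = j$scenario_speed_mm_min,
               technologies = technology_presets()),
    # cutter 30-38 cm band and RPO 100-130 cm band; midpoints are the
    # default worker positions
    worker_distance_m = list(cutter = c(0.30, 0.38), rpo = c(1.00, 1.30))),
    class = "kori_fixture")
  if (verify_checksum && !is.na(.KORI_CHECKSUM)) {
    got <- kori_checksum(fix)
    if (got != .KORI_CHECKSUM)
      stop(sprintf("fixture checksum mismatch (%.0f != %.0f): packaged data drifted",
                   got, .KORI_CHECKSUM))
  }
  fix
}

#' Default worker dose point for a part of the RPV
#'
#' Cutter at the midpoint of the 30-38 cm band (34 cm) from the shell outer
#' surface, RPO at the midpoint of 100-130 cm (115 cm), at the axial
#' mid-height of the part's shell zone.
#'
#' @param fix a [build_kori_fixture()].
#' @param part "upper", "active" or "lower".
#' @param role "cutter" or "rpo".
#' @return position in metres (length 3).
#' @export
kori_worker_point <- function(fix, part = "active", role = c("cutter", "rpo")) {
  role <- match.arg(role)
  reg <- kori_part_region(fix, part)
  sh <- reg$shape
  z_mid <- (sh$base[3] + sh$height / 2) / M2CM
  standoff <- mean(fix$worker_distance_m[[role]])
  c(sh$r_outer / M2CM + standoff, 0, z_mid)
}

#' Region of the scene holding a part's shell
#' @inheritParams kori_worker_point
#' @export
kori_part_region <- function(fix, part = "active") {
  nm <- paste0(part, "_shell")
  for (r in fix$scene$regions) if (identical(r$name, nm)) return(r)
  stop("no scene region named ", nm)
}

# Deterministic midpoint-rule volume quadrature for a z-aligned cylindrical
# source in a homogeneous ambient material: the independent oracle for the
# Monte-Carlo kernel. No ray tracing: optical depth is mu * rho.
quadrature_flux_cylinder <- function(base_m, r_m, h_m, point_m, s_per_cm3,
                                     mu_lin_cm = 0, n_cells = 1e6,
                                     buildup_fun = NULL) {
  n1 <- max(8L, round(n_cells^(1 / 3)))
  xs <- seq(base_m[1] - r_m, base_m[1] + r_m, length.out = n1 + 1)
  ys <- seq(base_m[2] - r_m, base_m[2] + r_m, length.out = n1 + 1)
  zs <- seq(base_m[3], base_m[3] + h_m, length.out = n1 + 1)
  cx <- (xs[-1] + xs[-length(xs)]) / 2
  cy <- (ys[-1] + ys[-length(ys)]) / 2
  cz <- (zs[-1] + zs[-length(zs)]) / 2
  dv_cm3 <- diff(xs)[1] * diff(ys)[1] * diff(zs)[1] * M2CM^3
  total <- 0
  # loop z-slabs to bound memory; fully vectorized in x,y
  g <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  in_circle <- (g$x - base_m[1])^2 + (g$y - base_m[2])^2 <= r_m^2
  gx <- g$x[in_circle]; gy <- g$y[in_circle]
  for (z in cz) {
    rho_cm <- sqrt((gx - point_m[1])^2 + (gy - point_m[2])^2 +
                   (z - point_m[3])^2) * M2CM
    att <- exp(-mu_lin_cm * rho_cm)
    if (!is.null(buildup_fun)) att <- att * buildup_fun(mu_lin_cm * rho_cm)
    total <- total + sum(att / (4 * pi * rho_cm^2))
  }
  total * s_per_cm3 * dv_cm3
}

#' Analytic toy cases
#'
#' Small scenes whose answers are computable independently of the dose
#' engine: (1) a vacuum point-like source with the inverse-square closed
#' form; (2) transmission through a 2-mean-free-path steel slab,
#' `e^(-2)` times the vacuum kernel; (3) a cylindrical air source against a
#' deterministic midpoint-rule quadrature; (4) two mirrored sources whose
#' doses must superpose symmetrically.
#'
#' @param seed seed recorded in each case's sampling plan.
#' @param quad_cells number of quadrature cells for the cylinder oracle.
#' @return list of cases, each with `name`, `scene`, `source`, `point`,
#'   `plan`, `expected` (for flux cases, cm^-2 s^-1 in the single active
#'   group), `tol_rel`, `description`.
#' @export
make_toy_cases <- function(seed = 1, quad_cells = 1e6) {
  mats <- material_library()
  groups1 <- energy_groups(n_bins = 1, e_min = 1.2, e_max = 1.3)
  e_rep <- groups1$representative
  lib1 <- structure(list(
    nuclides = data.frame(nuclide = "toy", half_life_years = 5,
                          stringsAsFactors = FALSE),
    lines = data.frame(nuclide = "toy", energy_mev = 1.25, yield = 1,
                       stringsAsFactors = FALSE)), class = "nuclide_library")
  mk_spec <- function(activity) build_spectrum(inventory("toy", "toy", activity),
                                               groups1, lib1)
  cases <- list()

  # 1) vacuum point source: flux = S / (4 pi rho^2), B = 1, x = 0
  s_tot <- 4 * pi * 1e4
  src <- point_source(c(0, 0, 0), mk_spec(s_tot))
  sc <- scene_model(list(), ambient = "vacuum", materials = mats)
  cases$vacuum_point <- list(
    name = "vacuum_point", scene = sc, source = src, point = c(1, 0, 0),
    plan = sampling_plan(2000, seed = seed, exclusion_cm = 0.001),
    expected = s_tot / (4 * pi * 100^2), tol_rel = 1e-12,
    description = "inverse-square closed form; expected 1.0 cm^-2 s^-1 exactly")

  # 2) slab of 2 mean free paths: kernel attenuated by e^{-2}
  steel <- mats$stainless_steel
  thick_cm <- 2 / mu_linear(steel, e_rep)
  slab <- region(shape_box(c(0.40, -0.5, -0.5),
                           c(0.40 + thick_cm / M2CM, 0.5, 0.5)),
                 "stainless_steel")
  sc2 <- scene_model(list(slab), ambient = "vacuum", materials = mats)
  src2 <- point_source(c(0, 0, 0), mk_spec(s_tot))
  cases$slab_2mfp <- list(
    name = "slab_2mfp", scene = sc2, source = src2, point = c(1, 0, 0),
    plan = sampling_plan(2000, seed = seed, exclusion_cm = 0.001),
    expected = exp(-2) * s_tot / (4 * pi * 100^2), tol_rel = 1e-9,
    description = "transmission e^{-x} through a 2-mfp steel slab (build-up off)")

  # 3) cylindrical air source vs deterministic midpoint quadrature
  cyl_r <- 0.3; cyl_h <- 0.8; base <- c(0, 0, 0); pt <- c(1.5, 0, 0.4)
  act <- 1e8
  srcreg <- region(shape_cylinder(base, c(0, 0, 1), cyl_r, cyl_h), "air")
  sc3 <- scene_model(list(srcreg), ambient = "air", materials = mats)
  src3 <- source_region(srcreg, mk_spec(act))
  mu_air <- mu_linear(mats$air, e_rep)
  vol_cm3 <- pi * cyl_r^2 * cyl_h * M2CM^3
  cases$cylinder_quadrature <- list(
    name = "cylinder_quadrature", scene = sc3, source = src3, point = pt,
    plan = sampling_plan(1e5, seed = seed, exclusion_cm = 1),
    expected = quadrature_flux_cylinder(base, cyl_r, cyl_h, pt, act / vol_cm3,
                                        mu_air, n_cells = quad_cells),
    tol_rel = 0.01,
    description = "midpoint-rule volume quadrature oracle, 1% band")

  # 4) two mirrored sources: superposition and symmetry
  sA <- region(shape_sphere(c(0, 0.5, 0), 0.05), "air")
  sB <- region(shape_sphere(c(0, -0.5, 0), 0.05), "air")
  sc4 <- scene_model(list(sA, sB), ambient = "air", materials = mats)
  cases$mirrored_pair <- list(
    name = "mirrored_pair", scene = sc4,
    source = list(source_region(sA, mk_spec(1e7)),
                  source_region(sB, mk_spec(1e7))),
    point = c(1, 0, 0),
    plan = sampling_plan(5000, seed = seed, exclusion_cm = 0.5),
    expected = NA_real_, tol_rel = NA_real_,
    description = "dose(A+B) = dose(A) + dose(B); symmetric halves")
  cases
}

#' Multiplicatively perturb a fixture (robustness support)
#'
#' Applies seeded lognormal factors (sdlog = `fraction`, unit mean) to all
#' inventory activities and task durations. `fraction = 0` returns the
#' fixture unchanged.
#'
#' @param fix a [build_kori_fixture()].
#' @param fraction perturbation scale in `[0, 1)`.
#' @param seed RNG seed.
#' @export
perturb_fixture <- function(fix, fraction, seed) {
  stopifnot(inherits(fix, "kori_fixture"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  if (fraction == 0) return(fix)
  with_seed(seed, {
    meanlog <- -fraction^2 / 2          # unit-mean lognormal
    for (p in names(fix$inventories)) {
      n <- nrow(fix$inventories[[p]]$entries)
      fix$inventories[[p]]$entries$activity_bq <-
        fix$inventories[[p]]$entries$activity_bq *
        exp(rnorm(n, meanlog, fraction))
    }
    for (w in names(fix$work_plans)) {
      for (i in seq_along(fix$work_plans[[w]]$tasks)) {
        fix$work_plans[[w]]$tasks[[i]]$duration_min <-
          fix$work_plans[[w]]$tasks[[i]]$duration_min *
          exp(rnorm(1, meanlog, fraction))
      }
    }
    fix
  })
}
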