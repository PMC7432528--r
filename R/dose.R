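# Point-kernel dose engine: Monte-Carlo sampling of source positions,
# per-group fluence rates with attenuation and build-up, and conversion to
# ambient dose equivalent rate.
#
# For a grouped source of total activity S_tot and group emission fractions
# F_Eb, the group fluence rate at a dose point is estimated over Ns sampled
# source positions as
#   phi_Eb = (S_tot F_Eb / Ns) * sum_i B(E_b, x_i) e^{-x_i} / (4 pi rho_i^2)
# with x_i the optical depth along the traced ray and rho_i the distance in
# cm, and the dose rate is sum_b h_Eb phi_Eb in mSv/h.

#' Volume source: an emitting region with a grouped spectrum
#'
#' The source is assumed uniform over the region volume; the strength
#' density S (photons/cm^3/s) is the total photon emission rate divided by
#' the volume. Self-absorption is automatic because rays traced from sample
#' points pass through the region's own material.
#'
#' @param reg a [region()] (the emitting volume).
#' @param spectrum a [build_spectrum()] result.
#' @return object of class `source_region`.
#' @export
source_region <- function(reg, spectrum) {
  stopifnot(inherits(reg, "scene_region"), inherits(spectrum, "grouped_spectrum"))
  vol <- shape_volume(reg$shape)
  if (vol <= 0) stop("source region must have positive volume")
  structure(list(region = reg, spectrum = spectrum, volume_cm3 = vol,
                 strength_density = spectrum$total_activity *
                   sum(spectrum$fractions) / vol),
            class = "source_region")
}

#' Degenerate point source
#'
#' An isotropic point emitter: the limit of a shrinking volume source. All
#' "sampled" positions coincide with the point, so the vacuum closed form
#' `S / (4 pi rho^2)` is reproduced to machine precision.
#'
#' @param position emitter location (metres).
#' @param spectrum a [build_spectrum()] result.
#' @return object of class `source_region` with `degenerate = TRUE`.
#' @export
point_source <- function(position, spectrum) {
  stopifnot(inherits(spectrum, "grouped_spectrum"))
  structure(list(region = NULL, spectrum = spectrum, volume_cm3 = 0,
                 strength_density = Inf, degenerate = TRUE,
                 position = as.numeric(position)),
            class = "source_region")
}

#' Monte-Carlo sampling plan
#'
#' @param n_samples number of source sample points Ns (>= 1). Default 20000.
#' @param seed mandatory RNG seed for reproducibility.
#' @param exclusion_cm samples closer than this to the dose point are
#'   rejected and redrawn (the 1/rho^2 kernel is integrable but numerically
#'   explosive); Ns is preserved.
#' @export
sampling_plan <- function(n_samples = 20000, seed, exclusion_cm = 1) {
  stopifnot_scalar_num(n_samples, "n_samples", positive = TRUE)
  if (missing(seed)) stop("seed is mandatory in sampling plans")
  stopifnot_scalar_num(seed, "seed")
  stopifnot_scalar_num(exclusion_cm, "exclusion_cm", nonneg = TRUE)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 exclusion_cm = exclusion_cm),
            class = "sampling_plan")
}

#' Sample uniform source positions
#'
#' Rejection sampling from the shape's bounding box; deterministic for a
#' fixed seed.
#'
#' @param source a [source_region()].
#' @param plan a [sampling_plan()].
#' @return `n_samples x 3` matrix of positions (metres).
#' @export
sample_source_points <- function(source, plan) {
  stopifnot(inherits(source, "source_region"), inherits(plan, "sampling_plan"))
  if (isTRUE(source$degenerate))
    return(matrix(source$position, plan$n_samples, 3, byrow = TRUE))
  shp <- source$region$shape
  bb <- shape_bbox(shp)                      # cm
  n <- plan$n_samples
  with_seed(plan$seed, {
    out <- matrix(NA_real_, 0, 3)
    guard <- 0L
    while (nrow(out) < n) {
      m <- max(2L * (n - nrow(out)), 64L)
      P <- cbind(runif(m, bb[1, 1], bb[2, 1]),
                 runif(m, bb[1, 2], bb[2, 2]),
                 runif(m, bb[1, 3], bb[2, 3]))
      out <- rbind(out, P[inside_pts(shp, P), , drop = FALSE])
      guard <- guard + 1L
      if (guard > 10000L) stop("rejection sampling failed; zero-volume region?")
    }
    out[seq_len(n), , drop = FALSE] / M2CM   # back to metres
  })
}

# Core kernel evaluation shared by group_flux() and dose_rate(): returns the
# per-sample, per-group kernel matrix B e^{-x} / (4 pi rho^2) (cm^-2).
.kernel_matrix <- function(scene, source, point, plan, buildup) {
  groups <- source$spectrum$group_structure
  erep <- groups$representative
  if (!isTRUE(source$degenerate) &&
      inside_pts(source$region$shape, matrix(as.numeric(point) * M2CM, 1)) &&
      plan$exclusion_cm <= 0)
    stop("dose point lies inside the source volume; set a positive ",
         "exclusion_cm in the sampling plan")
  pts <- sample_source_points(source, plan)
  # enforce the exclusion radius, redrawing rejected samples (seeded stream
  # continues deterministically past the first draw)
  n_rejected <- 0L
  with_seed(plan$seed + 1L, {
    for (round in 1:100) {
      d_cm <- sqrt(rowSums((sweep(pts, 2, as.numeric(point)))^2)) * M2CM
      bad <- which(d_cm < plan$exclusion_cm)
      if (!length(bad)) break
      n_rejected <- n_rejected + length(bad)
      if (round == 100)
        stop("could not place samples outside the exclusion radius; ",
             "is the source volume entirely within it?")
      repl <- sampling_plan(length(bad), seed = plan$seed + round,
                            exclusion_cm = plan$exclusion_cm)
      pts[bad, ] <- sample_source_points(source, repl)
    }
  })
  pl <- path_lengths_matrix(scene, pts, point)
  rho <- pl$dist_cm
  mat_names <- colnames(pl$lengths)
  mats <- scene$materials
  # linear attenuation per material per group
  mu <- vapply(mat_names, function(m) mu_linear(mats[[m]], erep),
               numeric(length(erep)))                    # n_groups x M
  mu <- matrix(mu, nrow = length(erep), ncol = length(mat_names),
               dimnames = list(NULL, mat_names))         # keep shape at 1 group
  x <- pl$lengths %*% t(mu)                              # n x n_groups
  B <- matrix(1, nrow(x), ncol(x))
  if (buildup$enabled) {
    for (bidx in seq_along(erep)) {
      contrib <- sweep(pl$lengths, 2, mu[bidx, ], `*`)   # n x M
      dom <- max.col(contrib, ties.method = "first")
      for (m in unique(dom)) {
        rows <- which(dom == m)
        B[rows, bidx] <- buildup_factor(buildup, mat_names[m], erep[bidx],
                                        x[rows, bidx])
      }
    }
  }
  k <- B * exp(-x) / (4 * pi * rho^2)
  attr(k, "n_rejected") <- n_rejected
  k
}

#' Per-group fluence rate at a dose point
#'
#' @param scene a [scene_model()].
#' @param source a [source_region()].
#' @param point dose point (metres); outside the source volume, or covered by
#'   the plan's exclusion radius.
#' @param plan a [sampling_plan()].
#' @param buildup a [buildup_model()] (or [buildup_none()]).
#' @return numeric vector of group fluence rates (cm^-2 s^-1), with the
#'   number of exclusion-rejected samples as attribute `n_rejected`.
#' @export
group_flux <- function(scene, source, point, plan, buildup = buildup_model()) {
  k <- .kernel_matrix(scene, source, point, plan, buildup)
  f <- source$spectrum$total_activity * source$spectrum$fractions *
    colSums(k) / plan$n_samples
  attr(f, "n_rejected") <- attr(k, "n_rejected")
  f
}

#' Fluence-to-dose conversion table aligned to a group structure
#'
#' Ambient dose equivalent per unit fluence, discretized at each bin's
#' representative energy from the bundled H*(10) coefficient curve
#' (log-log interpolated) and converted to (mSv/h)/(cm^-2 s^-1).
#'
#' @param groups an [energy_groups()].
#' @param curve optional data.frame `energy_mev, h10_psv_cm2` overriding the
#'   bundled coefficients.
#' @return object of class `dose_conversion` with `h` (length n_bins) and
#'   the group structure.
#' @export
dose_conversion_table <- function(groups = energy_groups(), curve = NULL) {
  stopifnot(inherits(groups, "energy_groups"))
  if (is.null(curve))
    curve <- utils::read.csv(pkg_extdata("dose_conversion.csv"),
                             stringsAsFactors = FALSE)
  h10 <- loglog_interp(curve$energy_mev, curve$h10_psv_cm2,
                       groups$representative, what = "dose-conversion table")
  # pSv cm^2 * 3600 s/h * 1e-9 mSv/pSv
  structure(list(h = h10 * 3.6e-6, groups = groups), class = "dose_conversion")
}

#' Dose rate at a point from a volume source
#'
#' Runs the point-kernel estimator and converts group fluence rates to an
#' ambient dose equivalent rate in mSv/h. The per-nuclide split re-uses the
#' common sampled kernel, so contributions sum to the total exactly.
#'
#' @inheritParams group_flux
#' @param h a [dose_conversion_table()] aligned with the source's groups.
#' @return object of class `dose_result`: `point`, `group_flux`, `dose_rate`
#'   (mSv/h), `per_nuclide` (named vector, mSv/h), `stderr` (MC standard
#'   error of the dose rate), `n_rejected`.
#' @export
dose_rate <- function(scene, source, point, plan, buildup = buildup_model(),
                      h = dose_conversion_table(source$spectrum$group_structure)) {
  stopifnot(inherits(h, "dose_conversion"))
  gs <- source$spectrum$group_structure
  if (length(h$h) != gs$n_bins ||
      max(abs(h$groups$boundaries - gs$boundaries)) > 1e-12)
    stop("dose-conversion table and source spectrum use different group structures")
  k <- .kernel_matrix(scene, source, point, plan, buildup)
  s_tot <- source$spectrum$total_activity
  flux <- s_tot * source$spectrum$fractions * colSums(k) / plan$n_samples
  per_sample <- s_tot * as.vector(k %*% (h$h * source$spectrum$fractions))
  dose <- sum(h$h * flux)
  K <- colSums(k) / plan$n_samples
  per_nuc <- s_tot * as.vector(source$spectrum$per_nuclide %*% (h$h * K))
  names(per_nuc) <- rownames(source$spectrum$per_nuclide)
  se <- if (plan$n_samples > 1) stats::sd(per_sample) / sqrt(plan$n_samples) else NA_real_
  structure(list(point = as.numeric(point), group_flux = flux,
                 dose_rate = dose, per_nuclide = per_nuc, stderr = se,
                 n_rejected = attr(k, "n_rejected")),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result> %.4e mSv/h (MC stderr %.2e) at (%.3g, %.3g, %.3g) m\n",
              x$dose_rate, x$stderr, x$point[1], x$point[2], x$point[3]))
  if (length(x$per_nuclide)) {
    fr <- nuclide_fractions(x)
    top <- sort(fr, decreasing = TRUE)
    cat("  leading contributors:",
        paste(sprintf("%s %.1f%%", names(top)[seq_len(min(3, length(top)))],
                      100 * top[seq_len(min(3, length(top)))]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Per-nuclide dose-rate fractions
#'
#' @param result a [dose_rate()] result.
#' @return named vector of fractions in `[0, 1]` summing to 1; empty for a
#'   zero dose rate.
#' @export
nuclide_fractions <- function(result) {
  stopifnot(inherits(result, "dose_result"))
  if (!is.finite(result$dose_rate) || result$dose_rate <= 0)
    return(stats::setNames(numeric(0), character(0)))
  result$per_nuclide / result$dose_rate
}

#' Dose map over an axis-aligned lattice
#'
#' Evaluates [dose_rate()] at every lattice node, summing over sources. The
#' per-node seed is derived from the plan seed and the node *position* (not
#' its index), so refining the grid does not change values at shared nodes.
#'
#' @param scene a [scene_model()].
#' @param sources a [source_region()] or list of them.
#' @param grid list with numeric vectors `x`, `y`, `z` (metres).
#' @param plan a [sampling_plan()]; its seed anchors all node seeds.
#' @param buildup a [buildup_model()].
#' @param h a [dose_conversion_table()].
#' @return data.frame `x_m, y_m, z_m, dose_rate_msv_h, stderr`.
#' @export
dose_map <- function(scene, sources, grid, plan, buildup = buildup_model(),
                     h = NULL) {
  if (inherits(sources, "source_region")) sources <- list(sources)
  stopifnot(all(vapply(sources, inherits, TRUE, "source_region")))
  nodes <- expand.grid(x = grid$x, y = grid$y, z = grid$z,
                       KEEP.OUT.ATTRS = FALSE)
  if (is.null(h))
    h <- dose_conversion_table(sources[[1]]$spectrum$group_structure)
  dose <- se2 <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    pt <- as.numeric(nodes[i, ])
    node_seed <- (plan$seed +
                    fnv1a32(sprintf("%.9g_%.9g_%.9g", pt[1], pt[2], pt[3]))) %% 2^31
    node_plan <- sampling_plan(plan$n_samples, seed = node_seed,
                               exclusion_cm = plan$exclusion_cm)
    for (src in sources) {
      r <- dose_rate(scene, src, pt, node_plan, buildup, h)
      dose[i] <- dose[i] + r$dose_rate
      se2[i] <- se2[i] + r$stderr^2
    }
  }
  data.frame(x_m = nodes$x, y_m = nodes$y, z_m = nodes$z,
             dose_rate_msv_h = dose, stderr = sqrt(se2))
}
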