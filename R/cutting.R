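# RPV decomposition and cutting-time computation: drum-driven
# fragmentation/segmentation planning and cutting-technology sensitivity.

#' Reactor-pressure-vessel dimensions
#'
#' @param total_height_m,body_length_m,inside_diameter_m,shell_thickness_m,cap_length_m,leg_fragment_height_m
#'   dimensions in metres, all positive.
#' @param outside_diameter_m optional; defaults to
#'   `inside_diameter + 2 * thickness` and is checked against it within
#'   rounding if supplied.
#' @export
rpv_spec <- function(total_height_m, body_length_m, inside_diameter_m,
                     shell_thickness_m, cap_length_m, leg_fragment_height_m,
                     outside_diameter_m = NULL) {
  for (v in c(total_height_m, body_length_m, inside_diameter_m,
              shell_thickness_m, cap_length_m, leg_fragment_height_m))
    stopifnot_scalar_num(v, "rpv dimension", positive = TRUE)
  od <- inside_diameter_m + 2 * shell_thickness_m
  if (!is.null(outside_diameter_m) && abs(outside_diameter_m - od) > 0.05)
    stop("outside diameter inconsistent with inside diameter + 2 x thickness")
  structure(list(total_height_m = total_height_m, body_length_m = body_length_m,
                 inside_diameter_m = inside_diameter_m,
                 shell_thickness_m = shell_thickness_m,
                 outside_diameter_m = outside_diameter_m %||% od,
                 cap_length_m = cap_length_m,
                 leg_fragment_height_m = leg_fragment_height_m),
            class = "rpv_spec")
}

#' Waste-drum dimensions
#' @param height_m,diameter_m drum envelope in metres, positive.
#' @export
drum_spec <- function(height_m, diameter_m) {
  stopifnot_scalar_num(height_m, "height_m", positive = TRUE)
  stopifnot_scalar_num(diameter_m, "diameter_m", positive = TRUE)
  structure(list(height_m = height_m, diameter_m = diameter_m),
            class = "drum_spec")
}

#' Cutting technology
#' @param name identifier.
#' @param speed_mm_min cutting speed, mm/min, > 0.
#' @param max_thickness_cm maximum cuttable thickness.
#' @export
cutting_tech <- function(name, speed_mm_min, max_thickness_cm = 20) {
  stopifnot_scalar_num(speed_mm_min, "speed_mm_min", positive = TRUE)
  structure(list(name = name, speed_mm_min = speed_mm_min,
                 max_thickness_cm = max_thickness_cm),
            class = "cutting_tech")
}

#' Bundled technology presets
#'
#' Named presets (waterjet, laser, shear, plasma) from the bundled table,
#' plus the scenario baseline speed of 15 mm/min used in every worked
#' calculation. The published speed table and the sensitivity narrative
#' contradict each other for plasma and laser; speeds are treated purely as
#' configuration here.
#'
#' @return named list of [cutting_tech()] objects.
#' @export
technology_presets <- function() {
  j <- jsonlite::fromJSON(pkg_extdata("kori_cutting.json"))
  t <- j$technologies
  out <- lapply(seq_len(nrow(t)), function(i)
    cutting_tech(t$name[i], t$speed_mm_min[i], t$max_thickness_cm[i]))
  names(out) <- t$name
  out$baseline <- cutting_tech("baseline", j$scenario_speed_mm_min)
  out
}

#' Circumference of a circular cut
#'
#' Follows the published arithmetic convention: pi approximated as 3.14 and
#' the length rounded to `round_to` metres before any time computation.
#' (True pi with 0.01 m rounding does not reproduce the published cut
#' times; see the methods vignette.)
#'
#' @param radius_m radius in metres, > 0.
#' @param pi_value default 3.14, the published convention; pass `base::pi`
#'   for the exact value.
#' @param round_to rounding quantum in metres (default 0.01).
#' @return circumference in metres, rounded.
#' @export
circumference <- function(radius_m, pi_value = 3.14, round_to = 0.01) {
  stopifnot_scalar_num(radius_m, "radius_m", positive = TRUE)
  round((2 * pi_value * radius_m) / round_to) * round_to
}

#' Cutting time for a given length
#'
#' `length / speed`, rounded to the nearest whole minute.
#'
#' @param length_mm cut length in millimetres, > 0.
#' @param tech a [cutting_tech()] (or a plain positive speed in mm/min).
#' @return minutes (integer-valued numeric).
#' @export
cutting_time <- function(length_mm, tech) {
  stopifnot_scalar_num(length_mm, "length_mm", positive = TRUE)
  speed <- if (inherits(tech, "cutting_tech")) tech$speed_mm_min else tech
  if (!is.numeric(speed) || speed <= 0) stop("cutting speed must be > 0")
  round(length_mm / speed)
}

# Smallest circumferential segment count whose piece fits the drum: the
# piece cross-section is bounded by chord x (thickness + sagitta), and its
# diagonal must fit the drum diameter minus a 2.5 cm handling clearance.
.segments_to_fit <- function(r_outer_m, thickness_m, drum, clearance_m = 0.025) {
  limit <- drum$diameter_m - clearance_m
  if (limit <= thickness_m)
    stop("piece thickness cannot fit the drum cross-section")
  for (n in 1:4096) {
    chord <- 2 * r_outer_m * sin(pi / n)
    sagitta <- r_outer_m * (1 - cos(pi / n))
    if (sqrt(chord^2 + (thickness_m + sagitta)^2) <= limit) return(n)
  }
  stop("no segment count fits the drum cross-section")
}

#' Decompose an RPV into a drum-driven cut plan
#'
#' Packing convention (emitted in the plan for audit): the nominal axial
#' fragment height is 85% of the drum height (0.8 m drum -> 0.68 m, the
#' published leg fragment height); the axial fragment count is
#' `floor(body length / nominal height)`. The body's circumferential segment
#' count is the smallest count whose piece bounding box (chord x thickness +
#' sagitta) fits the drum diameter minus a 2.5 cm clearance. The cap is cut
#' into four fragments; the top two reuse the body segment count
#' (cutting-pattern continuity), the two smaller ones use
#' `cap_small_segments` (default 10), validated against the fit rule. Legs
#' get `leg_cuts` fragmentation cuts at the leg fragment height.
#'
#' @param rpv an [rpv_spec()].
#' @param drum a [drum_spec()].
#' @param tech a [cutting_tech()]; default the 15 mm/min scenario baseline.
#' @param cap_small_segments segment count for the two small cap fragments.
#' @param leg_cuts number of leg fragmentation operations.
#' @param cut_lengths_m optional named list overriding the computed cut
#'   lengths (`body_circumference`, `cap_top_circumference`,
#'   `cap_small_circumference`, `radial_cut_length`) with published values.
#' @return object of class `cut_plan` with a per-part table (fragments,
#'   segments, cut lengths mm, per-cut minutes), the packing convention and
#'   the total piece count.
#' @export
decompose_rpv <- function(rpv, drum, tech = cutting_tech("baseline", 15),
                          cap_small_segments = 10, leg_cuts = 6,
                          cut_lengths_m = NULL) {
  stopifnot(inherits(rpv, "rpv_spec"), inherits(drum, "drum_spec"))
  r_out <- rpv$outside_diameter_m / 2
  nominal_h <- 0.85 * drum$height_m
  if (nominal_h <= 0) stop("drum too small for any fragment")
  body_frags <- floor(rpv$body_length_m / nominal_h)
  if (body_frags < 1) body_frags <- 1L
  frag_height <- rpv$body_length_m / body_frags
  if (frag_height > drum$height_m)
    stop("body fragments cannot fit the drum height: body")
  body_segs <- .segments_to_fit(r_out, rpv$shell_thickness_m, drum)
  min_cap_small <- .segments_to_fit(r_out / 4, rpv$shell_thickness_m, drum)
  if (cap_small_segments < min_cap_small)
    stop("cap_small_segments below the drum-fit minimum of ", min_cap_small)
  len <- list(
    body_circumference = circumference(r_out),
    cap_top_circumference = circumference(r_out / 2, round_to = 0.1),
    cap_small_circumference = circumference(r_out / 4),
    radial_cut_length = round(frag_height * body_segs, 2))
  if (!is.null(cut_lengths_m)) len[names(cut_lengths_m)] <- cut_lengths_m
  parts <- data.frame(
    part = c("body", "cap_top", "cap_small", "legs"),
    fragments = c(body_frags, 2, 2, leg_cuts),
    segments_per_fragment = c(body_segs, body_segs, cap_small_segments, 1),
    cut_length_mm = 1000 * c(len$body_circumference, len$cap_top_circumference,
                             len$cap_small_circumference,
                             rpv$leg_fragment_height_m),
    stringsAsFactors = FALSE)
  parts$cut_minutes <- vapply(parts$cut_length_mm, cutting_time, numeric(1), tech)
  structure(list(
    parts = parts,
    radial_cut_length_mm = 1000 * len$radial_cut_length,
    radial_cut_minutes = cutting_time(1000 * len$radial_cut_length, tech),
    fragment_height_m = frag_height, nominal_fragment_height_m = nominal_h,
    total_pieces = sum(parts$fragments * parts$segments_per_fragment),
    packing = list(nominal_fragment_height_frac_of_drum = 0.85,
                   clearance_m = 0.025,
                   rule = "diag(chord, thickness + sagitta) <= drum diameter - clearance"),
    tech = if (inherits(tech, "cutting_tech")) tech$name else "custom"),
    class = "cut_plan")
}

#' @export
print.cut_plan <- function(x, ...) {
  cat(sprintf("<cut_plan> %d pieces total; fragment height %.3f m; radial cut %d min\n",
              x$total_pieces, x$fragment_height_m, x$radial_cut_minutes))
  print(x$parts, row.names = FALSE)
  invisible(x)
}

#' Compare cutting technologies on a cut plan
#'
#' Recomputes every cut time per technology and, when work plans are given,
#' rescales task durations by the speed ratio (doses scale linearly with
#' duration at fixed dose rate).
#'
#' @param plan a [decompose_rpv()] cut plan.
#' @param techs list of at least two [cutting_tech()] objects.
#' @param work_plans optional named list of [work_plan()] objects whose
#'   cutter durations scale with cutting speed; RPO durations scale with the
#'   total plan duration.
#' @return data.frame, one row per technology: total cutting minutes per
#'   part and overall, plus (if work plans given) collective dose man-mSv.
#' @export
compare_technologies <- function(plan, techs, work_plans = NULL) {
  stopifnot(inherits(plan, "cut_plan"))
  if (length(techs) < 2) stop("need at least two technologies to compare")
  base_speed <- 15
  rows <- lapply(techs, function(tch) {
    per_cut <- vapply(plan$parts$cut_length_mm, cutting_time, numeric(1), tch)
    tot <- sum(plan$parts$fragments * plan$parts$segments_per_fragment * per_cut)
    row <- data.frame(technology = tch$name, speed_mm_min = tch$speed_mm_min,
                      total_cut_minutes = tot,
                      radial_cut_minutes = cutting_time(plan$radial_cut_length_mm, tch),
                      stringsAsFactors = FALSE)
    if (!is.null(work_plans)) {
      scale <- base_speed / tch$speed_mm_min
      cd <- sum(vapply(work_plans, function(p) {
        scaled <- work_plan(lapply(p$tasks, function(t)
          task(t$label, t$role, t$duration_min * scale, t$dose_rate_msv_h)),
          repetitions = p$repetitions,
          uncertainty_fraction = p$uncertainty_fraction, label = p$label)
        collective(scaled)$collective_dose_man_msv
      }, numeric(1)))
      ct <- sum(vapply(work_plans, function(p)
        collective(p)$collective_time_man_h, numeric(1))) * scale
      row$collective_time_man_h <- ct
      row$collective_dose_man_msv <- cd
    }
    row
  })
  do.call(rbind, rows)
}

#' Export a cut plan as CSV
#' @param plan a [decompose_rpv()] result.
#' @param path output file.
#' @export
write_cut_plan_csv <- function(plan, path) {
  utils::write.csv(plan$parts, path, row.names = FALSE)
  invisible(path)
}
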