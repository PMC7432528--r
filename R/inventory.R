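# Radionuclide inventories, decay correction and regrouping of photon
# emission lines to the 25-energy-group source format.

#' Bundled nuclide decay data
#'
#' Half-lives and photon emission lines for the eight nuclides of the bundled
#' source-term fixture. Line energies (MeV) and yields (photons per decay)
#' come from standard decay-data compilations; pure beta/X-ray emitters
#' (Fe-55, Tc-99) carry no gamma lines. The bundled half-life of Tc-99 is the
#' published study value (6 hours), which is physically wrong for the ground
#' state; set `use_corrected_half_lives = TRUE` for the 2.111e5-year value.
#'
#' @param use_corrected_half_lives replace published half-lives known to be
#'   erroneous with the physical values.
#' @return list with `nuclides` (data.frame: nuclide, half_life_years) and
#'   `lines` (data.frame: nuclide, energy_mev, yield).
#' @export
nuclide_library <- function(use_corrected_half_lives = FALSE) {
  nuc <- utils::read.csv(pkg_extdata("nuclides.csv"), stringsAsFactors = FALSE)
  lines <- utils::read.csv(pkg_extdata("decay_lines.csv"),
                           stringsAsFactors = FALSE)
  hl <- if (use_corrected_half_lives) nuc$corrected_half_life_years else
    nuc$half_life_years
  structure(
    list(nuclides = data.frame(nuclide = nuc$nuclide, half_life_years = hl,
                               stringsAsFactors = FALSE),
         lines = lines[, c("nuclide", "energy_mev", "yield")]),
    class = "nuclide_library")
}

#' Radionuclide inventory of a component part
#'
#' @param part_name identifier of the component part (e.g. "active").
#' @param nuclides character vector of nuclide names, unique.
#' @param activities_bq activities in Bq, same length, all >= 0.
#' @param reference_date optional `Date`.
#' @return an object of class `inventory`.
#' @examples
#' inv <- inventory("active", c("Co-60", "Fe-55"), c(2.23e12, 6.96e14))
#' total_activity(inv)
#' @export
inventory <- function(part_name, nuclides = character(), activities_bq = numeric(),
                      reference_date = NULL) {
  stopifnot(is.character(part_name), length(part_name) == 1L)
  if (length(nuclides) != length(activities_bq))
    stop("nuclides and activities_bq must have equal length")
  if (anyDuplicated(nuclides))
    stop("duplicate nuclide in inventory: ",
         paste(unique(nuclides[duplicated(nuclides)]), collapse = ", "))
  if (any(activities_bq < 0)) stop("activities must be >= 0")
  structure(list(part_name = part_name,
                 entries = data.frame(nuclide = as.character(nuclides),
                                      activity_bq = as.numeric(activities_bq),
                                      stringsAsFactors = FALSE),
                 reference_date = reference_date),
            class = "inventory")
}

#' @export
print.inventory <- function(x, ...) {
  cat(sprintf("<inventory> part '%s': %d nuclides, total %.3e Bq\n",
              x$part_name, nrow(x$entries), total_activity(x)))
  print(x$entries)
  invisible(x)
}

#' Decay-correct an inventory
#'
#' Multiplies every activity by `2^(-elapsed_years / half_life)`. No
#' ingrowth: parent/daughter coupling is out of scope.
#'
#' @param inv an [inventory()].
#' @param elapsed_years elapsed time in years, >= 0.
#' @param library a [nuclide_library()] supplying half-lives.
#' @return the decayed inventory (same part name and nuclide order).
#' @export
decay_correct <- function(inv, elapsed_years, library = nuclide_library()) {
  stopifnot(inherits(inv, "inventory"))
  stopifnot_scalar_num(elapsed_years, "elapsed_years")
  if (elapsed_years < 0) stop("elapsed_years must be >= 0")
  idx <- match(inv$entries$nuclide, library$nuclides$nuclide)
  if (anyNA(idx))
    stop("no half-life for nuclide(s): ",
         paste(inv$entries$nuclide[is.na(idx)], collapse = ", "))
  hl <- library$nuclides$half_life_years[idx]
  if (any(hl <= 0)) stop("half-lives must be > 0")
  out <- inv
  out$entries$activity_bq <- inv$entries$activity_bq * 2^(-elapsed_years / hl)
  out
}

#' Total activity of an inventory
#'
#' Arithmetic sum of the entry activities in Bq. Where a published total
#' disagrees with its own column sum, the computed sum is reported.
#'
#' @param inv an [inventory()].
#' @return total activity in Bq.
#' @export
total_activity <- function(inv) {
  stopifnot(inherits(inv, "inventory"))
  sum(inv$entries$activity_bq)
}

#' Energy-group structure
#'
#' The source spectrum is collapsed to a fixed number of energy bins
#' (25 by default, log-spaced over 0.01-3 MeV; the count is fixed by the
#' engine formulation, the boundaries are a configurable choice).
#'
#' @param n_bins number of bins (default 25).
#' @param e_min,e_max range in MeV.
#' @param boundaries optional explicit ascending boundary vector
#'   (length `n_bins + 1`), overriding the log-spaced default.
#' @return object of class `energy_groups` with `boundaries` (MeV) and
#'   `representative` (geometric mean of each bin's edges).
#' @export
energy_groups <- function(n_bins = 25, e_min = 0.01, e_max = 3.0,
                          boundaries = NULL) {
  if (is.null(boundaries))
    boundaries <- exp(seq(log(e_min), log(e_max), length.out = n_bins + 1))
  boundaries <- as.numeric(boundaries)
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly ascending")
  if (any(boundaries <= 0)) stop("boundaries must be positive")
  n <- length(boundaries) - 1L
  structure(list(boundaries = boundaries,
                 representative = sqrt(boundaries[-1] * boundaries[-(n + 1)]),
                 n_bins = n),
            class = "energy_groups")
}

#' Collapse an inventory to a grouped photon source
#'
#' Sums `activity x yield` over every photon line of every nuclide into the
#' energy bins, yielding the total activity `S_tot` and per-group emission
#' fractions `F_Eb` (photons per decay of the whole inventory per group).
#' Lines outside the group structure's range are dropped with a warning and
#' counted in the result. A per-nuclide fraction matrix is retained so the
#' dose engine can attribute dose to nuclides.
#'
#' @param inv an [inventory()].
#' @param groups an [energy_groups()].
#' @param library a [nuclide_library()].
#' @return object of class `grouped_spectrum`: `total_activity` (Bq),
#'   `fractions` (length-n, photons per decay per group), `per_nuclide`
#'   (matrix nuclide x group), `group_structure`, `n_dropped_lines`,
#'   `dropped_rate` (photons/s outside the structure).
#' @export
build_spectrum <- function(inv, groups = energy_groups(),
                           library = nuclide_library()) {
  stopifnot(inherits(inv, "inventory"), inherits(groups, "energy_groups"))
  known <- library$nuclides$nuclide
  missing <- setdiff(inv$entries$nuclide, known)
  if (length(missing))
    stop("unknown nuclide(s) without photon-line data: ",
         paste(missing, collapse = ", "))
  s_tot <- total_activity(inv)
  nb <- groups$n_bins
  per <- matrix(0, nrow = nrow(inv$entries), ncol = nb,
                dimnames = list(inv$entries$nuclide, NULL))
  n_dropped <- 0L
  dropped_rate <- 0
  lo <- groups$boundaries[1]; hi <- groups$boundaries[nb + 1]
  for (i in seq_len(nrow(inv$entries))) {
    nl <- library$lines[library$lines$nuclide == inv$entries$nuclide[i], ]
    if (!nrow(nl)) next
    act <- inv$entries$activity_bq[i]
    out_of_range <- nl$energy_mev < lo | nl$energy_mev > hi
    if (any(out_of_range)) {
      n_dropped <- n_dropped + sum(out_of_range)
      dropped_rate <- dropped_rate + sum(act * nl$yield[out_of_range])
    }
    nl <- nl[!out_of_range, , drop = FALSE]
    if (!nrow(nl)) next
    # right-closed bins; the lowest boundary is included in bin 1
    bin <- findInterval(nl$energy_mev, groups$boundaries,
                        rightmost.closed = TRUE)
    bin[bin < 1L] <- 1L; bin[bin > nb] <- nb
    for (j in seq_len(nrow(nl)))
      per[i, bin[j]] <- per[i, bin[j]] + act * nl$yield[j]
  }
  if (n_dropped > 0L)
    warning(sprintf("%d photon line(s) outside the group structure dropped (%.4g photons/s)",
                    n_dropped, dropped_rate))
  fractions <- if (s_tot > 0) colSums(per) / s_tot else rep(0, nb)
  per_frac <- if (s_tot > 0) per / s_tot else per
  structure(list(total_activity = s_tot, fractions = fractions,
                 per_nuclide = per_frac, group_structure = groups,
                 n_dropped_lines = n_dropped, dropped_rate = dropped_rate),
            class = "grouped_spectrum")
}

#' @export
print.grouped_spectrum <- function(x, ...) {
  cat(sprintf("<grouped_spectrum> S_tot = %.4e Bq, %d groups, %.4f photons/decay\n",
              x$total_activity, x$group_structure$n_bins, sum(x$fractions)))
  invisible(x)
}

#' Read / write inventories
#'
#' CSV files carry columns `part,nuclide,activity_bq`; JSON carries the same
#' structure. Multi-part CSV files yield a named list of inventories.
#'
#' @param path file path.
#' @return `read_inventory_csv`: named list of [inventory()] objects.
#' @export
read_inventory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("part", "nuclide", "activity_bq") %in% names(df)))
  parts <- unique(df$part)
  out <- lapply(parts, function(p) {
    sub <- df[df$part == p, ]
    inventory(p, sub$nuclide, sub$activity_bq)
  })
  names(out) <- parts
  out
}

#' @rdname read_inventory_csv
#' @param inventories named list of [inventory()] objects (or one inventory).
#' @export
write_inventory_csv <- function(inventories, path) {
  if (inherits(inventories, "inventory")) inventories <- list(inventories)
  rows <- do.call(rbind, lapply(inventories, function(iv)
    data.frame(part = iv$part_name, nuclide = iv$entries$nuclide,
               activity_bq = iv$entries$activity_bq,
               stringsAsFactors = FALSE)))
  # %.17g round-trips doubles bit-exactly through read.csv
  rows$activity_bq <- sprintf("%.17g", rows$activity_bq)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
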