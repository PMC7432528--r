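# Shared test helpers: tiny spectra, a marching transport oracle, and the
# published task tables used as cross-check fixtures.

# One-nuclide, one-line library and spectrum in a single energy bin.
toy_groups <- function() energy_groups(n_bins = 1, e_min = 1.2, e_max = 1.3)

toy_library <- function(energy = 1.25, yield = 1) {
  structure(list(
    nuclides = data.frame(nuclide = "toy", half_life_years = 5,
                          stringsAsFactors = FALSE),
    lines = data.frame(nuclide = "toy", energy_mev = energy, yield = yield,
                       stringsAsFactors = FALSE)),
    class = "nuclide_library")
}

toy_spectrum <- function(activity = 1e6, energy = 1.25, yield = 1)
  build_spectrum(inventory("toy", "toy", activity), toy_groups(),
                 toy_library(energy, yield))

# Brute-force fine-step ray marching: independent oracle for trace_ray().
# Returns per-material lengths (cm) from midpoint material sampling.
march_lengths <- function(scene, from, to, step_cm = 0.01) {
  d_cm <- sqrt(sum((to - from)^2)) * 100
  n <- max(2, ceiling(d_cm / step_cm))
  tmid <- (seq_len(n) - 0.5) / n
  P <- matrix(from, n, 3, byrow = TRUE) + outer(tmid, to - from)
  mats <- material_names_at(scene, P)
  tapply(rep(d_cm / n, n), mats, sum)
}

# Published per-task tables: durations (min), dose rates (mSv/h) and the
# printed task doses (mSv) used for the rounding cross-check.
printed_task_doses <- function() {
  list(
    upper_fragmentation = c(2.90e1, 2.30e-3, 1.60e1, 2.00e1, 2.10e-3, 3.40e1, 1.40e-2),
    active_fragmentation = c(1.60e3, 8.80e1, 6.50e1, 8.70e2, 4.10e1, 1.80e2, 4.10e-1),
    lower_fragmentation = c(2.70e1, 3.30e-2, 1.80e1, 2.80e1, 1.90e-2, 4.10e1, 2.10e-1),
    upper_segmentation = c(1.40e1, 2.10e1, 3.90e1, 2.80e1, 1.30e1, 1.10e1, 3.30e1),
    active_segmentation = c(1.60e2, 1.20e2, 9.90e1, 1.30e2, 1.80e2, 1.40e2, 2.10e2),
    lower_segmentation = c(1.30e1, 3.40e1, 1.50e1, 6.90e0, 6.20e0, 6.80e0, 1.30e1))
}
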