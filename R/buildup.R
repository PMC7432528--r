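# Geometric-progression (GP) build-up factors.
#
# B(material, E, x) multiplies the uncollided kernel to account for photons
# scattered back into the beam; B >= 1 and B(.,.,0) = 1 by construction of
# the GP form:
#   K(x) = c x^a + d [tanh(x/Xk - 2) - tanh(-2)] / [1 - tanh(-2)]
#   B(x) = 1 + (b-1)(K^x - 1)/(K - 1)     (K != 1; else 1 + (b-1) x)
# Coefficients are bundled per material at a coarse energy grid and
# interpolated linearly in log(E), clamped at the grid ends.

#' Build-up factor model
#'
#' @param table data.frame with columns `material, energy_mev, b, c, a, xk, d`;
#'   default is the bundled approximate GP coefficient set for air, water,
#'   carbon/stainless steel, concrete and lead.
#' @return object of class `buildup_model`.
#' @export
buildup_model <- function(table = NULL) {
  if (is.null(table))
    table <- utils::read.csv(pkg_extdata("buildup_gp.csv"),
                             stringsAsFactors = FALSE)
  stopifnot(all(c("material", "energy_mev", "b", "c", "a", "xk", "d") %in%
                  names(table)))
  if (any(table$b < 1))
    stop("GP coefficient b must be >= 1 so that B >= 1 everywhere")
  structure(list(table = table, enabled = TRUE), class = "buildup_model")
}

#' Disabled build-up (B = 1 everywhere)
#' @export
buildup_none <- function() {
  structure(list(table = NULL, enabled = FALSE), class = "buildup_model")
}

gp_eval <- function(b, cc, a, xk, d, x) {
  # GP fits are valid to ~40 mfp; clamp there (the attenuated kernel at
  # x > 40 is < e^-40, so the clamped tail is numerically irrelevant, and
  # clamping avoids K^x overflow meeting e^-x underflow as NaN).
  xe <- pmin(x, 40)
  K <- cc * xe^a +
    d * (tanh(xe / xk - 2) - tanh(-2)) / (1 - tanh(-2))
  K <- pmax(K, 1e-6)
  B <- ifelse(abs(K - 1) > 1e-9,
              1 + (b - 1) * (K^xe - 1) / (K - 1),
              1 + (b - 1) * xe)
  B[x <= 0] <- 1
  pmax(B, 1)
}

#' Evaluate the build-up factor
#'
#' @param model a [buildup_model()].
#' @param material_name material; materials absent from the coefficient table
#'   (e.g. custom toy materials) fall back to B = 1.
#' @param energy_mev photon energy (scalar), MeV.
#' @param mfp optical depth in mean free paths (vectorized), >= 0.
#' @return build-up factors, >= 1, equal to 1 at `mfp = 0`.
#' @export
buildup_factor <- function(model, material_name, energy_mev, mfp) {
  stopifnot(inherits(model, "buildup_model"))
  if (!model$enabled) return(rep(1, length(mfp)))
  tab <- model$table[model$table$material == material_name, ]
  if (!nrow(tab)) return(rep(1, length(mfp)))
  tab <- tab[order(tab$energy_mev), ]
  co <- vapply(c("b", "c", "a", "xk", "d"), function(col)
    loglin_interp_clamped(tab$energy_mev, tab[[col]], energy_mev), numeric(1))
  gp_eval(co["b"], co["c"], co["a"], co["xk"], co["d"], mfp)
}
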