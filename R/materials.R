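# Materials: densities and mass attenuation coefficient tables.

#' Construct a material
#'
#' @param name identifier.
#' @param density_g_cm3 bulk density in g/cm^3, > 0.
#' @param mu_table data.frame with ascending `energy_mev` and positive
#'   `mu_over_rho_cm2_g` (mass attenuation coefficient). Interpolation is
#'   log-log and restricted to the table range.
#' @return object of class `material`.
#' @export
material <- function(name, density_g_cm3, mu_table) {
  stopifnot_scalar_num(density_g_cm3, "density_g_cm3", positive = TRUE)
  stopifnot(is.data.frame(mu_table),
            all(c("energy_mev", "mu_over_rho_cm2_g") %in% names(mu_table)))
  mu_table <- mu_table[order(mu_table$energy_mev), ]
  if (any(diff(mu_table$energy_mev) <= 0))
    stop("mu_table energies must be strictly ascending")
  if (any(mu_table$mu_over_rho_cm2_g <= 0))
    stop("mass attenuation coefficients must be > 0")
  structure(list(name = name, density = density_g_cm3, mu_table = mu_table),
            class = "material")
}

#' Bundled material library
#'
#' Densities and mass attenuation curves for air, water, carbon steel,
#' stainless steel (both on the iron curve), ordinary concrete, lead, and a
#' numerical vacuum. Values are bundled approximations of the standard
#' photon cross-section compilations over 0.01-3 MeV (lead from 0.1 MeV,
#' above its K edge).
#'
#' @return named list of [material()] objects.
#' @export
material_library <- function() {
  dens <- utils::read.csv(pkg_extdata("materials.csv"), stringsAsFactors = FALSE)
  mu <- utils::read.csv(pkg_extdata("mu_rho.csv"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(dens)), function(i) {
    m <- dens$material[i]
    material(m, dens$density_g_cm3[i],
             mu[mu$material == m, c("energy_mev", "mu_over_rho_cm2_g")])
  })
  names(out) <- dens$material
  out
}

#' Mass attenuation coefficient at an energy
#'
#' Log-log interpolation inside the material's table range; energies outside
#' the range raise an error naming the material.
#'
#' @param mat a [material()].
#' @param energy_mev photon energy (vectorized), MeV.
#' @return mu/rho in cm^2/g.
#' @export
mu_over_rho <- function(mat, energy_mev) {
  stopifnot(inherits(mat, "material"))
  loglog_interp(mat$mu_table$energy_mev, mat$mu_table$mu_over_rho_cm2_g,
                energy_mev, what = paste0("'", mat$name, "' attenuation table"))
}

#' Linear attenuation coefficient (1/cm)
#' @inheritParams mu_over_rho
#' @export
mu_linear <- function(mat, energy_mev) mu_over_rho(mat, energy_mev) * mat$density
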