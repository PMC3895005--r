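# Single source of physical constants for the whole package. Every estimator
# obtains kB, the elementary charge and all unit conversions from here.

#' Physical constants and unit conversions
#'
#' Returns the package's unit system: energies in kcal/mol, lengths in
#' Angstrom, times in nanoseconds, temperatures in Kelvin, charge in
#' elementary charges. Conductance is computed in SI and reported in pS.
#'
#' @return A list with components:
#'   \describe{
#'     \item{kB}{Boltzmann constant, kcal/mol/K (0.0019872041).}
#'     \item{e_charge}{Elementary charge, coulomb.}
#'     \item{avogadro}{Avogadro's number, 1/mol.}
#'     \item{kcal_to_J}{Joule per thermochemical kilocalorie (4184).}
#'     \item{kcalmol_to_J_per_particle}{kcal/mol to joule per particle.}
#'     \item{angstrom_to_m}{Angstrom to metre.}
#'     \item{ns_to_s}{Nanosecond to second.}
#'   }
#' @examples
#' us <- unit_system()
#' us$kB * 310  # thermal energy at 310 K, kcal/mol
#' @export
unit_system <- function() {
  avogadro <- 6.02214076e23
  kcal_to_J <- 4184
  list(
    kB = 0.0019872041,
    e_charge = 1.602176634e-19,
    avogadro = avogadro,
    kcal_to_J = kcal_to_J,
    kcalmol_to_J_per_particle = kcal_to_J / avogadro,
    angstrom_to_m = 1e-10,
    ns_to_s = 1e-9
  )
}

#' Thermal energy kB*T
#'
#' @param temperature Temperature in Kelvin; must be positive.
#' @return Thermal energy in kcal/mol.
#' @examples
#' kbt(310)  # ~0.616 kcal/mol
#' @export
kbt <- function(temperature) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0)) {
    stop("`temperature` must be a positive, finite number (Kelvin)")
  }
  unit_system()$kB * temperature
}

#' Express a harmonic stiffness in kBT per square Angstrom
#'
#' @param k Stiffness in kcal/mol/A^2; must be non-negative.
#' @param temperature Temperature in Kelvin.
#' @return Stiffness in kBT/A^2 at the given temperature.
#' @examples
#' stiffness_in_kbt(0.6, 310)  # ~1.0
#' @export
stiffness_in_kbt <- function(k, temperature) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0)) {
    stop("`k` must be a non-negative, finite stiffness (kcal/mol/A^2)")
  }
  k / kbt(temperature)
}

#' Convert kcal/mol to joule per particle
#' @param x Energy in kcal/mol.
#' @return Energy in joule per particle.
#' @export
kcalmol_to_J <- function(x) x * unit_system()$kcalmol_to_J_per_particle

#' Convert joule per particle to kcal/mol
#' @param x Energy in joule per particle.
#' @return Energy in kcal/mol.
#' @export
J_to_kcalmol <- function(x) x / unit_system()$kcalmol_to_J_per_particle
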