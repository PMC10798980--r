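#' Physical constants and reduced units
#'
#' The engine works in reduced units: length in angstrom (Å), energy in
#' kcal/mol, mass in dalton (Da).  The derived time unit is
#' \eqn{\sqrt{\mathrm{Da}\,\mathrm{\AA}^2 / (\mathrm{kcal/mol})} \approx 48.89}
#' fs, so 1 ns corresponds to about 20455 reduced time units.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal/(mol K).}
#'   \item{time_unit_fs}{One reduced time unit in femtoseconds.}
#'   \item{pN_A_to_kcal_mol}{Energy of 1 pN acting over 1 Å, in kcal/mol.}
#'   \item{water_mass}{Average mass of one water molecule, Da.}
#' }
#' @export
dmd_constants <- local({
  avogadro <- 6.02214076e23
  dalton_kg <- 1.66053907e-27
  kcal_mol_J <- 4184 / avogadro
  list(
    kB = 0.0019872041,
    time_unit_fs = sqrt(dalton_kg * 1e-20 / kcal_mol_J) * 1e15,
    pN_A_to_kcal_mol = 1e-22 * avogadro / 4184,
    water_mass = 18.0153
  )
})

#' Convert nanoseconds to reduced time units (and back)
#'
#' @param ns Duration in nanoseconds.
#' @return Duration in reduced time units.
#' @export
ns_to_reduced <- function(ns) ns * 1e6 / dmd_constants$time_unit_fs

#' @rdname ns_to_reduced
#' @param t Duration in reduced time units.
#' @export
reduced_to_ns <- function(t) t * dmd_constants$time_unit_fs / 1e6

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in kelvin.
#' @return kB * T in kcal/mol.
#' @export
thermal_energy <- function(temperature = 300) dmd_constants$kB * temperature

#' Express a contact energy in units of kT
#'
#' The canonical Gō contact well of 0.4 kcal/mol corresponds to about
#' 0.67 kT at 300 K.
#'
#' @param energy Energy in kcal/mol.
#' @param temperature Temperature in kelvin.
#' @return Dimensionless energy / (kB T).
#' @export
energy_in_kT <- function(energy, temperature = 300) {
  energy / thermal_energy(temperature)
}
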