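# Unit system at every interface: energy eV, length angstrom, time fs,
# mass amu.  Dynamics needs energy in the mechanical unit amu*A^2/fs^2;
# conversion happens once, here.

# 1 eV in amu * A^2 / fs^2
.EV_MECH <- 0.009648533212331

# Boltzmann constant, eV / K
.KB_EV <- 8.617333262e-5

# Reduced Planck constant, eV * fs
.HBAR_EVFS <- 0.6582119569

#' Physical constants used at the package interfaces
#'
#' Returns the constants the package uses to convert between its interface
#' units (eV, angstrom, fs, amu) and the internal mechanical energy unit.
#'
#' @return A named list: `ev_mech` (1 eV in amu A^2/fs^2), `kb_ev`
#'   (Boltzmann constant in eV/K), `hbar_evfs` (hbar in eV fs).
#' @export
#' @examples
#' surfhop_constants()$kb_ev * 298  # thermal energy at 298 K in eV
surfhop_constants <- function() {
  list(ev_mech = .EV_MECH, kb_ev = .KB_EV, hbar_evfs = .HBAR_EVFS)
}

# kinetic energy in eV of a velocity vector (A/fs) with per-DOF masses (amu)
.kinetic_energy_ev <- function(v, masses) {
  sum(0.5 * masses * v^2) / .EV_MECH
}

# Maxwell-Boltzmann velocity draw (A/fs) for per-DOF masses at temperature K.
# Uses the current RNG stream.
.mb_velocities <- function(masses, temperature) {
  sd <- sqrt(.KB_EV * temperature * .EV_MECH / masses)
  stats::rnorm(length(masses), mean = 0, sd = sd)
}
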