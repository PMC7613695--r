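# Internal unit system: energies in eV, lengths in Angstrom, time in fs,
# masses in amu.  Angles (the C-S tilt) are carried in degrees with an
# effective mass chosen so that 1/2 * m * qdot^2, converted with
# .ev_per_amuA2fs2, is an energy in eV.

#' Physical constants used throughout the package
#'
#' A named list of the conversion constants the package uses internally:
#' `ev_nm` (h*c, 1239.841984 eV nm), `hartree_ev` (27.211386), `hbar_ev_fs`
#' (0.6582119569 eV fs), `ev_per_amuA2fs2` (1 amu A^2/fs^2 in eV),
#' `cm1_ev` (1 cm^-1 in eV).
#'
#' @return Named list of numeric constants.
#' @export
surfhop_constants <- function() {
  list(
    ev_nm          = 1239.841984,
    hartree_ev     = 27.211386,
    hbar_ev_fs     = 0.6582119569,
    ev_per_amuA2fs2 = 103.642697,
    cm1_ev         = 1.239841984e-4
  )
}

.EV_NM      <- 1239.841984
.HARTREE_EV <- 27.211386
.HBAR       <- 0.6582119569     # eV fs
.EV_AMU     <- 103.642697       # eV per amu A^2 fs^-2
.CM1_EV     <- 1.239841984e-4   # eV per cm^-1
.C_CM_FS    <- 2.99792458e-5    # speed of light, cm/fs
# hbar in mechanical units (amu A^2 / fs), used for Wigner widths
.HBAR_MW    <- .HBAR / .EV_AMU

#' Convert between photon energy (eV) and wavelength (nm)
#'
#' Uses lambda * E = 1239.841984 eV nm.  The conversion is involutive:
#' applying it twice returns the input.
#'
#' @param value Positive numeric vector, energies in eV or wavelengths in nm.
#' @return The converted values (nm if input was eV and vice versa).
#' @examples
#' ev_nm_convert(4.23)              # ~293.1 nm
#' ev_nm_convert(ev_nm_convert(5))  # 5
#' @export
ev_nm_convert <- function(value) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0))
    stop("ev_nm_convert() requires finite positive numeric input")
  .EV_NM / value
}

# angular frequency (fs^-1) from a wavenumber (cm^-1)
.omega_from_cm1 <- function(nu_cm1) 2 * pi * .C_CM_FS * nu_cm1

# wavenumber (cm^-1) from an angular frequency (fs^-1)
.cm1_from_omega <- function(omega) omega / (2 * pi * .C_CM_FS)

# kinetic energy in eV from momenta (amu A/fs equivalents) and masses (amu)
.kinetic_energy <- function(p, masses) {
  0.5 * sum(p^2 / masses) * .EV_AMU
}
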