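#' Nuclear-ensemble absorption spectrum
#'
#' Sums normalized Gaussian lines, one per (sample, excited state) pair,
#' weighted by oscillator strength:
#' `I(E) = (1/N) sum_samples sum_states f_osc * G(E - E_exc; fwhm)`.
#' The integrated intensity therefore equals the ensemble-mean total
#' oscillator strength.  Intensities are in arbitrary units (no
#' cross-section prefactor); only the band position and the
#' excitation-window overlap are consumed downstream.
#'
#' @param samples A [sample_wigner()] ensemble (or any object with a
#'   `positions` matrix).
#' @param model A [surface_model()].
#' @param states Singlet excited-state indices within the singlet manifold
#'   (1-based above the ground state); default all.  Including the ground
#'   state (0) is an error: there is no S0 -> S0 absorption.
#' @param broadening_fwhm Gaussian full width at half maximum in eV
#'   (default 0.1).
#' @param grid Energy grid in eV (strictly increasing).
#' @param window Optional `c(E_min, E_max)` reported as overlap metadata.
#' @return A `spectrum_grid`: data.frame with `energy_eV` and `intensity`,
#'   with attributes `n_samples`, `fwhm`, `peak_eV` and
#'   `window_fraction` (fraction of integrated intensity inside `window`).
#' @export
ensemble_spectrum <- function(samples, model, states = NULL,
                              broadening_fwhm = 0.1,
                              grid = seq(3.0, 7.0, by = 0.005),
                              window = NULL) {
  pos <- samples$positions
  if (is.null(pos) || nrow(pos) < 1) stop("need at least one sample")
  if (broadening_fwhm <= 0) stop("broadening_fwhm must be > 0")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (!is.null(states) && any(states < 1))
    stop("state list must not include the ground state (no S0 -> S0 absorption)")
  sigma <- broadening_fwhm / (2 * sqrt(2 * log(2)))
  intensity <- numeric(length(grid))
  n <- nrow(pos)
  for (i in seq_len(n)) {
    ad <- adiabatize(model, pos[i, ])
    sing <- which(ad$manifold == "singlet")
    gs <- sing[1]
    exc <- sing[-1]
    if (!is.null(states)) exc <- exc[seq_along(exc) %in% states]
    for (a in exc) {
      de <- ad$energies[a] - ad$energies[gs]
      f <- ad$fosc[a]
      if (f > 0)
        intensity <- intensity + f * stats::dnorm(grid, de, sigma)
    }
  }
  intensity <- intensity / n
  out <- data.frame(energy_eV = grid, intensity = intensity)
  attr(out, "n_samples") <- n
  attr(out, "fwhm") <- broadening_fwhm
  attr(out, "peak_eV") <- grid[which.max(intensity)]
  if (!is.null(window)) {
    inw <- grid >= window[1] & grid <= window[2]
    tot <- sum(intensity)
    attr(out, "window_fraction") <- if (tot > 0) sum(intensity[inw]) / tot else 0
  }
  class(out) <- c("spectrum_grid", "data.frame")
  out
}

#' Write a spectrum as CSV with a metadata header
#'
#' @param spectrum An [ensemble_spectrum()] result.
#' @param path Output file.
#' @param wavelength Add a `wavelength_nm` column?
#' @return The path, invisibly.
#' @export
write_spectrum <- function(spectrum, path, wavelength = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# surfhop spectrum v1",
    paste0("# n_samples: ", attr(spectrum, "n_samples")),
    paste0("# broadening_fwhm_eV: ", attr(spectrum, "fwhm")),
    paste0("# peak_eV: ", attr(spectrum, "peak_eV"))), con)
  df <- as.data.frame(spectrum)
  if (wavelength) df$wavelength_nm <- ev_nm_convert(df$energy_eV)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
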