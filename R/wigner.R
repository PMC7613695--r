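#' Harmonic normal modes of a surface model minimum
#'
#' Builds the mass-weighted Hessian of one adiabatic surface by central
#' finite differences of the analytic gradient and diagonalizes it.
#'
#' @param model A [surface_model()].
#' @param geometry Expansion point (default: the model reference, the S0
#'   minimum of the shipped surrogate).
#' @param state Spin-pure state label (default `"S0"`).
#' @param step Finite-difference step for the Hessian.
#' @return A `normal_mode_set`: list with `reference`, `masses`,
#'   `freq_cm1` (harmonic wavenumbers; negative entries mark imaginary
#'   modes), `modes` (columns are mass-weighted orthonormal displacement
#'   vectors) and `state`.
#' @export
normal_modes <- function(model, geometry = model$reference, state = "S0",
                         step = 1e-3) {
  q <- .coerce_coords(model, geometry)
  nc <- length(q)
  H <- matrix(0, nc, nc)
  for (i in seq_len(nc)) {
    qp <- q; qp[i] <- qp[i] + step
    qm <- q; qm[i] <- qm[i] - step
    H[, i] <- (.state_energy(model, qp, state)$g -
               .state_energy(model, qm, state)$g) / (2 * step)
  }
  H <- (H + t(H)) / 2
  m <- model$masses
  Hmw <- H / sqrt(outer(m, m))
  eig <- eigen(Hmw, symmetric = TRUE)
  idx <- order(eig$values)
  lam <- eig$values[idx]                       # eV / (amu u^2)
  omega2 <- lam / .EV_AMU                      # fs^-2
  freq <- sign(omega2) * .cm1_from_omega(sqrt(abs(omega2)))
  structure(list(
    reference = stats::setNames(q, model$coords),
    masses = m,
    freq_cm1 = freq,
    modes = eig$vectors[, idx, drop = FALSE],
    state = state
  ), class = "normal_mode_set")
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat("normal_mode_set:", length(x$freq_cm1), "modes at",
    paste(round(x$freq_cm1, 1), collapse = ", "), "cm^-1\n")
  invisible(x)
}

.check_modes <- function(modes) {
  if (!inherits(modes, "normal_mode_set"))
    stop("expected a normal_mode_set")
  bad <- which(modes$freq_cm1 <= 0)
  if (length(bad))
    stop("cannot Wigner-sample imaginary/zero-frequency mode(s): ",
         paste(bad, collapse = ", "), " (",
         paste(round(modes$freq_cm1[bad], 1), collapse = ", "), " cm^-1)")
  invisible(TRUE)
}

#' Sample geometries and momenta from the ground-state Wigner distribution
#'
#' For each harmonic mode the ground-vibrational-state Wigner density is a
#' product of Gaussians in the dimensionless position and momentum, each
#' with variance 1/2.  Draws are transformed to internal coordinates
#' (displacements about the reference) and conjugate momenta.  Sampling is
#' at 0 K (ground vibrational state only) and deterministic given the
#' seed.
#'
#' @param modes A [normal_modes()] result; all frequencies must be
#'   positive.
#' @param n_samples Number of phase-space samples (default 500, the
#'   standard ensemble size for spectrum simulation).
#' @param seed Integer RNG seed.
#' @return A `wigner_ensemble`: list with `positions` and `momenta`
#'   (`n_samples x ncoord` matrices; momenta in amu * coordinate-unit /
#'   fs), the dimensionless draws `Q` and `P`, `modes` and `seed`.
#' @export
sample_wigner <- function(modes, n_samples = 500, seed = 1) {
  .check_modes(modes)
  if (n_samples < 1) stop("n_samples must be >= 1")
  nm <- length(modes$freq_cm1)
  set.seed(seed)
  Q <- matrix(stats::rnorm(n_samples * nm, sd = sqrt(0.5)), n_samples, nm)
  P <- matrix(stats::rnorm(n_samples * nm, sd = sqrt(0.5)), n_samples, nm)
  omega <- .omega_from_cm1(modes$freq_cm1)     # fs^-1
  xm <- sweep(Q, 2, sqrt(.HBAR_MW / omega), "*")   # mass-weighted displ.
  pm <- sweep(P, 2, sqrt(.HBAR_MW * omega), "*")   # mass-weighted momenta
  L <- modes$modes
  sm <- sqrt(modes$masses)
  pos <- sweep(xm %*% t(L), 2, sm, "/")
  mom <- sweep(pm %*% t(L), 2, sm, "*")
  pos <- sweep(pos, 2, modes$reference, "+")
  colnames(pos) <- colnames(mom) <- names(modes$reference)
  structure(list(positions = pos, momenta = mom, Q = Q, P = P,
                 modes = modes, seed = seed),
            class = "wigner_ensemble")
}

#' @export
print.wigner_ensemble <- function(x, ...) {
  cat("wigner_ensemble:", nrow(x$positions), "samples over",
      ncol(x$positions), "coordinates (seed", x$seed, ")\n")
  invisible(x)
}

#' Select initial conditions from an excitation window
#'
#' Implements the stochastic-selection rule of the nuclear-ensemble
#' method: every (sample, excited singlet state) pair whose vertical
#' excitation energy falls inside the window is accepted with probability
#' `f_osc / f_max`, where `f_max` is the largest oscillator strength among
#' all in-window pairs.  A sample may therefore contribute initial
#' conditions on more than one state.  Selection is reproducible given the
#' seed.
#'
#' @param samples A [sample_wigner()] ensemble.
#' @param model A [surface_model()].
#' @param window Numeric `c(E_min, E_max)` in eV (default `c(4.5, 4.7)`,
#'   around the simulated absorption maximum).
#' @param states Singlet excited-state indices (within the singlet
#'   manifold, 1-based above the ground state) to consider; default all.
#' @param seed Integer RNG seed for the acceptance draws.
#' @return An `initial_conditions` object: list with `conditions` (a
#'   data.frame: sample, state label, adiabatic index, excitation energy,
#'   oscillator strength), `positions`/`momenta` rows matched to
#'   `conditions`, `counts` per initial state label, `window` and `seed`.
#'   An empty selection is returned as a zero-row object, not an error.
#' @export
select_excitation_window <- function(samples, model,
                                     window = c(4.5, 4.7),
                                     states = NULL, seed = 1) {
  if (!inherits(samples, "wigner_ensemble"))
    stop("samples must be a wigner_ensemble")
  if (window[1] >= window[2]) stop("window must satisfy E_min < E_max")
  n <- nrow(samples$positions)
  cand <- list()
  for (i in seq_len(n)) {
    ad <- adiabatize(model, samples$positions[i, ])
    sing <- which(ad$manifold == "singlet")
    gs <- sing[1]
    exc <- sing[-1]
    if (!is.null(states)) exc <- exc[seq_along(exc) %in% states]
    for (k in seq_along(exc)) {
      a <- exc[k]
      de <- ad$energies[a] - ad$energies[gs]
      if (de > window[1] && de < window[2])
        cand[[length(cand) + 1]] <- data.frame(
          sample = i, adiabat = a,
          label = paste0("S", which(sing == a) - 1),
          E_exc = de, f_osc = ad$fosc[a])
    }
  }
  empty <- structure(list(
    conditions = data.frame(sample = integer(0), adiabat = integer(0),
                            label = character(0), E_exc = numeric(0),
                            f_osc = numeric(0)),
    positions = samples$positions[0, , drop = FALSE],
    momenta = samples$momenta[0, , drop = FALSE],
    counts = integer(0), window = window, seed = seed),
    class = "initial_conditions")
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  fmax <- max(cand$f_osc)
  if (fmax <= 0) return(empty)
  set.seed(seed)
  u <- stats::runif(nrow(cand))
  keep <- u < cand$f_osc / fmax
  sel <- cand[keep, , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(
    conditions = sel,
    positions = samples$positions[sel$sample, , drop = FALSE],
    momenta = samples$momenta[sel$sample, , drop = FALSE],
    counts = table(sel$label),
    window = window, seed = seed),
    class = "initial_conditions")
}

#' Subset an initial-condition ensemble
#'
#' @param ics An `initial_conditions` object.
#' @param idx Row indices (or a single count, meaning the first `idx`
#'   conditions).
#' @return The subsetted `initial_conditions` object.
#' @export
subset_initial_conditions <- function(ics, idx) {
  if (!inherits(ics, "initial_conditions"))
    stop("expected an initial_conditions object")
  if (length(idx) == 1 && idx >= 1)
    idx <- seq_len(min(idx, nrow(ics$conditions)))
  ics$conditions <- ics$conditions[idx, , drop = FALSE]
  ics$positions <- ics$positions[idx, , drop = FALSE]
  ics$momenta <- ics$momenta[idx, , drop = FALSE]
  ics$counts <- table(ics$conditions$label)
  ics
}

#' @export
print.initial_conditions <- function(x, ...) {
  cat("initial_conditions:", nrow(x$conditions), "conditions in window [",
      x$window[1], ",", x$window[2], "] eV\n")
  if (length(x$counts)) print(x$counts)
  invisible(x)
}
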