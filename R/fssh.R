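# Tully fewest-switches surface hopping over coupled singlet/triplet
# manifolds.  Nuclei follow velocity Verlet on one spin-adiabatic surface
# (eigenstates of the diabatic + SOC potential); electronic amplitudes are
# propagated with time-derivative couplings obtained from finite-difference
# eigenvector overlaps; hops are drawn from the fewest-switches
# probabilities with energy-conserving momentum rescaling along the
# velocity; overcoherence is damped with the energy-based decoherence
# correction.

#' Dynamics configuration
#'
#' @param dt Nuclear time step in fs (default 0.5).
#' @param n_substeps Electronic substeps per nuclear step (default 25,
#'   i.e. a 0.02 fs electronic step).
#' @param t_max Maximum propagation time in fs (default 1000).
#' @param decoherence Apply the energy-based decoherence correction?
#' @param decoherence_C Decoherence parameter in Hartree (default 0.1);
#'   converted to eV internally.
#' @param termination_gap Energy gap to the ground state (eV) below which
#'   a trajectory is terminated (default 0.15); `0` disables the
#'   criterion.
#' @param forbid_ground_hops Disable surface hops into the ground
#'   adiabatic state (default `TRUE`: the gap criterion is then the sole
#'   ground-state-return mechanism, because the electronic-structure
#'   reference the protocol emulates is unreliable near ground-state
#'   conical intersections).
#' @param frustrated Policy for energetically forbidden hops; only
#'   `"keep"` (momentum unchanged) is implemented.
#' @param rescale Momentum rescaling direction on accepted hops; only
#'   `"velocity"` is implemented (the overlap-based coupling scheme yields
#'   scalar couplings, not coupling vectors).
#' @param record_every Store every n-th step in the trajectory record.
#' @param seed Master RNG seed for [run_ensemble()].
#' @return A `dynamics_config` list.
#' @export
dynamics_config <- function(dt = 0.5, n_substeps = 25, t_max = 1000,
                            decoherence = TRUE, decoherence_C = 0.1,
                            termination_gap = 0.15,
                            forbid_ground_hops = TRUE,
                            frustrated = "keep", rescale = "velocity",
                            record_every = 1L, seed = 1L) {
  stopifnot(dt > 0, n_substeps >= 1, t_max > 0, termination_gap >= 0,
            record_every >= 1)
  frustrated <- match.arg(frustrated)
  rescale <- match.arg(rescale)
  structure(list(dt = dt, n_substeps = as.integer(n_substeps),
                 t_max = t_max, decoherence = isTRUE(decoherence),
                 decoherence_C = decoherence_C,
                 decoherence_C_eV = decoherence_C * .HARTREE_EV,
                 termination_gap = termination_gap,
                 forbid_ground_hops = isTRUE(forbid_ground_hops),
                 frustrated = frustrated, rescale = rescale,
                 record_every = as.integer(record_every),
                 seed = as.integer(seed)),
            class = "dynamics_config")
}

# deterministic eigenvector sign convention at t = 0: largest-magnitude
# component of each column is positive
.fix_gauge <- function(U) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  U
}

#' One velocity-Verlet nuclear step on the active surface
#'
#' @param model A [surface_model()].
#' @param q,p Coordinates and momenta (amu * unit / fs).
#' @param active Active adiabatic state index (1-based, SOC-included
#'   representation).
#' @param dt Time step (fs).
#' @param ad Current [adiabatize()] result at `q` (recomputed if `NULL`).
#' @return List with `q`, `p`, `ad` (adiabatize result at the new
#'   geometry, sign-aligned to the old eigenvectors).
#' @export
nuclear_step <- function(model, q, p, active, dt, ad = NULL) {
  if (is.null(ad)) ad <- adiabatize(model, q)
  g <- ad$gradients[, active]
  phalf <- p - 0.5 * dt * g / .EV_AMU
  qn <- q + dt * phalf / model$masses
  ad2 <- adiabatize(model, qn, previous_eigenvectors = ad$vectors)
  pn <- phalf - 0.5 * dt * ad2$gradients[, active] / .EV_AMU
  list(q = qn, p = pn, ad = ad2)
}

#' Time-derivative couplings from eigenvector overlaps
#'
#' Computes the overlap matrix of consecutive eigenvector sets,
#' orthonormalizes it (Loewdin symmetrization via SVD) and returns the
#' antisymmetric finite-difference coupling matrix
#' `T = (S - S^T) / (2 dt)`.
#'
#' @param U1,U2 Eigenvector matrices at `t` and `t + dt` (sign-aligned).
#' @param dt Nuclear time step (fs).
#' @return List with `T` (couplings, fs^-1), `S` (orthonormalized
#'   overlap) and `detS` (determinant of the raw overlap; far from 1 in
#'   magnitude signals a pathological step).
#' @export
overlap_couplings <- function(U1, U2, dt) {
  S <- crossprod(U1, U2)
  d <- det(S)
  sv <- svd(S)
  So <- sv$u %*% t(sv$v)
  list(T = (So - t(So)) / (2 * dt), S = So, detS = d)
}

#' Propagate electronic amplitudes across one nuclear step
#'
#' Integrates `dc_k/dt = -(i/hbar) E_k(t) c_k - sum_j T_kj c_j` over
#' `n_substeps` substeps with linearly interpolated adiabatic energies and
#' a constant coupling matrix.  The stiff dynamical phase is removed
#' analytically (interaction picture), so the integrator only tracks the
#' slow coupling-driven rotation and the propagation is norm-preserving to
#' high accuracy.  Fewest-switches hop probabilities out of the active
#' state are accumulated substep by substep.
#'
#' @param coeff Complex amplitude vector at the start of the step.
#' @param E1,E2 Adiabatic energies at `t` and `t + dt` (eV).
#' @param Tmat Time-derivative coupling matrix (fs^-1), antisymmetric.
#' @param dt Nuclear time step (fs).
#' @param n_substeps Number of electronic substeps.
#' @param active Active state index (for probability accumulation).
#' @return List with `coeff` (propagated amplitudes) and `hop_g`
#'   (accumulated fewest-switches probabilities `g_{active -> k}`).
#' @export
electronic_step <- function(coeff, E1, E2, Tmat, dt, n_substeps, active) {
  n <- length(coeff)
  dte <- dt / n_substeps
  dE <- (E2 - E1) / dt                       # eV / fs
  phase <- function(t) (E1 * t + 0.5 * dE * t^2) / .HBAR
  a <- coeff * exp(1i * phase(0))            # = coeff
  g <- numeric(n)
  deriv <- function(t, avec) {
    e <- exp(1i * phase(t))
    -(e * (Tmat %*% (Conj(e) * avec)))
  }
  for (j in seq_len(n_substeps)) {
    t0 <- (j - 1) * dte
    # hop probabilities from the amplitudes at the substep start
    cnow <- a * exp(-1i * phase(t0))
    pa <- Re(Conj(cnow[active]) * cnow[active])
    if (pa > 1e-12) {
      b <- 2 * Re(Conj(cnow[active]) * cnow) * Tmat[active, ]
      g <- g + dte * pmax(0, b) / pa
    }
    k1 <- deriv(t0, a)
    k2 <- deriv(t0 + dte / 2, a + dte / 2 * k1)
    k3 <- deriv(t0 + dte / 2, a + dte / 2 * k2)
    k4 <- deriv(t0 + dte, a + dte * k3)
    a <- a + dte / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(coeff = as.vector(a * exp(-1i * phase(dt))), hop_g = g)
}

#' Fewest-switches hop decision with energy-conserving rescaling
#'
#' @param hop_g Accumulated hop probabilities `g_{active -> k}` (zeroed
#'   for the active state; the ground state is zeroed when ground hops are
#'   forbidden).
#' @param active Active state index.
#' @param energies Adiabatic energies at the end of the step (eV).
#' @param p Momenta after the nuclear step.
#' @param masses Coordinate masses (amu).
#' @param u Uniform random draw in `[0, 1)`.
#' @return List with `active` (possibly new), `p` (possibly rescaled),
#'   `attempt` (attempted target or `NA`), `accepted`, `frustrated`.
#' @export
hop_decision <- function(hop_g, active, energies, p, masses, u) {
  g <- pmax(hop_g, 0)
  g[active] <- 0
  tot <- sum(g)
  if (tot > 1) g <- g / tot                  # normalization guard
  cum <- cumsum(g)
  k <- which(u < cum)[1]
  if (is.na(k))
    return(list(active = active, p = p, attempt = NA_integer_,
                accepted = FALSE, frustrated = FALSE))
  dE <- energies[k] - energies[active]
  ekin <- .kinetic_energy(p, masses)
  if (dE > ekin)
    return(list(active = active, p = p, attempt = k,
                accepted = FALSE, frustrated = TRUE))
  fac <- sqrt(max(0, (ekin - dE)) / ekin)
  list(active = k, p = p * fac, attempt = k, accepted = TRUE,
       frustrated = FALSE)
}

#' Energy-based decoherence correction
#'
#' Damps every non-active amplitude by `exp(-dt / tau_k)` with
#' `tau_k = (hbar / |E_k - E_active|) * (1 + C / E_kin)` and rescales the
#' active amplitude so the norm returns to exactly one.  Degenerate states
#' (`E_k = E_active`) and zero kinetic energy give infinite lifetimes and
#' leave the amplitudes untouched.
#'
#' @param coeff Complex amplitudes.
#' @param energies Adiabatic energies (eV).
#' @param active Active state index (must be populated).
#' @param ekin Nuclear kinetic energy (eV).
#' @param dt Time step (fs).
#' @param C Decoherence parameter in eV (0.1 Hartree = 2.7211386 eV by
#'   default in [dynamics_config()]).
#' @return Damped, renormalized amplitude vector.
#' @export
apply_decoherence <- function(coeff, energies, active, ekin, dt,
                              C = 0.1 * .HARTREE_EV) {
  pa <- Re(Conj(coeff[active]) * coeff[active])
  if (pa <= 0) stop("active state must be populated")
  if (ekin <= 0) return(coeff)               # tau -> infinity
  dE <- abs(energies - energies[active])
  damp <- ifelse(dE > 0, exp(-dt / ((.HBAR / dE) * (1 + C / ekin))), 1)
  damp[active] <- 1
  out <- coeff * damp
  rest <- sum(Re(Conj(out) * out)) - Re(Conj(out[active]) * out[active])
  out[active] <- out[active] * sqrt(max(0, 1 - rest) / pa)
  out
}

#' Termination check
#'
#' A trajectory terminates by internal conversion when the active state is
#' a singlet whose gap to the closed-shell ground-state surface has
#' dropped below the threshold (a hop to S0 is then assumed); it
#' terminates triplet-trapped when the active state is a triplet whose gap
#' to S0 drops below the threshold (the molecule is assumed to remain in
#' the triplet manifold); it times out at `t_max`.  The ground-state
#' surface is identified as the adiabat with maximal closed-shell diabat
#' weight, so the criterion also fires when a dissociating trajectory has
#' passed diabatically through (below) the ground-state seam, where the
#' signed gap is negative.
#'
#' @param energies Adiabatic energies (eV).
#' @param manifold Manifold labels per state.
#' @param active Active state index.
#' @param t Current time (fs).
#' @param config A [dynamics_config()].
#' @param s0 Index of the ground-state (closed-shell) adiabat; defaults
#'   to 1.
#' @return `NULL` to continue, otherwise a list with `reason` (one of
#'   `"internal_conversion"`, `"triplet_trapped"`, `"timeout"`),
#'   `manifold` and `final_state`.
#' @export
check_termination <- function(energies, manifold, active, t, config,
                              s0 = 1L) {
  gap <- energies[active] - energies[s0]
  if (config$termination_gap > 0 && active != s0 &&
      gap < config$termination_gap) {
    if (manifold[active] == "singlet")
      return(list(reason = "internal_conversion", manifold = "singlet",
                  final_state = active))
    return(list(reason = "triplet_trapped", manifold = "triplet",
                final_state = active))
  }
  if (t >= config$t_max)
    return(list(reason = "timeout", manifold = manifold[active],
                final_state = active))
  NULL
}

# state label ("S0", "T1", ...) for each adiabat given manifold labels
.state_labels <- function(manifold) {
  lab <- character(length(manifold))
  lab[manifold == "singlet"] <-
    paste0("S", seq_len(sum(manifold == "singlet")) - 1)
  lab[manifold == "triplet"] <-
    paste0("T", seq_len(sum(manifold == "triplet")))
  lab
}

#' Propagate a single surface-hopping trajectory
#'
#' @param model A [surface_model()].
#' @param position,momentum Named initial coordinates and momenta.
#' @param state Initial adiabatic state index (1-based, SOC-included
#'   representation).
#' @param config A [dynamics_config()].
#' @param seed RNG seed for this trajectory (defaults to `config$seed`).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation); both produce identical trajectories for identical
#'   seeds.
#' @return An `sh_trajectory`: recorded `times`, `positions`, `momenta`,
#'   `active` states, `energies`, `populations`, `manifold` labels of the
#'   active state, hop table, termination record, total-energy series.
#' @export
run_trajectory <- function(model, position, momentum, state, config,
                           seed = config$seed, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  q <- .coerce_coords(model, position)
  p <- .coerce_coords(model, momentum)
  if (engine == "cpp")
    return(.run_trajectory_cpp(model, q, p, state, config, seed))
  set.seed(seed)
  n <- model$nstates
  nsteps <- ceiling(config$t_max / config$dt)
  ad <- adiabatize(model, q)
  ad$vectors <- .fix_gauge(ad$vectors)
  cc <- complex(n); cc[state] <- 1 + 0i
  a <- state
  rec_idx <- seq(0, nsteps, by = config$record_every)
  nrec <- length(rec_idx)
  R <- list(times = numeric(nrec),
            positions = matrix(NA_real_, nrec, length(q),
                               dimnames = list(NULL, model$coords)),
            momenta = matrix(NA_real_, nrec, length(q)),
            active = integer(nrec), energies = matrix(NA_real_, nrec, n),
            populations = matrix(NA_real_, nrec, n),
            manifold = character(nrec), label = character(nrec),
            total_energy = numeric(nrec))
  hops <- list()
  termination <- NULL
  failed <- FALSE
  ri <- 1
  record <- function(ri, t, ad) {
    R$times[ri] <<- t
    R$positions[ri, ] <<- q
    R$momenta[ri, ] <<- p
    R$active[ri] <<- a
    R$energies[ri, ] <<- ad$energies
    R$populations[ri, ] <<- Re(Conj(cc) * cc)
    R$manifold[ri] <<- ad$manifold[a]
    R$label[ri] <<- .state_labels(ad$manifold)[a]
    R$total_energy[ri] <<- ad$energies[a] + .kinetic_energy(p, model$masses)
  }
  record(ri, 0, ad)
  t <- 0
  for (istep in seq_len(nsteps)) {
    st <- tryCatch(nuclear_step(model, q, p, a, config$dt, ad),
                   error = function(e) NULL)
    if (is.null(st) || any(!is.finite(st$ad$energies)) ||
        any(!is.finite(st$p))) { failed <- TRUE; break }
    oc <- overlap_couplings(ad$vectors, st$ad$vectors, config$dt)
    if (abs(oc$detS) < 0.5) {
      # retry through a midpoint-chained overlap before giving up
      qm <- (q + st$q) / 2
      adm <- adiabatize(model, qm, previous_eigenvectors = ad$vectors)
      S <- crossprod(ad$vectors, adm$vectors) %*%
           crossprod(adm$vectors, st$ad$vectors)
      if (abs(det(S)) < 0.5) { failed <- TRUE; break }
      sv <- svd(S)
      So <- sv$u %*% t(sv$v)
      oc <- list(T = (So - t(So)) / (2 * config$dt), S = So, detS = det(S))
    }
    # trivial-crossing tracking: when the active adiabat swaps character
    # with a neighbour within one step (tiny or zero coupling), the
    # physical continuation follows the diabatic character, i.e. the new
    # adiabat with maximal overlap (no stochastic hop; the amplitudes are
    # rotated through the swap by the propagation itself)
    jstar <- which.max(abs(oc$S[a, ]))
    es <- electronic_step(cc, ad$energies, st$ad$energies, oc$T,
                          config$dt, config$n_substeps, a)
    cc <- es$coeff
    if (jstar != a) {
      a <- jstar
      hd <- list(active = a, p = st$p, attempt = NA_integer_,
                 accepted = FALSE, frustrated = FALSE)
    } else {
    g <- es$hop_g
    if (config$forbid_ground_hops)
      g[which.max(st$ad$weights[1, ])] <- 0
    u <- stats::runif(1)
    hd <- hop_decision(g, a, st$ad$energies, st$p, model$masses, u)
    }
    if (!is.na(hd$attempt))
      hops[[length(hops) + 1]] <- data.frame(
        time = t + config$dt, from = a, to = hd$attempt,
        accepted = hd$accepted)
    a <- hd$active
    q <- st$q; p <- hd$p; ad <- st$ad
    if (config$decoherence) {
      ek <- .kinetic_energy(p, model$masses)
      cc <- apply_decoherence(cc, ad$energies, a, ek, config$dt,
                              config$decoherence_C_eV)
    }
    t <- t + config$dt
    if (istep %in% rec_idx) { ri <- ri + 1; record(ri, t, ad) }
    termination <- check_termination(ad$energies, ad$manifold, a, t, config,
                                     s0 = which.max(ad$weights[1, ]))
    if (!is.null(termination)) break
  }
  keep <- seq_len(ri)
  for (f in c("times", "active", "manifold", "label", "total_energy"))
    R[[f]] <- R[[f]][keep]
  for (f in c("positions", "momenta", "energies", "populations"))
    R[[f]] <- R[[f]][keep, , drop = FALSE]
  if (failed) {
    termination <- list(reason = "failed", manifold = NA_character_,
                        final_state = a)
  } else if (is.null(termination)) {
    termination <- list(reason = "timeout", manifold = ad$manifold[a],
                        final_state = a)
  }
  termination$time <- t
  termination$final_label <-
    if (!failed) .state_labels(ad$manifold)[termination$final_state]
    else NA_character_
  structure(list(
    times = R$times, positions = R$positions, momenta = R$momenta,
    active = R$active, energies = R$energies,
    populations = R$populations, manifold = R$manifold,
    label = R$label, total_energy = R$total_energy,
    hops = if (length(hops)) do.call(rbind, hops) else
      data.frame(time = numeric(0), from = integer(0), to = integer(0),
                 accepted = logical(0)),
    termination = termination, seed = seed, config = config,
    failed = failed
  ), class = "sh_trajectory")
}

#' @export
print.sh_trajectory <- function(x, ...) {
  cat("sh_trajectory:", length(x$times), "records,",
      nrow(x$hops), "hop attempts; terminated at", round(x$termination$time, 1),
      "fs (", x$termination$reason, ")\n")
  invisible(x)
}

#' Run a surface-hopping ensemble
#'
#' Propagates one trajectory per initial condition, each with its own
#' seed derived deterministically from the master seed, so the ensemble
#' is reproducible and trajectories are independent (results do not
#' depend on execution order).  Failed trajectories are retained and
#' flagged; they are excluded from ensemble statistics downstream but
#' counted.
#'
#' @param ics A [select_excitation_window()] result, or a list of
#'   `list(position, momentum, state)` entries.
#' @param model A [surface_model()].
#' @param config A [dynamics_config()]; `config$seed` is the master seed.
#' @param engine `"cpp"` or `"r"`.
#' @return An `sh_ensemble`: list of trajectories plus `seeds` and
#'   `config`.
#' @export
run_ensemble <- function(ics, model, config, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(ics, "initial_conditions")) {
    ntraj <- nrow(ics$conditions)
    getic <- function(i) list(position = ics$positions[i, ],
                              momentum = ics$momenta[i, ],
                              state = ics$conditions$adiabat[i])
  } else {
    ntraj <- length(ics)
    getic <- function(i) ics[[i]]
  }
  if (ntraj < 1) stop("need at least one initial condition")
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, ntraj)
  trajs <- vector("list", ntraj)
  for (i in seq_len(ntraj)) {
    ic <- getic(i)
    trajs[[i]] <- run_trajectory(model, ic$position, ic$momentum, ic$state,
                                 config, seed = seeds[i], engine = engine)
  }
  structure(list(trajectories = trajs, seeds = seeds, config = config),
            class = "sh_ensemble")
}

#' @export
print.sh_ensemble <- function(x, ...) {
  rs <- vapply(x$trajectories, function(tr) tr$termination$reason, "")
  cat("sh_ensemble:", length(x$trajectories), "trajectories\n")
  print(table(rs))
  invisible(x)
}
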