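#' Spin-pure adiabatic energies and gradients
#'
#' Diagonalizes the singlet and triplet diabatic blocks separately (no
#' spin-orbit coupling), yielding the spin-pure adiabatic states
#' `S0, S1, ...` and `T1, T2, ...` ordered by energy within each manifold.
#' This is the representation used for excited-state minima, relaxed scans
#' and minimum-energy crossing points; the dynamics instead uses the
#' SOC-included representation from [adiabatize()].
#'
#' @param model A [surface_model()].
#' @param q Coordinate vector.
#' @return List with named `energies` (eV) and `gradients`
#'   (`ncoord x nstates`, eV per coordinate unit), columns named
#'   `S0..., T1...`.
#' @export
spin_pure_states <- function(model, q) {
  ed <- eval_diabatic(model, q)
  mult <- model$states$multiplicity
  out_E <- numeric(0)
  out_g <- NULL
  for (m in c("singlet", "triplet")) {
    sel <- which(mult == m)
    if (!length(sel)) next
    Vb <- ed$V[sel, sel, drop = FALSE]
    eig <- eigen(Vb, symmetric = TRUE)
    idx <- order(eig$values)
    E <- eig$values[idx]
    W <- eig$vectors[, idx, drop = FALSE]^2
    g <- ed$dV[, sel, drop = FALSE] %*% W
    lab <- if (m == "singlet") paste0("S", seq_along(sel) - 1)
           else paste0("T", seq_along(sel))
    names(E) <- lab; colnames(g) <- lab
    out_E <- c(out_E, E)
    out_g <- if (is.null(out_g)) g else cbind(out_g, g)
  }
  list(energies = out_E, gradients = out_g)
}

.state_energy <- function(model, q, state) {
  sp <- spin_pure_states(model, q)
  if (!state %in% names(sp$energies))
    stop("unknown state '", state, "'; available: ",
         paste(names(sp$energies), collapse = ", "))
  list(E = unname(sp$energies[state]), g = sp$gradients[, state])
}

#' Minimize an adiabatic surface
#'
#' Quasi-Newton (BFGS) minimization of one spin-pure adiabatic state using
#' analytic Hellmann-Feynman gradients.
#'
#' @param model A [surface_model()].
#' @param state State label (`"S0"`, `"S1"`, `"T1"`, ...).
#' @param start Starting geometry (named vector); defaults to the model
#'   reference.
#' @param gtol Gradient-norm convergence threshold (eV per coordinate
#'   unit).
#' @param lower,upper Optional named coordinate bounds (box-constrained
#'   L-BFGS-B); useful to stay inside one basin of a surface that also has
#'   dissociative regions.
#' @return List with `geometry`, `energy` (eV) and `grad_norm`.
#' @export
optimize_minimum <- function(model, state, start = model$reference,
                             gtol = 1e-6, lower = NULL, upper = NULL) {
  q0 <- .coerce_coords(model, start)
  fn <- function(x) .state_energy(model, x, state)$E
  gr <- function(x) .state_energy(model, x, state)$g
  boxed <- !is.null(lower) || !is.null(upper)
  run <- function(q) {
    if (boxed)
      stats::optim(q, fn, gr, method = "L-BFGS-B",
                   lower = .coerce_coords(model, lower),
                   upper = .coerce_coords(model, upper),
                   control = list(maxit = 500, factr = 10))
    else
      stats::optim(q, fn, gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
  }
  q <- run(q0)$par
  for (k in 1:50) {
    g <- gr(q)
    if (boxed) {
      lo <- .coerce_coords(model, lower); up <- .coerce_coords(model, upper)
      g[q <= lo + 1e-8 | q >= up - 1e-8] <- 0
    }
    if (sqrt(sum(g^2)) < gtol) break
    q <- run(q)$par
  }
  q <- stats::setNames(q, model$coords)
  list(geometry = q, energy = fn(q), grad_norm = sqrt(sum(g^2)))
}

#' Linear interpolation in internal coordinates (LIIC) path profile
#'
#' Builds a piecewise-linear path through the given anchor geometries,
#' interpolating each internal coordinate independently, and evaluates all
#' spin-pure adiabatic states at every point.  The path coordinate is the
#' cumulative mass-weighted arc length `sum sqrt(sum_i m_i dq_i^2)`
#' (amu^0.5 A).
#'
#' @param model A [surface_model()].
#' @param anchors List of >= 2 named coordinate vectors.
#' @param n_per_segment Interior points inserted per segment.
#' @param anchor_labels Optional character labels for the anchors.
#' @return An object of class `path_profile`: list with `geometries`
#'   (matrix, one row per point), `s` (mass-weighted path coordinate),
#'   `energies` (matrix, columns per state) and `anchor` (label or `NA`
#'   per point).
#' @export
liic_path <- function(model, anchors, n_per_segment = 8,
                      anchor_labels = NULL) {
  if (length(anchors) < 2) stop("need at least two anchor geometries")
  A <- t(vapply(anchors, function(a) .coerce_coords(model, a),
                numeric(length(model$coords))))
  colnames(A) <- model$coords
  if (is.null(anchor_labels))
    anchor_labels <- paste0("anchor", seq_len(nrow(A)))
  pts <- list(); labs <- character(0)
  for (seg in seq_len(nrow(A) - 1)) {
    fr <- seq(0, 1, length.out = n_per_segment + 2)
    if (seg > 1) fr <- fr[-1]            # avoid duplicating shared anchors
    for (f in fr) {
      pts[[length(pts) + 1]] <- (1 - f) * A[seg, ] + f * A[seg + 1, ]
      labs <- c(labs,
                if (f == 0) anchor_labels[seg]
                else if (f == 1) anchor_labels[seg + 1] else NA_character_)
    }
  }
  G <- do.call(rbind, pts)
  s <- c(0, cumsum(sqrt(rowSums(
    sweep(diff(G)^2, 2, model$masses, "*")))))
  E <- t(apply(G, 1, function(q) spin_pure_states(model, q)$energies))
  structure(list(geometries = G, s = s, energies = E, anchor = labs,
                 coords = model$coords),
            class = "path_profile")
}

#' @export
print.path_profile <- function(x, ...) {
  cat("path_profile:", nrow(x$geometries), "points,",
      "mass-weighted length", round(max(x$s), 3), "amu^0.5 A\n")
  cat("anchors:", paste(stats::na.omit(x$anchor), collapse = " -> "), "\n")
  invisible(x)
}

#' Write a path profile as CSV
#'
#' Columns: `path_coord_amu05_A`, one column per coordinate, one energy
#' column per state (eV), and `anchor_label`.
#'
#' @param profile A [liic_path()] / [relaxed_scan()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_path_profile <- function(profile, path) {
  df <- data.frame(path_coord_amu05_A = profile$s,
                   profile$geometries,
                   profile$energies,
                   anchor_label = ifelse(is.na(profile$anchor), "",
                                         profile$anchor),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Relaxed scan along one internal coordinate
#'
#' At each scan value the remaining coordinates are minimized on the
#' requested spin-pure adiabatic surface (BFGS on analytic gradients,
#' gradient norm below `gtol`), warm-started from the previous point.
#' Points whose minimization does not converge are flagged and the scan
#' continues.
#'
#' @param model A [surface_model()].
#' @param state State label (e.g. `"S1"`).
#' @param coordinate Name of the scanned coordinate.
#' @param values Numeric vector of scan values.
#' @param start Starting geometry for the first point.
#' @param gtol Gradient-norm threshold for the orthogonal coordinates.
#' @return A `path_profile` with an extra `converged` logical vector and
#'   `scan` metadata.
#' @export
relaxed_scan <- function(model, state, coordinate, values,
                         start = model$reference, gtol = 1e-4) {
  ci <- match(coordinate, model$coords)
  if (is.na(ci)) stop("'", coordinate, "' is not a model coordinate")
  q <- .coerce_coords(model, start)
  free <- setdiff(seq_along(model$coords), ci)
  G <- matrix(NA_real_, length(values), length(model$coords),
              dimnames = list(NULL, model$coords))
  conv <- logical(length(values))
  for (k in seq_along(values)) {
    q[ci] <- values[k]
    if (length(free)) {
      fn <- function(x) {qq <- q; qq[free] <- x; .state_energy(model, qq, state)$E}
      gr <- function(x) {qq <- q; qq[free] <- x; .state_energy(model, qq, state)$g[free]}
      opt <- stats::optim(q[free], fn, gr, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14))
      q[free] <- opt$par
      conv[k] <- sqrt(sum(gr(opt$par)^2)) < gtol
    } else conv[k] <- TRUE
    G[k, ] <- q
  }
  s <- c(0, cumsum(sqrt(rowSums(
    sweep(diff(G)^2, 2, model$masses, "*")))))
  E <- t(apply(G, 1, function(qq) spin_pure_states(model, qq)$energies))
  structure(list(geometries = G, s = s, energies = E,
                 anchor = rep(NA_character_, nrow(G)),
                 converged = conv,
                 scan = list(state = state, coordinate = coordinate,
                             values = values),
                 coords = model$coords),
            class = "path_profile")
}

#' Penalty-function optimization of a minimum-energy crossing point
#'
#' Minimizes the smoothed penalty objective
#' `F = (E_i + E_j)/2 + sigma * (E_i - E_j)^2 / (|E_i - E_j| + alpha)`
#' with an increasing penalty `sigma` (doubled each outer iteration) until
#' the gap closes below `gap_tol` and the mean-energy gradient projected
#' onto the seam falls below `seam_gtol`.  No nonadiabatic couplings are
#' required.  States are spin-pure labels, so crossings between states of
#' different multiplicity are optimized on SOC-free surfaces.
#'
#' @param model A [surface_model()].
#' @param states Character vector of two distinct state labels,
#'   e.g. `c("S1", "S0")` or `c("T1", "S0")`.
#' @param start Starting geometry.
#' @param sigma0 Initial penalty weight (default 3.5).
#' @param alpha Smoothing parameter in eV (default 0.02 Hartree).
#' @param gap_tol Gap convergence threshold (eV, default 1e-3 = 1 meV).
#' @param seam_gtol Seam-projected gradient threshold (eV per coordinate
#'   unit).
#' @param max_outer Maximum outer (sigma-doubling) iterations.
#' @param reference_minimum Optional state label (minimized from the model
#'   reference), reference energy (numeric scalar, eV) or geometry; when
#'   given, the result reports `barrier = E(MECP) - E(reference minimum)`.
#' @param lower,upper Optional named coordinate bounds.  When supplied the
#'   inner minimization is box-constrained (L-BFGS-B), which selects a
#'   particular basin when the crossing seam has several local minima.
#' @return List of class `mecp_result`: `geometry`, `states`, `energy`
#'   (mean of the pair, eV), `gap` (eV), `barrier` (eV or `NA`),
#'   `converged`, `trace` (data.frame of outer iterations).
#' @export
optimize_mecp <- function(model, states, start = model$reference,
                          sigma0 = 3.5, alpha = 0.02 * 27.211386,
                          gap_tol = 1e-3, seam_gtol = 1e-3,
                          max_outer = 30, reference_minimum = NULL,
                          lower = NULL, upper = NULL) {
  if (length(states) != 2 || states[1] == states[2])
    stop("states must name two distinct surfaces")
  q <- .coerce_coords(model, start)
  if (any(!is.finite(q))) stop("start geometry must be finite")
  pair <- function(x) {
    sp <- spin_pure_states(model, x)
    list(Ei = sp$energies[states[1]], Ej = sp$energies[states[2]],
         gi = sp$gradients[, states[1]], gj = sp$gradients[, states[2]])
  }
  sigma <- sigma0
  trace <- data.frame(sigma = numeric(0), gap = numeric(0),
                      energy = numeric(0), seam_grad = numeric(0))
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    fn <- function(x) {
      p <- pair(x); D <- p$Ei - p$Ej
      (p$Ei + p$Ej) / 2 + sigma * D^2 / (abs(D) + alpha)
    }
    gr <- function(x) {
      p <- pair(x); D <- p$Ei - p$Ej
      gm <- (p$gi + p$gj) / 2
      dpen <- (2 * D * (abs(D) + alpha) - D^2 * sign(D)) / (abs(D) + alpha)^2
      gm + sigma * dpen * (p$gi - p$gj)
    }
    opt <- if (is.null(lower) && is.null(upper))
      stats::optim(q, fn, gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
    else
      stats::optim(q, fn, gr, method = "L-BFGS-B",
                   lower = .coerce_coords(model, lower),
                   upper = .coerce_coords(model, upper),
                   control = list(maxit = 500, factr = 10))
    q <- opt$par
    p <- pair(q)
    gap <- abs(p$Ei - p$Ej)
    gm <- (p$gi + p$gj) / 2
    gd <- p$gi - p$gj
    if (!is.null(lower) || !is.null(upper)) {
      # ignore gradient components pinned by an active box constraint
      act <- rep(FALSE, length(q))
      if (!is.null(lower)) act <- act | q <= .coerce_coords(model, lower) + 1e-8
      if (!is.null(upper)) act <- act | q >= .coerce_coords(model, upper) - 1e-8
      gm[act] <- 0; gd[act] <- 0
    }
    nd <- sqrt(sum(gd^2))
    seam_g <- if (nd > 1e-12)
      sqrt(sum((gm - sum(gm * gd / nd) * gd / nd)^2)) else sqrt(sum(gm^2))
    trace <- rbind(trace, data.frame(sigma = sigma, gap = gap,
                                     energy = (p$Ei + p$Ej) / 2,
                                     seam_grad = seam_g))
    if (gap < gap_tol && seam_g < seam_gtol) { converged <- TRUE; break }
    sigma <- sigma * 2
  }
  if (!converged)
    stop("MECP optimization did not converge (final gap ",
         signif(gap, 3), " eV after ", nrow(trace), " penalty updates)")
  barrier <- NA_real_
  if (!is.null(reference_minimum)) {
    Eref <- if (is.character(reference_minimum))
      optimize_minimum(model, reference_minimum)$energy
    else if (is.numeric(reference_minimum) && length(reference_minimum) == 1)
      reference_minimum                         # an energy in eV
    else .state_energy(model, reference_minimum, states[1])$E
    barrier <- (p$Ei + p$Ej) / 2 - Eref
  }
  structure(list(geometry = stats::setNames(q, model$coords),
                 states = states,
                 energy = unname((p$Ei + p$Ej) / 2), gap = unname(gap),
                 barrier = unname(barrier), converged = converged,
                 trace = trace),
            class = "mecp_result")
}

#' @export
print.mecp_result <- function(x, ...) {
  cat("MECP", paste(x$states, collapse = "/"), ": E =",
      round(x$energy, 4), "eV, gap =", signif(x$gap, 3), "eV\n")
  if (!is.na(x$barrier))
    cat("barrier vs reference minimum:", round(x$barrier, 4), "eV\n")
  invisible(x)
}
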