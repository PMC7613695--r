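#' Analytic coupled diabatic surface models
#'
#' A `surface_model` packages everything the dynamics, spectrum and path
#' machinery needs from an electronic-structure provider, evaluated
#' analytically: a symmetric diabatic potential matrix (eV) over a small set
#' of named internal coordinates, its analytic gradient, a constant
#' spin-orbit-coupling block between singlet and triplet diabats, and
#' per-diabat oscillator strengths.
#'
#' The diagonal of the diabatic matrix is a sum of closed-form
#' one-coordinate terms per state (harmonic, Morse, exponential-repulsive,
#' symmetric double-well, linear), so diabatic gradients are exact and the
#' gradient of each adiabatic state follows from the Hellmann-Feynman
#' theorem (off-diagonal couplings are constants).
#'
#' @param coords Character vector of coordinate names.
#' @param masses Named numeric vector of per-coordinate effective masses
#'   (amu; for angle coordinates an inertia-derived effective mass so that
#'   kinetic energy in amu A^2/fs^2-equivalents is consistent).
#' @param reference Named numeric vector, the reference geometry.
#' @param states `data.frame` with columns `label`, `multiplicity`
#'   ("singlet"/"triplet"), `index` (within multiplicity, 0-based) and
#'   `character` (e.g. "closed-shell", "n_pi*", "pi_pi*", "pi_sigma*_CO",
#'   "pi_sigma*_NH").
#' @param origins Numeric vector of per-diabat electronic origins (eV).
#' @param coupling Symmetric matrix of constant diabatic couplings (eV);
#'   must vanish between states of different multiplicity.
#' @param soc Symmetric matrix of constant effective spin-orbit couplings
#'   (eV); must vanish between states of equal multiplicity.
#' @param fosc Numeric vector of per-diabat oscillator strengths (>= 0).
#' @param terms `data.frame` with columns `state`, `coord` (integer
#'   indices), `type` (one of "harm", "morse", "rep", "dwell", "lin") and
#'   parameters `p1`, `p2`, `p3` (see Details).
#' @param meta Optional list of provenance/calibration metadata.
#'
#' @details Term functional forms, with `d = q - p3` where noted:
#' \itemize{
#'   \item `harm`: `0.5 * p1 * (q - p2)^2`
#'   \item `morse`: `p1 * (1 - exp(-p2 * (q - p3)))^2`
#'   \item `rep`: `p1 * exp(-p2 * (q - p3))`
#'   \item `dwell`: `p1 * ((q / p2)^2 - 1)^2` (minima at `q = +/- p2`,
#'     barrier `p1` at `q = 0`)
#'   \item `quart`: `p1 * (q - p2)^4`
#'   \item `lin`: `p1 * (q - p2)`
#' }
#'
#' @return An object of class `surface_model`.
#' @seealso [adiabatize()], [build_lz_model()], [build_to_surrogate()]
#' @export
surface_model <- function(coords, masses, reference, states, origins,
                          coupling, soc, fosc, terms, meta = list()) {
  n <- nrow(states)
  nc <- length(coords)
  stopifnot(is.character(coords), nc >= 1)
  masses <- masses[coords]
  reference <- reference[coords]
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all coordinate masses must be finite and strictly positive")
  if (any(!is.finite(reference)))
    stop("reference geometry incomplete for the declared coordinates")
  req <- c("label", "multiplicity", "index", "character")
  if (!all(req %in% names(states)))
    stop("states data.frame must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(states[, c("multiplicity", "index")]))
    stop("(multiplicity, index) pairs must be unique within a model")
  if (length(origins) != n || length(fosc) != n)
    stop("origins and fosc must have one entry per diabat")
  if (any(fosc < 0)) stop("oscillator strengths must be >= 0")
  coupling <- as.matrix(coupling); soc <- as.matrix(soc)
  if (!isTRUE(all.equal(coupling, t(coupling), tolerance = 1e-12)))
    stop("diabatic coupling matrix must be symmetric")
  if (!isTRUE(all.equal(soc, t(soc), tolerance = 1e-12)))
    stop("SOC matrix must be symmetric")
  same_mult <- outer(states$multiplicity, states$multiplicity, "==")
  if (any(abs(soc[same_mult]) > 0))
    stop("SOC block may only couple states of different multiplicity")
  if (any(abs(coupling[!same_mult]) > 0))
    stop("diabatic couplings may only connect states of equal multiplicity")
  if (any(abs(diag(coupling)) > 0) || any(abs(diag(soc)) > 0))
    stop("coupling and SOC matrices must have zero diagonal")
  terms$type <- as.character(terms$type)
  if (!all(terms$type %in% c("harm", "morse", "rep", "dwell", "quart", "lin")))
    stop("unknown term type in terms table")
  if (any(terms$state < 1 | terms$state > n) ||
      any(terms$coord < 1 | terms$coord > nc))
    stop("terms table indexes a state or coordinate outside the model")
  structure(list(
    coords = coords, masses = masses, reference = reference,
    states = states, nstates = n, origins = origins,
    coupling = coupling, soc = soc, fosc = fosc,
    terms = terms, meta = meta
  ), class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat("surface_model:", x$nstates, "diabats over",
      length(x$coords), "coordinates (", paste(x$coords, collapse = ", "), ")\n")
  cat("states:", paste(x$states$label, collapse = ", "), "\n")
  if (!is.null(x$meta$name)) cat("name:", x$meta$name, "\n")
  invisible(x)
}

# value and derivative of a single term type at coordinate value q;
# exponents are clipped at +/-60 so optimizer excursions to unphysical
# geometries stay finite (values are then astronomically large but finite)
.cexp <- function(x) exp(pmin(pmax(x, -60), 60))

.term_value <- function(type, q, p1, p2, p3) {
  switch(type,
    harm  = 0.5 * p1 * (q - p2)^2,
    morse = p1 * (1 - .cexp(-p2 * (q - p3)))^2,
    rep   = p1 * .cexp(-p2 * (q - p3)),
    dwell = p1 * ((q / p2)^2 - 1)^2,
    quart = p1 * (q - p2)^4,
    lin   = p1 * (q - p2))
}

.term_deriv <- function(type, q, p1, p2, p3) {
  switch(type,
    harm  = p1 * (q - p2),
    morse = {e <- .cexp(-p2 * (q - p3)); 2 * p1 * (1 - e) * p2 * e},
    rep   = -p2 * p1 * .cexp(-p2 * (q - p3)),
    dwell = p1 * 2 * ((q / p2)^2 - 1) * 2 * q / p2^2,
    quart = 4 * p1 * (q - p2)^3,
    lin   = p1 + 0 * q)
}

#' Evaluate the diabatic potential matrix and its analytic gradient
#'
#' @param model A [surface_model()].
#' @param q Named (or model-ordered) numeric coordinate vector.
#' @return List with `V` (symmetric diabatic matrix, eV), `dV` (matrix
#'   `ncoord x nstates` of diagonal gradients, eV per coordinate unit;
#'   off-diagonal couplings are constant so their gradients vanish).
#' @export
eval_diabatic <- function(model, q) {
  q <- .coerce_coords(model, q)
  n <- model$nstates
  nc <- length(model$coords)
  V <- model$coupling
  diag(V) <- model$origins
  dV <- matrix(0, nc, n, dimnames = list(model$coords, model$states$label))
  tt <- model$terms
  for (i in seq_len(nrow(tt))) {
    s <- tt$state[i]; cidx <- tt$coord[i]
    V[s, s] <- V[s, s] +
      .term_value(tt$type[i], q[cidx], tt$p1[i], tt$p2[i], tt$p3[i])
    dV[cidx, s] <- dV[cidx, s] +
      .term_deriv(tt$type[i], q[cidx], tt$p1[i], tt$p2[i], tt$p3[i])
  }
  list(V = V, dV = dV)
}

.coerce_coords <- function(model, q) {
  if (!is.null(names(q))) {
    miss <- setdiff(model$coords, names(q))
    if (length(miss))
      stop("geometry is missing coordinates: ", paste(miss, collapse = ", "))
    q <- q[model$coords]
  }
  if (length(q) != length(model$coords))
    stop("coordinate vector length (", length(q),
         ") does not match model dimensionality (", length(model$coords), ")")
  if (any(!is.finite(q))) stop("non-finite coordinate value")
  as.numeric(q)
}

#' Adiabatic energies, eigenvectors, gradients and oscillator strengths
#'
#' Diagonalizes the diabatic-plus-SOC potential matrix at a geometry.
#' Eigenvector signs are aligned to maximize overlap with
#' `previous_eigenvectors` when given (adiabatic states are ordered by
#' energy; the sign of each column is flipped when its overlap with the
#' matching previous column is negative).  Adiabatic oscillator strengths
#' are squared-coefficient mixtures of the diabat oscillator strengths, and
#' adiabatic gradients follow from the Hellmann-Feynman theorem.
#'
#' @param model A [surface_model()].
#' @param q Coordinate vector.
#' @param previous_eigenvectors Optional eigenvector matrix from a nearby
#'   geometry used for sign alignment.
#' @param include_soc Include the spin-orbit block in the diagonalized
#'   matrix (the spin-adiabatic representation used by the dynamics)?
#'   Set `FALSE` for spin-pure surfaces (used by MECP optimization
#'   between states of different multiplicity).
#' @return List with `energies` (eV, ascending), `vectors` (columns are
#'   adiabatic states in the diabatic basis), `fosc`, `gradients`
#'   (`ncoord x nstates`), `manifold` ("singlet"/"triplet" by dominant
#'   diabat weight) and `weights` (squared coefficients).
#' @export
adiabatize <- function(model, q, previous_eigenvectors = NULL,
                       include_soc = TRUE) {
  ed <- eval_diabatic(model, q)
  V <- ed$V
  if (include_soc) V <- V + model$soc
  if (!isTRUE(all.equal(V, t(V), tolerance = 1e-9)))
    stop("internal consistency error: potential matrix not symmetric")
  eig <- eigen(V, symmetric = TRUE)
  idx <- order(eig$values)
  E <- eig$values[idx]
  U <- eig$vectors[, idx, drop = FALSE]
  if (!is.null(previous_eigenvectors)) {
    ov <- colSums(previous_eigenvectors * U)
    flip <- ov < 0
    if (any(flip)) U[, flip] <- -U[, flip]
  }
  W <- U^2
  grads <- ed$dV %*% W          # Hellmann-Feynman: dE_a = sum_d U_da^2 dV_dd
  mult_weight <- colSums(W[model$states$multiplicity == "triplet", ,
                           drop = FALSE])
  list(
    energies = E,
    vectors = U,
    fosc = as.numeric(model$fosc %*% W),
    gradients = grads,
    manifold = ifelse(mult_weight > 0.5, "triplet", "singlet"),
    weights = W
  )
}

#' Check analytic gradients against central finite differences
#'
#' @param model A [surface_model()].
#' @param q Coordinate vector.
#' @param step Finite-difference step (default 1e-4).
#' @return Maximum relative deviation over diagonal diabatic gradient
#'   entries.  Central differences at `step` and `step/2` are combined by
#'   Richardson extrapolation (truncation error O(step^4)), and
#'   deviations are measured relative to `max(|g|, 1)` eV per coordinate
#'   unit, so the check is relative for steep gradients and absolute near
#'   stationary points, where a purely relative measure would amplify
#'   finite-difference noise.
#' @export
gradient_check <- function(model, q, step = 1e-4) {
  q <- .coerce_coords(model, q)
  g <- eval_diabatic(model, q)$dV
  cdiff <- function(i, h) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    (diag(eval_diabatic(model, qp)$V) -
     diag(eval_diabatic(model, qm)$V)) / (2 * h)
  }
  worst <- 0
  for (i in seq_along(q)) {
    fd <- (4 * cdiff(i, step / 2) - cdiff(i, step)) / 3
    rel <- abs(fd - g[i, ]) / pmax(abs(g[i, ]), 1)
    worst <- max(worst, rel)
  }
  worst
}

#' One-dimensional two-state Landau-Zener model
#'
#' Linear diabats with constant coupling, the standard analytic benchmark
#' for nonadiabatic propagation.  The diabats cross at
#' `crossing_position` with slopes `-slope_difference/2` and
#' `+slope_difference/2`; the companion [lz_probability()] gives the
#' closed-form single-passage diabatic transition probability.
#'
#' @param coupling Constant diabatic coupling (eV), > 0.
#' @param slope_difference Difference of diabatic slopes (eV/A), != 0.
#' @param crossing_position Crossing coordinate (A).
#' @param mass Effective mass of the coordinate (amu).
#' @return A two-state [surface_model()] over the single coordinate `x`.
#' @export
build_lz_model <- function(coupling, slope_difference, crossing_position = 0,
                           mass = 6) {
  if (!(coupling > 0)) stop("coupling must be > 0")
  if (slope_difference == 0) stop("slope_difference must be nonzero")
  states <- data.frame(
    label = c("d1", "d2"), multiplicity = "singlet", index = 0:1,
    character = c("n_pi*", "pi_pi*"), stringsAsFactors = FALSE)
  terms <- data.frame(
    state = c(1L, 2L), coord = c(1L, 1L), type = "lin",
    p1 = c(-slope_difference / 2, slope_difference / 2),
    p2 = crossing_position, p3 = 0)
  K <- matrix(c(0, coupling, coupling, 0), 2, 2)
  surface_model(
    coords = "x", masses = c(x = mass),
    reference = c(x = crossing_position),
    states = states, origins = c(0, 0),
    coupling = K, soc = matrix(0, 2, 2), fosc = c(0, 1),
    terms = terms,
    meta = list(name = "landau-zener", coupling = coupling,
                slope_difference = slope_difference,
                crossing_position = crossing_position))
}

#' Analytic Landau-Zener single-passage probability
#'
#' `P = exp(-2 pi V^2 / (hbar v |dF|))` for a linear two-state crossing
#' traversed at constant velocity `v`: the probability of staying on the
#' diabat (i.e. switching adiabats).
#'
#' @param model A model returned by [build_lz_model()].
#' @param velocity Nuclear velocity at the crossing (A/fs).
#' @return Diabatic passage probability in `[0, 1]`.
#' @export
lz_probability <- function(model, velocity) {
  m <- model$meta
  if (is.null(m$coupling) || is.null(m$slope_difference))
    stop("lz_probability() needs a model built by build_lz_model()")
  exp(-2 * pi * m$coupling^2 /
        (.HBAR * abs(velocity) * abs(m$slope_difference)))
}
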