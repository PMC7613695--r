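# Shared fixtures, built in code.  The calibrated 2-TO surrogate is
# expensive to build, so all files share the package-cached instance.

to2 <- function() to2_default_model()

# single-state models for integrator checks
harmonic_model <- function(k = 5, mass = 6, x0 = 0) {
  surface_model(
    coords = "x", masses = c(x = mass), reference = c(x = x0),
    states = data.frame(label = "g", multiplicity = "singlet", index = 0L,
                        character = "closed-shell"),
    origins = 0, coupling = matrix(0, 1, 1), soc = matrix(0, 1, 1),
    fosc = 0,
    terms = data.frame(state = 1L, coord = 1L, type = "harm",
                       p1 = k, p2 = x0, p3 = 0))
}

free_model <- function(mass = 6) {
  surface_model(
    coords = "x", masses = c(x = mass), reference = c(x = 0),
    states = data.frame(label = "g", multiplicity = "singlet", index = 0L,
                        character = "closed-shell"),
    origins = 0, coupling = matrix(0, 1, 1), soc = matrix(0, 1, 1),
    fosc = 0,
    terms = data.frame(state = 1L, coord = 1L, type = "lin",
                       p1 = 0, p2 = 0, p3 = 0))
}

# two crossing 2-D paraboloids (uncoupled): known seam for the MECP oracle
cone_model <- function(kx = 8, ky = 6, a = 0.5, b = 0.6, offset = 0.4) {
  surface_model(
    coords = c("x", "y"), masses = c(x = 6, y = 6),
    reference = c(x = -a, y = 0),
    states = data.frame(label = c("lo", "hi"), multiplicity = "singlet",
                        index = 0:1,
                        character = c("closed-shell", "n_pi*")),
    origins = c(0, offset),
    coupling = matrix(0, 2, 2), soc = matrix(0, 2, 2), fosc = c(0, 1),
    terms = data.frame(
      state = c(1L, 1L, 2L, 2L),
      coord = c(1L, 2L, 1L, 2L),
      type = "harm",
      p1 = c(kx, ky, kx, ky),
      p2 = c(-a, 0, a, b),
      p3 = 0))
}

# brute-force seam minimum of the cone model on a dense grid
cone_grid_mecp <- function(model, nx = 401, ny = 401) {
  xs <- seq(-1.2, 1.2, length.out = nx)
  ys <- seq(-0.8, 1.4, length.out = ny)
  best <- list(E = Inf)
  for (y in ys) {
    # along x the gap is monotone in the difference term; scan densely
    E1 <- E2 <- numeric(nx)
    for (i in seq_len(nx)) {
      sp <- spin_pure_states(model, c(x = xs[i], y = y))
      E1[i] <- sp$energies["S0"]; E2[i] <- sp$energies["S1"]
    }
    d <- abs(E1 - E2)
    i <- which(d < 0.02)
    if (length(i)) {
      j <- i[which.min(E1[i])]
      if (E1[j] < best$E)
        best <- list(E = E1[j], x = xs[j], y = y, gap = d[j])
    }
  }
  best
}

# a three-state toy with two degenerate bright states, both always inside
# the excitation window: acceptance must then be unbiased between them
equal_f_model <- function() {
  surface_model(
    coords = "x", masses = c(x = 6), reference = c(x = 0),
    states = data.frame(label = c("g", "e1", "e2"),
                        multiplicity = "singlet", index = 0:2,
                        character = c("closed-shell", "n_pi*", "pi_pi*")),
    origins = c(0, 4.58, 4.62),
    coupling = matrix(0, 3, 3), soc = matrix(0, 3, 3),
    fosc = c(0, 0.5, 0.5),
    terms = data.frame(state = c(1L, 2L, 3L), coord = 1L, type = "harm",
                       p1 = 5, p2 = 0, p3 = 0))
}

# fabricate a minimal sh_trajectory for classification tests
fake_trajectory <- function(r_CO = 1.37, r_CS = 1.64, theta = 0,
                            r_NH = 1.01, reason = "internal_conversion",
                            manifold = "singlet", failed = FALSE,
                            n = 3) {
  pos <- matrix(rep(c(r_CO, r_CS, theta, r_NH), each = n), n, 4,
                dimnames = list(NULL, c("r_CO", "r_CS", "theta_tilt",
                                        "r_NH")))
  structure(list(
    times = seq(0, by = 0.5, length.out = n),
    positions = pos,
    momenta = pos * 0,
    active = rep(2L, n),
    energies = matrix(rep(c(0, 4), each = n), n, 2),
    populations = matrix(rep(c(0, 1), each = n), n, 2),
    manifold = rep(manifold, n),
    label = rep(if (manifold == "singlet") "S1" else "T1", n),
    total_energy = rep(4, n),
    hops = data.frame(time = numeric(0), from = integer(0),
                      to = integer(0), accepted = logical(0)),
    termination = list(reason = reason, manifold = manifold,
                       final_state = 2L, time = (n - 1) * 0.5,
                       final_label = if (manifold == "singlet") "S1" else "T1"),
    seed = 1L, config = dynamics_config(), failed = failed
  ), class = "sh_trajectory")
}
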