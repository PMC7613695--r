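test_that("velocity Verlet conserves energy on a harmonic surface", {
  m <- harmonic_model(k = 5, mass = 6)
  cfg <- dynamics_config(dt = 0.5, t_max = 500, decoherence = FALSE,
                         termination_gap = 0, forbid_ground_hops = FALSE)
  tr <- run_trajectory(m, c(x = 0.1), c(x = 0), 1, cfg, seed = 1,
                       engine = "r")
  E <- tr$total_energy
  # secular drift: compare mean energy over the first and last tenth
  n <- length(E)
  drift <- abs(mean(E[seq_len(n %/% 10)]) -
               mean(E[seq(n - n %/% 10, n)]))
  expect_lt(drift, 1e-6)
})

test_that("a particle at rest at the minimum stays put", {
  m <- harmonic_model(k = 5, mass = 6, x0 = 0.3)
  cfg <- dynamics_config(dt = 0.5, t_max = 20, termination_gap = 0)
  tr <- run_trajectory(m, c(x = 0.3), c(x = 0), 1, cfg, seed = 1,
                       engine = "r")
  expect_lt(max(abs(tr$positions - 0.3)), 1e-12)
})

test_that("zero gradient gives exactly uniform motion", {
  m <- free_model(mass = 6)
  cfg <- dynamics_config(dt = 0.5, t_max = 50, termination_gap = 0)
  tr <- run_trajectory(m, c(x = -1), c(x = 6 * 0.05), 1, cfg, seed = 1,
                       engine = "r")
  expect_equal(tr$positions[, 1], -1 + 0.05 * tr$times, tolerance = 1e-12)
})

test_that("a stationary electronic state only acquires a phase", {
  n <- 4
  cc <- complex(n); cc[2] <- 1
  E <- c(0, 2, 3, 4)
  out <- electronic_step(cc, E, E, matrix(0, n, n), dt = 0.5,
                         n_substeps = 25, active = 2)
  expect_equal(Mod(out$coeff), Mod(cc), tolerance = 1e-12)
  expect_equal(sum(out$hop_g), 0)
  hbar <- surfhop_constants()$hbar_ev_fs
  expect_equal(Arg(out$coeff[2]), -2 * 0.5 / hbar, tolerance = 1e-9)
})

test_that("electronic propagation is norm-preserving under random couplings", {
  set.seed(99)
  n <- 6
  cc <- complex(real = rnorm(n), imaginary = rnorm(n))
  cc <- cc / sqrt(sum(Mod(cc)^2))
  for (i in 1:1000) {
    Tm <- matrix(rnorm(n * n, sd = 0.02), n)
    Tm <- Tm - t(Tm)
    E1 <- sort(runif(n, 0, 5)); E2 <- E1 + rnorm(n, sd = 0.02)
    cc <- electronic_step(cc, E1, E2, Tm, dt = 0.5, n_substeps = 25,
                          active = 1)$coeff
  }
  expect_equal(sum(Mod(cc)^2), 1, tolerance = 1e-6)
})

test_that("a driven linear sweep reproduces the Landau-Zener population", {
  V <- 0.01; sd <- 1; v <- 0.01
  lz <- build_lz_model(V, sd, 0)
  hbar <- surfhop_constants()$hbar_ev_fs
  dt <- 0.25
  xs <- seq(-2, 2, by = v * dt)
  ad <- adiabatize(lz, c(x = xs[1]))
  cc <- complex(2); cc[2] <- 1            # upper adiabat = diabat 1 at left
  for (i in seq_along(xs)[-1]) {
    ad2 <- adiabatize(lz, c(x = xs[i]), previous_eigenvectors = ad$vectors)
    oc <- overlap_couplings(ad$vectors, ad2$vectors, dt)
    cc <- electronic_step(cc, ad$energies, ad2$energies, oc$T, dt,
                          n_substeps = 25, active = 2)$coeff
    ad <- ad2
  }
  # diabatic passage = ending on the lower adiabat on the right side
  p_lower <- Mod(cc[1])^2
  expect_lt(abs(p_lower - lz_probability(lz, v)), 0.01)
})

test_that("hop decisions respect probabilities and energy conservation", {
  # no couplings: no hop regardless of the draw
  hd <- hop_decision(c(0, 0, 0), 2, c(0, 2, 3), c(x = 0.5), c(x = 6),
                     u = 0.0)
  expect_false(hd$accepted)
  expect_equal(hd$active, 2)
  # target above the available kinetic energy: frustrated, momentum kept
  p <- c(x = 0.05)
  ekin <- 0.5 * 0.05^2 / 6 * surfhop_constants()$ev_per_amuA2fs2
  hd <- hop_decision(c(0, 0, 1), 2, c(0, 2, 2 + ekin * 2), p, c(x = 6),
                     u = 0.0)
  expect_true(hd$frustrated)
  expect_equal(hd$p, p)
  expect_equal(hd$active, 2)
  # allowed downward hop rescales to conserve total energy exactly
  hd <- hop_decision(c(1, 0, 0), 2, c(0.5, 2, 3), p, c(x = 6), u = 0.0)
  expect_true(hd$accepted)
  ekin2 <- 0.5 * sum(hd$p^2 / 6) * surfhop_constants()$ev_per_amuA2fs2
  expect_equal(ekin2 + 0.5, ekin + 2, tolerance = 1e-10)
})

test_that("the surface-switch fraction matches Landau-Zener statistics", {
  V <- 0.05; sd <- 1; mass <- 6
  lz <- build_lz_model(V, sd, 0, mass = mass)
  cfg <- dynamics_config(dt = 0.1, t_max = 25, decoherence = FALSE,
                         termination_gap = 0, forbid_ground_hops = FALSE,
                         record_every = 50L)
  p0 <- mass * 0.1
  ntraj <- 2000
  ics <- lapply(seq_len(ntraj), function(i)
    list(position = c(x = -1), momentum = c(x = p0), state = 1))
  ens <- run_ensemble(ics, lz, dynamics_config(dt = 0.1, t_max = 25,
    decoherence = FALSE, termination_gap = 0, forbid_ground_hops = FALSE,
    record_every = 50L, seed = 77))
  finals <- vapply(ens$trajectories, function(tr)
    tr$active[length(tr$active)], 0L)
  switch_frac <- mean(finals == 2)       # left on the upper surface
  # analytic reference at the crossing velocity from energy conservation
  cst <- surfhop_constants()
  E_lower_start <- adiabatize(lz, c(x = -1))$energies[1]
  E_lower_x0 <- adiabatize(lz, c(x = 0))$energies[1]
  ek0 <- 0.5 * p0^2 / mass * cst$ev_per_amuA2fs2
  vX <- sqrt(2 * (ek0 + E_lower_start - E_lower_x0) /
               cst$ev_per_amuA2fs2 / mass)
  p_lz <- lz_probability(lz, vX)
  se <- sqrt(p_lz * (1 - p_lz) / ntraj)
  expect_lt(abs(switch_frac - p_lz), 3 * se + 0.01)
  # internal consistency: surface fractions track the mean populations
  pop_upper <- mean(vapply(ens$trajectories, function(tr)
    tr$populations[nrow(tr$populations), 2], 0))
  expect_lt(abs(switch_frac - pop_upper), 4 * se + 0.02)
})

test_that("decoherence damps inactive amplitudes and restores the norm", {
  C <- 0.1 * surfhop_constants()$hartree_ev
  hbar <- surfhop_constants()$hbar_ev_fs
  # degenerate states are untouched
  cc <- complex(real = c(sqrt(0.5), sqrt(0.5)))
  out <- apply_decoherence(cc, c(2, 2), active = 1, ekin = 1, dt = 0.5,
                           C = C)
  expect_equal(out, cc, tolerance = 1e-14)
  # independent constants arithmetic: dE = 1 eV, Ekin = 1 eV
  tau <- (hbar / 1) * (1 + C / 1)
  expect_equal(tau, 0.6582119569 * (1 + 2.7211386), tolerance = 1e-9)
  out <- apply_decoherence(cc, c(2, 3), active = 1, ekin = 1, dt = 0.5,
                           C = C)
  expect_equal(Mod(out[2]), sqrt(0.5) * exp(-0.5 / tau), tolerance = 1e-12)
  # norm restored exactly for random inputs
  set.seed(12)
  for (i in 1:20) {
    cc <- complex(real = rnorm(5), imaginary = rnorm(5))
    cc <- cc / sqrt(sum(Mod(cc)^2))
    out <- apply_decoherence(cc, sort(runif(5, 0, 5)), active = 3,
                             ekin = runif(1, 0.01, 2), dt = 0.5, C = C)
    expect_equal(sum(Mod(out)^2), 1, tolerance = 1e-12)
  }
  # zero kinetic energy: infinite lifetimes, no division error
  cc <- complex(real = c(sqrt(0.5), sqrt(0.5)))
  expect_equal(apply_decoherence(cc, c(2, 3), 1, ekin = 0, dt = 0.5, C = C),
               cc)
})

test_that("termination classifies gap closures by manifold", {
  cfg <- dynamics_config()
  out <- check_termination(c(0, 0.14, 3), c("singlet", "singlet", "triplet"),
                           active = 2, t = 10, cfg)
  expect_equal(out$reason, "internal_conversion")
  out <- check_termination(c(0, 0.10, 3), c("singlet", "triplet", "triplet"),
                           active = 2, t = 10, cfg)
  expect_equal(out$reason, "triplet_trapped")
  expect_null(check_termination(c(0, 0.5, 3),
                                c("singlet", "singlet", "triplet"),
                                active = 2, t = 10, cfg))
  out <- check_termination(c(0, 0.5, 3), c("singlet", "singlet", "triplet"),
                           active = 2, t = 1000, cfg)
  expect_equal(out$reason, "timeout")
})

test_that("both engines produce the same trajectory for the same seed", {
  m <- to2()
  nm <- normal_modes(m)
  w <- sample_wigner(nm, 30, seed = 41)
  ic <- select_excitation_window(w, m, seed = 42)
  cfg <- dynamics_config(t_max = 60, seed = 5)
  for (i in 1:2) {
    tr <- run_trajectory(m, ic$positions[i, ], ic$momenta[i, ],
                         ic$conditions$adiabat[i], cfg, seed = 100 + i,
                         engine = "r")
    tc <- run_trajectory(m, ic$positions[i, ], ic$momenta[i, ],
                         ic$conditions$adiabat[i], cfg, seed = 100 + i,
                         engine = "cpp")
    expect_equal(tr$positions, tc$positions, tolerance = 1e-8)
    expect_identical(tr$active, tc$active)
    expect_identical(tr$termination$reason, tc$termination$reason)
    expect_equal(tr$populations, tc$populations, tolerance = 1e-8)
  }
})

test_that("ensembles are reproducible and energy-conserving", {
  m <- to2()
  nm <- normal_modes(m)
  w <- sample_wigner(nm, 40, seed = 51)
  ic <- select_excitation_window(w, m, seed = 52)
  cfg <- dynamics_config(t_max = 150, seed = 6)
  e1 <- run_ensemble(ic, m, cfg)
  e2 <- run_ensemble(ic, m, cfg)
  expect_identical(e1, e2)
  # coefficient norms stay at one and total energy does not drift while
  # the active surface is unchanged (hops and trivial-crossing switches
  # may shift it; accepted-hop rescaling exactness is checked separately)
  for (tr in e1$trajectories[1:5]) {
    expect_lt(max(abs(rowSums(tr$populations) - 1)), 1e-6)
    E <- tr$total_energy; tt <- tr$times
    runs <- rle(tr$active)
    stops <- cumsum(runs$lengths)
    starts <- c(1, head(stops, -1) + 1)
    for (k in seq_along(stops)) {
      seg <- starts[k]:stops[k]
      if (length(seg) > 40) {
        fit <- stats::coef(stats::lm(E[seg] ~ tt[seg]))[2]
        expect_lt(abs(fit), 1e-4)      # eV / fs on one surface
      }
    }
  }
})

test_that("with zero spin-orbit coupling no trajectory reaches a triplet", {
  m <- to2()
  m$soc[] <- 0
  nm <- normal_modes(m)
  w <- sample_wigner(nm, 25, seed = 61)
  ic <- select_excitation_window(w, m, seed = 62)
  cfg <- dynamics_config(t_max = 200, seed = 7)
  ens <- run_ensemble(ic, m, cfg)
  for (tr in ens$trajectories)
    expect_true(all(tr$manifold == "singlet"))
})

test_that("failed trajectories are flagged and counted, not dropped", {
  m <- to2()
  nm <- normal_modes(m)
  w <- sample_wigner(nm, 30, seed = 71)
  ic <- select_excitation_window(w, m, seed = 72)
  good <- lapply(1:8, function(i) list(position = ic$positions[i, ],
                                       momentum = ic$momenta[i, ],
                                       state = ic$conditions$adiabat[i]))
  # two conditions with overflowing momenta blow up the integration
  bad <- lapply(1:2, function(i) list(
    position = ic$positions[i, ],
    momentum = ic$momenta[i, ] * 1e200,
    state = ic$conditions$adiabat[i]))
  ens <- run_ensemble(c(good, bad), m, dynamics_config(t_max = 50, seed = 8))
  expect_length(ens$trajectories, 10)
  expect_equal(sum(vapply(ens$trajectories, function(tr) tr$failed, TRUE)),
               2)
  s <- summarize_ensemble(ens)
  expect_equal(s$excluded, 2)
  expect_equal(s$n, 8)
})
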