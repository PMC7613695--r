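test_that("adiabatization reduces to the diagonal for uncoupled diabats", {
  m <- equal_f_model()           # all couplings zero
  ad <- adiabatize(m, c(x = 0.3))
  ed <- eval_diabatic(m, c(x = 0.3))
  expect_equal(ad$energies, sort(diag(ed$V)), tolerance = 1e-12)
  expect_equal(abs(ad$vectors), diag(3), tolerance = 1e-12)
})

test_that("a two-state crossing splits by exactly twice the coupling", {
  V <- 0.07
  lz <- build_lz_model(coupling = V, slope_difference = 1.2,
                       crossing_position = 0.4)
  ad <- adiabatize(lz, c(x = 0.4))
  expect_equal(diff(ad$energies), 2 * V, tolerance = 1e-12)
})

test_that("eigendecomposition reconstructs a random symmetric potential", {
  set.seed(7)
  n <- 5
  K <- matrix(rnorm(n * n, sd = 0.2), n)
  K <- (K + t(K)) / 2; diag(K) <- 0
  m <- surface_model(
    coords = "x", masses = c(x = 1), reference = c(x = 0),
    states = data.frame(label = paste0("d", 1:n),
                        multiplicity = "singlet", index = 0:(n - 1),
                        character = c("closed-shell", "n_pi*", "pi_pi*",
                                      "pi_sigma*_CO", "pi_sigma*_NH")),
    origins = sort(rnorm(n, 3)), coupling = K,
    soc = matrix(0, n, n), fosc = rep(0, n),
    terms = data.frame(state = 1L, coord = 1L, type = "lin",
                       p1 = 0, p2 = 0, p3 = 0))
  ad <- adiabatize(m, c(x = 0))
  V <- eval_diabatic(m, c(x = 0))$V
  expect_equal(ad$vectors %*% diag(ad$energies) %*% t(ad$vectors), V,
               tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  m <- to2()
  set.seed(11)
  worst <- 0
  for (i in 1:100) {
    q <- m$reference + c(runif(1, -0.15, 0.4), runif(1, -0.1, 0.4),
                         runif(1, -40, 40), runif(1, -0.05, 0.3))
    worst <- max(worst, gradient_check(m, q))
  }
  expect_lt(worst, 1e-6)
  lz <- build_lz_model(0.05, 1, 0)
  expect_lt(gradient_check(lz, c(x = 0.37)), 1e-6)
})

test_that("constructor enforces the coupling block structure", {
  st <- data.frame(label = c("s", "t"),
                   multiplicity = c("singlet", "triplet"), index = c(0L, 0L),
                   character = c("closed-shell", "pi_pi*"))
  tm <- data.frame(state = 1L, coord = 1L, type = "harm",
                   p1 = 1, p2 = 0, p3 = 0)
  # SOC between equal multiplicities is rejected
  expect_error(surface_model("x", c(x = 1), c(x = 0),
    data.frame(label = c("a", "b"), multiplicity = "singlet",
               index = 0:1, character = c("closed-shell", "n_pi*")),
    origins = c(0, 1), coupling = matrix(0, 2, 2),
    soc = matrix(c(0, 0.1, 0.1, 0), 2), fosc = c(0, 0), terms = tm),
    "SOC")
  # diabatic coupling across multiplicities is rejected
  expect_error(surface_model("x", c(x = 1), c(x = 0), st,
    origins = c(0, 1), coupling = matrix(c(0, 0.1, 0.1, 0), 2),
    soc = matrix(0, 2, 2), fosc = c(0, 0), terms = tm),
    "equal multiplicity")
  expect_error(surface_model("x", c(x = -1), c(x = 0), st,
    origins = c(0, 1), coupling = matrix(0, 2, 2),
    soc = matrix(0, 2, 2), fosc = c(0, 0), terms = tm),
    "positive")
})

test_that("adiabatic energies are continuous along a straight-line scan", {
  m <- to2()
  q0 <- m$reference
  q1 <- q0 + c(0.6, 0.3, 40, 0.4)
  fr <- seq(0, 1, length.out = 241)
  E <- t(vapply(fr, function(f)
    adiabatize(m, (1 - f) * q0 + f * q1)$energies, numeric(m$nstates)))
  # bound the jump between neighbours by a coarse local gradient estimate
  step_jumps <- abs(diff(E))
  expect_lt(max(step_jumps), 0.2)
})

test_that("Landau-Zener companion probability obeys its limits", {
  lz <- build_lz_model(coupling = 1e-6, slope_difference = 1)
  expect_gt(lz_probability(lz, 0.05), 0.999)       # uncoupled: diabatic
  lz2 <- build_lz_model(coupling = 0.8, slope_difference = 1)
  expect_lt(lz_probability(lz2, 1e-4), 1e-6)       # adiabatic limit
  expect_error(build_lz_model(coupling = 0, slope_difference = 1))
  expect_error(build_lz_model(coupling = 0.1, slope_difference = 0))
})

test_that("Landau-Zener formula agrees with a numerical TDSE sweep", {
  skip_if_not_installed("deSolve")
  V <- 0.01; sd <- 1; v <- 0.01
  hbar <- surfhop_constants()$hbar_ev_fs
  p_formula <- exp(-2 * pi * V^2 / (hbar * v * sd))
  # independent oracle: integrate the two-state TDSE along x = v t
  rhs <- function(t, y, parms) {
    c1 <- complex(real = y[1], imaginary = y[2])
    c2 <- complex(real = y[3], imaginary = y[4])
    x <- v * t
    d1 <- (-1i / hbar) * (-sd / 2 * x * c1 + V * c2)
    d2 <- (-1i / hbar) * (V * c1 + sd / 2 * x * c2)
    list(c(Re(d1), Im(d1), Re(d2), Im(d2)))
  }
  sol <- deSolve::ode(y = c(1, 0, 0, 0), times = seq(-400, 400, by = 0.5),
                      func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-10)
  fin <- sol[nrow(sol), -1]
  p_stay <- unname(fin[1]^2 + fin[2]^2)
  expect_lt(abs(p_stay - p_formula), 0.01)
  expect_equal(p_stay, lz_probability(build_lz_model(V, sd), v),
               tolerance = 0.02)
})
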