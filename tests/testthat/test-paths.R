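test_that("linear interpolation preserves anchors and averages midpoints", {
  m <- to2()
  a1 <- m$reference
  a2 <- m$reference + c(0.2, 0.1, 20, 0.05)
  prof <- liic_path(m, list(a1, a2), n_per_segment = 1)
  expect_equal(nrow(prof$geometries), 3)
  expect_equal(unname(prof$geometries[1, ]), unname(a1))
  expect_equal(unname(prof$geometries[3, ]), unname(a2))
  expect_equal(unname(prof$geometries[2, ]), unname((a1 + a2) / 2))
  expect_equal(prof$s[1], 0)
  expect_true(all(diff(prof$s) >= 0))
})

test_that("the mass-weighted path length matches hand arithmetic", {
  m <- to2()
  a1 <- m$reference
  a2 <- a1; a2["r_CO"] <- a2["r_CO"] + 0.5
  prof <- liic_path(m, list(a1, a2), n_per_segment = 4)
  expect_equal(max(prof$s), sqrt(6.862) * 0.5, tolerance = 1e-10)
})

test_that("path coordinates are additive under concatenation", {
  m <- to2()
  a <- m$reference
  b <- a + c(0.1, 0.05, 10, 0.02)
  cc <- a + c(0.3, 0.15, 25, 0.06)
  p12 <- liic_path(m, list(a, b), n_per_segment = 3)
  p23 <- liic_path(m, list(b, cc), n_per_segment = 3)
  p123 <- liic_path(m, list(a, b, cc), n_per_segment = 3)
  expect_equal(max(p123$s), max(p12$s) + max(p23$s), tolerance = 1e-10)
  expect_equal(p123$energies[1:nrow(p12$energies), ], p12$energies,
               tolerance = 1e-10)
})

test_that("relaxed scans leave separable orthogonal coordinates untouched", {
  # scan on one side of the seam, where the lower adiabat is a single
  # harmonic diabat with no cross-terms
  m <- cone_model()
  prof <- relaxed_scan(m, "S0", "x", seq(-1.2, -0.4, length.out = 6),
                       start = c(x = -0.5, y = 0.3))
  expect_true(all(prof$converged))
  expect_lt(max(abs(prof$geometries[, "y"] - 0)), 1e-5)
})

test_that("the S1 C-O scan closes the gap monotonically past the barrier", {
  m <- to2()
  vals <- seq(1.43, 2.05, length.out = 18)
  prof <- relaxed_scan(m, "S1", "r_CO", vals,
                       start = m$meta$anchors$s1_min)
  E1 <- prof$energies[, "S1"]; E0 <- prof$energies[, "S0"]
  gap <- E1 - E0
  top <- which.max(E1)
  if (top < length(vals) - 2) {
    after <- gap[top:length(gap)]
    expect_true(all(diff(after) < 1e-6))
  }
  expect_lt(min(gap), 0.2)
  # scan energies dominate the unconstrained surface minimum
  smin <- optimize_minimum(m, "S1", start = m$meta$anchors$s1_min)$energy
  expect_true(all(E1 >= smin - 1e-8))
})

test_that("the penalty MECP optimizer matches a dense grid search", {
  m <- cone_model()
  ref <- cone_grid_mecp(m)
  r <- optimize_mecp(m, c("S1", "S0"), start = c(x = 0, y = 0.2))
  expect_lt(r$gap, 1e-3)
  expect_lt(abs(r$geometry["x"] - ref$x), 1e-2)
  expect_lt(abs(r$geometry["y"] - ref$y), 1e-2)
  expect_lt(abs(r$energy - ref$E), 1e-3 + 0.01)
})

test_that("the optimizer is a fixed point at the seam minimum", {
  m <- cone_model()
  r1 <- optimize_mecp(m, c("S1", "S0"), start = c(x = 0, y = 0.2))
  r2 <- optimize_mecp(m, c("S1", "S0"), start = r1$geometry)
  expect_lt(sum(abs(r2$geometry - r1$geometry)), 1e-3)
  expect_lt(nrow(r2$trace), 4)
})

test_that("the result does not depend on the starting penalty weight", {
  m <- cone_model()
  r1 <- optimize_mecp(m, c("S1", "S0"), start = c(x = 0, y = 0.2),
                      sigma0 = 1)
  r2 <- optimize_mecp(m, c("S1", "S0"), start = c(x = 0, y = 0.2),
                      sigma0 = 20)
  expect_lt(sum(abs(r1$geometry - r2$geometry)), 2e-3)
  expect_lt(abs(r1$energy - r2$energy), 2e-3)
})

test_that("surrogate crossing barriers are recovered by the MECP stack", {
  m <- to2()
  s1min <- optimize_minimum(m, "S1", start = m$meta$anchors$s1_min)
  tilt <- optimize_mecp(m, c("S1", "S0"),
                        start = m$meta$anchors$mecp_s1_tilt,
                        reference_minimum = s1min$energy)
  co <- optimize_mecp(m, c("S1", "S0"),
                      start = m$meta$anchors$mecp_s1_co,
                      reference_minimum = s1min$energy)
  expect_equal(tilt$barrier, 0.3, tolerance = 0.02)
  expect_equal(co$barrier, 0.4, tolerance = 0.02)
  t1min <- optimize_minimum(m, "T1", start = m$meta$anchors$t1_min)
  t1 <- optimize_mecp(m, c("T1", "S0"),
                      start = m$meta$anchors$mecp_t1_tilt,
                      reference_minimum = t1min$energy)
  expect_equal(t1$barrier, 0.2, tolerance = 0.02)
})

test_that("path profiles export cleanly to CSV", {
  m <- to2()
  prof <- liic_path(m, list(m$meta$anchors$s0_min, m$meta$anchors$s1_min),
                    n_per_segment = 4,
                    anchor_labels = c("S0_min", "S1_min"))
  path <- tempfile(fileext = ".csv")
  write_path_profile(prof, path)
  df <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(df), nrow(prof$geometries))
  expect_true(all(c("path_coord_amu05_A", "S0", "S1", "anchor_label")
                  %in% names(df)))
  expect_equal(df$anchor_label[1], "S0_min")
})
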