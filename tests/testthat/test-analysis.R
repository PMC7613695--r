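test_that("initial-state percentages round to the published convention", {
  pct <- initial_state_percentages(c(S2 = 120, S3 = 16, S1 = 5))
  expect_equal(unname(pct[c("S2", "S3", "S1")]), c(85, 11, 4))
  exact <- attr(pct, "exact")
  expect_equal(sum(exact), 1, tolerance = 1e-12)
  expect_error(initial_state_percentages(c(a = 0)), "positive")
})

test_that("population curves start at the initial-state split and sum to one", {
  m <- to2()
  nm <- normal_modes(m)
  w <- sample_wigner(nm, 40, seed = 81)
  ic <- select_excitation_window(w, m, seed = 82)
  ens <- run_ensemble(ic, m, dynamics_config(t_max = 120, seed = 9))
  pop <- adiabatic_populations(ens)
  expect_equal(unname(rowSums(pop[, -1])), rep(1, nrow(pop)),
               tolerance = 1e-12)
  init <- table(vapply(ens$trajectories, function(tr) tr$label[1], ""))
  for (lab in names(init))
    expect_equal(pop[[lab]][1], unname(init[lab]) / sum(init),
                 tolerance = 1e-12)
  # curves are step functions: values change only at recorded events
  expect_true(all(pop[, -1] >= 0 & pop[, -1] <= 1))
})

test_that("terminated trajectories are carried in S0 or T1 afterwards", {
  m <- to2()
  nm <- normal_modes(m)
  w <- sample_wigner(nm, 40, seed = 83)
  ic <- select_excitation_window(w, m, seed = 84)
  ens <- run_ensemble(ic, m, dynamics_config(t_max = 300, seed = 10))
  pop <- adiabatic_populations(ens)
  reasons <- vapply(ens$trajectories, function(tr) tr$termination$reason, "")
  n <- sum(!vapply(ens$trajectories, function(tr) tr$failed, TRUE))
  last <- nrow(pop)
  expect_gte(pop$S0[last], sum(reasons == "internal_conversion") / n - 1e-9)
  expect_gte(pop$T1[last], sum(reasons == "triplet_trapped") / n - 1e-9)
})

test_that("internal coordinates report absolute tilt angles", {
  tr <- fake_trajectory(r_CO = 1.37, r_CS = 1.64, theta = 0, r_NH = 1.01)
  ic <- internal_coordinates(tr)
  expect_equal(unique(ic$r_CO), 1.37)
  expect_equal(unique(ic$r_CS), 1.64)
  expect_equal(unique(ic$theta_tilt), 0)
  trm <- fake_trajectory(theta = -35)
  trp <- fake_trajectory(theta = 35)
  expect_equal(internal_coordinates(trm)$theta_tilt,
               internal_coordinates(trp)$theta_tilt)
  expect_error(internal_coordinates(tr, "bogus"), "available")
})

test_that("dissociative motion is monotone past the last turning point", {
  lz <- build_lz_model(0.05, 1, 0)
  cfg <- dynamics_config(dt = 0.1, t_max = 40, decoherence = FALSE,
                         termination_gap = 0, forbid_ground_hops = FALSE)
  tr <- run_trajectory(lz, c(x = -1), c(x = 0.6), 1, cfg, seed = 3,
                       engine = "cpp")
  p <- tr$momenta[, 1]
  turn <- which(diff(sign(p)) != 0)
  lastturn <- if (length(turn)) max(turn) + 1 else 1
  xs <- tr$positions[lastturn:nrow(tr$positions), 1]
  expect_true(all(diff(xs) * sign(p[length(p)]) > 0))
})

test_that("channels are classified with C-O before N-H precedence", {
  thr <- c(r_CO = 1.8, r_NH = 1.8)
  t1 <- fake_trajectory(r_CO = 1.85, manifold = "singlet")
  expect_equal(classify_channel(t1, thr)$channel, "ring-opening-CO")
  expect_equal(classify_channel(t1, thr)$manifold, "singlet")
  t2 <- fake_trajectory(r_CO = 1.85, r_NH = 2.0)
  expect_equal(classify_channel(t2, thr)$channel, "ring-opening-CO")
  t3 <- fake_trajectory(r_NH = 1.9)
  expect_equal(classify_channel(t3, thr)$channel, "NH-fission")
  t4 <- fake_trajectory(reason = "triplet_trapped", manifold = "triplet")
  expect_equal(classify_channel(t4, thr),
               list(channel = "photostabilising", manifold = "triplet"))
  t5 <- fake_trajectory(reason = "timeout")
  expect_equal(classify_channel(t5, thr)$channel, "other")
  t6 <- fake_trajectory(failed = TRUE)
  expect_equal(classify_channel(t6, thr)$channel, "excluded")
})

test_that("ensemble summaries are exact, order-invariant recounts", {
  trajs <- c(
    replicate(6, fake_trajectory(r_CO = 1.9), simplify = FALSE),
    replicate(3, fake_trajectory(r_NH = 1.95), simplify = FALSE),
    replicate(2, fake_trajectory(), simplify = FALSE),
    list(fake_trajectory(failed = TRUE)))
  ens <- structure(list(trajectories = trajs, seeds = seq_along(trajs),
                        config = dynamics_config()),
                   class = "sh_ensemble")
  s <- summarize_ensemble(ens)
  expect_equal(s$n, 11)
  expect_equal(s$excluded, 1)
  expect_equal(unname(s$counts["ring-opening-CO"]), 6L)
  expect_equal(unname(s$counts["NH-fission"]), 3L)
  expect_equal(unname(s$counts["photostabilising"]), 2L)
  expect_equal(sum(s$fractions), 1, tolerance = 1e-12)
  # independent recount straight over the trajectory list
  manual <- table(vapply(trajs, function(tr)
    classify_channel(tr)$channel, ""))
  expect_equal(unname(s$counts["ring-opening-CO"]),
               unname(manual[["ring-opening-CO"]]))
  # order invariance
  ens2 <- ens; ens2$trajectories <- rev(trajs)
  s2 <- summarize_ensemble(ens2)
  expect_equal(s$counts, s2$counts)
  expect_equal(s$manifold_split, s2$manifold_split)
  # manifold splits add up to the channel counts
  expect_equal(unname(rowSums(s$manifold_split)), unname(s$counts))
})

test_that("a degenerate one-channel ensemble has fraction exactly one", {
  trajs <- replicate(5, fake_trajectory(r_CO = 2.2), simplify = FALSE)
  ens <- structure(list(trajectories = trajs, seeds = 1:5,
                        config = dynamics_config()),
                   class = "sh_ensemble")
  s <- summarize_ensemble(ens)
  expect_equal(unname(s$fractions["ring-opening-CO"]), 1)
})

test_that("channel summaries serialize to JSON", {
  trajs <- c(replicate(3, fake_trajectory(r_CO = 1.9), simplify = FALSE),
             list(fake_trajectory()))
  ens <- structure(list(trajectories = trajs, seeds = 1:4,
                        config = dynamics_config()),
                   class = "sh_ensemble")
  path <- tempfile(fileext = ".json")
  write_channel_summary(summarize_ensemble(ens), path)
  x <- jsonlite::read_json(path)
  expect_equal(x$n, 4)
  ch <- vapply(x$channels, function(c) c$channel, "")
  expect_equal(x$channels[[which(ch == "ring-opening-CO")]]$count, 3)
})
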