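test_that("distance-dependent jump probability follows its analytic form", {
  # at d = d_norm the exponential collapses to theta itself
  expect_equal(transition_probability(1e5, 0.1, 1e5), 0.1 + 0.9 * 0.1,
               tolerance = 1e-12)
  # d = 2 d_norm: theta + (1 - theta) sqrt(theta)
  expect_equal(transition_probability(2e5, 0.1, 1e5), 0.1 + 0.9 * sqrt(0.1),
               tolerance = 1e-12)
  # limits: theta at small d, 1 at large d
  expect_equal(transition_probability(0, 0.1, 1e5), 0.1)
  expect_equal(transition_probability(1e5 / 1e6, 0.1, 1e5), 0.1,
               tolerance = 1e-12)
  expect_lt(abs(transition_probability(1e9 * 1e5, 0.1, 1e5) - 1), 1e-8)
  expect_lt(abs(transition_probability(1e13 * 1e5, 0.1, 1e5) - 1), 1e-12)
  # continuous, strictly increasing where resolvable, bounded by [theta, 1)
  d <- c(10^seq(4, 9, by = 0.25))
  eta <- transition_probability(d, 0.05, 1e5)
  expect_true(all(diff(eta) > 0))
  eta_all <- transition_probability(10^seq(0, 9, by = 0.25), 0.05, 1e5)
  expect_true(all(diff(eta_all) >= 0))
  expect_true(all(eta_all >= 0.05 & eta_all < 1))

  expect_error(transition_probability(100, 1.5, 1e5), "theta")
  expect_error(transition_probability(100, 0.1, -1), "d_norm")
  expect_error(transition_probability(-5, 0.1, 1e5), "non-negative")
})

test_that("heterogeneous transition matrices embed eta(d) per step", {
  grid <- list(levels = c(-1, 0, 1), prior = c(0.25, 0.5, 0.25))
  # zero distances reduce every step to the homogeneous matrix at theta
  mats0 <- build_heterogeneous_transitions(grid, 0.1, 1e5, c(0, 0))
  A0 <- build_transition_matrix(grid, 0.1)
  expect_identical(mats0[[1]], A0)
  expect_identical(mats0[[2]], A0)

  # a huge gap makes the step nearly memoryless: off-diagonals ~ pi_k
  mats <- build_heterogeneous_transitions(grid, 0.1, 1e5, 1000 * 1e5)
  eta_big <- transition_probability(1000 * 1e5, 0.1, 1e5)
  expect_gt(eta_big, 0.99)
  expect_equal(mats[[1]][1, 2], eta_big * 0.5)
  expect_equal(rowSums(mats[[1]]), rep(1, 3))

  # step-eta values from the d_norm and 2 d_norm gaps
  m2 <- build_heterogeneous_transitions(grid, 0.1, 1e5, c(1e5, 2e5))
  expect_equal(m2[[1]][1, 2], 0.19 * 0.5, tolerance = 1e-12)
  expect_equal(m2[[2]][1, 2], (0.1 + 0.9 * sqrt(0.1)) * 0.5,
               tolerance = 1e-12)

  expect_error(build_heterogeneous_transitions(grid, 0.1, 1e5, -4),
               "non-negative")
})

test_that("HSLM on a gapless profile reproduces SLM bit-identically", {
  sim <- simulate_profile(n_altered = 60, total_windows = 3000,
                          noise_sd = 0.25, seed = 31)
  expect_identical(profile_distances(sim$profile), rep(0, 2999))
  a <- hslm_segment(sim$profile, theta = 2e-4)
  b <- slm_segment(sim$profile, eta = 2e-4)
  expect_identical(a$levels, b$levels)
  expect_identical(a$segments, b$segments)
  expect_identical(a$breakpoints, b$breakpoints)
})

test_that("a true shift at a large gap is decoded at the gap", {
  sim <- simulate_sparse_profile(n_altered = 50, total_windows = 500,
                                 noise_sd = 0.2, window_bp = 100,
                                 max_gap = 1e4, seed = 6,
                                 gap_at_breakpoints = 5e4)
  seg <- hslm_segment(sim$profile, theta = 1e-5, d_norm = 1e4)
  d <- breakpoint_distances(seg$breakpoints, sim$truth)$truth_to_pred
  expect_true(all(d == 0))
})

test_that("smaller d_norm does not reduce decoded breakpoints (trend)", {
  dnorms <- c(1e4, 1e5, 1e6)
  counts <- sapply(1:20, function(i) {
    sim <- simulate_sparse_profile(n_altered = 100, total_windows = 2000,
                                   noise_sd = 0.3, max_gap = 1e6,
                                   seed = 7000 + i)
    vapply(dnorms, function(dn)
      length(hslm_segment(sim$profile, theta = 1e-5,
                          d_norm = dn)$breakpoints), numeric(1))
  })
  means <- rowMeans(counts)
  # non-increasing in d_norm, in expectation over seeds (5% slack for
  # discreteness)
  expect_true(means[1] >= 0.95 * means[2])
  expect_true(means[2] >= 0.95 * means[3])
})
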