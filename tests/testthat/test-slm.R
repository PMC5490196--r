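test_that("moment estimator recovers the noise variance and grid", {
  set.seed(1)
  x <- rnorm(10000, 0, 0.2)
  p <- estimate_parameters(x)
  expect_lt(abs(p$mu), 0.01)
  # first-difference MAD scale identifies the white-noise variance
  expect_lt(abs(p$sigma2_eps - 0.04) / 0.04, 0.15)
  expect_equal(p$sigma2_eps / (p$sigma2_eps + p$sigma2_m), p$omega)
  expect_length(p$grid$levels, 41)
  expect_true(all(diff(p$grid$levels) > 0))
  expect_equal(sum(p$grid$prior), 1)
  expect_true(all(p$grid$prior > 0))

  # constant profile is degenerate
  pc <- estimate_parameters(rep(0.3, 100))
  expect_true(pc$degenerate)
  expect_equal(pc$mu, 0.3)

  # noise-free two-level profile: grid brackets both levels
  x2 <- rep(c(-1, 0), each = 500)
  p2 <- estimate_parameters(x2)
  step <- max(diff(p2$grid$levels))
  expect_lt(min(abs(p2$grid$levels - (-1))), step + 1e-12)
  expect_lt(min(abs(p2$grid$levels - 0)), step + 1e-12)
})

test_that("transition matrix embeds the jump process on the level grid", {
  g4 <- list(levels = 1:4, prior = rep(0.25, 4))
  expect_equal(build_transition_matrix(g4, 0), diag(4))
  expect_equal(build_transition_matrix(g4, 1),
               matrix(0.25, 4, 4))
  g2 <- list(levels = c(-1, 0), prior = c(0.5, 0.5))
  expect_equal(build_transition_matrix(g2, 0.1),
               matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2))
  # rows sum to 1 and diagonal dominates for small eta
  set.seed(2)
  pr <- runif(5); pr <- pr / sum(pr)
  A <- build_transition_matrix(list(levels = 1:5, prior = pr), 0.2)
  expect_equal(rowSums(A), rep(1, 5))
  expect_true(all(diag(A) >= 1 - 0.2))
})

test_that("Viterbi decode matches intuition on clean signals", {
  g <- list(levels = c(-1, 0, 0.585), prior = rep(1 / 3, 3))
  path <- viterbi_decode(rep(0, 6), g, eta = 0.1, sigma2_eps = 0.01)
  expect_equal(path, rep(2L, 6))

  g2 <- list(levels = c(-1, 0), prior = c(0.5, 0.5))
  x <- c(0, 0, 0, -1, -1, -1)
  path2 <- viterbi_decode(x, g2, eta = 0.01, sigma2_eps = 0.05^2)
  expect_equal(path2, c(2L, 2L, 2L, 1L, 1L, 1L))
  expect_equal(path2, viterbi_brute(x, g2, 0.01, 0.05^2))

  expect_error(viterbi_decode(x, g2, eta = 0.01, sigma2_eps = 0),
               "positive")
})

test_that("dynamic program equals exhaustive-path argmax on random instances", {
  for (seed in 1:40) {
    inst <- random_viterbi_instance(seed, heterogeneous = seed %% 2 == 0)
    got <- viterbi_decode(inst$x, inst$grid, inst$eta, inst$sigma2_eps)
    want <- viterbi_brute(inst$x, inst$grid, inst$eta, inst$sigma2_eps)
    expect_identical(got, want)
  }
})

test_that("segmentation recovers an embedded event and its invariants hold", {
  sim <- simulate_profile(n_altered = 100, total_windows = 10000,
                          noise_sd = 0.2, seed = 1)
  seg <- slm_segment(sim$profile)
  expect_equal(nrow(seg$segments), 3)
  expect_true(all(abs(seg$breakpoints - sim$truth$breakpoints) <= 2))
  # reported means are empirical window means, not grid levels
  s <- seg$segments
  expect_equal(s$mean_level[2],
               mean(sim$profile$value[s$start[2]:s$end[2]]))
  # partition invariants
  expect_equal(sum(s$n_windows), 10000)
  expect_equal(length(seg$breakpoints) + 1, nrow(s))
  expect_equal(length(seg$levels), 10000)

  # constant profile collapses to one segment
  pc <- genomic_profile("chr1", (0:9) * 10, (1:10) * 10, rep(0.3, 10))
  expect_equal(nrow(slm_segment(pc)$segments), 1)

  # vanishing jump probability keeps a noisy shift-free profile whole
  set.seed(8)
  pn <- genomic_profile("chr1", (0:1999) * 100, (1:2000) * 100,
                        rnorm(2000, 0, 0.3))
  expect_equal(nrow(slm_segment(pn, eta = 1e-12)$segments), 1)
})

test_that("fewer jumps are decoded as eta decreases", {
  sim <- simulate_profile(n_altered = 50, total_windows = 3000,
                          noise_sd = 0.35, seed = 13)
  n_bp <- vapply(10^-(2:7), function(e)
    length(slm_segment(sim$profile, eta = e)$breakpoints), numeric(1))
  expect_true(all(diff(n_bp) <= 0))
})

test_that("segmentation is equivariant under a constant shift", {
  sim <- simulate_profile(n_altered = 80, total_windows = 2000,
                          noise_sd = 0.2, seed = 21)
  seg <- slm_segment(sim$profile)
  shifted <- sim$profile
  shifted$value <- shifted$value + 0.35
  seg2 <- slm_segment(shifted)
  expect_identical(seg2$breakpoints, seg$breakpoints)
  expect_equal(seg2$segments$mean_level, seg$segments$mean_level + 0.35,
               tolerance = 1e-12)
})

test_that("short segments merge into the closer-mean neighbour", {
  set.seed(4)
  x <- c(rnorm(20, 0, 0.05), rnorm(2, -1, 0.05), rnorm(20, 0, 0.05))
  p <- genomic_profile("chr1", (0:41) * 100, (1:42) * 100, x)
  seg <- slm_segment(p, eta = 1e-3)
  expect_equal(nrow(seg$segments), 3)
  # absorbing the 2-window event into a neighbour leaves two segments whose
  # means are recomputed from the pooled windows
  merged <- slm_segment(p, eta = 1e-3, min_seg_windows = 5)
  s <- merged$segments
  expect_equal(nrow(s), 2)
  expect_true(all(s$n_windows >= 5))
  expect_equal(s$mean_level,
               vapply(seq_len(2), function(i) mean(x[s$start[i]:s$end[i]]),
                      numeric(1)))
})

test_that("CNV calling thresholds and merges segments", {
  mk <- function(vals, seed = 2) {
    set.seed(seed)
    x <- rep(vals, each = 10) + rnorm(10 * length(vals), 0, 0.02)
    genomic_profile("chr1", (seq_along(x) - 1) * 1000,
                    seq_along(x) * 1000, x)
  }
  p <- mk(c(-0.9, 0.02, 0.55))
  seg <- slm_segment(p)
  expect_equal(nrow(seg$segments), 3)
  calls <- call_cnvs(seg, p)
  expect_equal(calls$copy_state, c("LOSS", "GAIN"))
  expect_equal(calls$start, c(0, 20000))

  # all-neutral segmentation yields no calls
  pn <- mk(c(0.02, -0.1))
  expect_equal(nrow(call_cnvs(slm_segment(pn), pn)), 0)

  # adjacent same-state altered segments merge into one call
  pl <- mk(c(-0.8, -1.1, 0))
  segl <- slm_segment(pl)
  expect_equal(nrow(segl$segments), 3)
  cl <- call_cnvs(segl, pl)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$copy_state, "LOSS")
  expect_equal(cl$start, 0)
  expect_equal(cl$end, 20000)
  expect_equal(cl$mean_level, mean(pl$value[1:20]))

  expect_error(call_cnvs(seg, p, loss_threshold = 0.1), "loss")
})
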