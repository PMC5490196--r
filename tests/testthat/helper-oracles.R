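# Brute-force Viterbi oracle: enumerate all K^N state paths, score each in
# the same left-to-right order as the dynamic program, and break score ties
# by the reverse-lexicographically smallest path (last state first) —
# the tie-break the decoder documents.
viterbi_brute <- function(x, grid, eta, sigma2_eps) {
  n <- length(x)
  K <- length(grid$levels)
  sd <- sqrt(sigma2_eps)
  emis <- vapply(grid$levels, function(l) dnorm(x, mean = l, sd = sd, log = TRUE),
                 numeric(n))
  if (n == 1) emis <- matrix(emis, nrow = 1)
  lA <- if (length(eta) == 1)
    rep(list(log(build_transition_matrix(grid, eta))), n - 1)
  else lapply(eta, function(e) log(build_transition_matrix(grid, e)))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  scores <- log(grid$prior)[paths[, 1]] + emis[cbind(1L, paths[, 1])]
  if (n >= 2) {
    for (i in 2:n) {
      scores <- scores + lA[[i - 1]][cbind(paths[, i - 1], paths[, i])]
      scores <- scores + emis[cbind(i, paths[, i])]
    }
  }
  cand <- which(scores == max(scores))
  cp <- paths[cand, , drop = FALSE]
  ord <- do.call(order, as.data.frame(cp[, n:1, drop = FALSE]))
  as.integer(unname(cp[ord[1], ]))
}

# random small decoding instance; heterogeneous = per-step eta vector
random_viterbi_instance <- function(seed, heterogeneous = FALSE) {
  set.seed(seed)
  n <- sample(2:8, 1)
  K <- sample(2:4, 1)
  levels <- sort(rnorm(K, 0, 1))
  prior <- runif(K, 0.1, 1)
  prior <- prior / sum(prior)
  eta <- if (heterogeneous) runif(n - 1, 1e-4, 0.5) else runif(1, 1e-4, 0.5)
  list(x = rnorm(n, sample(levels, 1), 0.5),
       grid = list(levels = levels, prior = prior),
       eta = eta,
       sigma2_eps = runif(1, 0.05, 1))
}

# dense simulated profiles for evaluation tests
make_profiles <- function(n, n_altered, noise_sd, seed0, total = 10000) {
  lapply(seq_len(n), function(i)
    simulate_profile(n_altered = n_altered, total_windows = total,
                     noise_sd = noise_sd, seed = seed0 + i))
}
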