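# Shared fixtures and independent oracles, built in code at test time.

# Hand-built two-session table: 3 participants x 2 items, exactly 2
# discordant pairs out of 6 (p1/i2 yes->no, p3/i1 yes->unknown).
toy_two_session_table <- function() {
  response_table(
    participant = rep(c("p1", "p2", "p3"), each = 4),
    category = "Fish",
    item = rep(c("i1", "i2"), times = 6),
    session = rep(c(1L, 1L, 2L, 2L), times = 3),
    response = c(
      "yes", "yes", "yes", "no",      # p1: i2 flips
      "no",  "no",  "no",  "no",      # p2: consistent
      "yes", "no",  "unknown", "no"   # p3: i1 yes -> unknown
    )
  )
}

# A small, fully specified 2-group parameter state.
toy_params <- function(P = 3L, I = 3L, seed = 11L) {
  set.seed(seed)
  model_parameters(
    pi = c(0.4, 0.6),
    z = rep_len(c(1L, 2L), P),
    beta = matrix(rnorm(2 * I), 2, I),
    theta = rnorm(P),
    mu = c(-0.3, 0.4),
    alpha = c(1.5, 0.8)
  )
}

# Brute-force oracle: total probability of all 2^(P*I) response matrices
# under a fixed parameter state, by direct enumeration.
enumerate_total_probability <- function(params, P, I) {
  total <- 0
  n_cells <- P * I
  for (k in 0:(2^n_cells - 1)) {
    bits <- as.integer(intToBits(k))[seq_len(n_cells)]
    x <- matrix(bits, P, I)
    total <- total + exp(complete_loglik(params, x))
  }
  total
}

# Independent term-by-term log-prior oracle, written against the density
# functions directly (uniform Dirichlet constant, half-normal as folded
# standard normal, unit-variance normals, categorical mass).
oracle_log_prior <- function(p) {
  G <- p$G
  dirichlet_const <- lgamma(G)           # log (G-1)!
  halfn <- sum(log(2 * exp(-p$alpha^2 / 2) / sqrt(2 * pi)))
  betas <- sum(-p$beta^2 / 2 - log(sqrt(2 * pi)))
  mus <- sum(-p$mu^2 / 2 - log(sqrt(2 * pi)))
  thetas <- sum(-(p$theta - p$mu[p$z])^2 / 2 - log(sqrt(2 * pi)))
  zmass <- sum(log(p$pi[p$z]))
  dirichlet_const + halfn + betas + mus + thetas + zmass
}

# Reduced simulation configuration for fast MCMC unit tests.
small_sim_config <- function(seed = 5L, ...) {
  sim_config(n_participants = 20L, n_archival = 40L, n_items = 10L,
             seed = seed, ...)
}

# Best-permutation label matching between estimated and true groups for
# G = 2; returns the permutation as an integer vector.
match_labels_2g <- function(est_z, true_z) {
  if (mean(est_z == true_z) >= mean((3L - est_z) == true_z)) c(1L, 2L) else c(2L, 1L)
}

# Pooled posterior-mean of a draw block across chains.
pooled_mean <- function(s, block) {
  Reduce(`+`, lapply(s$chains, function(d) colMeans(d[[block]]))) / s$n_chains
}
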