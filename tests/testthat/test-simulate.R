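# Likelihood-based oracle classifier: assigns each respondent-session to
# the criterion group maximizing the marginal likelihood of their response
# row, integrating the threshold over its hyper-distribution by a grid.
# Independent of the MCMC machinery.
oracle_classify <- function(x_row, beta, mu, alpha, pi) {
  grid <- seq(-4, 4, length.out = 81)
  w <- dnorm(grid)
  vapply(seq_len(nrow(beta)), function(g) {
    th <- mu[g] + grid
    ll <- vapply(seq_along(th), function(j) {
      eta <- alpha * (beta[g, ] - th[j])
      cell <- x_row * plogis(eta, log.p = TRUE) +
        (1 - x_row) * plogis(-eta, log.p = TRUE)
      sum(cell[!is.na(x_row)])
    }, numeric(1))
    log(pi[g]) + log(sum(w * exp(ll - max(ll)))) + max(ll)
  }, numeric(1))
}

oracle_detected_changes <- function(truth, cfg) {
  m <- merge_sessions(truth$table, NULL, cfg$category)
  ids <- unique(truth$table$participant)
  bt <- truth$params_session1$beta
  g_of <- function(session) {
    vapply(ids, function(p) {
      row <- m$x[paste0(p, ".s", session), ]
      which.max(oracle_classify(row, bt, cfg$mu, cfg$alpha[1], cfg$pi))
    }, integer(1))
  }
  mean(g_of(1) != g_of(2))
}

test_that("population sampling is deterministic and respects the mixture", {
  cfg <- small_sim_config(seed = 12L)
  p1 <- sample_population(cfg)
  p2 <- sample_population(cfg)
  expect_identical(p1, p2)

  degenerate <- sim_config(n_participants = 30L, n_archival = 0L,
                           n_items = 6L, pi = c(1, 0), switch_fraction = 0,
                           seed = 4L)
  expect_true(all(sample_population(degenerate)$z == 1L))

  big <- sim_config(n_participants = 4000L, n_archival = 0L, n_items = 4L,
                    mu = c(-1, 1), switch_fraction = 0, seed = 9L)
  pop <- sample_population(big)
  for (g in 1:2) {
    th <- pop$theta[pop$z == g]
    se <- 1 / sqrt(length(th))
    expect_lt(abs(mean(th) - big$mu[g]), 3 * se)
  }
})

test_that("invalid configurations report all violations at once", {
  err <- tryCatch(sim_config(G = 1L, pi = 1, mu = 0, alpha = 1,
                             switch_fraction = 0.5, unknown_rate = 2),
                  error = conditionMessage)
  expect_match(err, "unknown_rate")
  expect_match(err, "switch_fraction > 0 requires G >= 2")
})

test_that("session generation follows the response model", {
  # beta == theta everywhere: long-run yes-proportion near .5
  cfg <- sim_config(n_participants = 400L, n_archival = 0L, n_items = 10L,
                    beta = matrix(0, 2, 10), mu = c(0, 0),
                    switch_fraction = 0, unknown_rate = 0, seed = 14L)
  pop <- sample_population(cfg)
  pop$theta[] <- 0
  tab <- generate_session(pop, 1L, cfg)
  expect_equal(mean(tab$response == "yes"), 0.5, tolerance = 0.02)

  # near-step steepness with beta - theta = +2: all yes
  cfg2 <- sim_config(n_participants = 50L, n_archival = 0L, n_items = 5L,
                     beta = matrix(2, 2, 5), alpha = c(500, 500),
                     mu = c(0, 0), switch_fraction = 0, unknown_rate = 0,
                     seed = 15L)
  pop2 <- sample_population(cfg2)
  pop2$theta[] <- 0
  tab2 <- generate_session(pop2, 1L, cfg2)
  expect_true(all(tab2$response == "yes"))
})

test_that("unknown contamination count lies in its binomial 99% interval", {
  cfg <- sim_config(n_participants = 1000L, n_archival = 0L, n_items = 10L,
                    unknown_rate = 0.05, switch_fraction = 0, seed = 16L)
  pop <- sample_population(cfg)
  tab <- generate_session(pop, 1L, cfg)
  n_unknown <- sum(tab$response == "unknown")
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.05)
  expect_gte(n_unknown, bounds[1])
  expect_lte(n_unknown, bounds[2])
})

test_that("two-session study honors switcher bookkeeping", {
  cfg <- small_sim_config(seed = 18L)
  truth <- generate_two_session_study(cfg)
  expect_s3_class(validate_response_table(truth$table), "response_table")
  expect_equal(length(truth$switcher_ids),
               round(cfg$switch_fraction * cfg$n_participants))
  ids <- unique(truth$table$participant)
  sw <- ids %in% truth$switcher_ids
  expect_true(all(truth$params_session1$z[sw] != truth$params_session2$z[sw]))
  expect_true(all(truth$params_session1$z[!sw] == truth$params_session2$z[!sw]))

  all_switch <- generate_two_session_study(
    small_sim_config(seed = 19L, switch_fraction = 1))
  expect_equal(length(all_switch$switcher_ids), 20L)

  expect_error(sim_config(G = 1L, pi = 1, mu = 0, alpha = 1,
                          switch_fraction = 0.5), "requires G >= 2")
})

test_that("without switching or drift, disagreement matches 2p(1-p)", {
  cfg <- sim_config(n_participants = 200L, n_archival = 0L, n_items = 24L,
                    switch_fraction = 0, redraw_thresholds = FALSE,
                    unknown_rate = 0, seed = 22L)
  truth <- generate_two_session_study(cfg)
  p <- truth$params_session1
  pr <- response_probability(p$beta[p$z, , drop = FALSE], p$theta,
                             p$alpha[p$z])
  expected <- mean(2 * pr * (1 - pr))    # closed-form Bernoulli disagreement
  realized <- build_consistency_report(
    truth$table, c(synthetic = "nominal"))$overall
  expect_equal(realized, expected, tolerance = 0.15)
  expect_lt(abs(realized - expected), 0.02)
})

test_that("detected criterion-change rate increases with switch_fraction", {
  rates <- vapply(c(0, 0.25, 0.5, 1), function(f) {
    mean(vapply(1:2, function(s) {
      cfg <- sim_config(n_participants = 24L, n_archival = 0L,
                        n_items = 16L, switch_fraction = f,
                        seed = 500L + s)
      oracle_detected_changes(generate_two_session_study(cfg), cfg)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("archival generation shares criteria and is deterministic", {
  cfg <- small_sim_config(seed = 25L)
  pop <- sample_population(cfg)
  a1 <- generate_archival(cfg, params = pop)
  a2 <- generate_archival(cfg, params = pop)
  expect_identical(a1, a2)
  expect_equal(nrow(a1$table), cfg$n_archival * cfg$n_items)
  expect_equal(a1$params$beta, pop$beta)
  expect_true(all(a1$table$session == 1L))
  expect_true(all(a1$table$provenance == "archival"))

  none <- sim_config(n_archival = 0L, seed = 26L)
  expect_equal(nrow(generate_archival(none)$table), 0L)
})
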