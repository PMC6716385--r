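#' Configuration for the two-session simulation
#'
#' Describes a synthetic two-session categorization study with the same
#' statistical structure the mixture model assumes: a population split
#' into `G` latent criterion groups with group-specific item scales,
#' normally distributed thresholds around group means (unit variance), an
#' S-shaped response function, and — between the two sessions — a
#' controlled minority of participants who switch criterion group plus
#' optional threshold drift for everyone else. A configurable fraction of
#' cells is replaced by `unknown` (missing completely at random).
#'
#' The defaults mirror the dimensions and conditions of a two-session
#' study with archival augmentation: 60 two-session participants plus 250
#' archival respondents on 24 items (370 entries), two equally likely
#' groups with threshold means -0.5 and +0.5, group item scales i.i.d.
#' standard normal constructed with between-group correlation 0.3, a 20%
#' criterion-switch fraction, mild threshold drift for non-switchers
#' (persistence 0.95), a 2% unknown rate, and steepness 6 in both groups
#' (fairly deterministic responding, so that clear members are answered
#' consistently). Under these defaults the realized two-session response
#' inconsistency averages roughly 20%, in the range typically observed in
#' repeated categorization studies.
#'
#' @param n_participants number of two-session participants.
#' @param n_archival number of single-session archival respondents.
#' @param n_items number of items in the category.
#' @param G number of latent criterion groups.
#' @param pi mixing probabilities (simplex of length `G`).
#' @param mu group threshold means (length `G`).
#' @param alpha group steepness values (length `G`, positive).
#' @param beta optional explicit `G x I` item-scale matrix; if `NULL`,
#'   rows are drawn i.i.d. standard normal and, for `G = 2`, rotated so the
#'   empirical between-group correlation equals `beta_cor`.
#' @param beta_cor target between-group correlation of generated item
#'   scales (used only when `beta` is `NULL` and `G = 2`).
#' @param switch_fraction fraction of two-session participants whose
#'   criterion group changes in session 2 (`round(switch_fraction *
#'   n_participants)` switchers).
#' @param redraw_thresholds if `TRUE`, non-switchers' thresholds drift
#'   between sessions (see `theta_persistence`); if `FALSE` their
#'   thresholds carry over exactly and sessions differ only by response
#'   noise.
#' @param theta_persistence session-to-session threshold correlation for
#'   non-switchers when `redraw_thresholds = TRUE`: session 2 uses the
#'   stationary autoregressive step
#'   `theta2 = mu + rho * (theta1 - mu) + sqrt(1 - rho^2) * eps`, which
#'   keeps thresholds marginally `Normal(mu[z], 1)` in both sessions.
#'   `0` is a fully independent redraw; values near 1 give the mild degree
#'   drift expected over a retest interval.
#' @param unknown_rate probability that any response is replaced by
#'   `unknown`.
#' @param category category id used in generated tables.
#' @param seed master seed for all randomness in the generators.
#' @return a validated object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 60L, n_archival = 250L,
                       n_items = 24L, G = 2L,
                       pi = c(0.5, 0.5), mu = c(-0.5, 0.5),
                       alpha = c(6, 6), beta = NULL, beta_cor = 0.3,
                       switch_fraction = 0.2, redraw_thresholds = TRUE,
                       theta_persistence = 0.95,
                       unknown_rate = 0.02, category = "synthetic",
                       seed = 1L) {
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    n_archival = as.integer(n_archival), n_items = as.integer(n_items),
    G = as.integer(G), pi = as.numeric(pi), mu = as.numeric(mu),
    alpha = as.numeric(alpha), beta = beta, beta_cor = beta_cor,
    switch_fraction = switch_fraction,
    redraw_thresholds = isTRUE(redraw_thresholds),
    theta_persistence = theta_persistence,
    unknown_rate = unknown_rate, category = as.character(category),
    seed = as.integer(seed)
  ), class = "sim_config")
  errs <- sim_config_errors(cfg)
  if (length(errs)) {
    stop("invalid simulation config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg
}

## All violations at once, for actionable error messages.
sim_config_errors <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(cfg$n_participants >= 0, "n_participants must be >= 0")
  chk(cfg$n_archival >= 0, "n_archival must be >= 0")
  chk(cfg$n_items >= 1, "n_items must be >= 1")
  chk(cfg$G >= 1, "G must be >= 1")
  chk(length(cfg$pi) == cfg$G, "pi must have length G")
  chk(abs(sum(cfg$pi) - 1) < 1e-8 && all(cfg$pi >= 0),
      "pi must be a simplex (non-negative, summing to 1)")
  chk(length(cfg$mu) == cfg$G, "mu must have length G")
  chk(length(cfg$alpha) == cfg$G && all(cfg$alpha > 0),
      "alpha must have length G and be strictly positive")
  chk(cfg$switch_fraction >= 0 && cfg$switch_fraction <= 1,
      "switch_fraction must lie in [0, 1]")
  chk(cfg$unknown_rate >= 0 && cfg$unknown_rate <= 1,
      "unknown_rate must lie in [0, 1]")
  chk(cfg$theta_persistence >= 0 && cfg$theta_persistence <= 1,
      "theta_persistence must lie in [0, 1]")
  chk(!(cfg$switch_fraction > 0 && cfg$G < 2),
      "switch_fraction > 0 requires G >= 2")
  if (!is.null(cfg$beta)) {
    chk(is.matrix(cfg$beta) && nrow(cfg$beta) == cfg$G &&
          ncol(cfg$beta) == cfg$n_items,
        "explicit beta must be a G x n_items matrix")
  } else {
    chk(abs(cfg$beta_cor) <= 1, "beta_cor must lie in [-1, 1]")
  }
  errs
}

## Group item scales: i.i.d. N(0, 1) rows; for G = 2 the second row is
## rebuilt from the first plus an orthogonalized residual so the empirical
## correlation equals beta_cor exactly.
sample_beta <- function(cfg) {
  if (!is.null(cfg$beta)) return(cfg$beta)
  I <- cfg$n_items
  beta <- matrix(stats::rnorm(cfg$G * I), cfg$G, I)
  if (cfg$G == 2L && I >= 3L) {
    b1 <- as.numeric(scale(beta[1, ]))
    e <- stats::residuals(stats::lm(beta[2, ] ~ beta[1, ]))
    e <- as.numeric(scale(e))
    beta[2, ] <- cfg$beta_cor * b1 + sqrt(1 - cfg$beta_cor^2) * e
  }
  beta
}

#' Draw a population state from the generative model
#'
#' Samples group memberships `z ~ Categorical(pi)` and thresholds
#' `theta ~ Normal(mu[z], 1)` for `n_participants` respondents, together
#' with the item-scale matrix described by the configuration. The result
#' is a complete [model_parameters] state usable as simulation ground
#' truth.
#'
#' @param cfg a [sim_config].
#' @param seed seed (defaults to `cfg$seed`); identical seeds give
#'   identical populations.
#' @param n number of respondents (defaults to `cfg$n_participants`).
#' @param beta optional item-scale matrix to reuse (so that several
#'   populations share the same criteria).
#' @return a [model_parameters] state with one entry per respondent.
#' @export
sample_population <- function(cfg, seed = cfg$seed, n = cfg$n_participants,
                              beta = NULL) {
  errs <- sim_config_errors(cfg)
  if (length(errs)) {
    stop("invalid simulation config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  set.seed(seed)
  if (is.null(beta)) beta <- sample_beta(cfg)
  z <- sample.int(cfg$G, n, replace = TRUE, prob = cfg$pi)
  theta <- stats::rnorm(n, mean = cfg$mu[z], sd = 1)
  model_parameters(pi = cfg$pi, z = z, beta = beta, theta = theta,
                   mu = cfg$mu, alpha = cfg$alpha)
}

#' Generate one session of categorization responses
#'
#' Each (respondent, item) cell is a Bernoulli draw with success
#' probability [response_probability()] evaluated at the respondent's
#' group item scale, threshold, and group steepness; afterwards each cell
#' is independently replaced by `unknown` with probability
#' `cfg$unknown_rate`.
#'
#' @param params a [model_parameters] state (one entry per respondent).
#' @param session session index recorded in the output (1 or 2).
#' @param cfg the [sim_config] (supplies item count, category id, unknown
#'   rate).
#' @param participant_ids ids for the respondents (defaults to
#'   `p1, p2, ...`).
#' @param provenance provenance recorded in the output table.
#' @param seed seed (defaults to `cfg$seed + 100 * session`).
#' @return a [response_table] with one record per respondent x item.
#' @export
generate_session <- function(params, session, cfg,
                             participant_ids = NULL,
                             provenance = "synthetic",
                             seed = cfg$seed + 100L * as.integer(session)) {
  validate_model_parameters(params)
  set.seed(seed)
  n <- length(params$z); I <- ncol(params$beta)
  if (is.null(participant_ids)) participant_ids <- paste0("p", seq_len(n))
  items <- item_labels(I)
  pr <- response_probability(params$beta[params$z, , drop = FALSE],
                             params$theta, params$alpha[params$z])
  yes <- matrix(stats::runif(n * I) < pr, n, I)
  resp <- ifelse(yes, "yes", "no")
  unk <- matrix(stats::runif(n * I) < cfg$unknown_rate, n, I)
  resp[unk] <- "unknown"
  response_table(
    participant = rep(participant_ids, times = I),
    category = cfg$category,
    item = rep(items, each = n),
    session = as.integer(session),
    response = as.character(resp),
    provenance = provenance
  )
}

item_labels <- function(I) sprintf("item%03d", seq_len(I))

#' Generate a complete two-session study with known ground truth
#'
#' Builds session 1 from a freshly sampled population, then constructs
#' session 2 by (a) flipping the criterion group of a random set of
#' `round(switch_fraction * n_participants)` switchers, whose thresholds
#' are redrawn from the new group's hyper-distribution (a criterion change
#' plausibly resets the threshold's frame of reference), and (b) for
#' non-switchers, applying the stationary threshold drift controlled by
#' `theta_persistence` (`redraw_thresholds = TRUE`) or keeping thresholds
#' fixed, in which case the sessions differ only by response noise.
#' Optionally an independent archival population sharing the same
#' item scales, mixing probabilities and hyper-parameters is generated.
#'
#' @param cfg a [sim_config].
#' @return an object of class `simulation_truth`: a list with
#'   `params_session1`, `params_session2`, `params_archival` (or `NULL`),
#'   `switcher_ids`, `table` (both sessions, provenance `synthetic`),
#'   `archival_table` (provenance `archival`, or `NULL`), and `config`.
#' @export
generate_two_session_study <- function(cfg) {
  errs <- sim_config_errors(cfg)
  if (length(errs)) {
    stop("invalid simulation config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  p1 <- sample_population(cfg, seed = cfg$seed)
  n <- cfg$n_participants
  ids <- paste0("p", seq_len(n))

  set.seed(cfg$seed + 17L)
  n_switch <- round(cfg$switch_fraction * n)
  switchers <- sort(sample(ids, n_switch))
  sw <- ids %in% switchers

  z2 <- p1$z
  theta2 <- p1$theta
  if (n_switch > 0) {
    ## switchers move to a uniformly chosen other group; their threshold is
    ## redrawn from the new group's hyper-distribution
    z2[sw] <- vapply(p1$z[sw], function(g) {
      others <- setdiff(seq_len(cfg$G), g)
      if (length(others) == 1L) others else sample(others, 1L)
    }, integer(1))
    theta2[sw] <- stats::rnorm(n_switch, mean = cfg$mu[z2[sw]], sd = 1)
  }
  if (cfg$redraw_thresholds && any(!sw)) {
    ## stationary degree drift: marginally Normal(mu, 1) in both sessions
    rho <- cfg$theta_persistence
    ns <- !sw
    theta2[ns] <- cfg$mu[z2[ns]] + rho * (p1$theta[ns] - cfg$mu[p1$z[ns]]) +
      sqrt(1 - rho^2) * stats::rnorm(sum(ns))
  }
  p2 <- model_parameters(pi = cfg$pi, z = z2, beta = p1$beta,
                         theta = theta2, mu = cfg$mu, alpha = cfg$alpha)

  t1 <- generate_session(p1, 1L, cfg, participant_ids = ids,
                         seed = cfg$seed + 100L)
  t2 <- generate_session(p2, 2L, cfg, participant_ids = ids,
                         seed = cfg$seed + 200L)
  tab <- rbind(as.data.frame(t1), as.data.frame(t2))
  tab <- validate_response_table(
    structure(tab, class = c("response_table", "data.frame")))

  arch <- NULL; arch_params <- NULL
  if (cfg$n_archival > 0) {
    g <- generate_archival(cfg, params = p1)
    arch <- g$table
    arch_params <- g$params
  }

  structure(list(params_session1 = p1, params_session2 = p2,
                 params_archival = arch_params,
                 switcher_ids = switchers, table = tab,
                 archival_table = arch, config = cfg),
            class = "simulation_truth")
}

#' Generate single-session archival respondents
#'
#' Samples an independent population of `cfg$n_archival` respondents with
#' the same item scales, mixing probabilities, threshold means and
#' steepness as the study population (fresh `z` and `theta`), and one
#' session of responses, labeled provenance `archival`.
#'
#' @param cfg a [sim_config].
#' @param params optional [model_parameters] whose `beta` is reused so the
#'   archival respondents answer under the same criteria; if `NULL` the
#'   item scales are drawn from the configuration recipe.
#' @param seed seed (defaults to `cfg$seed + 1000`).
#' @return a list with `table` (a [response_table]) and `params` (the
#'   archival ground truth); `table` is empty when `n_archival = 0`.
#' @export
generate_archival <- function(cfg, params = NULL, seed = cfg$seed + 1000L) {
  errs <- sim_config_errors(cfg)
  if (length(errs)) {
    stop("invalid simulation config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  if (cfg$n_archival == 0L) {
    empty <- response_table(character(0), character(0), character(0),
                            integer(0), character(0), character(0))
    return(list(table = empty, params = NULL))
  }
  beta <- if (!is.null(params)) params$beta else NULL
  ap <- sample_population(cfg, seed = seed, n = cfg$n_archival, beta = beta)
  ids <- paste0("a", seq_len(cfg$n_archival))
  tab <- generate_session(ap, 1L, cfg, participant_ids = ids,
                          provenance = "archival", seed = seed + 1L)
  list(table = tab, params = ap)
}

#' Ground-truth group per merged-matrix entry
#'
#' Looks up, for every entry of a merged matrix built from a simulated
#' study, the criterion group that actually generated it: session-1
#' entries use the session-1 memberships, session-2 entries the (possibly
#' switched) session-2 memberships, and archival entries the archival
#' population's memberships. Useful for parameter-recovery checks against
#' [assign_groups()] output.
#'
#' @param truth a `simulation_truth` from [generate_two_session_study()].
#' @param m the `merged_matrix` built from `truth$table` (and
#'   `truth$archival_table`).
#' @return integer vector of true group indices, one per entry of `m`.
#' @export
truth_entry_groups <- function(truth, m) {
  stopifnot(inherits(truth, "simulation_truth"), inherits(m, "merged_matrix"))
  ei <- m$entry_index
  study_ids <- unique(truth$table$participant)
  arch_ids <- if (!is.null(truth$archival_table)) {
    unique(truth$archival_table$participant)
  } else character(0)
  vapply(seq_len(nrow(ei)), function(r) {
    p <- ei$participant[r]
    if (ei$provenance[r] == "archival") {
      truth$params_archival$z[match(p, arch_ids)]
    } else if (ei$session[r] == 1L) {
      truth$params_session1$z[match(p, study_ids)]
    } else {
      truth$params_session2$z[match(p, study_ids)]
    }
  }, integer(1))
}
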