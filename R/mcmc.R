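#' Fit the criterion-group mixture model by MCMC
#'
#' Samples the posterior of the mixture model (see [model_parameters] for
#' the generative structure) on a merged response matrix. The sampler is a
#' Metropolis-within-Gibbs scheme:
#'
#' * group indicators `z_p`: exact Gibbs from their conditional categorical
#'   distribution (mixing weight x threshold hyper-density x row
#'   likelihood, computable in closed form);
#' * mixing probabilities `pi`: conjugate Dirichlet update given the group
#'   counts;
#' * group threshold means `mu_g`: conjugate normal update given the
#'   members' thresholds;
#' * item scales `beta[g, i]` and thresholds `theta_p`: elementwise
#'   random-walk Metropolis (their likelihood contributions factorize, so
#'   all proposals in a block are accepted or rejected independently);
#' * steepness `alpha_g`: random-walk Metropolis on the log scale, with the
#'   log-normal proposal's Jacobian in the acceptance ratio.
#'
#' Random-walk step sizes are adapted toward an acceptance rate of ~0.4 in
#' batches during burn-in only, so the post-burn-in chain is a fixed
#' Markov kernel. Chains are run sequentially with per-chain seeds derived
#' deterministically from `seed`; identical calls give identical draws.
#'
#' @param m a `merged_matrix` from [merge_sessions()] (or a bare 0/1/`NA`
#'   matrix).
#' @param G number of latent criterion groups (>= 2; default 2, the
#'   configuration used throughout the package).
#' @param n_chains number of independent chains (default 3).
#' @param n_iter total iterations per chain, including burn-in
#'   (default 10000).
#' @param n_burnin burn-in iterations discarded from each chain
#'   (default 4000).
#' @param seed master seed; chain `c` uses `seed + c - 1`.
#' @param allow_all_missing normally a matrix with no observed cell is
#'   rejected as degenerate; set `TRUE` to sample anyway (the posterior is
#'   then the prior, which is useful for prior-recovery checks).
#' @param verbose print per-chain progress.
#' @return an object of class `posterior_samples`: post-burn-in draws per
#'   chain (matrices with canonical column names `pi.g`, `beta.g.i`,
#'   `theta.p`, `mu.g`, `alpha.g`, `z.p`), plus the protocol metadata and
#'   `relabeled = FALSE`. Pass it to [relabel()] before summarizing any
#'   group-specific quantity.
#' @seealso [relabel()], [convergence_diagnostics()], [assign_groups()]
#' @export
fit_mcmc <- function(m, G = 2L, n_chains = 3L, n_iter = 10000L,
                     n_burnin = 4000L, seed = 1L,
                     allow_all_missing = FALSE, verbose = FALSE) {
  x <- if (inherits(m, "merged_matrix")) m$x else as.matrix(m)
  if (!all(x %in% c(0, 1) | is.na(x))) {
    stop("response matrix may contain only 0, 1 and NA", call. = FALSE)
  }
  P <- nrow(x); I <- ncol(x)
  if (G < 2L) stop("G must be >= 2", call. = FALSE)
  if (n_iter <= n_burnin) stop("n_iter must exceed n_burnin", call. = FALSE)
  if (P < 2L || I < 2L) stop("need at least 2 entries and 2 items", call. = FALSE)
  if (all(is.na(x)) && !allow_all_missing) {
    stop("matrix is degenerate: every cell is missing ",
         "(set allow_all_missing = TRUE to sample from the prior)",
         call. = FALSE)
  }
  seed <- as.integer(seed)

  chains <- vector("list", n_chains)
  accept <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    if (verbose) message(sprintf("chain %d/%d (seed %d)", ch, n_chains,
                                 seed + ch - 1L))
    res <- run_chain(x, G, n_iter, n_burnin, seed + ch - 1L)
    chains[[ch]] <- res$draws
    accept[[ch]] <- res$accept
  }

  entry_ids <- rownames(x)
  if (is.null(entry_ids)) entry_ids <- paste0("e", seq_len(P))
  item_ids <- colnames(x)
  if (is.null(item_ids)) item_ids <- paste0("i", seq_len(I))

  structure(list(
    chains = chains, G = G, P = P, I = I,
    n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
    n_kept = n_iter - n_burnin, seed = seed, relabeled = FALSE,
    entry_ids = entry_ids, item_ids = item_ids, accept = accept,
    category = if (inherits(m, "merged_matrix")) m$category else NA_character_
  ), class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "posterior_samples: %d chains x %d kept draws (burn-in %d), G = %d, %d entries x %d items\n",
    x$n_chains, x$n_kept, x$n_burnin, x$G, x$P, x$I))
  cat("  relabeled:", x$relabeled, " seed:", x$seed, "\n")
  invisible(x)
}

## One chain of the Metropolis-within-Gibbs sampler. Internal.
run_chain <- function(x, G, n_iter, n_burnin, chain_seed) {
  set.seed(chain_seed)
  P <- nrow(x); I <- ncol(x)
  n_kept <- n_iter - n_burnin

  ## initial state drawn from the prior (alpha floored away from 0)
  pi <- as.numeric(rdirichlet1(G))
  z <- sample.int(G, P, replace = TRUE, prob = pi)
  beta <- matrix(stats::rnorm(G * I), G, I)
  mu <- stats::rnorm(G)
  theta <- stats::rnorm(P, mean = mu[z])
  alpha <- pmax(abs(stats::rnorm(G)), 0.05)

  ## adaptive step sizes (frozen after burn-in)
  step_beta <- matrix(0.5, G, I)
  step_theta <- rep(0.5, P)
  step_alpha <- rep(0.3, G)
  acc_beta <- matrix(0, G, I); acc_theta <- rep(0, P); acc_alpha <- rep(0, G)
  batch <- 50L; in_batch <- 0L

  keep <- list(
    pi = matrix(NA_real_, n_kept, G),
    beta = matrix(NA_real_, n_kept, G * I),
    theta = matrix(NA_real_, n_kept, P),
    mu = matrix(NA_real_, n_kept, G),
    alpha = matrix(NA_real_, n_kept, G),
    z = matrix(NA_integer_, n_kept, P)
  )
  colnames(keep$pi) <- paste0("pi.", seq_len(G))
  colnames(keep$beta) <- paste0("beta.", rep(seq_len(G), times = I), ".",
                                rep(seq_len(I), each = G))
  colnames(keep$theta) <- paste0("theta.", seq_len(P))
  colnames(keep$mu) <- paste0("mu.", seq_len(G))
  colnames(keep$alpha) <- paste0("alpha.", seq_len(G))
  colnames(keep$z) <- paste0("z.", seq_len(P))

  total_acc <- c(beta = 0, theta = 0, alpha = 0); total_n <- 0L

  for (it in seq_len(n_iter)) {
    ## --- z: exact Gibbs from its conditional categorical distribution ---
    lw <- matrix(0, P, G)
    for (g in seq_len(G)) {
      eta <- alpha[g] * (matrix(beta[g, ], P, I, byrow = TRUE) - theta)
      lw[, g] <- log(pi[g]) +
        stats::dnorm(theta, mean = mu[g], log = TRUE) +
        rowSums(bernoulli_loglik_cells(x, eta))
    }
    z <- sample_rowwise_categorical(lw)

    ## --- pi: conjugate Dirichlet(1 + n_g) ---
    n_g <- tabulate(z, nbins = G)
    pi <- as.numeric(rdirichlet1(G, shape = 1 + n_g))

    ## --- beta: elementwise random-walk Metropolis per (group, item) ---
    prop <- beta + step_beta * matrix(stats::rnorm(G * I), G, I)
    for (g in seq_len(G)) {
      idx <- which(z == g)
      if (length(idx)) {
        xs <- x[idx, , drop = FALSE]
        th <- theta[idx]
        eta_cur <- alpha[g] * (matrix(beta[g, ], length(idx), I, byrow = TRUE) - th)
        eta_prop <- alpha[g] * (matrix(prop[g, ], length(idx), I, byrow = TRUE) - th)
        dll <- colSums(bernoulli_loglik_cells(xs, eta_prop)) -
          colSums(bernoulli_loglik_cells(xs, eta_cur))
      } else dll <- numeric(I)
      logr <- dll + stats::dnorm(prop[g, ], log = TRUE) -
        stats::dnorm(beta[g, ], log = TRUE)
      acc <- log(stats::runif(I)) < logr
      beta[g, acc] <- prop[g, acc]
      acc_beta[g, ] <- acc_beta[g, ] + acc
      total_acc["beta"] <- total_acc["beta"] + mean(acc)
    }

    ## --- theta: elementwise random-walk Metropolis per entry ---
    prop_t <- theta + step_theta * stats::rnorm(P)
    B <- beta[z, , drop = FALSE]
    A <- alpha[z]
    ll_cur <- rowSums(bernoulli_loglik_cells(x, A * (B - theta)))
    ll_prop <- rowSums(bernoulli_loglik_cells(x, A * (B - prop_t)))
    logr <- ll_prop - ll_cur +
      stats::dnorm(prop_t, mean = mu[z], log = TRUE) -
      stats::dnorm(theta, mean = mu[z], log = TRUE)
    acc <- log(stats::runif(P)) < logr
    theta[acc] <- prop_t[acc]
    acc_theta <- acc_theta + acc
    total_acc["theta"] <- total_acc["theta"] + mean(acc)

    ## --- mu: conjugate normal given members' thresholds ---
    s_g <- vapply(seq_len(G), function(g) sum(theta[z == g]), numeric(1))
    post_var <- 1 / (1 + n_g)
    mu <- stats::rnorm(G, mean = s_g * post_var, sd = sqrt(post_var))

    ## --- joint location move per group (exact Gibbs along the ridge) ---
    ## The likelihood depends on beta - theta only, so shifting a group's
    ## item scales, its members' thresholds, and its threshold mean by a
    ## common delta leaves it unchanged; along that direction the
    ## conditional posterior is Gaussian in delta via the beta and mu
    ## priors. Sampling it decorrelates the otherwise slowly mixing
    ## location of the (beta, theta, mu) block.
    for (g in seq_len(G)) {
      delta <- stats::rnorm(1, mean = -(sum(beta[g, ]) + mu[g]) / (I + 1),
                            sd = sqrt(1 / (I + 1)))
      beta[g, ] <- beta[g, ] + delta
      mu[g] <- mu[g] + delta
      theta[z == g] <- theta[z == g] + delta
    }

    ## --- alpha: random-walk Metropolis on the log scale ---
    for (g in seq_len(G)) {
      idx <- which(z == g)
      a_prop <- exp(log(alpha[g]) + step_alpha[g] * stats::rnorm(1))
      if (length(idx)) {
        xs <- x[idx, , drop = FALSE]
        d <- matrix(beta[g, ], length(idx), I, byrow = TRUE) - theta[idx]
        dll <- sum(bernoulli_loglik_cells(xs, a_prop * d)) -
          sum(bernoulli_loglik_cells(xs, alpha[g] * d))
      } else dll <- 0
      logr <- dll + dhalfnorm_log(a_prop) - dhalfnorm_log(alpha[g]) +
        log(a_prop) - log(alpha[g])
      if (log(stats::runif(1)) < logr) {
        alpha[g] <- a_prop
        acc_alpha[g] <- acc_alpha[g] + 1
        total_acc["alpha"] <- total_acc["alpha"] + 1 / G
      }
    }
    total_n <- total_n + 1L

    ## --- step-size adaptation, burn-in only ---
    in_batch <- in_batch + 1L
    if (it <= n_burnin && in_batch == batch) {
      step_beta <- clamp_step(step_beta * exp(acc_beta / batch - 0.4))
      step_theta <- clamp_step(step_theta * exp(acc_theta / batch - 0.4))
      step_alpha <- clamp_step(step_alpha * exp(acc_alpha / batch - 0.4))
      acc_beta[] <- 0; acc_theta[] <- 0; acc_alpha[] <- 0
      in_batch <- 0L
    } else if (in_batch == batch) {
      in_batch <- 0L
    }

    if (it > n_burnin) {
      k <- it - n_burnin
      keep$pi[k, ] <- pi
      keep$beta[k, ] <- beta        # column-major: beta.g.i ordered g fastest
      keep$theta[k, ] <- theta
      keep$mu[k, ] <- mu
      keep$alpha[k, ] <- alpha
      keep$z[k, ] <- z
    }
  }

  list(draws = keep, accept = total_acc / total_n)
}

## Dirichlet draw via normalized gammas (shape defaults to the uniform case)
rdirichlet1 <- function(G, shape = rep(1, G)) {
  g <- stats::rgamma(G, shape = shape)
  if (all(g == 0)) g <- rep(1, G)
  g / sum(g)
}

## Sample one categorical index per row from unnormalized log-weights
sample_rowwise_categorical <- function(lw) {
  mx <- apply(lw, 1, max)
  w <- exp(lw - mx)
  p <- w / rowSums(w)
  u <- stats::runif(nrow(lw))
  cum <- t(apply(p, 1, cumsum))
  as.integer(1L + rowSums(cum < u))
}

clamp_step <- function(s) pmin(pmax(s, 1e-3), 10)

## Reconstruct the model_parameters state of draw k of chain ch. Internal,
## used by relabeling checks and tests.
draw_to_parameters <- function(s, ch, k) {
  d <- s$chains[[ch]]
  G <- s$G; I <- s$I
  model_parameters(
    pi = d$pi[k, ],
    z = d$z[k, ],
    beta = matrix(d$beta[k, ], G, I),
    theta = d$theta[k, ],
    mu = d$mu[k, ],
    alpha = d$alpha[k, ]
  )
}
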