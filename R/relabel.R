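#' Resolve label switching in mixture posterior draws
#'
#' A finite mixture posterior is invariant under permutation of the group
#' labels, so raw draws from different chains (or different parts of one
#' chain) may use different labelings; group-specific summaries are
#' meaningless until a common labeling is imposed. This function relabels
#' every draw against a single reference profile:
#'
#' 1. Within the first chain, each draw's groups are provisionally ordered
#'    by the group threshold means `mu` (ascending), and the item-scale
#'    matrices `beta` are averaged over draws to give a reference profile.
#' 2. For every draw of every chain, the group permutation that maximizes
#'    the sum over groups of the Pearson correlation between the draw's
#'    `beta` rows and the reference rows is applied to `pi`, `beta`, `mu`,
#'    `alpha`, and (consistently) to `z`. When a `beta` row is constant
#'    (correlation undefined) the draw falls back to matching on `mu`.
#'
#' Relabeling permutes components jointly, so the complete-data
#' log-likelihood and log-prior of every draw are unchanged. Applying
#' [relabel()] to an already-relabeled object is a no-op.
#'
#' @param s a `posterior_samples` object from [fit_mcmc()].
#' @return `s` with aligned group labels and `relabeled = TRUE`.
#' @export
relabel <- function(s) {
  stopifnot(inherits(s, "posterior_samples"))
  if (isTRUE(s$relabeled)) return(s)
  G <- s$G; I <- s$I
  perms <- permutations_of(G)

  ## reference: posterior-mean beta of chain 1 after provisional mu-ordering
  d1 <- s$chains[[1]]
  n1 <- nrow(d1$beta)
  ref <- matrix(0, G, I)
  for (k in seq_len(n1)) {
    ord <- order(d1$mu[k, ])
    ref <- ref + matrix(d1$beta[k, ], G, I)[ord, , drop = FALSE]
  }
  ref <- ref / n1

  for (ch in seq_along(s$chains)) {
    d <- s$chains[[ch]]
    for (k in seq_len(nrow(d$beta))) {
      b <- matrix(d$beta[k, ], G, I)
      perm <- best_permutation(b, d$mu[k, ], ref, perms)
      if (!identical(perm, seq_len(G))) {
        d$pi[k, ] <- d$pi[k, perm]
        d$beta[k, ] <- as.numeric(b[perm, , drop = FALSE])
        d$mu[k, ] <- d$mu[k, perm]
        d$alpha[k, ] <- d$alpha[k, perm]
        d$z[k, ] <- match(d$z[k, ], perm)
      }
    }
    s$chains[[ch]] <- d
  }
  s$relabeled <- TRUE
  s
}

## Choose the permutation of a draw's groups that best matches the
## reference beta profile; ties (and undefined correlations from constant
## rows) are resolved by ascending mu.
best_permutation <- function(beta, mu, ref, perms) {
  G <- nrow(beta)
  sds <- apply(beta, 1, stats::sd)
  ref_sds <- apply(ref, 1, stats::sd)
  if (any(sds == 0) || any(ref_sds == 0) || ncol(beta) < 2L) {
    return(order(mu))
  }
  scores <- vapply(perms, function(p) {
    sum(vapply(seq_len(G),
               function(g) stats::cor(beta[p[g], ], ref[g, ]),
               numeric(1)))
  }, numeric(1))
  top <- which(scores > max(scores) - 1e-12)
  if (length(top) > 1L) {
    ## tie: prefer the permutation that orders mu ascending
    mu_score <- vapply(perms[top], function(p) -sum(abs(order(mu) - p)),
                       numeric(1))
    top <- top[which.max(mu_score)]
  }
  perms[[top[1]]]
}

permutations_of <- function(G) {
  if (G == 1L) return(list(1L))
  out <- list()
  for (g in seq_len(G)) {
    sub <- permutations_of(G - 1L)
    rest <- setdiff(seq_len(G), g)
    out <- c(out, lapply(sub, function(p) c(g, rest[p])))
  }
  out
}

#' Convergence diagnostics for relabeled posterior draws
#'
#' Computes the split potential-scale-reduction statistic (split R-hat) and
#' an effective sample size for every continuous scalar parameter (`pi`,
#' `beta`, `theta`, `mu`, `alpha`). Each chain is split in half before
#' computing the between/within variance ratio, so slow trends inside a
#' chain inflate the statistic as well as disagreement between chains.
#' Values near 1 (conventionally <= 1.1) indicate convergence.
#'
#' The effective sample size uses the standard multi-chain autocorrelation
#' estimate with Geyer's initial-positive-sequence truncation.
#'
#' @param s a relabeled `posterior_samples` object with at least 2 chains.
#' @return a data frame with columns `parameter`, `rhat`, `ess`, and
#'   `degenerate` (`TRUE` for parameters with (near-)zero variance in
#'   every chain, for which the ratio is undefined and `rhat`/`ess` are
#'   `NA` rather than a division by zero).
#' @export
convergence_diagnostics <- function(s) {
  stopifnot(inherits(s, "posterior_samples"))
  if (s$n_chains < 2L) {
    stop("convergence diagnostics require at least 2 chains", call. = FALSE)
  }
  if (!isTRUE(s$relabeled)) {
    stop("relabel the draws first (see relabel())", call. = FALSE)
  }
  blocks <- c("pi", "beta", "theta", "mu", "alpha")
  out <- list()
  for (b in blocks) {
    cols <- colnames(s$chains[[1]][[b]])
    for (j in seq_along(cols)) {
      draws <- lapply(s$chains, function(d) d[[b]][, j])
      out[[length(out) + 1L]] <- data.frame(
        parameter = cols[j],
        rhat = split_rhat(draws),
        ess = multichain_ess(draws),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res$degenerate <- is.na(res$rhat)
  res
}

## Split potential scale reduction over a list of per-chain draw vectors
split_rhat <- function(draws) {
  halves <- list()
  for (d in draws) {
    n <- length(d) %/% 2L
    halves <- c(halves, list(d[seq_len(n)], d[n + seq_len(n)]))
  }
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  if (!is.finite(W) || W < .Machine$double.eps) return(NA_real_)
  B <- n * stats::var(means)
  var_hat <- (n - 1) / n * W + B / n
  sqrt(var_hat / W)
}

## Multi-chain effective sample size (initial positive sequence truncation)
multichain_ess <- function(draws) {
  m <- length(draws); n <- length(draws[[1]])
  vars <- vapply(draws, stats::var, numeric(1))
  if (any(!is.finite(vars)) || all(vars < .Machine$double.eps)) return(NA_real_)
  means <- vapply(draws, mean, numeric(1))
  W <- mean(vars)
  B_over_n <- stats::var(means)
  var_hat <- (n - 1) / n * W + B_over_n
  max_lag <- min(n - 1L, 500L)
  ## chain-averaged autocovariances
  acov <- matrix(0, m, max_lag + 1L)
  for (i in seq_len(m)) {
    a <- stats::acf(draws[[i]], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    acov[i, ] <- a
  }
  rho <- 1 - (W - colMeans(acov)[-1]) / var_hat
  ## Geyer: sum consecutive lag pairs while their sum stays positive
  tau <- 1
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  max(m * n / tau, 1e-8)
}
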