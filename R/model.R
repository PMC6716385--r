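#' One complete parameter state of the mixture model
#'
#' The model explains a binary membership matrix (entries x items) as a
#' finite mixture over latent criterion groups. Each entry `p` belongs to a
#' group `z_p` drawn from mixing probabilities `pi`; group `g` carries its
#' own item scale values `beta[g, ]` (how strongly each item displays that
#' group's categorization criterion) and steepness `alpha[g]`; each entry
#' has a threshold `theta[p]`, drawn from a normal hyper-distribution with
#' group mean `mu[g]` and unit variance, representing the amount of
#' evidence that respondent requires before endorsing membership. The
#' probability of a `yes` is an S-shaped (logistic) function of
#' `alpha[g] * (beta[g, i] - theta[p])`, so it is exactly .50 when the item
#' scale value equals the threshold.
#'
#' The same object serves as simulation ground truth and as an MCMC state.
#'
#' @param pi numeric simplex of length `G` (mixing probabilities).
#' @param z integer vector of group indices in `1..G`, one per entry.
#' @param beta numeric `G x I` matrix of item scale values.
#' @param theta numeric vector of thresholds, one per entry.
#' @param mu numeric vector of group threshold means, length `G`.
#' @param alpha numeric vector of positive steepness parameters, length `G`.
#' @return an object of class `model_parameters`.
#' @export
model_parameters <- function(pi, z, beta, theta, mu, alpha) {
  beta <- as.matrix(beta)
  G <- length(pi)
  p <- structure(list(G = G, pi = as.numeric(pi), z = as.integer(z),
                      beta = beta, theta = as.numeric(theta),
                      mu = as.numeric(mu), alpha = as.numeric(alpha)),
                 class = "model_parameters")
  validate_model_parameters(p)
}

#' @rdname model_parameters
#' @param x object to validate.
#' @export
validate_model_parameters <- function(x) {
  stopifnot(inherits(x, "model_parameters"))
  G <- x$G
  if (G < 1L) stop("G must be >= 1", call. = FALSE)
  if (abs(sum(x$pi) - 1) > 1e-8 || any(x$pi < -1e-12)) {
    stop("pi must be a simplex (non-negative, summing to 1)", call. = FALSE)
  }
  if (any(x$alpha <= 0)) stop("alpha must be strictly positive", call. = FALSE)
  if (nrow(x$beta) != G) stop("beta must have G rows", call. = FALSE)
  if (length(x$mu) != G || length(x$alpha) != G) {
    stop("mu and alpha must have length G", call. = FALSE)
  }
  if (length(x$z) != length(x$theta)) {
    stop("z and theta must have one element per entry", call. = FALSE)
  }
  if (length(x$z) && (any(x$z < 1L) || any(x$z > G))) {
    stop("z values must lie in 1..G", call. = FALSE)
  }
  invisible(x)
}

#' S-shaped response function
#'
#' Probability of a `yes` response given an item scale value, a respondent
#' threshold, and a steepness: the logistic function
#' `1 / (1 + exp(-alpha * (beta - theta)))`. It equals .50 exactly at
#' `beta == theta` (the point of subjective equality), rises to 1 as
#' `beta - theta` grows large and positive, and falls to 0 as it grows
#' large and negative; `alpha` sets the slope at the crossing point, with
#' larger values giving more deterministic responding.
#'
#' @param beta item scale value(s).
#' @param theta threshold(s).
#' @param alpha steepness, strictly positive.
#' @return probabilities in (0, 1); vectorized over all arguments.
#' @export
response_probability <- function(beta, theta, alpha) {
  if (any(alpha <= 0)) stop("alpha must be strictly positive", call. = FALSE)
  stats::plogis(alpha * (beta - theta))
}

## Stable elementwise Bernoulli log-likelihood on the linear predictor scale.
## x in {0,1,NA}; missing cells contribute 0.
bernoulli_loglik_cells <- function(x, eta) {
  ll <- x * stats::plogis(eta, log.p = TRUE) +
    (1 - x) * stats::plogis(-eta, log.p = TRUE)
  ll[is.na(x)] <- 0
  ll
}

## Per-entry log-likelihood of the observed rows under each group's item
## scales: returns an entries x G matrix. Used by the likelihood, the exact
## Gibbs update of z, and posterior assignment.
entry_loglik_by_group <- function(params, x) {
  P <- nrow(x)
  G <- params$G
  out <- matrix(0, P, G)
  for (g in seq_len(G)) {
    eta <- params$alpha[g] *
      (matrix(params$beta[g, ], P, ncol(x), byrow = TRUE) - params$theta)
    out[, g] <- rowSums(bernoulli_loglik_cells(x, eta))
  }
  out
}

#' Complete-data log-likelihood
#'
#' Sum over all observed (non-missing) cells of the Bernoulli log-mass
#' `x * log(r) + (1 - x) * log(1 - r)`, where `r` is
#' [response_probability()] evaluated with the item scales of each entry's
#' current group `z_p`. Missing cells (unknown responses) contribute
#' nothing.
#'
#' @param params a [model_parameters] state.
#' @param m a `merged_matrix` (or a bare numeric matrix with values
#'   0/1/`NA`).
#' @return a scalar log-likelihood; 0 for an empty matrix.
#' @export
complete_loglik <- function(params, m) {
  x <- if (inherits(m, "merged_matrix")) m$x else as.matrix(m)
  validate_model_parameters(params)
  if (length(params$z) != nrow(x)) {
    stop("parameter state has ", length(params$z),
         " entries but matrix has ", nrow(x), " rows", call. = FALSE)
  }
  if (ncol(params$beta) != ncol(x)) {
    stop("beta has ", ncol(params$beta), " items but matrix has ",
         ncol(x), " columns", call. = FALSE)
  }
  if (!length(x)) return(0)
  eta <- params$alpha[params$z] *
    (params$beta[params$z, , drop = FALSE] - params$theta)
  sum(bernoulli_loglik_cells(x, eta))
}

## log density of the half-normal with unit variance (|N(0,1)|)
dhalfnorm_log <- function(a) {
  ifelse(a < 0, -Inf, log(2) + stats::dnorm(a, log = TRUE))
}

#' Joint log-prior of a parameter state
#'
#' The priors mirror the model's hierarchical specification: a uniform
#' Dirichlet on the mixing probabilities `pi`; a half-normal with unit
#' variance on each steepness `alpha_g`; standard normal priors on every
#' item scale `beta[g, i]` and every group threshold mean `mu_g`; a normal
#' with mean `mu[z_p]` and unit variance on each threshold `theta_p`
#' (thresholds are drawn from group-specific hyper-distributions with
#' precision 1); and categorical mass `pi[z_p]` on each group indicator.
#'
#' "Precision 1" is the inverse-variance convention: all normal scales here
#' are unit variance.
#'
#' @param params a [model_parameters] state.
#' @return scalar log prior density (`-Inf` outside the support).
#' @export
log_prior <- function(params) {
  validate_model_parameters(params)
  G <- params$G
  ## Dirichlet(1, ..., 1) has constant density (G-1)! on the simplex
  lp <- lgamma(G)
  lp <- lp + sum(dhalfnorm_log(params$alpha))
  lp <- lp + sum(stats::dnorm(params$beta, log = TRUE))
  lp <- lp + sum(stats::dnorm(params$mu, log = TRUE))
  if (length(params$theta)) {
    lp <- lp + sum(stats::dnorm(params$theta, mean = params$mu[params$z],
                                log = TRUE))
    lp <- lp + sum(log(params$pi[params$z]))
  }
  lp
}

## Apply a group permutation perm to a parameter state: new group g is old
## group perm[g]. Leaves loglik + log_prior unchanged when z is remapped
## consistently (new z = position of old z in perm).
permute_groups <- function(params, perm) {
  params$pi <- params$pi[perm]
  params$beta <- params$beta[perm, , drop = FALSE]
  params$mu <- params$mu[perm]
  params$alpha <- params$alpha[perm]
  params$z <- match(params$z, perm)
  params
}
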