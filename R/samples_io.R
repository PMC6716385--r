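#' Persist posterior samples to a directory
#'
#' Writes a `posterior_samples` object as plain text: a `meta.json` with
#' the protocol (dimensions, seed, burn-in, relabeling status, entry and
#' item ids) and one flat CSV per chain (`chain1.csv`, ...) whose columns
#' use the canonical parameter names `pi.g`, `beta.g.i`, `theta.p`,
#' `mu.g`, `alpha.g`, `z.p`. [read_samples()] restores the object exactly
#' (draw values round-trip through full decimal precision).
#'
#' @param s a `posterior_samples` object.
#' @param dir directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_samples <- function(s, dir) {
  stopifnot(inherits(s, "posterior_samples"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(G = s$G, P = s$P, I = s$I, n_chains = s$n_chains,
               n_iter = s$n_iter, n_burnin = s$n_burnin, n_kept = s$n_kept,
               seed = s$seed, relabeled = s$relabeled,
               entry_ids = s$entry_ids, item_ids = s$item_ids,
               category = s$category)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (ch in seq_len(s$n_chains)) {
    d <- s$chains[[ch]]
    df <- data.frame(d$pi, d$beta, d$theta, d$mu, d$alpha, d$z,
                     check.names = FALSE)
    names(df) <- c(colnames(d$pi), colnames(d$beta), colnames(d$theta),
                   colnames(d$mu), colnames(d$alpha), colnames(d$z))
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     file.path(dir, sprintf("chain%d.csv", ch)),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_samples
#' @export
read_samples <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  chains <- vector("list", meta$n_chains)
  G <- meta$G; P <- meta$P; I <- meta$I
  for (ch in seq_len(meta$n_chains)) {
    df <- utils::read.csv(file.path(dir, sprintf("chain%d.csv", ch)),
                          check.names = FALSE)
    pick <- function(prefix) {
      cols <- grep(paste0("^", prefix, "\\."), names(df), value = TRUE)
      m <- as.matrix(df[, cols, drop = FALSE])
      m
    }
    z <- pick("z"); storage.mode(z) <- "integer"
    chains[[ch]] <- list(pi = pick("pi"), beta = pick("beta"),
                         theta = pick("theta"), mu = pick("mu"),
                         alpha = pick("alpha"), z = z)
  }
  structure(list(chains = chains, G = G, P = P, I = I,
                 n_chains = meta$n_chains, n_iter = meta$n_iter,
                 n_burnin = meta$n_burnin, n_kept = meta$n_kept,
                 seed = meta$seed, relabeled = meta$relabeled,
                 entry_ids = meta$entry_ids, item_ids = meta$item_ids,
                 accept = NULL, category = meta$category),
            class = "posterior_samples")
}
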