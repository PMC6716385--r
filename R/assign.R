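#' Posterior-mode group assignment per entry
#'
#' Pools the relabeled group-indicator draws across chains and, for every
#' respondent entry, reports the posterior assignment probabilities (the
#' fraction of pooled draws placing the entry in each group) and the modal
#' group. This is the group-membership rule used throughout the package:
#' an entry belongs to the group it is assigned to in the largest share of
#' posterior draws. Exact ties are flagged and broken toward the lower
#' group index.
#'
#' @param s a relabeled `posterior_samples` object.
#' @return an object of class `assignment_result`: a data frame with one
#'   row per entry and columns `entry_id`, `modal_group`, `tie_flag`, and
#'   `prob.1` ... `prob.G` (each row a simplex).
#' @seealso [assign_sessions()] to turn entry-level assignments into
#'   per-participant session pairs.
#' @export
assign_groups <- function(s) {
  stopifnot(inherits(s, "posterior_samples"))
  if (!isTRUE(s$relabeled)) {
    stop("relabel the draws first (see relabel())", call. = FALSE)
  }
  G <- s$G
  z_all <- do.call(rbind, lapply(s$chains, function(d) d$z))
  n_draws <- nrow(z_all)
  counts <- vapply(seq_len(G), function(g) colSums(z_all == g),
                   numeric(s$P))
  if (s$P == 1L) counts <- matrix(counts, 1L, G)
  prob <- counts / n_draws
  modal <- max.col(prob, ties.method = "first")
  mx <- prob[cbind(seq_len(s$P), modal)]
  tie <- rowSums(abs(prob - mx) < .Machine$double.eps^0.5) > 1L
  res <- data.frame(entry_id = s$entry_ids, modal_group = modal,
                    tie_flag = tie, stringsAsFactors = FALSE)
  pr <- as.data.frame(prob)
  names(pr) <- paste0("prob.", seq_len(G))
  res <- cbind(res, pr)
  attr(res, "G") <- G
  attr(res, "n_draws") <- n_draws
  class(res) <- c("assignment_result", "data.frame")
  res
}

#' Per-participant session pair of group assignments
#'
#' Maps entry-level posterior assignments back to the two-session
#' participants: archival entries are excluded, and each participant is
#' reported with their session-1 and session-2 modal group and assignment
#' probability profiles. A participant whose modal group differs between
#' sessions is a detected criterion change.
#'
#' @param assignments an `assignment_result` from [assign_groups()].
#' @param entry_index the `entry_index` of the `merged_matrix` the model
#'   was fitted to (or the `merged_matrix` itself).
#' @return a data frame with one row per two-session participant:
#'   `participant`, `group1`, `group2`, `changed`, `tie1`, `tie2`, and the
#'   per-session probability profiles `prob1.g` / `prob2.g`.
#' @export
assign_sessions <- function(assignments, entry_index) {
  stopifnot(inherits(assignments, "assignment_result"))
  if (inherits(entry_index, "merged_matrix")) entry_index <- entry_index$entry_index
  G <- attr(assignments, "G")
  idx <- merge(entry_index, as.data.frame(assignments),
               by = "entry_id", sort = FALSE)
  if (nrow(idx) != nrow(entry_index)) {
    stop("assignments do not cover every entry in entry_index", call. = FALSE)
  }
  idx <- idx[idx$provenance != "archival", , drop = FALSE]
  parts <- sort(unique(idx$participant))
  bad <- parts[vapply(parts, function(p) sum(idx$participant == p) != 2L,
                      logical(1))]
  if (length(bad)) {
    stop("participant(s) without exactly 2 entries: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pcols <- paste0("prob.", seq_len(G))
  rows <- lapply(parts, function(p) {
    e1 <- idx[idx$participant == p & idx$session == 1L, , drop = FALSE]
    e2 <- idx[idx$participant == p & idx$session == 2L, , drop = FALSE]
    if (nrow(e1) != 1L || nrow(e2) != 1L) {
      stop("participant ", p, " lacks one entry per session", call. = FALSE)
    }
    out <- data.frame(participant = p,
                      group1 = e1$modal_group, group2 = e2$modal_group,
                      changed = e1$modal_group != e2$modal_group,
                      tie1 = e1$tie_flag, tie2 = e2$tie_flag,
                      stringsAsFactors = FALSE)
    p1 <- e1[, pcols]; names(p1) <- paste0("prob1.", seq_len(G))
    p2 <- e2[, pcols]; names(p2) <- paste0("prob2.", seq_len(G))
    cbind(out, p1, p2)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
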