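#' Merge two-session and archival responses into a model-ready matrix
#'
#' The mixture model treats every respondent-session as an independent row:
#' a participant who did the task twice contributes two entries, so that the
#' two sessions can be assigned to latent criterion groups independently,
#' and single-session archival respondents contribute one entry each. This
#' function builds that binary matrix for one category: `yes` becomes 1,
#' `no` becomes 0, and `unknown` becomes `NA` (missing, dropped from the
#' likelihood).
#'
#' @param new_data a [response_table] holding both sessions for every
#'   participant in `category_id`. Participants present in only one session
#'   are an error: the analysis is restricted to completers.
#' @param archival_data optional [response_table] of single-session
#'   (session 1) respondents for the same items, or `NULL`.
#' @param category_id the category to extract.
#' @return an object of class `merged_matrix`: a list with
#'   * `category`: the category id;
#'   * `x`: entries x items matrix with values 0, 1, `NA`; items are ordered
#'     lexicographically so that item-scale indexing is reproducible;
#'   * `entry_index`: data frame mapping each row of `x` to
#'     (`entry_id`, `participant`, `session`, `provenance`).
#'
#' The number of rows equals `2 * n_two_session + n_archival`.
#' @seealso [write_matrix()], [fit_mcmc()]
#' @export
merge_sessions <- function(new_data, archival_data = NULL, category_id) {
  new_data <- validate_response_table(new_data)
  nd <- new_data[new_data$category == category_id, , drop = FALSE]
  if (!nrow(nd)) stop("no records for category '", category_id, "' in new_data",
                      call. = FALSE)
  tab <- table(nd$participant, nd$session)
  have1 <- rownames(tab)[tab[, "1", drop = TRUE] > 0]
  have2 <- if ("2" %in% colnames(tab)) rownames(tab)[tab[, "2"] > 0] else character(0)
  incomplete <- union(setdiff(have1, have2), setdiff(have2, have1))
  if (length(incomplete)) {
    stop("participant(s) present in only one session for category '",
         category_id, "': ", paste(sort(incomplete), collapse = ", "),
         call. = FALSE)
  }
  ad <- NULL
  if (!is.null(archival_data)) {
    archival_data <- validate_response_table(archival_data)
    ad <- archival_data[archival_data$category == category_id, , drop = FALSE]
    if (any(ad$session != 1L)) {
      stop("archival data must contain session 1 only", call. = FALSE)
    }
  }

  items <- sort(unique(c(nd$item, if (!is.null(ad)) ad$item)))
  participants <- sort(unique(nd$participant))

  entry_index <- data.frame(
    entry_id = character(0), participant = character(0),
    session = integer(0), provenance = character(0),
    stringsAsFactors = FALSE
  )
  for (s in c(1L, 2L)) {
    prov <- vapply(participants, function(p) nd$provenance[nd$participant == p][1],
                   character(1))
    entry_index <- rbind(entry_index, data.frame(
      entry_id = paste0(participants, ".s", s),
      participant = participants, session = s, provenance = prov,
      stringsAsFactors = FALSE
    ))
  }
  if (!is.null(ad) && nrow(ad)) {
    arch_p <- sort(unique(ad$participant))
    entry_index <- rbind(entry_index, data.frame(
      entry_id = paste0(arch_p, ".s1"),
      participant = arch_p, session = 1L, provenance = "archival",
      stringsAsFactors = FALSE
    ))
  }
  if (anyDuplicated(entry_index$entry_id)) {
    stop("participant ids collide between new and archival data", call. = FALSE)
  }
  rownames(entry_index) <- NULL

  x <- matrix(NA_real_, nrow(entry_index), length(items),
              dimnames = list(entry_index$entry_id, items))
  code <- function(r) ifelse(r == "yes", 1, ifelse(r == "no", 0, NA_real_))
  fill <- function(df) {
    rows <- paste0(df$participant, ".s", df$session)
    x[cbind(match(rows, entry_index$entry_id), match(df$item, items))] <<-
      code(df$response)
  }
  fill(nd)
  if (!is.null(ad) && nrow(ad)) fill(ad)

  structure(list(category = category_id, x = x, entry_index = entry_index),
            class = "merged_matrix")
}

#' @export
print.merged_matrix <- function(x, ...) {
  cat(sprintf("merged_matrix: category '%s', %d entries x %d items (%d missing cells)\n",
              x$category, nrow(x$x), ncol(x$x), sum(is.na(x$x))))
  prov <- table(x$entry_index$provenance)
  cat("  entries by provenance:",
      paste(sprintf("%s=%d", names(prov), prov), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a merged matrix as CSV
#'
#' One row per entry; the first columns are
#' `entry_id,participant,session,provenance`, then one column per item.
#' Missing cells (unknown responses) are encoded as the literal `NA`, never
#' as 0. The pair of functions round-trips exactly.
#'
#' @param m a `merged_matrix`.
#' @param path output path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()`
#'   returns a `merged_matrix`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "merged_matrix"))
  df <- cbind(m$entry_index,
              as.data.frame(m$x, check.names = FALSE))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#category=", m$category), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#category=")) {
    stop("format error: not a merged-matrix file (missing #category header)",
         call. = FALSE)
  }
  category <- sub("^#category=", "", header)
  df <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE,
                        check.names = FALSE, encoding = "UTF-8")
  meta <- c("entry_id", "participant", "session", "provenance")
  if (!all(meta %in% names(df))) {
    stop("format error: merged-matrix file must start with columns ",
         paste(meta, collapse = ","), call. = FALSE)
  }
  items <- setdiff(names(df), meta)
  x <- as.matrix(df[, items, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- df$entry_id
  entry_index <- df[, meta]
  entry_index$session <- as.integer(entry_index$session)
  entry_index$participant <- as.character(entry_index$participant)
  entry_index$entry_id <- as.character(entry_index$entry_id)
  structure(list(category = category, x = x, entry_index = entry_index),
            class = "merged_matrix")
}
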