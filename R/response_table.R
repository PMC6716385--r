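#' Long-format repeated categorization responses
#'
#' A `response_table` is a validated long-format data frame of category
#' membership decisions: one row per (participant, category, item, session)
#' with a three-option response (`yes`, `no`, `unknown`). It is the common
#' currency of the package: real study data are read into it with
#' [read_responses()], synthetic data are generated into it by
#' [generate_two_session_study()], and [merge_sessions()] turns it into the
#' binary matrix the mixture model consumes.
#'
#' @param participant,category,item character vectors (recycled to a common
#'   length) identifying the respondent, the category whose membership is
#'   probed, and the target item.
#' @param session integer session index, 1 or 2. Single-session (archival)
#'   data use session 1 throughout.
#' @param response character vector of responses; one of `"yes"`, `"no"`,
#'   `"unknown"` (case-insensitive; stored lower-case).
#' @param provenance record origin: `"new"` (the two-session study),
#'   `"archival"` (earlier single-session data merged in to stabilize the
#'   item-scale estimates), or `"synthetic"`.
#'
#' @return A data frame of class `response_table` with columns
#'   `participant`, `category`, `item`, `session`, `response`, `provenance`.
#'
#' @details Invariants enforced by [validate_response_table()]:
#'   * at most one record per (participant, category, item, session);
#'   * archival records carry session 1 only;
#'   * responses are exactly `yes`, `no`, or `unknown` (a skipped or
#'     unanswerable trial is an `unknown` row, never an absent row).
#'
#' @seealso [read_responses()], [write_responses()], [merge_sessions()]
#' @export
response_table <- function(participant, category, item, session, response,
                           provenance = "new") {
  df <- data.frame(
    participant = as.character(participant),
    category    = as.character(category),
    item        = as.character(item),
    session     = as.integer(session),
    response    = tolower(as.character(response)),
    provenance  = as.character(provenance),
    stringsAsFactors = FALSE
  )
  validate_response_table(structure(df, class = c("response_table", "data.frame")))
}

RESPONSE_TOKENS <- c("yes", "no", "unknown")
PROVENANCE_TOKENS <- c("new", "archival", "synthetic")

#' Validate a response table
#'
#' Checks the `response_table` invariants and returns the table invisibly,
#' or stops with a message naming every offending row.
#'
#' @param x a `response_table` (or coercible data frame with the five
#'   required columns).
#' @return `x`, invisibly, with class `response_table`.
#' @export
validate_response_table <- function(x) {
  req <- c("participant", "category", "item", "session", "response")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("response table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"provenance" %in% names(x)) x$provenance <- "new"
  bad_resp <- which(!(x$response %in% RESPONSE_TOKENS))
  if (length(bad_resp)) {
    stop(sprintf("unrecognized response token '%s' at row %d (expected yes/no/unknown)",
                 x$response[bad_resp[1]], bad_resp[1]), call. = FALSE)
  }
  bad_prov <- which(!(x$provenance %in% PROVENANCE_TOKENS))
  if (length(bad_prov)) {
    stop(sprintf("unrecognized provenance '%s' at row %d",
                 x$provenance[bad_prov[1]], bad_prov[1]), call. = FALSE)
  }
  if (any(!x$session %in% c(1L, 2L))) {
    stop("session must be 1 or 2", call. = FALSE)
  }
  key <- paste(x$participant, x$category, x$item, x$session, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate record for (%s, %s, %s, session %d) at row %d",
                 x$participant[dup[1]], x$category[dup[1]], x$item[dup[1]],
                 x$session[dup[1]], dup[1]), call. = FALSE)
  }
  arch2 <- which(x$provenance == "archival" & x$session != 1L)
  if (length(arch2)) {
    stop("archival records must have session = 1 (row ", arch2[1], ")",
         call. = FALSE)
  }
  if (!inherits(x, "response_table")) class(x) <- c("response_table", class(x))
  invisible(x)
}

#' Read a response CSV
#'
#' Reads a UTF-8 CSV with header
#' `participant,category,item,session,response` (an optional `provenance`
#' column is honored; archival files may omit `session`, which then
#' defaults to 1). Response tokens are case-normalized and validated.
#'
#' @param path path to the CSV file.
#' @param provenance default provenance for files without a `provenance`
#'   column.
#' @return a [response_table].
#' @export
read_responses <- function(path, provenance = "new") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  req <- c("participant", "category", "item", "response")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  }
  if (!"session" %in% names(df)) df$session <- "1"
  if (!"provenance" %in% names(df)) df$provenance <- provenance
  response_table(df$participant, df$category, df$item,
                 as.integer(df$session), df$response, df$provenance)
}

#' Write a response table to CSV
#'
#' @param x a [response_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path) {
  x <- validate_response_table(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
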