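#' Classify a pair of repeated responses
#'
#' A repeated membership question is inconsistent when the answer changed
#' across sessions: yes/no, yes/unknown, or no/unknown (in either order).
#' Identical answers — including unknown on both occasions — are
#' consistent.
#'
#' @param r1,r2 response tokens (`yes`, `no`, `unknown`); vectorized.
#' @return character vector of `"consistent"` / `"inconsistent"`.
#' @export
classify_pair <- function(r1, r2) {
  r1 <- tolower(as.character(r1)); r2 <- tolower(as.character(r2))
  bad <- c(r1[!r1 %in% RESPONSE_TOKENS], r2[!r2 %in% RESPONSE_TOKENS])
  if (length(bad)) {
    stop("unrecognized response token '", bad[1], "'", call. = FALSE)
  }
  ifelse(r1 == r2, "consistent", "inconsistent")
}

#' Descriptive inconsistency report for a two-session table
#'
#' Pairs every participant's session-1 and session-2 answers per item and
#' summarizes inconsistency at every level the descriptive analysis needs:
#' per response pair, per participant (overall, per block, per category),
#' and per item, plus the flags for fully consistent participants and
#' items that drew no inconsistent answers at all.
#'
#' @param new_data a [response_table] in which every participant has both
#'   sessions for every category present.
#' @param block_map named character vector mapping each category id to its
#'   block (`"nominal"` or `"ad hoc"`). Every category in the data must be
#'   mapped.
#' @param drop_unknown_pairs if `TRUE`, items answered `unknown` in both
#'   sessions are removed from the denominators; by default they stay (an
#'   unknown given twice is an answered, consistent trial under the
#'   three-option task).
#' @return an object of class `consistency_report`: a list with
#'   * `pairs`: one row per (participant, category, item) with both
#'     responses and the pair class;
#'   * `participant_overall`, `participant_block`, `participant_category`:
#'     per-participant inconsistency proportions at the three levels, the
#'     last with a `fully_consistent` flag per category;
#'   * `item_summary`: per (category, item) the proportion of participants
#'     answering it inconsistently and a `zero_inconsistency` flag;
#'   * `overall`: the grand proportion of inconsistent pairs;
#'   * `block_map`, `drop_unknown_pairs`: the conventions used.
#' @export
build_consistency_report <- function(new_data, block_map,
                                     drop_unknown_pairs = FALSE) {
  new_data <- validate_response_table(new_data)
  cats <- unique(new_data$category)
  unmapped <- setdiff(cats, names(block_map))
  if (length(unmapped)) {
    stop("category(ies) missing from block_map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  if (!all(block_map %in% c("nominal", "ad hoc"))) {
    stop("block_map values must be 'nominal' or 'ad hoc'", call. = FALSE)
  }
  s1 <- new_data[new_data$session == 1L, ]
  s2 <- new_data[new_data$session == 2L, ]
  pr <- merge(s1[, c("participant", "category", "item", "response")],
              s2[, c("participant", "category", "item", "response")],
              by = c("participant", "category", "item"),
              suffixes = c("1", "2"))
  complete <- nrow(pr) == nrow(s1) && nrow(pr) == nrow(s2)
  if (!complete) {
    stop("every participant must have both sessions for every ",
         "(category, item) cell", call. = FALSE)
  }
  if (drop_unknown_pairs) {
    pr <- pr[!(pr$response1 == "unknown" & pr$response2 == "unknown"), ,
             drop = FALSE]
  }
  pr$block <- unname(block_map[pr$category])
  pr$pair_class <- classify_pair(pr$response1, pr$response2)
  pr$inc <- pr$pair_class == "inconsistent"

  prop <- function(v) if (length(v)) mean(v) else NA_real_
  participant_overall <- aggregate(inc ~ participant, pr, prop)
  names(participant_overall)[2] <- "proportion"
  participant_block <- aggregate(inc ~ participant + block, pr, prop)
  names(participant_block)[3] <- "proportion"
  participant_category <- aggregate(inc ~ participant + category, pr,
                                    function(v) c(sum(v), mean(v)))
  participant_category <- data.frame(
    participant = participant_category$participant,
    category = participant_category$category,
    n_inconsistent = participant_category$inc[, 1],
    proportion = participant_category$inc[, 2],
    stringsAsFactors = FALSE
  )
  participant_category$fully_consistent <- participant_category$n_inconsistent == 0

  item_summary <- aggregate(inc ~ category + item, pr, prop)
  names(item_summary)[3] <- "proportion"
  item_summary$zero_inconsistency <- item_summary$proportion == 0

  structure(list(
    pairs = pr[, c("participant", "category", "item", "block",
                   "response1", "response2", "pair_class")],
    participant_overall = participant_overall,
    participant_block = participant_block,
    participant_category = participant_category,
    item_summary = item_summary,
    overall = prop(pr$inc),
    block_map = block_map,
    drop_unknown_pairs = drop_unknown_pairs
  ), class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("consistency_report: %d pairs, overall inconsistency %.2f%%\n",
              nrow(x$pairs), 100 * x$overall))
  invisible(x)
}

#' Criterion-change report across sessions
#'
#' Combines per-participant session group assignments (one data frame per
#' category, as returned by [assign_sessions()]) with the inconsistency
#' report to produce the criterion-change bookkeeping: per category, how
#' many participants were placed in different groups on the two occasions,
#' both out of all participants and out of the participants who showed at
#' least one inconsistent answer in that category (the restricted
#' denominator); and per participant, in how many categories the group
#' changed.
#'
#' @param session_pairs a named list (by category id) of data frames from
#'   [assign_sessions()], or a single data frame with a `category` column.
#' @param consistency a `consistency_report` covering the same
#'   participants and categories.
#' @return an object of class `group_change_report`: a list with
#'   * `per_participant_category`: one row per (participant, category)
#'     with both groups, `changed`, and `had_inconsistency`;
#'   * `per_category`: `n_participants`, `n_changed`,
#'     `n_with_inconsistency`, `change_rate`,
#'     `change_rate_among_inconsistent`;
#'   * `per_participant`: number of categories changed per participant;
#'   * `change_count_distribution`: participants by number of categories
#'     changed (0, 1, 2, 3+).
#' @export
build_group_change_report <- function(session_pairs, consistency) {
  stopifnot(inherits(consistency, "consistency_report"))
  if (is.data.frame(session_pairs)) {
    if (!"category" %in% names(session_pairs)) {
      stop("a single session_pairs data frame needs a 'category' column",
           call. = FALSE)
    }
    sp <- session_pairs
  } else {
    sp <- do.call(rbind, lapply(names(session_pairs), function(cat) {
      df <- session_pairs[[cat]]
      df$category <- cat
      df
    }))
  }
  pc <- consistency$participant_category
  merged <- merge(sp[, c("participant", "category", "group1", "group2",
                         "changed")],
                  pc[, c("participant", "category", "n_inconsistent")],
                  by = c("participant", "category"), all.x = TRUE)
  if (anyNA(merged$n_inconsistent)) {
    stop("consistency report does not cover every (participant, category) ",
         "in session_pairs", call. = FALSE)
  }
  if (!setequal(unique(merged$participant), unique(pc$participant))) {
    stop("session_pairs and consistency report cover different participants",
         call. = FALSE)
  }
  merged$had_inconsistency <- merged$n_inconsistent > 0

  per_category <- do.call(rbind, lapply(split(merged, merged$category),
                                        function(d) {
    n_inc <- sum(d$had_inconsistency)
    n_chg <- sum(d$changed)
    data.frame(
      category = d$category[1],
      n_participants = nrow(d),
      n_changed = n_chg,
      n_with_inconsistency = n_inc,
      change_rate = if (nrow(d)) n_chg / nrow(d) else NA_real_,
      change_rate_among_inconsistent = if (n_inc) {
        sum(d$changed & d$had_inconsistency) / n_inc
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_category) <- NULL

  per_participant <- aggregate(changed ~ participant, merged, sum)
  names(per_participant)[2] <- "n_categories_changed"
  bins <- cut(per_participant$n_categories_changed,
              breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
              labels = c("0", "1", "2", "3+"))
  dist <- table(bins)

  structure(list(
    per_participant_category = merged,
    per_category = per_category,
    per_participant = per_participant,
    change_count_distribution = dist
  ), class = "group_change_report")
}

#' Per-block prevalence summary
#'
#' Summarizes either report at the block (nominal vs. ad hoc) level: for a
#' `consistency_report`, the mean over participants of their per-block
#' inconsistency proportions, with the dispersion statistics behind a
#' boxplot-style display (sd, quartiles); for a `group_change_report`, the
#' per-block criterion-change rates. Blocks with no categories are
#' reported explicitly with `n = 0` rather than propagating `NaN`.
#'
#' @param report a `consistency_report` or `group_change_report`.
#' @param block_map required for a `group_change_report` (the
#'   `consistency_report` carries its own).
#' @return a data frame with one row per block.
#' @export
block_prevalence_summary <- function(report, block_map = NULL) {
  blocks <- c("nominal", "ad hoc")
  if (inherits(report, "consistency_report")) {
    pb <- report$participant_block
    rows <- lapply(blocks, function(b) {
      v <- pb$proportion[pb$block == b]
      if (!length(v)) {
        return(data.frame(block = b, n = 0L, mean = NA_real_, sd = NA_real_,
                          q25 = NA_real_, median = NA_real_, q75 = NA_real_,
                          empty = TRUE, stringsAsFactors = FALSE))
      }
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(block = b, n = length(v), mean = mean(v),
                 sd = stats::sd(v), q25 = q[1], median = q[2], q75 = q[3],
                 empty = FALSE, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  if (inherits(report, "group_change_report")) {
    if (is.null(block_map)) {
      stop("block_map is required for a group_change_report", call. = FALSE)
    }
    pc <- report$per_category
    pc$block <- unname(block_map[pc$category])
    rows <- lapply(blocks, function(b) {
      d <- pc[pc$block == b & !is.na(pc$block), , drop = FALSE]
      if (!nrow(d)) {
        return(data.frame(block = b, n = 0L, change_rate = NA_real_,
                          change_rate_among_inconsistent = NA_real_,
                          empty = TRUE, stringsAsFactors = FALSE))
      }
      data.frame(block = b, n = nrow(d),
                 change_rate = sum(d$n_changed) / sum(d$n_participants),
                 change_rate_among_inconsistent =
                   sum(d$n_changed) / sum(d$n_with_inconsistency),
                 empty = FALSE, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  stop("report must be a consistency_report or group_change_report",
       call. = FALSE)
}
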