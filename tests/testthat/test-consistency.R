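test_that("pair classification follows the change taxonomy and is symmetric", {
  tok <- c("yes", "no", "unknown")
  for (a in tok) for (b in tok) {
    got <- classify_pair(a, b)
    expect_equal(got, if (a == b) "consistent" else "inconsistent",
                 info = paste(a, b))
    expect_equal(got, classify_pair(b, a))           # symmetry
  }
  expect_error(classify_pair("yes", "maybe"), "maybe")
})

test_that("hand-built toy table yields exact hand-enumerated proportions", {
  rep_ <- build_consistency_report(toy_two_session_table(),
                                   c(Fish = "nominal"))
  # 2 discordant pairs out of 6 (p1/i2, p3/i1)
  expect_equal(rep_$overall, 1 / 3)
  po <- rep_$participant_overall
  expect_equal(po$proportion[match(c("p1", "p2", "p3"), po$participant)],
               c(1 / 2, 0, 1 / 2))
  pc <- rep_$participant_category
  expect_true(pc$fully_consistent[pc$participant == "p2"])
  expect_false(any(pc$fully_consistent[pc$participant != "p2"]))
  it <- rep_$item_summary
  expect_equal(it$proportion[match(c("i1", "i2"), it$item)], c(1 / 3, 1 / 3))
  expect_false(any(it$zero_inconsistency))
})

test_that("perfect repetition and total flips give proportions 0 and 1", {
  base <- expand.grid(participant = c("p1", "p2"), item = c("a", "b"),
                      stringsAsFactors = FALSE)
  same <- response_table(
    participant = rep(base$participant, 2), category = "C",
    item = rep(base$item, 2), session = rep(1:2, each = 4),
    response = rep(c("yes", "no", "unknown", "yes"), 2))
  r0 <- build_consistency_report(same, c(C = "ad hoc"))
  expect_equal(r0$overall, 0)
  expect_true(all(r0$participant_category$fully_consistent))
  expect_true(all(r0$item_summary$zero_inconsistency))

  flipped <- response_table(
    participant = rep(base$participant, 2), category = "C",
    item = rep(base$item, 2), session = rep(1:2, each = 4),
    response = c("yes", "no", "unknown", "yes", "no", "yes", "yes", "no"))
  r1 <- build_consistency_report(flipped, c(C = "ad hoc"))
  expect_equal(r1$overall, 1)
  expect_equal(r1$participant_overall$proportion, c(1, 1))
})

test_that("unmapped categories and incomplete sessions are errors", {
  tab <- toy_two_session_table()
  expect_error(build_consistency_report(tab, c(Sports = "nominal")),
               "missing from block_map")
  broken <- as.data.frame(tab)[-1, ]
  class(broken) <- class(tab)
  expect_error(build_consistency_report(broken, c(Fish = "nominal")),
               "both sessions")
})

test_that("unknown/unknown pairs can be dropped from denominators", {
  tab <- response_table(
    participant = rep("p1", 6), category = "C",
    item = rep(c("a", "b", "c"), 2), session = rep(1:2, each = 3),
    response = c("unknown", "yes", "no", "unknown", "no", "no"))
  keep <- build_consistency_report(tab, c(C = "nominal"))
  expect_equal(keep$overall, 1 / 3)        # 1 change among 3 pairs
  drop <- build_consistency_report(tab, c(C = "nominal"),
                                   drop_unknown_pairs = TRUE)
  expect_equal(drop$overall, 1 / 2)        # unknown/unknown pair removed
})

test_that("overall proportion equals both marginal decompositions", {
  cfg <- small_sim_config(seed = 33L)
  truth <- generate_two_session_study(cfg)
  rep_ <- build_consistency_report(truth$table, c(synthetic = "nominal"))
  # equal item counts per participant and participant counts per item, so
  # both marginal means reproduce the overall proportion exactly
  expect_equal(mean(rep_$participant_overall$proportion), rep_$overall)
  expect_equal(mean(rep_$item_summary$proportion), rep_$overall)
})

test_that("group-change bookkeeping matches hand enumeration", {
  # 4 participants, 2 categories, 2 items; engineered inconsistencies:
  # cat1: A, B, C inconsistent, D fully consistent; cat2: only A
  mk <- function(cat, s2_resp) {
    response_table(
      participant = rep(c("A", "B", "C", "D"), each = 2),
      category = cat, item = rep(c("x", "y"), 4), session = 1L,
      response = rep("yes", 8)) -> s1
    s2 <- response_table(
      participant = rep(c("A", "B", "C", "D"), each = 2),
      category = cat, item = rep(c("x", "y"), 4), session = 2L,
      response = s2_resp)
    validate_response_table(structure(rbind(as.data.frame(s1),
                                            as.data.frame(s2)),
                                      class = class(s1)))
  }
  t1 <- mk("cat1", c("no", "yes", "no", "yes", "no", "yes", "yes", "yes"))
  t2 <- mk("cat2", c("no", "yes", "yes", "yes", "yes", "yes", "yes", "yes"))
  tab <- validate_response_table(structure(rbind(as.data.frame(t1),
                                                 as.data.frame(t2)),
                                           class = class(t1)))
  cons <- build_consistency_report(tab, c(cat1 = "nominal", cat2 = "ad hoc"))

  sp <- function(changed) {
    data.frame(participant = c("A", "B", "C", "D"),
               group1 = 1L, group2 = ifelse(changed, 2L, 1L),
               changed = changed, stringsAsFactors = FALSE)
  }
  pairs <- list(cat1 = sp(c(TRUE, TRUE, FALSE, FALSE)),   # A, B change
                cat2 = sp(c(TRUE, FALSE, FALSE, FALSE)))  # A changes
  rep_ <- build_group_change_report(pairs, cons)

  pp <- rep_$per_participant
  expect_equal(pp$n_categories_changed[match(c("A", "B", "C", "D"),
                                             pp$participant)],
               c(2, 1, 0, 0))
  expect_equal(as.numeric(rep_$change_count_distribution),
               c(2, 1, 1, 0))    # two with 0, one with 1, one with 2

  per_cat <- rep_$per_category
  c1 <- per_cat[per_cat$category == "cat1", ]
  # D is fully consistent on cat1, so the restricted denominator is 3
  expect_equal(c1$n_with_inconsistency, 3)
  expect_equal(c1$n_changed, 2)
  expect_equal(c1$change_rate_among_inconsistent, 2 / 3)
  c2 <- per_cat[per_cat$category == "cat2", ]
  expect_equal(c2$n_with_inconsistency, 1)
  expect_equal(c2$change_rate_among_inconsistent, 1)

  # change counts are label-invariant: swapping group identities changes
  # nothing about who changed
  pairs_swapped <- lapply(pairs, function(d) {
    d2 <- d; d2$group1 <- 3L - d$group1; d2$group2 <- 3L - d$group2; d2
  })
  rep2 <- build_group_change_report(pairs_swapped, cons)
  expect_equal(rep2$per_category$n_changed, per_cat$n_changed)

  # no changes anywhere: all mass at zero
  none <- lapply(pairs, function(d) { d$group2 <- d$group1; d$changed <- FALSE; d })
  rep0 <- build_group_change_report(none, cons)
  expect_equal(sum(rep0$per_category$n_changed), 0)
  expect_equal(as.numeric(rep0$change_count_distribution), c(4, 0, 0, 0))
})

test_that("block summaries aggregate rates and mark empty blocks", {
  tab <- toy_two_session_table()
  cons <- build_consistency_report(tab, c(Fish = "nominal"))
  bs <- block_prevalence_summary(cons)
  expect_equal(nrow(bs), 2L)
  nom <- bs[bs$block == "nominal", ]
  expect_equal(nom$mean, mean(c(1 / 2, 0, 1 / 2)))
  expect_equal(nom$n, 3L)
  adhoc <- bs[bs$block == "ad hoc", ]
  expect_true(adhoc$empty)
  expect_equal(adhoc$n, 0L)
  expect_false(any(is.nan(unlist(bs))))

  pairs <- data.frame(participant = c("p1", "p2", "p3"), category = "Fish",
                      group1 = 1L, group2 = c(2L, 1L, 1L),
                      changed = c(TRUE, FALSE, FALSE))
  gc_rep <- build_group_change_report(pairs, cons)
  gb <- block_prevalence_summary(gc_rep, c(Fish = "nominal"))
  expect_equal(gb$change_rate[gb$block == "nominal"], 1 / 3)
  expect_true(gb$empty[gb$block == "ad hoc"])
})
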