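test_that("reading a well-formed response CSV yields a validated table", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant,category,item,session,response",
               "p1,Fish,goldfish,1,yes",
               "p1,Fish,goldfish,2,YES"), f)
  tab <- read_responses(f)
  expect_s3_class(tab, "response_table")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$response, c("yes", "yes"))  # case-normalized
})

test_that("malformed response files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant,category,item,session,response",
               "p1,Fish,goldfish,1,yes",
               "p1,Fish,goldfish,1,no"), f)
  expect_error(read_responses(f), "duplicate")

  writeLines(c("participant,category,item,session,response",
               "p1,Fish,goldfish,1,maybe"), f)
  expect_error(read_responses(f), "maybe")

  writeLines(c("participant,category,session,response",
               "p1,Fish,1,yes"), f)
  expect_error(read_responses(f), "missing column")

  expect_error(read_responses(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("archival files without a session column default to session 1", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant,category,item,response",
               "a1,Fish,goldfish,yes"), f)
  tab <- read_responses(f, provenance = "archival")
  expect_equal(tab$session, 1L)
  expect_equal(tab$provenance, "archival")
})

test_that("archival records with session 2 violate the invariant", {
  expect_error(
    response_table("a1", "Fish", "goldfish", 2L, "yes", "archival"),
    "session = 1"
  )
})

test_that("merge_sessions builds 2n + archival entries with 0/1/NA coding", {
  new_tab <- response_table(
    participant = rep(c("p1", "p2"), each = 6),
    category = "Fish",
    item = rep(c("a", "b", "c"), times = 4),
    session = rep(rep(1:2, each = 3), times = 2),
    response = c("yes", "no", "unknown", "yes", "yes", "no",
                 "no", "no", "no", "yes", "no", "yes")
  )
  m <- merge_sessions(new_tab, NULL, "Fish")
  expect_equal(dim(m$x), c(4L, 3L))
  expect_equal(colnames(m$x), c("a", "b", "c"))       # lexicographic
  expect_equal(unname(m$x["p1.s1", ]), c(1, 0, NA))
  expect_equal(unname(m$x["p1.s2", ]), c(1, 1, 0))
  expect_equal(nrow(m$entry_index), 4L)

  arch <- response_table(
    participant = rep(c("a1", "a2", "a3"), each = 3),
    category = "Fish",
    item = rep(c("a", "b", "c"), times = 3),
    session = 1L,
    response = rep("yes", 9), provenance = "archival"
  )
  m2 <- merge_sessions(new_tab, arch, "Fish")
  expect_equal(nrow(m2$x), 2L * 2L + 3L)
  expect_equal(sum(m2$entry_index$provenance == "archival"), 3L)
})

test_that("participants missing a session are rejected (completers only)", {
  tab <- response_table(
    participant = c("p1", "p1", "p2"),
    category = "Fish", item = "a",
    session = c(1L, 2L, 1L),
    response = "yes"
  )
  expect_error(merge_sessions(tab, NULL, "Fish"), "only one session")
})

test_that("merge entry count is 2*n_new + n_archival over random sizes", {
  set.seed(401)
  for (trial in 1:8) {
    n_new <- sample(1:6, 1); n_arch <- sample(0:6, 1); n_it <- sample(2:5, 1)
    items <- paste0("it", seq_len(n_it))
    new_tab <- response_table(
      participant = rep(paste0("p", seq_len(n_new)), each = 2 * n_it),
      category = "C",
      item = rep(items, times = 2 * n_new),
      session = rep(rep(1:2, each = n_it), times = n_new),
      response = sample(c("yes", "no", "unknown"), 2 * n_new * n_it, TRUE)
    )
    arch <- if (n_arch > 0) {
      response_table(
        participant = rep(paste0("a", seq_len(n_arch)), each = n_it),
        category = "C", item = rep(items, times = n_arch), session = 1L,
        response = sample(c("yes", "no", "unknown"), n_arch * n_it, TRUE),
        provenance = "archival"
      )
    } else NULL
    m <- merge_sessions(new_tab, arch, "C")
    expect_equal(nrow(m$x), 2L * n_new + n_arch)
    expect_true(all(m$x %in% c(0, 1) | is.na(m$x)))
  }
})

test_that("merged matrices round-trip through CSV, including missing cells", {
  set.seed(77)
  new_tab <- response_table(
    participant = rep(c("p1", "p2"), each = 4),
    category = "C", item = rep(c("x", "y"), 4),
    session = rep(rep(1:2, each = 2), 2),
    response = sample(c("yes", "no", "unknown"), 8, TRUE, prob = c(.4, .4, .2))
  )
  m <- merge_sessions(new_tab, NULL, "C")
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, f)
  m2 <- read_matrix(f)
  expect_equal(m2$x, m$x)
  expect_equal(m2$entry_index, m$entry_index)
  expect_equal(m2$category, m$category)
  # missing is encoded distinctly from 0 in the file itself
  body <- readLines(f)
  expect_true(any(grepl("NA", body)))
})

test_that("response tables round-trip through CSV", {
  tab <- toy_two_session_table()
  f <- withr::local_tempfile(fileext = ".csv")
  write_responses(tab, f)
  back <- read_responses(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
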