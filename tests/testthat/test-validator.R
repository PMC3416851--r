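test_that("validation reports minimum distance, violations, and matrix", {
  rep <- validate_tags(tag_set(c("AAAA", "AAAT")), min_distance = 3)
  expect_identical(rep$observed_min_distance, 1L)
  expect_identical(nrow(rep$violations), 1L)
  expect_identical(rep$violations$distance, 1L)

  rep <- validate_tags(tag_set(c("AAAA", "TTTT")), min_distance = 3)
  expect_identical(rep$observed_min_distance, 4L)
  expect_identical(nrow(rep$violations), 0L)
  expect_identical(rep$conforming_count, 2L)

  expect_error(validate_tags(tag_set("AAAA"), min_distance = 3),
               "at least two")
  expect_error(validate_tags(tag_set(c("AAAA", "TTTT"))), "minimum distance")
})

test_that("the report matrix is symmetric with zero diagonal and exact violations", {
  set.seed(41)
  for (i in 1:6) {
    s <- random_tag_set(n_tags = 6L, len = 5L)
    d <- sample(2:4, 1L)
    rep <- validate_tags(s, min_distance = d)
    m <- rep$matrix
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0L))
    expect_identical(rep$observed_min_distance,
                     as.integer(min(m[upper.tri(m)])))
    n_below <- sum(m[upper.tri(m)] < d)
    expect_identical(nrow(rep$violations), n_below)
    expect_true(all(rep$violations$distance < d))
  }
})

test_that("validation is invariant to tag order", {
  set.seed(43)
  s <- random_tag_set(n_tags = 8L, len = 6L)
  rep <- validate_tags(s, min_distance = 3)
  for (i in 1:5) {
    perm <- sample(length(s))
    rep_p <- validate_tags(s[perm], min_distance = 3)
    expect_identical(rep_p$observed_min_distance, rep$observed_min_distance)
    expect_identical(nrow(rep_p$violations), nrow(rep$violations))
    key <- function(r) sort(paste(pmin(r$violations$tag1, r$violations$tag2),
                                  pmax(r$violations$tag1, r$violations$tag2),
                                  r$violations$distance))
    expect_identical(key(rep_p), key(rep))
    expect_identical(rep_p$matrix[names(s$sequences), names(s$sequences)],
                     rep$matrix)
  }
})

test_that("hamming and binary-hamming validation honour their metrics", {
  s <- tag_set(c("AAAA", "AATT"), metric = "hamming")
  rep <- validate_tags(s, min_distance = 2)
  expect_identical(rep$observed_min_distance, 2L)
  # A->T substitutions cost two bits each under binary encoding
  rep_b <- validate_tags(s, metric = "binary_hamming", min_distance = 2)
  expect_identical(rep_b$observed_min_distance, 4L)
})

test_that("slice validation extracts tags embedded in oligos", {
  s <- design_tags(4, 3)
  oligos <- paste0("GGTCA", s$sequences, "TTCAGGAC")
  embedded <- tag_set(oligos, names = names(s$sequences))
  rep_bare <- validate_tags(s, min_distance = 3)
  rep_slice <- validate_tags(embedded, metric = "edit", min_distance = 3,
                             slice = c(6, 9))
  expect_identical(rep_slice$matrix, rep_bare$matrix)
  expect_identical(rep_slice$observed_min_distance,
                   rep_bare$observed_min_distance)
  expect_error(validate_tags(embedded, metric = "edit", min_distance = 3,
                             slice = c(6, 99)), "beyond the end")
})

test_that("conforming-tag culling returns a conforming, near-maximal subset", {
  # already conforming: identity
  s <- tag_set(c("AAAA", "TTTT"))
  res <- conforming_tags(s, 3)
  expect_identical(res$count, 2L)
  expect_identical(res$tags$sequences, s$sequences)

  # one member of the close pair must go, the far tag stays
  res <- conforming_tags(tag_set(c("AAAA", "AAAT", "TTTT")), 3)
  expect_identical(res$count, 2L)
  expect_true("TTTT" %in% res$tags$sequences)

  # 4-mers can never be 5 apart
  res <- conforming_tags(tag_set(c("AAAA", "AAAT")), 5)
  expect_identical(res$count, 1L)

  expect_error(conforming_tags(s, 0), "integer >= 1")
})

test_that("culling is bounded by the exact maximum conforming subset", {
  set.seed(47)
  for (i in 1:5) {
    s <- random_tag_set(n_tags = 10L, len = 4L)
    d <- sample(2:3, 1L)
    res <- conforming_tags(s, d)
    if (res$count >= 2L) {
      rep <- validate_tags(res$tags, min_distance = d)
      expect_identical(nrow(rep$violations), 0L)
    }
    exact <- brute_force_max_conforming(unname(s$sequences), d)
    expect_lte(res$count, exact)
    # and at least as good as a random conforming subset
    random_sub <- plain_lexicode(sample(unname(s$sequences)), d)
    expect_gte(res$count, length(random_sub))
  }
})
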