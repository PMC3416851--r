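test_that("candidate enumeration is complete and lexicographic", {
  c1 <- enumerate_candidates(1)
  expect_identical(c1, c("A", "C", "G", "T"))
  c2 <- enumerate_candidates(2)
  expect_identical(length(c2), 16L)
  expect_identical(c2[1L], "AA")
  expect_identical(c2[16L], "TT")
  expect_identical(c2, sort(c2))
  expect_false(anyDuplicated(c2) > 0L)
  expect_error(enumerate_candidates(0), "integer >= 1")
  expect_error(enumerate_candidates(13), "not supported")
})

test_that("composition filters implement run, GC, and palindrome rules", {
  spec <- design_spec(4, 3)
  expect_false(passes_filters("AAAT", spec))  # run of three A
  expect_false(passes_filters("ACGT", spec))  # its own reverse complement
  expect_true(passes_filters("AACC", spec))   # GC 50%, runs of two, not palindromic
  expect_false(passes_filters("AATT", spec))  # GC 0%
  # inclusive GC bounds: 2/5 = 40% qualifies
  expect_true(passes_filters("CCATA", design_spec(5, 3)))
  off <- design_spec(4, 3, apply_filters = FALSE)
  expect_true(all(passes_filters(c("AAAA", "ACGT", "GGGG"), off)))
})

test_that("summary vectors histogram the pool by exact edit distance", {
  sv <- summarize_key("AA", enumerate_candidates(2))
  expect_identical(unname(sv$counts[1:3]), c(1L, 6L, 9L))
  expect_identical(sum(sv$counts), 16L)
  expect_gte(sv$counts[["0"]], 1L)

  sv1 <- summarize_key("ACG", "ACG")
  expect_identical(unname(sv1$counts[[1L]]), 1L)
  expect_identical(sum(sv1$counts), 1L)
})

test_that("key reduction keeps exactly the keys with the maximal count", {
  pool <- enumerate_candidates(2)
  vectors <- lapply(pool, summarize_key, candidates = pool)
  keys <- reduce_keys(vectors, 2)
  at2 <- vapply(vectors, function(v) v$counts[[3L]], integer(1L))
  expect_identical(keys, pool[at2 == max(at2)])
  expect_true("AA" %in% keys == (at2[1L] == max(at2)))

  # all tie -> all retained
  same <- lapply(c("AA", "TT"), summarize_key,
                 candidates = c("AA", "TT"))
  expect_identical(reduce_keys(same, 2), c("AA", "TT"))
  # a distance beyond the vector length counts as zero for every key
  expect_identical(reduce_keys(same, 9), c("AA", "TT"))
})

test_that("greedy construction yields pairwise-conforming sets", {
  pool <- enumerate_candidates(2)
  # d = 1: all distinct strings qualify
  expect_identical(length(build_set("AA", pool, 1)), 16L)
  # d = 3 exceeds the max distance between dimers
  expect_identical(unname(build_set("AA", pool, 3)$sequences), "AA")

  set.seed(53)
  for (i in 1:4) {
    pool4 <- enumerate_candidates(4)
    key <- sample(pool4, 1L)
    s <- build_set(key, pool4, 3)
    expect_identical(unname(s$sequences)[1L], key)
    rep <- validate_tags(s, min_distance = 3)
    expect_identical(nrow(rep$violations), 0L)
  }
})

test_that("full designs validate, conserve filters, and are maximal", {
  for (n in 4:6) {
    spec <- design_spec(n, 3)
    s <- design_tags(spec)
    rep <- validate_tags(s)
    expect_identical(nrow(rep$violations), 0L)
    expect_gte(rep$observed_min_distance, 3L)
    expect_true(all(passes_filters(unname(s$sequences), spec)))
    expect_true(is_maximal_design(s, spec))
  }
})

test_that("design without filters spans the whole space at distance one", {
  s <- design_tags(3, 1, apply_filters = FALSE)
  expect_identical(length(s), 64L)
})

test_that("default filters leave no candidates at length three", {
  # GC multiples of 1/3 never land in [40, 60]%
  expect_error(design_tags(3, 2), "no candidate survives")
})

test_that("design is deterministic and batching/workers do not change it", {
  ref <- design_tags(5, 3)
  expect_identical(design_tags(5, 3)$sequences, ref$sequences)
  chunked <- design_tags(design_spec(5, 3, filter_batch_size = 17L,
                                     row_batch_size = 7L))
  expect_identical(chunked$sequences, ref$sequences)
  parallel_run <- design_tags(design_spec(5, 3, workers = 2L,
                                          row_batch_size = 50L))
  expect_identical(parallel_run$sequences, ref$sequences)
})

test_that("design size is bracketed by the greedy baseline and the exact optimum", {
  skip_if_not_installed("igraph")
  # filtered length-4 pool at distance 3
  spec <- design_spec(4, 3)
  pool <- enumerate_candidates(4)
  pool <- pool[passes_filters(pool, spec)]
  size <- length(design_tags(spec))
  expect_gte(size, length(plain_lexicode(pool, 3)))
  expect_lte(size, igraph_max_code_size(pool, 3))

  # unfiltered length-3 pool at distance 2
  spec3 <- design_spec(3, 2, apply_filters = FALSE)
  pool3 <- enumerate_candidates(3)
  size3 <- length(design_tags(spec3))
  expect_gte(size3, length(plain_lexicode(pool3, 2)))
  expect_lte(size3, igraph_max_code_size(pool3, 2))
})

test_that("higher-distance subsets are conforming subsets of their parent", {
  s <- design_tags(6, 3)
  # identity at the design distance (same members, order aside)
  same <- extract_subset(s, 3)
  expect_setequal(unname(same$sequences), unname(s$sequences))

  sub <- extract_subset(s, 5)
  expect_true(all(sub$sequences %in% s$sequences))
  rep <- validate_tags(sub)
  expect_identical(rep$expected_min_distance, 5L)
  expect_identical(nrow(rep$violations), 0L)
  expect_gte(rep$observed_min_distance, 5L)

  expect_error(extract_subset(sub, 3), "below the set")
})

test_that("design specs validate their parameters", {
  expect_error(design_spec(5, 6), "cannot exceed")
  expect_error(design_spec(13, 3), "not supported")
  expect_error(design_spec(5, 3, gc_min = 70, gc_max = 60), "gc_min")
  expect_error(design_spec(5, 0), "integer >= 1")
})
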