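test_that("fusion primers collapse the tag/primer junction correctly", {
  r <- tag_primer("ACGT", "GTCCA", pigtail = "GTTT", trim = TRUE)
  expect_identical(r$sequence, "GTTTACGTCCA")
  expect_identical(r$trim_length, 2L)

  r <- tag_primer("ACGT", "GTCCA", pigtail = "GTTT", trim = FALSE)
  expect_identical(r$sequence, "GTTTACGTGTCCA")
  expect_identical(r$trim_length, 0L)

  # one-base overlap: the tag's trailing T and the primer's leading T
  # collapse, so only one survives in the oligo
  r <- tag_primer("ACGT", "TTCCA", pigtail = NULL, trim = TRUE)
  expect_identical(r$sequence, "ACGTTCCA")
  expect_identical(r$trim_length, 1L)

  expect_error(tag_primer("ACGT", "GT"), "swallows")
})

test_that("trimming removes exactly k bases of edit distance", {
  set.seed(61)
  for (i in 1:20) {
    tag <- random_dna(1L, 5L, 8L)
    primer <- random_dna(1L, 10L, 16L)
    untrimmed <- tag_primer(tag, primer, trim = FALSE)
    trimmed <- tag_primer(tag, primer, trim = TRUE)
    k <- trimmed$trim_length
    expect_identical(edit_distance(untrimmed$sequence, trimmed$sequence), k)
    # removing pigtail and tag leaves a suffix of the primer
    rest <- sub(paste0("^GTTT", tag), "", trimmed$sequence)
    expect_identical(rest, substring(primer, k + 1L))
  }
})

test_that("structure screening scores hairpins and dimers", {
  s <- screen_structure("GGGGAAACCCC")
  expect_gte(s$hairpin_stem_len, 4L)
  expect_true(s$flagged)

  s <- screen_structure("AAAAAAAAAA")
  expect_identical(s$hairpin_stem_len, 0L)
  expect_identical(s$self_dimer_len, 0L)
  expect_false(s$flagged)

  # a palindromic oligo pairs with a copy of itself over its full length
  s <- screen_structure("ACGT")
  expect_identical(s$self_dimer_len, 4L)
  expect_identical(s$hairpin_stem_len, 0L)

  s <- screen_structure("AAAA", partner = "TTTT")
  expect_identical(s$cross_dimer_len, 4L)
  expect_true(s$flagged)

  # loop shorter than min_loop does not count as a hairpin
  s <- screen_structure("GGGGACCCC", min_loop = 3)
  expect_lt(s$hairpin_stem_len, 4L)
})

test_that("batch primer tagging produces one row per tag with flags", {
  s <- design_tags(5, 3)
  tab <- tag_primers(s, "AGGTCAACGATGAGTC", "TGGTGCAGGTTCAGTT")
  expect_identical(nrow(tab), length(s))
  expect_identical(tab$tag, unname(s$sequences))
  expect_true(all(is.na(tab$error)))
  expect_true(all(startsWith(tab$upper_oligo, "GTTT")))

  passed <- tag_primers(s, "AGGTCAACGATGAGTC", "TGGTGCAGGTTCAGTT",
                        keep = "pass")
  expect_true(all(!passed$flagged))
  expect_lte(nrow(passed), nrow(tab))

  # per-row failures are recorded, not fatal
  short <- tag_set(c("AACAGT", "TTGGCA"))
  tab2 <- tag_primers(short, upper_primer = "GT", lower_primer = "CA")
  expect_identical(nrow(tab2), 2L)
  expect_true(any(!is.na(tab2$error)))
})

test_that("a pluggable screen replaces the internal heuristic", {
  s <- tag_set(c("AACAGT", "TTGGCA"))
  always_flag <- function(oligo, partner, min_stem, min_loop) {
    list(hairpin_stem_len = 99L, self_dimer_len = 0L,
         cross_dimer_len = 0L, flagged = TRUE)
  }
  tab <- tag_primers(s, "AGGTCAACGATGAGTC", "TGGTGCAGGTTCAGTT",
                     screen = always_flag)
  expect_true(all(tab$flagged))
  expect_identical(nrow(tag_primers(s, "AGGTCAACGATGAGTC",
                                    "TGGTGCAGGTTCAGTT",
                                    screen = always_flag, keep = "pass")),
                   0L)
})

test_that("adapters record the tag position for later extraction", {
  a <- tag_adapter("AATGA", "ACCTA", "AGATC")
  expect_identical(a$sequence, "AATGAACCTAAGATC")
  expect_identical(c(a$tag_start, a$tag_end), c(6L, 10L))
  expect_identical(substr(a$sequence, a$tag_start, a$tag_end), "ACCTA")

  bare <- tag_adapter("", "ACCTA", "")
  expect_identical(bare$sequence, "ACCTA")
  expect_identical(c(bare$tag_start, bare$tag_end), c(1L, 5L))
})

test_that("tagged adapters re-validate identically to the bare tag set", {
  s <- design_tags(5, 3)
  tab <- tag_adapters(s, "ACACTCTTTCCCTACACGACGCTCTTCCGATCT", "AGATCGGAAGAGC")
  expect_identical(nrow(tab), length(s))
  adapters <- tag_set(tab$sequence, names = tab$tag_name)
  rep_bare <- validate_tags(s, min_distance = 3)
  rep_embedded <- validate_tags(adapters, metric = "edit", min_distance = 3,
                                slice = c(tab$tag_start[1L], tab$tag_end[1L]))
  expect_identical(rep_embedded$matrix, rep_bare$matrix)
  expect_identical(rep_embedded$observed_min_distance,
                   rep_bare$observed_min_distance)
  expect_identical(nrow(rep_embedded$violations), 0L)
})
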