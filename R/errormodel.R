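#' Expected number of reads with errors in their tag
#'
#' Closed form for the number of reads, out of `reads`, whose tag
#' contains at least `min_errors` errors when each base errs
#' independently with probability `error_rate`: the per-read error count
#' is Binomial(`tag_length`, `error_rate`), so the expectation is
#' `reads * P(X >= min_errors)`. At a uniform 1% error rate, a million
#' reads, and 8-base tags, about 77,000 reads (8%) carry at least one tag
#' error -- which is why tag sets need error-correction headroom at all.
#'
#' @param error_rate per-base error probability, in `[0, 1]`.
#' @param tag_length tag length in bases.
#' @param reads number of reads per run.
#' @param min_errors count reads with at least this many tag errors. The
#'   default 1 ("any error") reproduces the conventional 8% figure;
#'   set 2 for the stricter "more than one error" reading.
#' @return expected count of affected reads (a real number).
#' @examples
#' expected_error_reads(0.01, 8, 1e6)
#' @export
expected_error_reads <- function(error_rate, tag_length, reads = 1e6,
                                 min_errors = 1L) {
  stopifnot(is.numeric(error_rate), error_rate >= 0, error_rate <= 1)
  tag_length <- check_count(tag_length, "tag_length", min = 1L)
  min_errors <- check_count(min_errors, "min_errors", min = 1L)
  stopifnot(is.numeric(reads), reads >= 0)
  reads * stats::pbinom(min_errors - 1L, tag_length, error_rate,
                        lower.tail = FALSE)
}

#' Monte-Carlo count of reads with errors in their tag
#'
#' Simulates `reads` tags whose bases err independently at `error_rate`,
#' the errors split among substitutions, insertions, and deletions
#' according to `error_mix` (the split does not change how many reads are
#' affected, only what the errors look like; it matters when corrupted
#' sequences themselves are needed, see [corrupt_tag()]). Returns the
#' number of reads with at least `min_errors` errors; converges to
#' [expected_error_reads()] as `reads` grows.
#'
#' @inheritParams expected_error_reads
#' @param error_mix length-3 non-negative proportions
#'   (substitution, insertion, deletion) summing to 1.
#' @param seed integer seed for reproducibility; `NULL` uses the current
#'   RNG state.
#' @return integer count of affected reads.
#' @examples
#' simulate_error_reads(0.01, 8, 1e5, seed = 1)
#' @export
simulate_error_reads <- function(error_rate, tag_length, reads = 1e6,
                                 min_errors = 1L, seed = NULL,
                                 error_mix = c(1, 0, 0)) {
  stopifnot(is.numeric(error_rate), error_rate >= 0, error_rate <= 1)
  tag_length <- check_count(tag_length, "tag_length", min = 1L)
  min_errors <- check_count(min_errors, "min_errors", min = 1L)
  reads <- check_count(reads, "reads", min = 0L)
  check_error_mix(error_mix)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  errs <- stats::rbinom(reads, tag_length, error_rate)
  sum(errs >= min_errors)
}

check_error_mix <- function(error_mix) {
  if (!is.numeric(error_mix) || length(error_mix) != 3L ||
      any(error_mix < 0) || abs(sum(error_mix) - 1) > 1e-9)
    stop("error_mix must be 3 non-negative proportions summing to 1",
         call. = FALSE)
  invisible(error_mix)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Corrupt a tag with random errors
#'
#' Applies `n_errors` random edit operations to a sequence, drawn from
#' `error_mix` (substitution, insertion, deletion). Substitutions always
#' change the base; insertions draw a uniform base. Useful for exercising
#' error-correcting demultiplexing.
#'
#' @param sequence tag sequence.
#' @param n_errors number of edit operations to apply.
#' @param error_mix see [simulate_error_reads()].
#' @return the corrupted sequence (possibly at edit distance less than
#'   `n_errors` from the input, since operations can cancel).
#' @export
corrupt_tag <- function(sequence, n_errors = 1L,
                        error_mix = c(1 / 3, 1 / 3, 1 / 3)) {
  sequence <- normalize_sequence(sequence)
  stopifnot(length(sequence) == 1L)
  n_errors <- check_count(n_errors, "n_errors", min = 0L)
  check_error_mix(error_mix)
  bases <- c("A", "C", "G", "T")
  s <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  for (i in seq_len(n_errors)) {
    op <- sample.int(3L, 1L, prob = error_mix)
    if (op == 3L && length(s) == 0L) op <- 2L
    if (op == 1L && length(s) == 0L) op <- 2L
    if (op == 1L) {            # substitution
      pos <- sample.int(length(s), 1L)
      s[pos] <- sample(setdiff(bases, s[pos]), 1L)
    } else if (op == 2L) {     # insertion
      pos <- sample.int(length(s) + 1L, 1L)
      s <- append(s, sample(bases, 1L), after = pos - 1L)
    } else {                   # deletion
      pos <- sample.int(length(s), 1L)
      s <- s[-pos]
    }
  }
  paste(s, collapse = "")
}

#' All sequences within an edit radius of a tag
#'
#' Exhaustively enumerates every string reachable from `sequence` by at
#' most `radius` single-base substitutions, insertions, or deletions over
#' the DNA alphabet. Used to verify the round-trip guarantee of
#' error-correcting tag sets: for a set of minimum edit distance `d`,
#' every corruption of a tag by up to `floor((d - 1) / 2)` edits must be
#' assigned back to that tag.
#'
#' @param sequence tag sequence.
#' @param radius maximum number of edit operations.
#' @return character vector of distinct sequences (including the input).
#' @export
edit_neighborhood <- function(sequence, radius = 1L) {
  sequence <- normalize_sequence(sequence)
  stopifnot(length(sequence) == 1L)
  radius <- check_count(radius, "radius", min = 0L)
  bases <- c("A", "C", "G", "T")
  one_edit <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    out <- character(0)
    for (i in seq_len(n)) {                       # substitutions
      for (b in bases[bases != ch[i]])
        out <- c(out, paste(c(ch[seq_len(i - 1L)], b,
                              ch[seq_len(n - i) + i]), collapse = ""))
    }
    if (n > 0L)                                    # deletions
      for (i in seq_len(n))
        out <- c(out, paste(ch[-i], collapse = ""))
    for (i in seq_len(n + 1L)) {                  # insertions
      for (b in bases)
        out <- c(out, paste(c(ch[seq_len(i - 1L)], b,
                              ch[seq_len(n - i + 1L) + i - 1L]),
                            collapse = ""))
    }
    out
  }
  frontier <- sequence
  seen <- sequence
  for (r in seq_len(radius)) {
    frontier <- setdiff(unique(unlist(lapply(frontier, one_edit))), seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' Fraction of single-base substitutions uncorrectable under binary
#' encoding
#'
#' Under a two-bit-per-base encoding, a single nucleotide substitution
#' changes one bit for four of the six unordered base pairs but two bits
#' for the remaining two "diagonal" pairs (A/T and C/G under the default
#' encoding). A bit-level Hamming code that corrects single-bit errors
#' therefore cannot correct those double-bit substitutions: 2/6 (33%) of
#' single-base substitutions are detectable but uncorrectable, whichever
#' systematic encoding is chosen.
#'
#' @param encoding see [binary_encode()].
#' @return a list with elements `uncorrectable` (2/6), `correctable`
#'   (4/6), and `pairs` (a data frame of the six base pairs and their bit
#'   distances).
#' @examples
#' uncorrectable_substitution_fraction()
#' @export
uncorrectable_substitution_fraction <- function(
    encoding = default_binary_encoding()) {
  bases <- c("A", "C", "G", "T")
  combs <- utils::combn(bases, 2L)
  bits <- binary_hamming_distance(combs[1L, ], combs[2L, ],
                                  encoding = encoding)
  pairs <- data.frame(base1 = combs[1L, ], base2 = combs[2L, ],
                      bit_distance = bits, stringsAsFactors = FALSE)
  list(uncorrectable = mean(bits == 2L), correctable = mean(bits == 1L),
       pairs = pairs)
}

#' Assign an observed sequence to a tag by error correction
#'
#' Nearest-tag assignment within the set's correction radius
#' `r = floor((d - 1) / 2)`, where `d` is the set's validated minimum
#' edit distance: an exact match wins; otherwise the unique tag within
#' edit distance `r` is returned; anything else (nothing within `r`, or a
#' tie) is unassignable and yields `NA`.
#'
#' @param observed character vector of observed (possibly corrupted) tag
#'   sequences.
#' @param set a [tag_set()] with a declared `min_distance`; the set is
#'   re-validated unless `validated = TRUE` (the correction radius is
#'   meaningless for a non-conforming set).
#' @param validated set `TRUE` to skip re-validation (e.g. in a loop over
#'   many reads).
#' @return character vector of assigned tag names, `NA` where
#'   unassignable.
#' @examples
#' s <- tag_set(c("AACC", "GGTT"), min_distance = 3)
#' assign_tag("AACG", s)
#' @export
assign_tag <- function(observed, set, validated = FALSE) {
  stopifnot(inherits(set, "tag_set"))
  if (is.null(set$min_distance))
    stop("set has no declared minimum distance; correction radius undefined",
         call. = FALSE)
  if (!isTRUE(validated)) {
    rep <- validate_tags(set, metric = "edit")
    if (nrow(rep$violations) > 0L)
      stop("set does not conform to its declared minimum distance (",
           nrow(rep$violations), " violating pair(s)); refusing to correct",
           call. = FALSE)
  }
  observed <- normalize_sequence(observed, allow_empty = TRUE)
  r <- (set$min_distance - 1L) %/% 2L
  pool <- unname(set$sequences)
  nms <- names(set$sequences)
  vapply(observed, function(q) {
    d <- .dist_to_pool_cpp(q, pool)
    hit <- which(d == 0L)
    if (length(hit) == 1L) return(nms[[hit]])
    within <- which(d <= r)
    if (length(within) == 1L) nms[[within]] else NA_character_
  }, character(1L), USE.NAMES = FALSE)
}
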