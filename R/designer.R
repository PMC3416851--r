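#' Specify a tag design run
#'
#' Collects the parameters of an edit-metric tag design: tag length,
#' target minimum distance, composition filters, and throughput knobs.
#' The default filters reject candidates with a homopolymer run longer
#' than 2, GC content outside 40--60% (inclusive), or perfect
#' self-complementarity (a sequence equal to its own reverse complement,
#' which favours hairpin/dimer formation). Batch sizes and worker count
#' only affect how the work is chunked; the result is identical to a
#' serial run.
#'
#' @param tag_length tag length in nucleotides (1--12).
#' @param min_distance target minimum edit distance `d`, `1 <= d <=`
#'   `tag_length`.
#' @param max_homopolymer_run longest allowed run of a single base.
#'   Homopolymers are error-prone on pyrosequencing-type platforms.
#' @param gc_min,gc_max inclusive GC-content bounds, in percent.
#' @param reject_self_complement drop candidates equal to their own
#'   reverse complement.
#' @param apply_filters set `FALSE` to disable all composition filters.
#' @param filter_batch_size candidates per chunk during filtering.
#' @param row_batch_size keys per chunk during summary-vector computation.
#' @param workers number of worker processes ([parallel::mclapply()]); 1
#'   means serial.
#' @return an object of class `design_spec`.
#' @examples
#' design_spec(5, 3)
#' @export
design_spec <- function(tag_length, min_distance, max_homopolymer_run = 2L,
                        gc_min = 40, gc_max = 60,
                        reject_self_complement = TRUE, apply_filters = TRUE,
                        filter_batch_size = 25000L, row_batch_size = 500L,
                        workers = 1L) {
  tag_length <- check_count(tag_length, "tag_length", min = 1L)
  if (tag_length > 12L)
    stop("tag_length above 12 is not supported (4^n candidates)",
         call. = FALSE)
  min_distance <- check_count(min_distance, "min_distance", min = 1L)
  if (min_distance > tag_length)
    stop("min_distance cannot exceed tag_length", call. = FALSE)
  max_homopolymer_run <- check_count(max_homopolymer_run,
                                     "max_homopolymer_run", min = 1L)
  if (!is.numeric(gc_min) || !is.numeric(gc_max) || gc_min < 0 ||
      gc_max > 100 || gc_min > gc_max)
    stop("need 0 <= gc_min <= gc_max <= 100", call. = FALSE)
  structure(
    list(tag_length = tag_length, min_distance = min_distance,
         max_homopolymer_run = max_homopolymer_run,
         gc_min = gc_min, gc_max = gc_max,
         reject_self_complement = isTRUE(reject_self_complement),
         apply_filters = isTRUE(apply_filters),
         filter_batch_size = check_count(filter_batch_size,
                                         "filter_batch_size", min = 1L),
         row_batch_size = check_count(row_batch_size, "row_batch_size",
                                      min = 1L),
         workers = check_count(workers, "workers", min = 1L)),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> length %d, min edit distance %d\n",
              x$tag_length, x$min_distance))
  if (x$apply_filters) {
    cat(sprintf("  filters: max run %d, GC in [%g, %g]%%, %s\n",
                x$max_homopolymer_run, x$gc_min, x$gc_max,
                if (x$reject_self_complement) "no self-complements"
                else "self-complements allowed"))
  } else cat("  filters: off\n")
  cat(sprintf("  batching: %d candidates / %d rows per chunk, %d worker(s)\n",
              x$filter_batch_size, x$row_batch_size, x$workers))
  invisible(x)
}

#' Enumerate all candidate tags of a given length
#'
#' All `4^n` sequences of length `n` in lexicographic order with
#' `A < C < G < T`. This ordering is the committed convention of the
#' designer; greedy code construction is order-sensitive, so a different
#' (equally valid) ordering can change the designed set and its size by a
#' few tags.
#'
#' @param n tag length, 1--12.
#' @return character vector of `4^n` sequences.
#' @examples
#' enumerate_candidates(2)[1:5]
#' @export
enumerate_candidates <- function(n) {
  n <- check_count(n, "n", min = 1L)
  if (n > 12L) stop("n above 12 is not supported", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  out <- bases
  for (i in seq_len(n - 1L)) {
    out <- as.vector(t(outer(out, bases, paste0)))
  }
  out
}

#' Composition filters for candidate tags
#'
#' @param seqs character vector of candidate sequences.
#' @param spec a [design_spec()]; only its filter fields are used.
#' @return logical vector: `TRUE` where the candidate passes every
#'   enabled filter.
#' @examples
#' passes_filters(c("AAAT", "ACGT", "AACC"), design_spec(4, 3))
#' @export
passes_filters <- function(seqs, spec) {
  stopifnot(inherits(spec, "design_spec"))
  seqs <- normalize_sequence(seqs)
  if (!spec$apply_filters) return(rep(TRUE, length(seqs)))
  k <- spec$max_homopolymer_run + 1L
  run_re <- sprintf("A{%d}|C{%d}|G{%d}|T{%d}", k, k, k, k)
  ok <- !grepl(run_re, seqs)
  gc <- 100 * nchar(gsub("[AT]", "", seqs)) / nchar(seqs)
  ok <- ok & gc >= spec$gc_min & gc <= spec$gc_max
  if (spec$reject_self_complement)
    ok <- ok & seqs != reverse_complement(seqs)
  ok
}

#' Summary vector of a key against a candidate pool
#'
#' Histogram of edit distances from one key to every candidate:
#' element `i + 1` of `counts` is the number of candidates at edit
#' distance exactly `i`. Keeping one short vector per key instead of the
#' full pairwise matrix is what makes long-tag design tractable: the full
#' matrix for length-10 tags (about 550 billion pairs) would occupy
#' hundreds of gigabytes.
#'
#' @param key a single sequence drawn from the pool.
#' @param candidates character vector of candidate sequences.
#' @return an object of class `summary_vector`: a list with elements
#'   `key` and `counts` (integer vector indexed by distance 0..max).
#' @examples
#' summarize_key("AA", enumerate_candidates(2))
#' @export
summarize_key <- function(key, candidates) {
  key <- normalize_sequence(key)
  candidates <- normalize_sequence(candidates)
  stopifnot(length(key) == 1L)
  max_d <- max(nchar(key), nchar(candidates))
  counts <- .count_by_distance_cpp(key, candidates, max_d)[1L, ]
  names(counts) <- 0:max_d
  structure(list(key = key, counts = counts), class = "summary_vector")
}

#' @export
print.summary_vector <- function(x, ...) {
  cat(sprintf("<summary_vector> key %s\n", x$key))
  nz <- x$counts[x$counts > 0]
  cat(paste(sprintf("  distance %s: %d", names(nz), nz), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Reduce a set of keys by their summary vectors
#'
#' Retains the keys whose count of candidates at exactly the target
#' distance is maximal, preserving their original order. This pruning
#' removes the overwhelming majority of keys before the expensive greedy
#' construction (roughly 99% for length-8 tags) while keeping the keys
#' most likely to seed large codes.
#'
#' @param vectors a list of [summarize_key()] results computed over the
#'   same candidate pool.
#' @param min_distance the target minimum edit distance.
#' @return character vector of the retained key sequences.
#' @export
reduce_keys <- function(vectors, min_distance) {
  min_distance <- check_count(min_distance, "min_distance", min = 1L)
  stopifnot(all(vapply(vectors, inherits, logical(1L), "summary_vector")))
  at_d <- vapply(vectors, function(v) {
    if (min_distance + 1L > length(v$counts)) 0L
    else as.integer(v$counts[[min_distance + 1L]])
  }, integer(1L))
  keys <- vapply(vectors, `[[`, character(1L), "key")
  keys[at_d == max(at_d)]
}

#' Greedy code construction around a key
#'
#' Builds a minimum-distance code seeded by `key`: candidates are scanned
#' in their given (lexicographic) order, any candidate closer than
#' `min_distance` to the key is dropped, and a candidate is retained iff
#' it is at least `min_distance` from every previously retained one. The
#' key is the first member of the returned set, so every pair in the
#' result is at least `min_distance` apart.
#'
#' @param key seed sequence (a member of the pool).
#' @param candidates character vector of candidates in scan order.
#' @param min_distance target minimum edit distance.
#' @return a [tag_set()] whose first tag is the key.
#' @examples
#' build_set("AACC", enumerate_candidates(4), min_distance = 3)
#' @export
build_set <- function(key, candidates, min_distance) {
  key <- normalize_sequence(key)
  stopifnot(length(key) == 1L)
  candidates <- normalize_sequence(candidates)
  min_distance <- check_count(min_distance, "min_distance", min = 1L)
  keep <- .greedy_build_cpp(key, candidates, min_distance)
  seqs <- c(key, candidates[keep])
  out <- tag_set(seqs, metric = "edit", min_distance = min_distance,
                 set_name = sprintf("L%dD%d", nchar(key), min_distance))
  attr(out, "key") <- key
  out
}

#' Design a maximal edit-metric tag set
#'
#' End-to-end greedy lexicode design: enumerate all candidates of the
#' requested length, apply the composition filters, compute a summary
#' vector for every surviving candidate (in batches, optionally across
#' workers), prune to the keys with the maximal count at the target
#' distance, run the greedy construction around each retained key, and
#' return the largest resulting set (ties broken by the lexicographically
#' smallest key). The result always validates at the target distance with
#' zero violations and is maximal: no filtered candidate outside the set
#' is at least `min_distance` from every member.
#'
#' @param spec a [design_spec()], or a tag length (with `min_distance`
#'   given) for convenience.
#' @param min_distance target minimum edit distance when `spec` is a
#'   length.
#' @param ... passed to [design_spec()] when `spec` is a length.
#' @return a [tag_set()]; attribute `key` records the seed key.
#' @examples
#' design_tags(4, 3)
#' @export
design_tags <- function(spec, min_distance = NULL, ...) {
  if (!inherits(spec, "design_spec"))
    spec <- design_spec(spec, min_distance, ...)
  d <- spec$min_distance
  pool <- enumerate_candidates(spec$tag_length)
  keep <- in_batches(pool, spec$filter_batch_size, spec$workers,
                     function(chunk) passes_filters(chunk, spec))
  pool <- pool[keep]
  if (length(pool) == 0L)
    stop("no candidate survives the composition filters", call. = FALSE)
  counts_at_d <- in_batches(pool, spec$row_batch_size, spec$workers,
                            function(chunk) {
                              .count_by_distance_cpp(chunk, pool, d)[, d + 1L]
                            })
  keys <- pool[counts_at_d == max(counts_at_d)]
  sets <- lapply(keys, build_set, candidates = pool, min_distance = d)
  sizes <- lengths(sets)
  # largest set wins; ties go to the lexicographically smallest key,
  # which is the earliest since keys inherit the pool's order
  best <- sets[[which.max(sizes)]]
  best$name <- sprintf("L%dD%d", spec$tag_length, d)
  attr(best, "design_spec") <- spec
  best
}

in_batches <- function(x, batch_size, workers, fn) {
  idx <- seq_along(x)
  chunks <- split(idx, ceiling(idx / batch_size))
  apply_fn <- if (workers > 1L) {
    function(ch) parallel::mclapply(ch, function(i) fn(x[i]),
                                    mc.cores = workers)
  } else {
    function(ch) lapply(ch, function(i) fn(x[i]))
  }
  unlist(apply_fn(chunks), use.names = FALSE)
}

#' Extract a higher-distance subset from a designed set
#'
#' Shortcut for obtaining tags at a distance above the design distance
#' without re-running the full design: each member of the set is tried as
#' a key, the members at least `min_distance` from it are greedily
#' retained (in set order) subject to pairwise conformance, and the
#' largest resulting subset is returned (ties to the lexicographically
#' smallest key). The subset validates at `min_distance` but is generally
#' smaller than a from-scratch design at that distance.
#'
#' @param set a designed [tag_set()].
#' @param min_distance target distance, at least the set's design
#'   distance.
#' @return a [tag_set()] with `min_distance` updated.
#' @export
extract_subset <- function(set, min_distance) {
  stopifnot(inherits(set, "tag_set"))
  min_distance <- check_count(min_distance, "min_distance", min = 1L)
  if (!is.null(set$min_distance) && min_distance < set$min_distance)
    stop("min_distance is below the set's design distance", call. = FALSE)
  seqs <- unname(set$sequences)
  best <- NULL; best_key <- NULL
  for (i in seq_along(seqs)) {
    keep <- .greedy_build_cpp(seqs[[i]], seqs, min_distance)
    cand <- c(seqs[[i]], seqs[keep])
    better <- is.null(best) || length(cand) > length(best) ||
      (length(cand) == length(best) && seqs[[i]] < best_key)
    if (better) { best <- cand; best_key <- seqs[[i]] }
  }
  nm <- names(set$sequences)[match(best, set$sequences)]
  out <- tag_set(best, names = nm, metric = "edit",
                 min_distance = min_distance,
                 set_name = sprintf("%s_D%d", set$name, min_distance))
  attr(out, "key") <- best_key
  out
}
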