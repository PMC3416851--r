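#' Validate a tag set against its distance metric
#'
#' Computes all `N(N-1)/2` pairwise distances among the tags and reports
#' the observed minimum distance, every pair falling below the expected
#' minimum, and the full distance matrix. Published tag sets -- commercial
#' and otherwise -- sometimes contain pairs below their advertised
#' distance, which silently breaks error-corrected demultiplexing, so
#' auditing a set before use is cheap insurance.
#'
#' Tags embedded in primers or adapters can be audited in place: pass the
#' oligos as the set and give `slice` the 1-based inclusive start and end
#' of the tag within each oligo; the slice is extracted and validation
#' proceeds on the extracted tags.
#'
#' @param set a [tag_set()] with at least two tags.
#' @param metric distance metric; defaults to the metric declared on the
#'   set.
#' @param min_distance expected minimum distance; defaults to the value
#'   declared on the set.
#' @param slice optional integer pair `c(start, end)` (1-based, inclusive)
#'   locating the tag within each sequence.
#' @return an object of class `tag_report`: a list with elements `metric`,
#'   `expected_min_distance`, `observed_min_distance`, `violations` (a
#'   data frame with columns `tag1`, `tag2`, `distance` for every pair
#'   below the expected minimum), `matrix` (symmetric pairwise distance
#'   matrix with zero diagonal), and `conforming_count` (tags retained by
#'   [conforming_tags()] at the expected minimum).
#' @examples
#' s <- tag_set(c("AAAA", "AAAT", "TTTT"), min_distance = 3)
#' validate_tags(s)
#' @export
validate_tags <- function(set, metric = NULL, min_distance = NULL,
                          slice = NULL) {
  stopifnot(inherits(set, "tag_set"))
  if (is.null(metric)) metric <- set$metric
  metric <- match.arg(metric, TAG_METRICS)
  if (is.null(min_distance)) min_distance <- set$min_distance
  if (is.null(min_distance))
    stop("no expected minimum distance declared on the set or supplied",
         call. = FALSE)
  min_distance <- check_count(min_distance, "min_distance", min = 1L)
  seqs <- slice_sequences(set$sequences, slice)
  if (length(seqs) < 2L)
    stop("validation needs at least two tags", call. = FALSE)
  m <- pairwise_matrix(seqs, metric)
  ut <- upper.tri(m)
  d_obs <- min(m[ut])
  viol <- which(ut & m < min_distance, arr.ind = TRUE)
  violations <- data.frame(
    tag1 = rownames(m)[viol[, 1L]],
    tag2 = colnames(m)[viol[, 2L]],
    distance = m[viol],
    stringsAsFactors = FALSE
  )
  report <- structure(
    list(metric = metric, expected_min_distance = min_distance,
         observed_min_distance = as.integer(d_obs), violations = violations,
         matrix = m, conforming_count = NA_integer_),
    class = "tag_report"
  )
  report$conforming_count <-
    if (nrow(violations) == 0L) length(seqs)
    else conforming_from_matrix(m, seqs, min_distance)$count
  report
}

slice_sequences <- function(seqs, slice) {
  if (is.null(slice)) return(seqs)
  if (length(slice) != 2L || any(slice < 1L) || slice[2L] < slice[1L])
    stop("slice must be c(start, end), 1-based inclusive", call. = FALSE)
  if (any(nchar(seqs) < slice[2L]))
    stop("slice extends beyond the end of at least one sequence",
         call. = FALSE)
  out <- substr(seqs, slice[1L], slice[2L])
  names(out) <- names(seqs)
  out
}

pairwise_matrix <- function(seqs, metric) {
  if (metric != "edit" && length(unique(nchar(seqs))) > 1L)
    stop("all sequences must have equal length under a Hamming metric",
         call. = FALSE)
  x <- if (metric == "binary_hamming") binary_encode(seqs) else seqs
  m <- .dist_matrix_cpp(unname(x), if (metric == "edit") 0L else 1L)
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}

#' @export
print.tag_report <- function(x, ...) {
  cat(sprintf("<tag_report> metric = %s, expected min distance = %d\n",
              x$metric, x$expected_min_distance))
  cat(sprintf("  tags: %d; observed min distance: %d; violating pairs: %d\n",
              nrow(x$matrix), x$observed_min_distance, nrow(x$violations)))
  if (nrow(x$violations)) {
    v <- utils::head(x$violations, 10L)
    cat(paste0("    ", v$tag1, " ~ ", v$tag2, " : ", v$distance,
               collapse = "\n"), "\n")
    if (nrow(x$violations) > 10L)
      cat(sprintf("    ... and %d more\n", nrow(x$violations) - 10L))
  }
  invisible(x)
}

#' Cull a tag set down to a conforming subset
#'
#' Greedily removes tags until every remaining pair is at least
#' `min_distance` apart: at each step the tag participating in the most
#' sub-threshold pairs is dropped (ties are broken by dropping the
#' lexicographically larger sequence). This reproduces the
#' "tags at or above the expected distance" accounting used when auditing
#' published sets, and gives a deterministic, usually near-maximal
#' conforming subset of a corrupted set.
#'
#' @param set a [tag_set()].
#' @param min_distance distance threshold every retained pair must meet.
#' @param metric distance metric; defaults to the set's declared metric.
#' @return a list with elements `count` (number of retained tags) and
#'   `tags` (a [tag_set()] of the retained tags, in input order, with
#'   `min_distance` updated to the threshold).
#' @examples
#' s <- tag_set(c("AAAA", "AAAT", "TTTT"))
#' conforming_tags(s, min_distance = 3)
#' @export
conforming_tags <- function(set, min_distance, metric = NULL) {
  stopifnot(inherits(set, "tag_set"))
  if (is.null(metric)) metric <- set$metric
  metric <- match.arg(metric, TAG_METRICS)
  min_distance <- check_count(min_distance, "min_distance", min = 1L)
  m <- pairwise_matrix(set$sequences, metric)
  res <- conforming_from_matrix(m, set$sequences, min_distance)
  retained <- set[res$keep]
  retained$min_distance <- min_distance
  list(count = res$count, tags = retained)
}

conforming_from_matrix <- function(m, seqs, min_distance) {
  n <- length(seqs)
  alive <- rep(TRUE, n)
  conflict <- m < min_distance
  diag(conflict) <- FALSE
  repeat {
    deg <- rowSums(conflict[, alive, drop = FALSE]) * alive
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    if (length(worst) > 1L) {
      # drop the lexicographically larger sequence
      worst <- worst[order(seqs[worst], decreasing = TRUE)][1L]
    }
    alive[worst] <- FALSE
    conflict[worst, ] <- FALSE
    conflict[, worst] <- FALSE
  }
  list(count = sum(alive), keep = which(alive))
}
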