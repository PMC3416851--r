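#' Normalize nucleotide sequences
#'
#' Uppercases sequences and verifies they contain only A, C, G, T. IUPAC
#' ambiguity codes, gaps, and U are rejected: sequence tags are synthetic
#' oligonucleotides and are always written in the four-letter DNA alphabet.
#'
#' @param x character vector of sequences.
#' @param allow_empty logical; accept empty strings (distances to the empty
#'   string are well defined, tags themselves may not be empty).
#' @return the normalized (uppercase) character vector.
#' @examples
#' normalize_sequence(c("acgt", "TTaa"))
#' @export
normalize_sequence <- function(x, allow_empty = FALSE) {
  if (!is.character(x)) stop("sequences must be character", call. = FALSE)
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x)
  if (!allow_empty) bad <- bad | !nzchar(x)
  if (any(bad)) {
    stop("invalid sequence(s), only A/C/G/T allowed: ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  }
  x
}

#' Reverse complement
#'
#' @param x character vector of normalized sequences.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("AACG")
#' @export
reverse_complement <- function(x) {
  x <- normalize_sequence(x, allow_empty = TRUE)
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

#' Levenshtein (edit) distance
#'
#' Unit-cost global edit distance: the minimum number of single-base
#' insertions, deletions, and substitutions transforming one sequence into
#' the other, computed by dynamic programming. This is the metric under
#' which indel-robust sequence tags are designed: two equal-length tags can
#' be Hamming distance 8 apart yet edit distance 2, so Hamming separation
#' alone does not protect against indels.
#'
#' @param a,b character vectors of sequences (recycled to a common length).
#'   Empty strings are allowed; the distance to the empty string is the
#'   length of the other sequence.
#' @return integer vector of distances.
#' @examples
#' edit_distance("ACGTACGT", "GACGTACG")   # 2, despite Hamming distance 8
#' @seealso [hamming_distance()], [binary_hamming_distance()]
#' @export
edit_distance <- function(a, b) {
  a <- normalize_sequence(a, allow_empty = TRUE)
  b <- normalize_sequence(b, allow_empty = TRUE)
  n <- max(length(a), length(b))
  .edit_dist_cpp(rep_len(a, n), rep_len(b, n))
}

#' Hamming distance
#'
#' Number of differing positions between equal-length sequences. Undefined
#' (an error) for unequal lengths, because the Hamming metric has no notion
#' of insertion or deletion.
#'
#' @inheritParams edit_distance
#' @return integer vector of distances.
#' @examples
#' hamming_distance("ACGTACGT", "GACGTACG")  # 8
#' @export
hamming_distance <- function(a, b) {
  a <- normalize_sequence(a, allow_empty = TRUE)
  b <- normalize_sequence(b, allow_empty = TRUE)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b)))
    stop("Hamming distance is undefined for unequal lengths", call. = FALSE)
  .hamming_dist_cpp(a, b)
}

#' Default two-bit nucleotide encoding
#'
#' The conventional binary encoding used when Hamming codes are applied to
#' DNA barcodes: T = 00, G = 01, C = 10, A = 11. Any systematic two-bit
#' assignment works; this is the default throughout the package.
#'
#' @return named character vector of two-bit codes for A, C, G, T.
#' @export
default_binary_encoding <- function() {
  c(A = "11", C = "10", G = "01", T = "00")
}

check_encoding <- function(encoding) {
  if (!is.character(encoding) || length(encoding) != 4L ||
      !setequal(names(encoding), c("A", "C", "G", "T")) ||
      any(!grepl("^[01]{2}$", encoding)) || anyDuplicated(encoding))
    stop("encoding must assign a distinct 2-bit code to each of A, C, G, T",
         call. = FALSE)
  encoding[c("A", "C", "G", "T")]
}

#' Binary encoding of a nucleotide sequence
#'
#' Concatenates the two-bit code of each base. Used to analyse
#' Hamming-code barcode schemes that operate on bits rather than bases: a
#' single nucleotide substitution flips one bit for four of the six possible
#' base changes but two bits for the remaining two (the "diagonal" pairs,
#' A<->T and C<->G under the default encoding), which is why bit-level
#' Hamming codes cannot correct a third of single-base substitutions.
#'
#' @param x character vector of sequences.
#' @param encoding named character vector mapping A, C, G, T to distinct
#'   2-bit strings; see [default_binary_encoding()].
#' @return character vector of bit strings, each twice the sequence length.
#' @examples
#' binary_encode("AT")   # "1100"
#' @export
binary_encode <- function(x, encoding = default_binary_encoding()) {
  x <- normalize_sequence(x, allow_empty = TRUE)
  encoding <- check_encoding(encoding)
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    paste(encoding[strsplit(s, "", fixed = TRUE)[[1L]]], collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Hamming distance between binary encodings
#'
#' Hamming distance between the two-bit encodings of two equal-length
#' sequences; each base position contributes 0, 1, or 2 bit differences.
#'
#' @inheritParams edit_distance
#' @param encoding see [binary_encode()].
#' @return integer vector of bit distances.
#' @examples
#' binary_hamming_distance("A", "G")  # 1 (11 vs 01)
#' binary_hamming_distance("A", "T")  # 2 (11 vs 00)
#' @export
binary_hamming_distance <- function(a, b, encoding = default_binary_encoding()) {
  a <- normalize_sequence(a, allow_empty = TRUE)
  b <- normalize_sequence(b, allow_empty = TRUE)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b)))
    stop("Hamming distance is undefined for unequal lengths", call. = FALSE)
  .hamming_dist_cpp(binary_encode(a, encoding), binary_encode(b, encoding))
}

#' Error-correction capacity of a minimum-distance code
#'
#' A tag set with minimum (edit or Hamming) distance `d` can detect up to
#' `d - 1` errors and correct up to `floor((d - 1) / 2)`: a set with edit
#' distance five corrects up to two errors per tag, distance three corrects
#' one.
#'
#' @param d integer minimum distance, `d >= 1`.
#' @return an object of class `correction_capacity`: a list with elements
#'   `distance`, `detectable`, `correctable`.
#' @examples
#' correction_capacity(5)
#' @export
correction_capacity <- function(d) {
  d <- check_count(d, "d", min = 1L)
  structure(
    list(distance = d, detectable = d - 1L, correctable = (d - 1L) %/% 2L),
    class = "correction_capacity"
  )
}

#' @export
print.correction_capacity <- function(x, ...) {
  cat(sprintf("minimum distance %d: detects <= %d error(s), corrects <= %d\n",
              x$distance, x$detectable, x$correctable))
  invisible(x)
}

check_count <- function(x, what, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) ||
      x < min)
    stop(sprintf("%s must be a single integer >= %d", what, min), call. = FALSE)
  as.integer(x)
}

TAG_METRICS <- c("edit", "hamming", "binary_hamming")

#' Construct a tag set
#'
#' A tag set is an ordered collection of uniquely named tag sequences with a
#' declared distance metric and an expected minimum distance between
#' members.
#'
#' @param sequences character vector of tag sequences (lowercase input is
#'   uppercased; anything outside A/C/G/T is an error).
#' @param names optional character vector of tag names; defaults to
#'   `Tag1..TagN`. Must be unique.
#' @param metric distance metric the set is declared against: `"edit"`
#'   (Levenshtein), `"hamming"`, or `"binary_hamming"`. Under the Hamming
#'   metrics all sequences must have equal length.
#' @param min_distance expected minimum pairwise distance of the set (the
#'   `d` of the codeword scheme), or `NULL` when unknown.
#' @param set_name name of the set.
#' @return an object of class `tag_set`: a list with elements `name`,
#'   `metric`, `min_distance`, and `sequences` (a named character vector in
#'   input order).
#' @examples
#' tag_set(c("ACGT", "TTAA"), metric = "edit", min_distance = 3)
#' @export
tag_set <- function(sequences, names = NULL, metric = c("edit", "hamming",
                    "binary_hamming"), min_distance = NULL,
                    set_name = "tags") {
  metric <- match.arg(metric)
  sequences <- normalize_sequence(sequences)
  if (length(sequences) < 1L) stop("tag set is empty", call. = FALSE)
  if (is.null(names)) names <- paste0("Tag", seq_along(sequences))
  names <- as.character(names)
  if (length(names) != length(sequences))
    stop("names and sequences differ in length", call. = FALSE)
  if (anyDuplicated(names))
    stop("duplicate tag names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  if (metric != "edit" && length(unique(nchar(sequences))) > 1L)
    stop("all sequences must have equal length under a Hamming metric",
         call. = FALSE)
  if (!is.null(min_distance))
    min_distance <- check_count(min_distance, "min_distance", min = 1L)
  names(sequences) <- names
  structure(
    list(name = set_name, metric = metric, min_distance = min_distance,
         sequences = sequences),
    class = "tag_set"
  )
}

#' @export
print.tag_set <- function(x, n = 6L, ...) {
  cat(sprintf("<tag_set> %s: %d tag(s), metric = %s, expected min distance = %s\n",
              x$name, length(x$sequences), x$metric,
              if (is.null(x$min_distance)) "?" else x$min_distance))
  show <- utils::head(x$sequences, n)
  cat(paste0("  ", format(names(show)), "  ", show, collapse = "\n"), "\n")
  if (length(x$sequences) > n)
    cat(sprintf("  ... and %d more\n", length(x$sequences) - n))
  invisible(x)
}

#' @export
length.tag_set <- function(x) length(x$sequences)

#' @export
as.character.tag_set <- function(x, ...) x$sequences

#' Subset a tag set
#'
#' @param x a `tag_set`.
#' @param i index vector over tags.
#' @param ... unused.
#' @return a `tag_set` with the selected tags, other fields unchanged.
#' @export
`[.tag_set` <- function(x, i, ...) {
  seqs <- x$sequences[i]
  if (anyNA(seqs)) stop("subscript out of bounds", call. = FALSE)
  tag_set(unname(seqs), names = names(seqs), metric = x$metric,
          min_distance = x$min_distance, set_name = x$name)
}
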