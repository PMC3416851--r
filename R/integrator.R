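#' Prepend a sequence tag to a PCR primer
#'
#' Builds a fusion primer: `pigtail + tag + primer`, optionally collapsing
#' the junction where the tag's 3' end repeats the primer's 5' start. The
#' trim length `k` is the longest suffix of the tag equal to a prefix of
#' the primer; those `k` primer bases are dropped once, shortening the
#' synthesized oligo without changing the amplicon. The default pigtail
#' `GTTT` promotes non-templated +A addition, aiding downstream T/A
#' ligation of sequencing adapters.
#'
#' @param tag tag sequence.
#' @param primer primer sequence (5' to 3').
#' @param pigtail 5' extension, or `NULL`/`""` for none.
#' @param trim collapse the common tag/primer junction.
#' @return a list with elements `sequence` (the final oligo) and
#'   `trim_length` (`k`).
#' @examples
#' tag_primer("ACGT", "GTCCA")            # GTTTACGTCCA, k = 2
#' tag_primer("ACGT", "GTCCA", trim = FALSE)
#' @export
tag_primer <- function(tag, primer, pigtail = "GTTT", trim = TRUE) {
  tag <- normalize_sequence(tag)
  primer <- normalize_sequence(primer)
  stopifnot(length(tag) == 1L, length(primer) == 1L)
  if (is.null(pigtail) || identical(pigtail, "")) pigtail <- ""
  else pigtail <- normalize_sequence(pigtail)
  k <- 0L
  if (isTRUE(trim)) {
    for (len in rev(seq_len(min(nchar(tag), nchar(primer))))) {
      if (substr(tag, nchar(tag) - len + 1L, nchar(tag)) ==
          substr(primer, 1L, len)) { k <- len; break }
    }
  }
  if (k == nchar(primer))
    stop("tag swallows the entire primer (overlap spans the primer)",
         call. = FALSE)
  list(sequence = paste0(pigtail, tag, substr(primer, k + 1L, nchar(primer))),
       trim_length = k)
}

#' Screen an oligo for secondary structure
#'
#' String-complementarity heuristic for hairpins and dimers (an external
#' thermodynamic evaluator can be used instead via the `screen` hook of
#' [tag_primers()]). The hairpin score is the longest stem: the longest
#' substring whose reverse complement also occurs downstream in the same
#' oligo, separated by at least `min_loop` bases (the loop). The
#' self-dimer score is the longest substring whose reverse complement
#' occurs anywhere in the oligo; note a perfectly self-complementary
#' (palindromic) oligo therefore scores its full length. With `partner`
#' given, the cross-dimer score is the longest substring of `oligo` whose
#' reverse complement occurs in `partner`. A structure is flagged when a
#' score reaches `min_stem`.
#'
#' @param oligo sequence to screen.
#' @param partner optional second oligo for cross-dimer screening.
#' @param min_stem shortest paired stretch considered a problem.
#' @param min_loop minimum unpaired bases between a hairpin's stem halves.
#' @return a list with elements `hairpin_stem_len`, `self_dimer_len`,
#'   `cross_dimer_len` (`NA` without a partner), and `flagged`.
#' @examples
#' screen_structure("GGGGAAACCCC")  # 4-bp stem over a 3-base loop
#' @export
screen_structure <- function(oligo, partner = NULL, min_stem = 4L,
                             min_loop = 3L) {
  oligo <- normalize_sequence(oligo)
  stopifnot(length(oligo) == 1L)
  min_stem <- check_count(min_stem, "min_stem", min = 1L)
  min_loop <- check_count(min_loop, "min_loop", min = 0L)
  n <- nchar(oligo)
  hairpin <- 0L
  self_dimer <- 0L
  for (len in seq_len(n)) {
    found_self <- FALSE
    found_hp <- FALSE
    for (i in seq_len(n - len + 1L)) {
      sub <- substr(oligo, i, i + len - 1L)
      rc <- reverse_complement(sub)
      hits <- match_positions(rc, oligo)
      if (length(hits)) {
        found_self <- TRUE
        if (any(hits >= i + len + min_loop)) found_hp <- TRUE
      }
      if (found_self && found_hp) break
    }
    if (found_self) self_dimer <- len
    if (found_hp) hairpin <- len
    if (!found_self) break
  }
  cross <- NA_integer_
  if (!is.null(partner)) {
    partner <- normalize_sequence(partner)
    cross <- 0L
    for (len in seq_len(n)) {
      found <- FALSE
      for (i in seq_len(n - len + 1L)) {
        rc <- reverse_complement(substr(oligo, i, i + len - 1L))
        if (length(match_positions(rc, partner))) { found <- TRUE; break }
      }
      if (found) cross <- len else break
    }
  }
  flagged <- hairpin >= min_stem || self_dimer >= min_stem ||
    (!is.na(cross) && cross >= min_stem)
  list(hairpin_stem_len = hairpin, self_dimer_len = self_dimer,
       cross_dimer_len = cross, flagged = flagged)
}

# all (possibly overlapping) start positions of fixed pattern in subject
match_positions <- function(pattern, subject) {
  out <- integer(0)
  start <- 1L
  repeat {
    hit <- regexpr(pattern, substr(subject, start, nchar(subject)),
                   fixed = TRUE)
    if (hit == -1L) break
    pos <- start + as.integer(hit) - 1L
    out <- c(out, pos)
    start <- pos + 1L
  }
  out
}

#' Tag a primer pair with every member of a tag set
#'
#' Builds the full table of candidate fusion primers: one row per tag,
#' with both final oligos, junction trim lengths, secondary-structure
#' scores (the worse of the two oligos for hairpin and self-dimer, plus
#' the upper/lower cross-dimer), and a flag column. Rows whose
#' construction fails (e.g. a tag swallowing the primer) are recorded
#' with an `error` note rather than aborting the batch.
#'
#' @param set a [tag_set()].
#' @param upper_primer,lower_primer primer sequences (5' to 3').
#' @param pigtail,trim see [tag_primer()].
#' @param min_stem,min_loop see [screen_structure()].
#' @param screen screening function called as
#'   `screen(oligo, partner, min_stem, min_loop)`; defaults to
#'   [screen_structure()]. Supply a wrapper around an external
#'   thermodynamic evaluator to replace the internal heuristic.
#' @param keep `"all"` or `"pass"` (drop flagged rows).
#' @return a data frame with columns `tag_name`, `tag`, `upper_oligo`,
#'   `lower_oligo`, `upper_trim`, `lower_trim`, `hairpin_stem_len`,
#'   `self_dimer_len`, `cross_dimer_len`, `flagged`, `error`.
#' @export
tag_primers <- function(set, upper_primer, lower_primer, pigtail = "GTTT",
                        trim = TRUE, min_stem = 4L, min_loop = 3L,
                        screen = NULL, keep = c("all", "pass")) {
  stopifnot(inherits(set, "tag_set"))
  keep <- match.arg(keep)
  upper_primer <- normalize_sequence(upper_primer)
  lower_primer <- normalize_sequence(lower_primer)
  if (is.null(screen)) {
    screen <- function(oligo, partner, min_stem, min_loop)
      screen_structure(oligo, partner, min_stem, min_loop)
  }
  rows <- lapply(seq_along(set$sequences), function(i) {
    tag <- set$sequences[[i]]
    nm <- names(set$sequences)[[i]]
    res <- tryCatch({
      up <- tag_primer(tag, upper_primer, pigtail, trim)
      lo <- tag_primer(tag, lower_primer, pigtail, trim)
      s_up <- screen(up$sequence, lo$sequence, min_stem, min_loop)
      s_lo <- screen(lo$sequence, NULL, min_stem, min_loop)
      data.frame(
        tag_name = nm, tag = tag,
        upper_oligo = up$sequence, lower_oligo = lo$sequence,
        upper_trim = up$trim_length, lower_trim = lo$trim_length,
        hairpin_stem_len = max(s_up$hairpin_stem_len, s_lo$hairpin_stem_len),
        self_dimer_len = max(s_up$self_dimer_len, s_lo$self_dimer_len),
        cross_dimer_len = s_up$cross_dimer_len,
        flagged = s_up$flagged || s_lo$flagged,
        error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(tag_name = nm, tag = tag, upper_oligo = NA_character_,
                 lower_oligo = NA_character_, upper_trim = NA_integer_,
                 lower_trim = NA_integer_, hairpin_stem_len = NA_integer_,
                 self_dimer_len = NA_integer_, cross_dimer_len = NA_integer_,
                 flagged = NA, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep == "pass") out <- out[!is.na(out$flagged) & !out$flagged, ]
  out
}

#' Insert a tag into a sequencing adapter
#'
#' Concatenates the adapter part 5' of the tag, the tag, and the part 3'
#' of the tag, recording where the tag sits so it can be sliced back out
#' (e.g. for in-place validation with [validate_tags()]'s `slice`
#' argument).
#'
#' @param five_prime_part,three_prime_part flanking adapter sequence;
#'   either may be empty.
#' @param tag tag sequence.
#' @return a list with elements `sequence`, `tag_start`, `tag_end`
#'   (1-based, inclusive).
#' @examples
#' tag_adapter("AATGA", "ACCTA", "AGATC")
#' @export
tag_adapter <- function(five_prime_part, tag, three_prime_part) {
  five_prime_part <- if (identical(five_prime_part, "")) ""
    else normalize_sequence(five_prime_part)
  three_prime_part <- if (identical(three_prime_part, "")) ""
    else normalize_sequence(three_prime_part)
  tag <- normalize_sequence(tag)
  list(sequence = paste0(five_prime_part, tag, three_prime_part),
       tag_start = nchar(five_prime_part) + 1L,
       tag_end = nchar(five_prime_part) + nchar(tag))
}

#' Insert every tag of a set into an adapter template
#'
#' @param set a [tag_set()].
#' @inheritParams tag_adapter
#' @return a data frame with columns `tag_name`, `tag`, `sequence`,
#'   `tag_start`, `tag_end`, one row per tag in set order.
#' @export
tag_adapters <- function(set, five_prime_part, three_prime_part) {
  stopifnot(inherits(set, "tag_set"))
  rows <- lapply(seq_along(set$sequences), function(i) {
    a <- tag_adapter(five_prime_part, set$sequences[[i]], three_prime_part)
    data.frame(tag_name = names(set$sequences)[[i]],
               tag = set$sequences[[i]], sequence = a$sequence,
               tag_start = a$tag_start, tag_end = a$tag_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
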