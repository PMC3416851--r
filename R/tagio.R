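#' Read a tag set from a file
#'
#' Three dialects are supported:
#' \describe{
#'   \item{ini}{a `[section]` header per set with `name:sequence` lines;
#'     `#` starts a comment. This is the format used to collect
#'     heterogeneous published tag sets under one roof.}
#'   \item{plain}{one sequence per line; tags are auto-named `Tag1..TagN`
#'     in file order.}
#'   \item{fasta}{standard FASTA, single-line or wrapped sequences (read
#'     via Biostrings).}
#' }
#' With `dialect = "auto"` the format is detected from the first
#' non-blank, non-comment character: `>` is FASTA, `[` is ini, anything
#' else is plain.
#'
#' @param path file to read.
#' @param dialect one of `"auto"`, `"ini"`, `"plain"`, `"fasta"`.
#' @param metric,min_distance declared metric and expected minimum
#'   distance recorded on the returned set (see [tag_set()]).
#' @param section for the ini dialect: which `[section]` to read. Defaults
#'   to the only section present; an error names the available sections if
#'   there are several.
#' @return a [tag_set()].
#' @export
read_tag_set <- function(path, dialect = c("auto", "ini", "plain", "fasta"),
                         metric = c("edit", "hamming", "binary_hamming"),
                         min_distance = NULL, section = NULL) {
  dialect <- match.arg(dialect)
  metric <- match.arg(metric)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "auto") dialect <- detect_dialect(path)
  parsed <- switch(dialect,
    fasta = parse_fasta(path),
    ini   = parse_ini(path, section),
    plain = parse_plain(path)
  )
  if (length(parsed$sequences) == 0L)
    stop("no tags found in ", path, call. = FALSE)
  tag_set(parsed$sequences, names = parsed$names, metric = metric,
          min_distance = min_distance, set_name = parsed$set_name)
}

detect_dialect <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  first <- substr(lines[[1L]], 1L, 1L)
  if (first == ">") "fasta" else if (first == "[") "ini" else "plain"
}

parse_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  list(sequences = as.character(seqs), names = names(seqs),
       set_name = tools::file_path_sans_ext(basename(path)))
}

parse_plain <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  list(sequences = lines, names = NULL,
       set_name = tools::file_path_sans_ext(basename(path)))
}

parse_ini <- function(path, section = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  is_header <- grepl("^\\[.+\\]$", lines)
  if (!any(is_header)) stop("ini file has no [section] header", call. = FALSE)
  headers <- gsub("^\\[|\\]$", "", lines[is_header])
  if (is.null(section)) {
    if (length(headers) > 1L)
      stop("file has several sections, pick one with `section`: ",
           paste(headers, collapse = ", "), call. = FALSE)
    section <- headers[[1L]]
  }
  if (!section %in% headers)
    stop("no section [", section, "] in file; available: ",
         paste(headers, collapse = ", "), call. = FALSE)
  idx <- which(is_header & gsub("^\\[|\\]$", "", lines) == section)[[1L]]
  after <- lines[seq_len(length(lines)) > idx]
  ends <- which(grepl("^\\[.+\\]$", after))
  if (length(ends)) after <- after[seq_len(ends[[1L]] - 1L)]
  bad <- !grepl(":", after, fixed = TRUE)
  if (any(bad))
    stop("malformed ini line (expected name:sequence): ", after[bad][[1L]],
         call. = FALSE)
  nm <- trimws(sub(":.*$", "", after))
  sq <- trimws(sub("^[^:]*:", "", after))
  list(sequences = sq, names = nm, set_name = section)
}

#' Write a tag set to a file
#'
#' Serializes in any of the dialects accepted by [read_tag_set()];
#' parsing the result yields an identical set (names, order, sequences).
#'
#' @param set a [tag_set()].
#' @param path output file.
#' @param dialect `"ini"`, `"plain"`, or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_tag_set <- function(set, path, dialect = c("ini", "plain", "fasta")) {
  stopifnot(inherits(set, "tag_set"))
  dialect <- match.arg(dialect)
  switch(dialect,
    ini = writeLines(c(sprintf("[%s]", set$name),
                       sprintf("%s:%s", names(set$sequences), set$sequences)),
                     path),
    plain = writeLines(unname(set$sequences), path),
    fasta = {
      x <- Biostrings::DNAStringSet(set$sequences)
      Biostrings::writeXStringSet(x, path)
    }
  )
  invisible(path)
}

#' Write a validation report to a file
#'
#' @param report a `tag_report` from [validate_tags()].
#' @param path output file.
#' @param format `"csv"` writes the full pairwise distance matrix with tag
#'   names as both header row and first column; `"text"` writes the
#'   observed minimum distance followed by one `name1,name2,distance` line
#'   per violating pair.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "text")) {
  stopifnot(inherits(report, "tag_report"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(report$matrix, path)
  } else {
    lines <- sprintf("minimum distance: %d", report$observed_min_distance)
    v <- report$violations
    if (nrow(v))
      lines <- c(lines, sprintf("%s,%s,%d", v$tag1, v$tag2, v$distance))
    writeLines(lines, path)
  }
  invisible(path)
}
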