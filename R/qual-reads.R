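#' Sets of quality-scored reads
#'
#' A `qual_reads` object is a data frame with one row per read and columns
#' `id`, `seq` (bases over A/C/G/T/N), `qual` (Sanger Phred+33 ASCII string,
#' one character per base), `orientation` (`"forward"` or `"reverse"`),
#' `sample_id`, and `discarded` (reads dropped by a trimming step stay in the
#' object, flagged, so losses are auditable).
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of sequences.
#' @param qual per-base qualities: either Phred+33 ASCII strings or a list of
#'   integer vectors (scores 0-60).
#' @param orientation `"forward"` or `"reverse"`, recycled.
#' @param sample_id sample each read belongs to, recycled.
#' @return A `qual_reads` data frame.
#' @export
qual_reads <- function(id, seq, qual, orientation = "forward",
                       sample_id = NA_character_) {
  if (is.list(qual)) qual <- phred_encode(qual)
  stopifnot(length(id) == length(seq), length(qual) == length(seq))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad) > 0)
    stop("sequence/quality length mismatch for read(s): ",
         paste(head(id[bad], 5), collapse = ", "))
  out <- data.frame(
    id = as.character(id), seq = as.character(seq),
    qual = as.character(qual),
    orientation = rep_len(orientation, length(seq)),
    sample_id = rep_len(as.character(sample_id), length(seq)),
    discarded = logical(length(seq)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("qual_reads", "data.frame")
  out
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual character vector of Phred+33 ASCII strings.
#' @return A list of integer vectors, one per string.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) integer(0) else utf8ToInt(q) - 33L
  })
}

#' Encode integer Phred scores as Phred+33 strings
#'
#' @param scores a list of integer vectors (or a single integer vector).
#' @return A character vector of ASCII quality strings.
#' @export
phred_encode <- function(scores) {
  if (!is.list(scores)) scores <- list(scores)
  bad <- vapply(scores, function(s) any(s < 0 | s > 93), logical(1))
  if (any(bad)) stop("Phred scores must be in [0, 93]")
  vapply(scores, function(s) if (length(s) == 0) "" else intToUtf8(s + 33L),
         character(1))
}

#' Reverse-complement nucleotide sequences
#'
#' Vectorised over a character vector; `N` (and any non-ACGT character) maps
#' to `N`.
#'
#' @param x character vector of sequences.
#' @return The reverse complements.
#' @export
reverse_complement <- function(x) .revcomp_cpp(as.character(x))

#' @export
print.qual_reads <- function(x, ...) {
  cat(sprintf("qual_reads: %d read(s), %d discarded\n",
              nrow(x), sum(x$discarded)))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 6), ...)
  invisible(x)
}
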