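#' Read a FASTQ file into a qual_reads object
#'
#' Only the Sanger dialect (Phred+33) is supported.  The parser validates the
#' record structure and reports the offending line number on malformed input
#' (truncated file, missing `@`/`+` markers, or a quality string whose length
#' differs from its sequence).
#'
#' @param path path to an uncompressed FASTQ file.
#' @param sample_id sample label to attach to every read.
#' @param orientation orientation tag to attach (`"forward"` by default).
#' @return A [qual_reads] data frame in file order.
#' @export
parse_fastq <- function(path, sample_id = NA_character_,
                        orientation = "forward") {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0)
    return(qual_reads(character(0), character(0), character(0)))
  if (n %% 4 != 0)
    stop(sprintf("malformed FASTQ '%s': file truncated mid-record near line %d",
                 path, n))
  hdr <- lines[seq(1, n, by = 4)]
  seq <- lines[seq(2, n, by = 4)]
  plus <- lines[seq(3, n, by = 4)]
  qual <- lines[seq(4, n, by = 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0)
    stop(sprintf("malformed FASTQ '%s': expected '@' header at line %d",
                 path, (bad[1] - 1) * 4 + 1))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0)
    stop(sprintf("malformed FASTQ '%s': expected '+' separator at line %d",
                 path, (bad[1] - 1) * 4 + 3))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad) > 0)
    stop(sprintf(
      "malformed FASTQ '%s': quality length differs from sequence length at line %d",
      path, (bad[1] - 1) * 4 + 4))
  qual_reads(sub("^@", "", hdr), seq, qual,
             orientation = orientation, sample_id = sample_id)
}

#' Write a qual_reads object as FASTQ (Phred+33)
#'
#' @param reads a [qual_reads] object; discarded reads are skipped.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  keep <- reads[!reads$discarded, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(keep) > 0)
    writeLines(paste0("@", keep$id, "\n", keep$seq, "\n+\n", keep$qual), con)
  invisible(path)
}
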