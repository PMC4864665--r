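#' Read preparation: primer, tail and quality trimming
#'
#' These operations take and return [qual_reads] objects; reads that fail a
#' step are kept but flagged `discarded`, so the audit trail (how many reads
#' each rule removed) is always available.  Two preparation profiles are used
#' by the pipeline: a stringent centroid pass (quality threshold 25) that
#' feeds OTU clustering, and a lenient mapping pass (threshold 20) that feeds
#' read-to-centroid counting.
#'
#' @name read_prep
NULL

iupac_sets_ <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

#' Remove a 5'-anchored primer from reads
#'
#' The primer is matched at position 1 under IUPAC degeneracy (e.g. `N`
#' matches any base, `W` matches A or T).  Reads whose 5' end does not match
#' within `max_mismatch` are flagged discarded, as are reads left empty by
#' the trim.
#'
#' @param reads a [qual_reads] object.
#' @param primer IUPAC primer string, e.g. the bacterial 341F primer
#'   `"CCTACGGGNGGCWGCAG"`.
#' @param max_mismatch mismatches allowed beyond IUPAC degeneracy (default 0).
#' @return The trimmed [qual_reads].
#' @export
trim_primer <- function(reads, primer, max_mismatch = 0L) {
  if (!nzchar(primer)) stop("empty primer")
  pl <- nchar(primer)
  pp <- strsplit(toupper(primer), "")[[1]]
  unknown <- setdiff(pp, names(iupac_sets_))
  if (length(unknown) > 0)
    stop("invalid IUPAC code(s) in primer: ", paste(unknown, collapse = ", "))
  live <- which(!reads$discarded)
  if (length(live) == 0) return(reads)
  prefix <- substr(reads$seq[live], 1, pl)
  mism <- integer(length(live))
  long_enough <- nchar(reads$seq[live]) >= pl
  for (p in seq_len(pl)) {
    ok <- substr(prefix, p, p) %in% iupac_sets_[[pp[p]]]
    mism <- mism + !ok
  }
  pass <- long_enough & mism <= max_mismatch
  idx <- live[pass]
  reads$seq[idx] <- substr(reads$seq[idx], pl + 1, nchar(reads$seq[idx]))
  reads$qual[idx] <- substr(reads$qual[idx], pl + 1, nchar(reads$qual[idx]))
  reads$discarded[live[!pass]] <- TRUE
  reads$discarded[idx[!nzchar(reads$seq[idx])]] <- TRUE
  reads
}

#' Remove a fixed number of 3'-end bases
#'
#' Reverse reads of both markers carry low-quality tails that are cut by a
#' fixed amount (40 bases for the 16S protocol, 44 for 18S) before
#' quality-based truncation.
#'
#' @param reads a [qual_reads] object.
#' @param n number of 3' bases to remove (>= 0).
#' @return The trimmed [qual_reads]; reads trimmed to nothing are discarded.
#' @export
trim_fixed_tail <- function(reads, n) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(reads)
  live <- which(!reads$discarded)
  len <- nchar(reads$seq[live])
  newlen <- pmax(len - n, 0L)
  reads$seq[live] <- substr(reads$seq[live], 1, newlen)
  reads$qual[live] <- substr(reads$qual[live], 1, newlen)
  reads$discarded[live[newlen == 0]] <- TRUE
  reads
}

#' Truncate reads at the first low-quality base
#'
#' Each read is cut immediately before the first position (5' to 3') whose
#' Phred score falls below `qmin`, which is the only deterministic rule that
#' guarantees every remaining base has quality >= `qmin`.
#'
#' @param reads a [qual_reads] object.
#' @param qmin minimum acceptable Phred score (0-60).
#' @return The truncated [qual_reads]; reads whose first base already fails
#'   become empty and are discarded.
#' @export
quality_truncate <- function(reads, qmin) {
  stopifnot(qmin >= 0, qmin <= 60)
  live <- which(!reads$discarded)
  if (length(live) == 0) return(reads)
  pos <- .first_below_q_cpp(reads$qual[live], as.integer(qmin))
  cut <- which(pos > 0)
  idx <- live[cut]
  reads$seq[idx] <- substr(reads$seq[idx], 1, pos[cut] - 1)
  reads$qual[idx] <- substr(reads$qual[idx], 1, pos[cut] - 1)
  reads$discarded[idx[pos[cut] == 1]] <- TRUE
  reads
}

prepared_seqs_ <- function(seq, qual, sample_id, kind, junction, reason) {
  out <- data.frame(seq = seq, qual = qual, sample_id = sample_id,
                    kind = kind, junction = junction,
                    accepted = is.na(reason), reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("prepared_seqs", "data.frame")
  out
}

#' Merge read pairs by overlap
#'
#' The reverse read is reverse-complemented, then every overlap offset is
#' scored exactly and the one maximising matching bases is chosen.  A pair is
#' rejected when the best overlap is shorter than `min_overlap` (reason
#' `"overlap"`), has more than `max_mismatches` mismatches
#' (`"mismatches"`), or yields a merged sequence shorter than
#' `min_merged_len` (`"length"`); pairs with an empty or discarded mate get
#' reason `"empty"`.  Within the overlap the base with the higher Phred
#' score wins and the merged quality is the maximum of the two.
#'
#' @param fwd,rev [qual_reads] of equal length (mates in matching order).
#' @param min_overlap minimum acceptable overlap (bases).
#' @param max_mismatches maximum mismatches tolerated in the overlap.
#' @param min_merged_len minimum merged length.
#' @return A `prepared_seqs` data frame (columns `seq`, `qual`, `sample_id`,
#'   `kind`, `junction`, `accepted`, `reason`), one row per input pair.
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 100L, max_mismatches = 3L,
                        min_merged_len = 300L) {
  stopifnot(nrow(fwd) == nrow(rev))
  n <- nrow(fwd)
  reason <- rep(NA_character_, n)
  dead <- fwd$discarded | rev$discarded | !nzchar(fwd$seq) | !nzchar(rev$seq)
  reason[dead] <- "empty"
  seq <- rep(NA_character_, n)
  qual <- rep(NA_character_, n)
  live <- which(!dead)
  if (length(live) > 0) {
    rc <- reverse_complement(rev$seq[live])
    rq <- .rev_str_cpp(rev$qual[live])
    res <- .merge_pairs_cpp(fwd$seq[live], rc, fwd$qual[live], rq,
                            as.integer(min_overlap),
                            as.integer(max_mismatches),
                            as.integer(min_merged_len))
    codes <- c("overlap", "mismatches", "length")
    st <- res$status
    reason[live[st > 0]] <- codes[st[st > 0]]
    ok <- which(st == 0)
    seq[live[ok]] <- res$seq[ok]
    qual[live[ok]] <- res$qual[ok]
  }
  prepared_seqs_(seq, qual, fwd$sample_id, "merged", NA_integer_, reason)
}

#' Concatenate read pairs that cannot overlap
#'
#' For amplicons too long for the mates to overlap, the forward read is
#' joined to the reverse-complemented reverse read; the junction index (where
#' the forward part ends) is recorded and carried through clustering and
#' classification.
#'
#' @param fwd,rev [qual_reads] of equal length (mates in matching order).
#' @return A `prepared_seqs` data frame with `kind = "concatenated"` and a
#'   `junction` per accepted pair; pairs with an empty mate are rejected with
#'   reason `"empty"`.
#' @export
concatenate_pairs <- function(fwd, rev) {
  stopifnot(nrow(fwd) == nrow(rev))
  n <- nrow(fwd)
  reason <- rep(NA_character_, n)
  dead <- fwd$discarded | rev$discarded | !nzchar(fwd$seq) | !nzchar(rev$seq)
  reason[dead] <- "empty"
  seq <- rep(NA_character_, n)
  qual <- rep(NA_character_, n)
  junction <- rep(NA_integer_, n)
  live <- which(!dead)
  if (length(live) > 0) {
    rc <- reverse_complement(rev$seq[live])
    rq <- .rev_str_cpp(rev$qual[live])
    seq[live] <- paste0(fwd$seq[live], rc)
    qual[live] <- paste0(fwd$qual[live], rq)
    junction[live] <- nchar(fwd$seq[live])
  }
  prepared_seqs_(seq, qual, fwd$sample_id, "concatenated", junction, reason)
}

#' One-call read preparation profile
#'
#' Applies the full trimming chain of one preparation pass: primer removal on
#' both mates, fixed 3'-tail trim on the reverse mate, quality truncation at
#' `qmin`, then overlap merging (16S geometry) or concatenation (18S
#' geometry).
#'
#' @param fwd,rev raw mate [qual_reads].
#' @param fwd_primer,rev_primer IUPAC primer strings.
#' @param tail_trim 3' bases to cut from the reverse mate.
#' @param qmin quality-truncation threshold (25 for the centroid pass, 20 for
#'   the mapping pass).
#' @param mode `"merge"` or `"concatenate"`.
#' @param ... passed to [merge_pairs()].
#' @return A `prepared_seqs` data frame; the per-reason rejection tally is
#'   attached as `attr(, "audit")`.
#' @export
prepare_reads <- function(fwd, rev, fwd_primer, rev_primer, tail_trim,
                          qmin, mode = c("merge", "concatenate"), ...) {
  mode <- match.arg(mode)
  fwd <- quality_truncate(trim_primer(fwd, fwd_primer), qmin)
  rev <- trim_primer(rev, rev_primer)
  rev <- quality_truncate(trim_fixed_tail(rev, tail_trim), qmin)
  out <- if (mode == "merge") merge_pairs(fwd, rev, ...)
         else concatenate_pairs(fwd, rev)
  audit <- table(factor(ifelse(out$accepted, "accepted", out$reason),
                        levels = c("accepted", "empty", "overlap",
                                   "mismatches", "length")))
  attr(out, "audit") <- audit
  out
}
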