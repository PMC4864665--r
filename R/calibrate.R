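#' Hold-out test sets for cutoff calibration
#'
#' Samples `n` reference entries without replacement, excises an artificial
#' forward/reverse read pair from each at the primer-binding coordinates
#' (error-free by default), and removes the sampled entries from the
#' reference used for classification.  Entries in which a primer site cannot
#' be located are skipped with a warning and resampled.
#'
#' @param refdb a [reference_db].
#' @param n number of entries to hold out (`< length(refdb$ids)`).
#' @param fwd_primer,rev_primer IUPAC primer strings (the reverse primer in
#'   its own 5'->3' orientation, as published).
#' @param read_len lengths of the excised forward and reverse parts (the
#'   reverse part is returned in forward orientation, ready for
#'   [assign_paired()]).
#' @param error_rate optional per-base substitution rate applied to the
#'   artificial reads (0 = error-free).
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return A list: `test` (data frame `ref_id`, `fwd`, `rev`, plus the 8 true
#'   rank columns) and `refdb` (the reduced reference).
#' @export
make_holdout_testset <- function(refdb, n, fwd_primer, rev_primer,
                                 read_len = c(270L, 215L), error_rate = 0,
                                 seed = NULL) {
  if (n >= length(refdb$ids)) stop("n must be smaller than the reference")
  with_seed_(seed, {
    fpat <- iupac_regex_(fwd_primer)
    rpat <- iupac_regex_(reverse_complement(rev_primer))
    pool <- sample(refdb$ids)
    chosen <- character(0)
    test <- list()
    for (id in pool) {
      if (length(chosen) == n) break
      s <- refdb$seq[[id]]
      fpos <- regexpr(fpat, s)
      rpos <- regexpr(rpat, s)
      if (fpos < 0 || rpos < 0) {
        warning(sprintf("primer site not found in '%s'; entry skipped", id))
        next
      }
      fstart <- fpos + attr(fpos, "match.length")
      rend <- rpos - 1L
      if (rend - fstart + 1 < sum(read_len)) {
        warning(sprintf("amplicon too short in '%s'; entry skipped", id))
        next
      }
      fwd <- substr(s, fstart, fstart + read_len[1] - 1L)
      rev <- substr(s, rend - read_len[2] + 1L, rend)
      chosen <- c(chosen, id)
      test[[length(test) + 1L]] <- c(id, fwd, rev)
    }
    if (length(chosen) < n)
      stop("could not excise reads from enough entries")
    m <- do.call(rbind, test)
    fwd <- m[, 2]; rev <- m[, 3]
    if (error_rate > 0) {
      fwd <- .mutate_seqs_cpp(fwd, error_rate)
      rev <- .mutate_seqs_cpp(rev, error_rate)
    }
    df <- data.frame(ref_id = m[, 1], fwd = fwd, rev = rev,
                     refdb$lineage[m[, 1], , drop = FALSE],
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
    list(test = df, refdb = drop_reference_entries(refdb, chosen))
  })
}

iupac_regex_ <- function(primer) {
  pp <- strsplit(toupper(primer), "")[[1]]
  paste(vapply(pp, function(ch) {
    set <- iupac_sets_[[ch]]
    if (is.null(set)) stop("invalid IUPAC code: ", ch)
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Precision and sensitivity over a cutoff grid
#'
#' Classifies every held-out read pair against the reduced reference while
#' scanning a range of identity cutoffs at each taxonomic level: the row for
#' rank r and cutoff c uses a scheme with c at ranks r..8 and the grid floor
#' at ranks above, so the candidate set a consensus is built from does not
#' change along the scan (only the rank bound does), which makes sensitivity
#' non-increasing in the cutoff by construction.  Per rank and cutoff:
#' sensitivity = fraction of test reads assigned at that depth or deeper,
#' and precision = fraction of those whose assigned name at the rank equals
#' the true lineage's name.  Ranks with no assignment report `NA` precision
#' (undefined, deliberately distinct from 0).  Alignments are computed once
#' and reused across the grid.
#'
#' @param testset the list returned by [make_holdout_testset()].
#' @param refdb the reduced reference from the same call.
#' @param grid numeric vector of identity cutoffs to scan.
#' @param min_aln_len_fwd,min_aln_len_rev,band see [classify_otus()].
#' @return A `calibration_result` data frame: `rank`, `level`, `cutoff`,
#'   `precision`, `sensitivity`, `n_test`.
#' @export
evaluate_cutoff_grid <- function(testset, refdb,
                                 grid = c(0.80, 0.85, 0.90, 0.95, 0.97, 0.99),
                                 min_aln_len_fwd = 250L,
                                 min_aln_len_rev = 210L, band = 48L) {
  if (length(grid) == 0) stop("empty cutoff grid")
  test <- testset$test
  n_test <- nrow(test)
  fsets <- align_queries_to_refs_(test$fwd, refdb, min_aln_len_fwd, band = band)
  rsets <- align_queries_to_refs_(test$rev, refdb, min_aln_len_rev, band = band)
  truth <- as.matrix(test[, rank_names_])
  floor_cut <- min(grid)
  rows <- list()
  for (r in 1:8) {
    for (cut in grid) {
      scheme <- cutoff_scheme(c(rep(min(floor_cut, cut), r - 1),
                                rep(cut, 8 - r + 1)))
      asg <- lapply(seq_len(n_test), function(i)
        assign_paired(fsets[[i]], rsets[[i]], refdb, scheme))
      depth <- vapply(asg, function(a) a$lineage$depth, integer(1))
      ranks <- t(vapply(asg, function(a) a$lineage$ranks, character(8)))
      assigned <- depth >= r
      sens <- sum(assigned) / n_test
      prec <- if (any(assigned))
        sum(ranks[assigned, r] == truth[assigned, r]) / sum(assigned)
      else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(rank = rank_names_[r], level = r, cutoff = cut,
                   precision = prec, sensitivity = sens, n_test = n_test,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_result", "data.frame")
  out
}

#' Choose cutoffs from a calibration result
#'
#' Per rank, the lowest cutoff whose precision meets the floor is selected
#' (sensitivity falls as the cutoff rises, so the lowest qualifying cutoff
#' maximises sensitivity subject to the precision floor); the resulting
#' scheme is then forced monotone non-decreasing across ranks.
#'
#' @param result a `calibration_result` from [evaluate_cutoff_grid()].
#' @param precision_floor a single floor or one per rank (length 8).
#' @return A [cutoff_scheme].
#' @export
select_cutoffs <- function(result, precision_floor) {
  if (nrow(result) == 0) stop("empty calibration result")
  floors <- rep_len(precision_floor, 8)
  chosen <- numeric(8)
  for (r in 1:8) {
    sub <- result[result$level == r & !is.na(result$precision) &
                    result$precision >= floors[r] - 1e-12, , drop = FALSE]
    if (nrow(sub) == 0)
      stop(sprintf("no grid point meets the precision floor at rank %s",
                   rank_names_[r]))
    chosen[r] <- min(sub$cutoff)
  }
  cutoff_scheme(cummax(chosen))
}
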