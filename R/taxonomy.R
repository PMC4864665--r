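#' Rank-specific identity cutoff schemes
#'
#' Consensus classification truncates a lineage at the deepest rank whose
#' identity cutoff is met.  Cutoffs must be non-decreasing from kingdom
#' (level 1) to species (level 8).  The defaults are the calibrated scheme
#' used throughout: 90% for kingdom-family (levels 1-6), 97% at genus, 99%
#' at species.
#'
#' @param cutoffs numeric vector of 8 identity cutoffs (fractions).
#' @return A `cutoff_scheme` (named numeric vector of length 8).
#' @export
cutoff_scheme <- function(cutoffs) {
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) != 8) stop("a cutoff scheme has 8 ranks")
  if (any(diff(cutoffs) < -1e-12))
    stop("cutoffs must be non-decreasing from kingdom to species")
  structure(setNames(cutoffs, rank_names_), class = "cutoff_scheme")
}

#' @rdname cutoff_scheme
#' @export
default_cutoffs <- function() cutoff_scheme(c(rep(0.90, 6), 0.97, 0.99))

default_scoring_ <- function() {
  list(match = 1, mismatch = -2, gap = -2.5, lambda = 1.28, K = 0.46)
}

hit_set_ <- function(df, query_id, n_filtered = 0L) {
  rownames(df) <- NULL
  attr(df, "query_id") <- query_id
  attr(df, "n_filtered") <- n_filtered
  class(df) <- c("hit_set", "data.frame")
  df
}

#' Align a query against every reference sequence
#'
#' Local (Smith-Waterman-style) alignment of the query against each
#' reference, on both strands; the better strand and the best alignment per
#' reference id are kept.  Hits shorter than `min_aln_len` alignment columns
#' are dropped (the classifier requires alignments covering about 90% of the
#' read).  Identity is matches/columns of the local alignment; the bit-score
#' is `(lambda * raw_score - ln K) / ln 2` with configurable Karlin-Altschul
#' constants -- only ratios between bit-scores matter downstream.
#'
#' @param query a single sequence.
#' @param refdb a [reference_db].
#' @param min_aln_len minimum alignment length in columns (>= 1).
#' @param scoring list with `match`, `mismatch`, `gap` (per gap column),
#'   `lambda`, `K`.
#' @param band banded-alignment half-width around the seeded diagonal;
#'   `NULL` runs the full matrix on both strands.
#' @return A `hit_set` data frame: `ref_id`, `identity`, `aln_len`,
#'   `bitscore`, `strand`; the number of length-filtered alignments is
#'   attached as `attr(, "n_filtered")`.
#' @export
align_query_to_refs <- function(query, refdb, min_aln_len = 1L,
                                scoring = default_scoring_(), band = 48L) {
  if (min_aln_len < 1) stop("min_aln_len must be >= 1")
  sets <- align_queries_to_refs_(query, refdb, min_aln_len, scoring, band)
  sets[[1]]
}

# Batch version: one hit_set per query, sharing the reference k-mer index.
align_queries_to_refs_ <- function(queries, refdb, min_aln_len,
                                   scoring = default_scoring_(),
                                   band = 48L) {
  if (length(refdb$ids) == 0) stop("empty reference database")
  if (any(!nzchar(queries))) stop("queries must be non-empty")
  sc <- 2L  # scale so the half-integer gap penalty stays integral
  res <- .sw_hits_cpp(as.character(queries), unname(refdb$seq),
                      as.integer(scoring$match * sc),
                      as.integer(scoring$mismatch * sc),
                      as.integer(scoring$gap * sc), sc,
                      as.integer(band %||% -1L), 12L)
  min_aln_len <- rep_len(as.integer(min_aln_len), length(queries))
  keep <- res$aln_len >= min_aln_len[res$query]
  bits <- (scoring$lambda * res$score - log(scoring$K)) / log(2)
  lapply(seq_along(queries), function(qi) {
    rows <- which(res$query == qi & keep)
    nf <- sum(res$query == qi & !keep)
    hit_set_(data.frame(
      ref_id = refdb$ids[res$ref[rows]],
      identity = res$matches[rows] / res$aln_len[rows],
      aln_len = res$aln_len[rows],
      bitscore = bits[rows],
      strand = res$strand[rows],
      stringsAsFactors = FALSE), query_id = qi, n_filtered = nf)
  })
}

assignment_ <- function(otu_id, ranks, depth, reason, evidence) {
  structure(list(otu_id = otu_id,
                 lineage = lineage(ranks[seq_len(depth)], depth),
                 reason = reason, evidence = evidence),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("%s: %s (depth %d, %s)\n", x$otu_id %||% "query",
              lineage_string(x$lineage), x$lineage$depth, x$reason))
  invisible(x)
}

# Number of ranks whose cutoff is met by `id` (cutoffs are non-decreasing, so
# the allowed ranks form a prefix).  "Exceeding the cutoff" is implemented
# inclusively (>=): the published cutoffs are round percentages applied to
# discretised identities.
allowed_depth_ <- function(id, cutoffs) sum(cutoffs <= id + 1e-12)

# Depth of agreement of a set of full lineages (matrix rows).
consensus_depth_ <- function(lin) {
  for (d in seq_len(ncol(lin))) {
    if (length(unique(lin[, d])) > 1) return(d - 1L)
  }
  ncol(lin)
}

# Shared machinery of assign_paired / assign_single.  `ids` is the
# per-candidate identity used against the cutoffs, `score` the value entering
# the 95%-of-best rule.
consensus_assign_ <- function(cand_ids, ids, score, refdb, cutoffs,
                              otu_id, top_frac, empty_reason) {
  if (length(cand_ids) == 0)
    return(assignment_(otu_id, character(0), 0L, empty_reason, character(0)))
  allowed <- vapply(ids, allowed_depth_, integer(1), cutoffs = cutoffs)
  keep <- allowed >= 1L
  if (!any(keep))
    return(assignment_(otu_id, character(0), 0L, "identity_cutoff",
                       character(0)))
  cand_ids <- cand_ids[keep]; ids <- ids[keep]
  score <- score[keep]; allowed <- allowed[keep]
  overall_allowed <- max(allowed)
  if (length(cand_ids) == 1) {
    ranks <- refdb$lineage[cand_ids, ]
    depth <- overall_allowed
    reason <- if (depth == 8L) "none" else "identity_cutoff"
    return(assignment_(otu_id, ranks, depth, reason, cand_ids))
  }
  retained <- cand_ids[score >= top_frac * max(score) - 1e-9]
  lin <- refdb$lineage[retained, , drop = FALSE]
  cdepth <- consensus_depth_(lin)
  depth <- min(cdepth, overall_allowed)
  reason <- if (depth == 8L) "none"
            else if (cdepth < overall_allowed) "consensus_conflict"
            else "identity_cutoff"
  assignment_(otu_id, lin[1, ], depth, reason, retained)
}

#' Consensus taxonomy from paired hit sets
#'
#' The classifier for concatenated (two-read) amplicons: the centroid is
#' split at its junction, each half is aligned to the reference, and a
#' consensus is built from references hit by *both* halves.  Per shared
#' reference the paired identity is the minimum of the two halves'
#' identities (the conservative reading); the deepest rank whose cutoff that
#' identity meets bounds the assignment.  With several shared references,
#' their forward+reverse bit-score sums are compared and only those within
#' `top_frac` (95%) of the best sum are retained; the lineage is the deepest
#' rank at which all retained references agree, further truncated by the
#' identity bound.  A single shared reference donates its lineage directly
#' (truncated by its identity bound).
#'
#' @param fwd_hits,rev_hits `hit_set`s of the two halves of one centroid.
#' @param refdb the [reference_db] the hits refer to.
#' @param cutoffs a [cutoff_scheme].
#' @param otu_id optional id carried into the result.
#' @param top_frac bit-score retention fraction (default 0.95).
#' @return An `assignment`: `lineage`, `reason` (one of `none`,
#'   `identity_cutoff`, `consensus_conflict`, `no_hits`, `length_filter`)
#'   and the retained `evidence` reference ids.
#' @export
assign_paired <- function(fwd_hits, rev_hits, refdb, cutoffs = default_cutoffs(),
                          otu_id = NULL, top_frac = 0.95) {
  if (!inherits(cutoffs, "cutoff_scheme")) cutoffs <- cutoff_scheme(cutoffs)
  shared <- intersect(fwd_hits$ref_id, rev_hits$ref_id)
  nf <- (attr(fwd_hits, "n_filtered") %||% 0L) +
        (attr(rev_hits, "n_filtered") %||% 0L)
  if (length(shared) == 0) {
    reason <- if (nrow(fwd_hits) + nrow(rev_hits) == 0 && nf > 0)
      "length_filter" else "no_hits"
    return(assignment_(otu_id, character(0), 0L, reason, character(0)))
  }
  fi <- fwd_hits$identity[match(shared, fwd_hits$ref_id)]
  ri <- rev_hits$identity[match(shared, rev_hits$ref_id)]
  fb <- fwd_hits$bitscore[match(shared, fwd_hits$ref_id)]
  rb <- rev_hits$bitscore[match(shared, rev_hits$ref_id)]
  consensus_assign_(shared, pmin(fi, ri), fb + rb, refdb, cutoffs,
                    otu_id, top_frac, "no_hits")
}

#' Consensus taxonomy from a single hit set
#'
#' The one-read variant of [assign_paired()] used for merged (fully
#' overlapped) amplicons: the hit identity plays the role of the paired
#' identity and the single bit-score enters the 95%-of-best rule.
#'
#' @inheritParams assign_paired
#' @param hits a `hit_set` for the merged centroid.
#' @return An `assignment`.
#' @export
assign_single <- function(hits, refdb, cutoffs = default_cutoffs(),
                          otu_id = NULL, top_frac = 0.95) {
  if (!inherits(cutoffs, "cutoff_scheme")) cutoffs <- cutoff_scheme(cutoffs)
  if (nrow(hits) == 0) {
    reason <- if ((attr(hits, "n_filtered") %||% 0L) > 0) "length_filter"
              else "no_hits"
    return(assignment_(otu_id, character(0), 0L, reason, character(0)))
  }
  consensus_assign_(hits$ref_id, hits$identity, hits$bitscore, refdb,
                    cutoffs, otu_id, top_frac, "no_hits")
}

#' Classify every centroid of an OTU table
#'
#' Concatenated centroids are split at their junction and classified with
#' [assign_paired()] (alignment-length floors default to 250/210 columns for
#' the forward/reverse half, about 90% of the trimmed read lengths); merged
#' centroids are classified with [assign_single()] (floor 90% of the centroid
#' length).
#'
#' @param table an [otu_table] with centroid sequences.
#' @param refdb a [reference_db].
#' @param cutoffs a [cutoff_scheme].
#' @param min_aln_len_fwd,min_aln_len_rev alignment-length floors for the two
#'   halves of concatenated centroids.
#' @param band see [align_query_to_refs()].
#' @return A data frame of assignments: `otu_id`, the 8 rank columns,
#'   `depth`, `reason`, `evidence` (comma-joined reference ids).  The
#'   table's `lineages` can be updated with [set_lineages()].
#' @export
classify_otus <- function(table, refdb, cutoffs = default_cutoffs(),
                          min_aln_len_fwd = 250L, min_aln_len_rev = 210L,
                          band = 48L) {
  ids <- rownames(table$counts)
  cent <- table$centroids[ids]
  junc <- if (is.null(table$junctions)) rep(NA_integer_, length(ids))
          else table$junctions[ids]
  concat <- !is.na(junc)
  out <- vector("list", length(ids))
  if (any(concat)) {
    fwd <- substr(cent[concat], 1, junc[concat])
    rev <- substr(cent[concat], junc[concat] + 1, nchar(cent[concat]))
    fsets <- align_queries_to_refs_(fwd, refdb, min_aln_len_fwd, band = band)
    rsets <- align_queries_to_refs_(rev, refdb, min_aln_len_rev, band = band)
    w <- which(concat)
    for (i in seq_along(w)) {
      out[[w[i]]] <- assign_paired(fsets[[i]], rsets[[i]], refdb, cutoffs,
                                   otu_id = ids[w[i]])
    }
  }
  if (any(!concat)) {
    w <- which(!concat)
    floors <- as.integer(round(0.9 * nchar(cent[w])))
    sets <- align_queries_to_refs_(cent[w], refdb, floors, band = band)
    for (i in seq_along(w)) {
      out[[w[i]]] <- assign_single(sets[[i]], refdb, cutoffs,
                                   otu_id = ids[w[i]])
    }
  }
  assignments_df_(out)
}

assignments_df_ <- function(assignments) {
  ranks <- t(vapply(assignments, function(a) a$lineage$ranks, character(8)))
  colnames(ranks) <- rank_names_
  data.frame(
    otu_id = vapply(assignments, function(a) a$otu_id %||% NA_character_,
                    character(1)),
    ranks,
    depth = vapply(assignments, function(a) a$lineage$depth, integer(1)),
    reason = vapply(assignments, function(a) a$reason, character(1)),
    evidence = vapply(assignments, function(a)
      paste(a$evidence, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

#' Attach classifier assignments to an OTU table
#'
#' @param table an [otu_table].
#' @param assignments the data frame returned by [classify_otus()].
#' @return The table with its `lineages` (semicolon-joined, truncated at the
#'   assignment depth) filled in.
#' @export
set_lineages <- function(table, assignments) {
  lin <- apply(assignments, 1, function(r) {
    d <- as.integer(r[["depth"]])
    if (d == 0) "" else paste(r[rank_names_][seq_len(d)], collapse = ";")
  })
  table$lineages <- setNames(lin, assignments$otu_id)
  table
}

#' Apply curated manual annotations
#'
#' Manual annotations (e.g. from interactive searches against a broader
#' database) replace the automatic lineage only when both the reported
#' alignment coverage and identity exceed 0.99; weaker overrides are ignored
#' with a warning.  Every application is recorded in `attr(, "override_log")`.
#'
#' @param assignments data frame from [classify_otus()].
#' @param overrides data frame with columns `otu_id`, `lineage`
#'   (semicolon-joined), `coverage`, `identity`.
#' @return The (possibly modified) assignments.
#' @export
apply_manual_overrides <- function(assignments, overrides) {
  if (nrow(overrides) == 0) {
    attr(assignments, "override_log") <- character(0)
    return(assignments)
  }
  unknown <- setdiff(overrides$otu_id, assignments$otu_id)
  if (length(unknown) > 0)
    stop("override(s) for unknown OTU id(s): ",
         paste(unknown, collapse = ", "))
  log <- character(0)
  for (i in seq_len(nrow(overrides))) {
    o <- overrides[i, ]
    if (o$coverage > 0.99 && o$identity > 0.99) {
      ranks <- strsplit(o$lineage, ";", fixed = TRUE)[[1]]
      row <- which(assignments$otu_id == o$otu_id)
      assignments[row, rank_names_] <-
        c(ranks, rep("", 8 - length(ranks)))[1:8]
      assignments$depth[row] <- length(ranks)
      assignments$reason[row] <- "manual_override"
      log <- c(log, sprintf("%s: override applied (cov %.3f, id %.3f)",
                            o$otu_id, o$coverage, o$identity))
    } else {
      warning(sprintf(
        "override for %s ignored: coverage/identity must both exceed 0.99",
        o$otu_id))
      log <- c(log, sprintf("%s: override ignored", o$otu_id))
    }
  }
  attr(assignments, "override_log") <- log
  assignments
}
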