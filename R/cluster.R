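#' Pairwise sequence identity
#'
#' Identity is defined as matching columns divided by total alignment columns
#' of an optimal end-free (semi-global) alignment under unit costs, so
#' terminal length differences -- e.g. mapping-pass reads trimmed at a
#' different quality threshold than the centroids -- are not penalised.  The
#' measure is symmetric.
#'
#' @param a,b sequences (vectorised; recycling is not performed, supply equal
#'   lengths or a scalar against a vector).
#' @param band half-width of the alignment band around the main diagonal
#'   (widened automatically by the length difference); `NULL` computes the
#'   full dynamic programme.  The pipeline's substitution-dominated reads sit
#'   within a narrow band; the full matrix is the reference behaviour.
#' @return Numeric identity values in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, band = NULL) {
  if (length(a) == 1 && length(b) > 1) a <- rep(a, length(b))
  if (length(b) == 1 && length(a) > 1) b <- rep(b, length(a))
  if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b))
    stop("sequences must be non-empty")
  .sg_identity_cpp(as.character(a), as.character(b),
                   as.integer(band %||% -1L))
}

#' Dereplicate prepared sequences
#'
#' Exact-string dereplication with per-sample counts, sorted by total count
#' descending (ties broken lexicographically by sequence) -- the input order
#' required by [greedy_cluster()].  Counts are conserved: the column sums
#' equal the per-sample input sizes.
#'
#' @param prepared a `prepared_seqs` data frame (see [merge_pairs()]); only
#'   accepted rows are used.  Alternatively a character vector of sequences
#'   (single sample).  Mixing merged and concatenated sequences is an error.
#' @param samples optional sample-id ordering for the count columns.
#' @return A `unique_seqs` object: list with `seq`, `junction`, `total`, and
#'   a `counts` matrix (unique sequence x sample).
#' @export
dereplicate <- function(prepared, samples = NULL) {
  if (is.character(prepared)) {
    n <- length(prepared)
    prepared <- data.frame(seq = prepared,
                           sample_id = rep("sample_1", n),
                           kind = rep("merged", n),
                           junction = rep(NA_integer_, n),
                           accepted = rep(TRUE, n),
                           stringsAsFactors = FALSE)
  }
  keep <- prepared[prepared$accepted %||% TRUE & !is.na(prepared$seq), ,
                   drop = FALSE]
  if (length(unique(keep$kind)) > 1)
    stop("cannot dereplicate mixed merged/concatenated sequences")
  samples <- samples %||% unique(keep$sample_id)
  if (nrow(keep) == 0) {
    return(structure(list(seq = character(0), junction = integer(0),
                          total = integer(0),
                          counts = matrix(0L, 0, length(samples),
                                          dimnames = list(NULL, samples))),
                     class = "unique_seqs"))
  }
  dt <- data.table::data.table(seq = keep$seq,
                               junction = keep$junction %||% NA_integer_,
                               sample = keep$sample_id)
  agg <- dt[, .N, by = c("seq", "junction", "sample")]
  tot <- agg[, list(total = sum(N)), by = c("seq", "junction")]
  data.table::setorder(tot, -total, seq)
  counts <- matrix(0L, nrow(tot), length(samples),
                   dimnames = list(NULL, samples))
  ri <- match(paste(agg$seq, agg$junction), paste(tot$seq, tot$junction))
  ci <- match(agg$sample, samples)
  if (anyNA(ci)) stop("sample id(s) outside the declared sample set")
  counts[cbind(ri, ci)] <- agg$N
  structure(list(seq = tot$seq, junction = tot$junction,
                 total = tot$total, counts = counts),
            class = "unique_seqs")
}

#' Greedy centroid clustering at a fixed identity threshold
#'
#' Unique sequences are scanned in abundance order; each joins the first
#' existing centroid with identity at or above the threshold, otherwise it
#' founds a new OTU whose centroid is the sequence itself (first-fit in
#' abundance order, the documented behaviour of the classic greedy
#' centroid-based clustering tools, and deterministic given the input order).
#' Concatenated sequences are compared over the full concatenation and the
#' founder's junction is kept for the OTU.
#'
#' @param uniques a `unique_seqs` object from [dereplicate()].
#' @param threshold identity threshold in `(0, 1]`; OTUs are built at 0.99.
#' @param band alignment band half-width (see [pairwise_identity()]).
#' @param kmer,screen_from k-mer length and centroid count from which the
#'   k-mer prescreen activates (below it every centroid is aligned, which is
#'   exact).
#' @return A `cluster_result`: list with `centroids` (data frame `otu_id`,
#'   `seq`, `junction`) and `membership` (centroid index per unique
#'   sequence).
#' @export
greedy_cluster <- function(uniques, threshold = 0.99, band = 16L,
                           kmer = 10L, screen_from = 8L) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  n <- length(uniques$seq)
  if (n == 0) {
    return(structure(list(centroids = data.frame(otu_id = character(0),
                                                 seq = character(0),
                                                 junction = integer(0)),
                          membership = integer(0)),
                     class = "cluster_result"))
  }
  assign <- .greedy_cluster_cpp(uniques$seq, threshold, as.integer(band),
                                as.integer(kmer), as.integer(screen_from))
  founder <- which(!duplicated(assign))
  ord <- assign[founder]             # founding order is 1..K already
  founder <- founder[order(ord)]
  centroids <- data.frame(
    otu_id = sprintf("OTU_%d", seq_along(founder)),
    seq = uniques$seq[founder],
    junction = uniques$junction[founder],
    stringsAsFactors = FALSE)
  structure(list(centroids = centroids, membership = assign),
            class = "cluster_result")
}

#' Map prepared reads onto OTU centroids
#'
#' Each read is assigned to the centroid of maximal identity if that identity
#' reaches the threshold, otherwise it is counted as unassigned; ties go to
#' the earlier (more abundant) centroid.  Reads are dereplicated internally,
#' so repeated sequences are aligned once.  For concatenated amplicons the
#' identity is pooled over the two halves using both junctions, so the
#' different junction geometry of the lenient mapping pass is not charged as
#' an internal gap.
#'
#' @param prepared a `prepared_seqs` data frame (mapping-pass reads).
#' @param clusters a `cluster_result` from [greedy_cluster()].
#' @param threshold minimum identity for assignment (default 0.99).
#' @param marker marker tag for the resulting table.
#' @param samples optional sample ordering; reads from samples outside it are
#'   an error.
#' @param band,kmer,screen_from see [greedy_cluster()].
#' @return An [otu_table] whose column sums equal the per-sample assigned
#'   read totals; unassigned counts are kept in `$unassigned` so that
#'   assigned + unassigned equals the input size per sample.
#' @export
map_reads_to_centroids <- function(prepared, clusters, threshold = 0.99,
                                   marker = c("16S", "18S"), samples = NULL,
                                   band = 16L, kmer = 10L,
                                   screen_from = 8L) {
  marker <- match.arg(marker)
  uniq <- dereplicate(prepared, samples = samples)
  cent <- clusters$centroids
  if (nrow(cent) == 0) stop("no centroids to map against")
  cj <- ifelse(is.na(cent$junction), 0L, as.integer(cent$junction))
  qj <- ifelse(is.na(uniq$junction), 0L, as.integer(uniq$junction))
  res <- .map_to_centroids_cpp(uniq$seq, qj, cent$seq, cj,
                               threshold, as.integer(band),
                               as.integer(kmer), as.integer(screen_from))
  k <- nrow(cent)
  counts <- matrix(0L, k, ncol(uniq$counts),
                   dimnames = list(cent$otu_id, colnames(uniq$counts)))
  hit <- res$centroid
  for (c_idx in seq_len(k)) {
    rows <- which(hit == c_idx)
    if (length(rows) > 0)
      counts[c_idx, ] <- as.integer(colSums(uniq$counts[rows, , drop = FALSE]))
  }
  unassigned <- colSums(uniq$counts[hit == 0, , drop = FALSE])
  junctions <- setNames(cent$junction, cent$otu_id)
  otu_table(counts,
            centroids = setNames(cent$seq, cent$otu_id),
            junctions = junctions, marker = marker,
            unassigned = unassigned)
}
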