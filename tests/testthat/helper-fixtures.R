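# Shared fixture builders and independent oracles.  Everything here is
# deliberately naive (quadratic scans, full enumerations) so it can stand as
# an independent check of the optimised implementations.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Substitute `k` bases of `seq` at distinct random positions.
mutate_at <- function(seq, k) {
  x <- strsplit(seq, "")[[1]]
  pos <- sample(length(x), k)
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste(x, collapse = "")
}

make_reads <- function(seqs, quals = NULL, sample_id = "s1", ids = NULL) {
  quals <- quals %||% vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  qual_reads(ids %||% sprintf("r%d", seq_along(seqs)), seqs, quals,
             sample_id = sample_id)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A tiny fully-annotated reference database: `n` sequences of length `len`,
# lineages optionally supplied as semicolon strings.
make_refdb <- function(seqs, lineages = NULL) {
  n <- length(seqs)
  lineages <- lineages %||% vapply(seq_len(n), function(i)
    paste(sprintf("%s%d", c("k", "sg", "dv", "cl", "or", "fa", "ge", "sp"), i),
          collapse = ";"), character(1))
  reference_db(sprintf("ref_%d", seq_len(n)), seqs, lineages)
}

# Hand-built hit_set (bypasses alignment) for classifier unit tests.
make_hits <- function(ref_id, identity, bitscore, aln_len = 300L) {
  df <- data.frame(ref_id = ref_id, identity = identity,
                   aln_len = rep_len(aln_len, length(ref_id)),
                   bitscore = bitscore,
                   strand = rep(1L, length(ref_id)),
                   stringsAsFactors = FALSE)
  attr(df, "n_filtered") <- 0L
  class(df) <- c("hit_set", "data.frame")
  df
}

# ---- oracle: greedy first-fit clustering --------------------------------
# Literal first-fit re-implementation over full pairwise identities.
oracle_greedy_cluster <- function(seqs, threshold) {
  centroids <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (c in centroids) {
      if (pairwise_identity(seqs[i], seqs[c]) >= threshold) { hit <- c; break }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      assign[i] <- i
    } else assign[i] <- hit
  }
  # renumber in founding order
  match(assign, unique(assign))
}

# ---- oracle: paired consensus classification ----------------------------
# Direct transcription of the classification rules, computed step by step
# with no shared code: shared refs, min identity vs the rank cutoffs,
# bit-score top set, consensus depth by column scan.
oracle_assign_paired <- function(fwd_hits, rev_hits, refdb, cutoffs,
                                 top_frac = 0.95) {
  shared <- intersect(fwd_hits$ref_id, rev_hits$ref_id)
  if (length(shared) == 0) return(list(depth = 0L, ranks = rep("", 8)))
  id_of <- function(h, r) h$identity[h$ref_id == r]
  bs_of <- function(h, r) h$bitscore[h$ref_id == r]
  paired_id <- vapply(shared, function(r)
    min(id_of(fwd_hits, r), id_of(rev_hits, r)), numeric(1))
  # cutoffs are monotone, so the deepest satisfied rank is a prefix count
  allowed <- vapply(paired_id, function(id)
    sum(cutoffs <= id + 1e-12), integer(1))
  keep <- allowed >= 1
  if (!any(keep)) return(list(depth = 0L, ranks = rep("", 8)))
  shared <- shared[keep]; paired_id <- paired_id[keep]
  allowed <- allowed[keep]
  if (length(shared) == 1) {
    d <- allowed
    ranks <- refdb$lineage[shared, ]
    ranks[seq_len(8) > d] <- ""
    return(list(depth = as.integer(d), ranks = unname(ranks)))
  }
  score <- vapply(shared, function(r)
    bs_of(fwd_hits, r) + bs_of(rev_hits, r), numeric(1))
  retained <- shared[score >= top_frac * max(score) - 1e-9]
  lin <- refdb$lineage[retained, , drop = FALSE]
  cdepth <- 0L
  for (r in 1:8) {
    if (length(unique(lin[, r])) == 1) cdepth <- r else break
  }
  d <- min(cdepth, max(allowed))
  ranks <- lin[1, ]
  ranks[seq_len(8) > d] <- ""
  list(depth = as.integer(d), ranks = unname(ranks))
}

# Random classification instance on a miniature reference; identities and
# bitscores drawn so that ties and near-cutoff cases occur.
random_paired_instance <- function(n_refs = NULL) {
  n_refs <- n_refs %||% sample(2:20, 1)
  # build lineages with shared upper ranks so consensus depths vary
  base <- c("k1", "sg1", "dv1", "cl1", "or1", "fa1", "ge1", "sp1")
  lineages <- vapply(seq_len(n_refs), function(i) {
    div <- sample(1:8, 1)  # rank at which this ref branches off
    ranks <- base
    if (div <= 8)
      ranks[div:8] <- sprintf("%s_%d", base[div:8], i)
    paste(ranks, collapse = ";")
  }, character(1))
  refdb <- make_refdb(replicate(n_refs, random_seq(40)), lineages)
  pick <- sample(n_refs, sample(0:min(6, n_refs), 1))
  mk <- function(ids) {
    pool <- setdiff(seq_len(n_refs), ids)
    extra <- pool[sample.int(length(pool), min(length(pool), sample(0:2, 1)))]
    all_ids <- c(ids, extra)
    make_hits(refdb$ids[all_ids],
              identity = round(runif(length(all_ids), 0.85, 1), 3),
              bitscore = round(runif(length(all_ids), 90, 100), 1))
  }
  cutoffs <- cutoff_scheme(sort(round(runif(8, 0.86, 0.99), 2)))
  list(fwd = mk(pick), rev = mk(pick), refdb = refdb, cutoffs = cutoffs)
}

# ---- small deterministic communities ------------------------------------
make_otu_table <- function(counts, lineages = NULL, marker = "16S") {
  centroids <- setNames(replicate(nrow(counts), random_seq(30)),
                        rownames(counts))
  otu_table(counts, centroids = centroids, lineages = lineages,
            marker = marker)
}
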