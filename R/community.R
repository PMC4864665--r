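#' Relative OTU abundances
#'
#' @param table an [otu_table] or a counts matrix (OTU x sample).
#' @return A matrix of per-sample OTU frequencies (columns sum to 1).
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  tot <- colSums(counts)
  empty <- which(tot == 0)
  if (length(empty) > 0)
    stop("sample(s) with zero reads: ",
         paste(colnames(counts)[empty], collapse = ", "))
  sweep(counts, 2, tot, "/")
}

#' Spearman-correlation community dissimilarity
#'
#' Beta-diversity between two samples is `1 - rho`, where `rho` is Spearman's
#' rank correlation between their OTU frequency vectors (ties mid-ranked);
#' values lie in `[0, 2]`.  The constant offset does not affect the ordering
#' of samples in downstream ordination.
#'
#' @param freqs OTU x sample frequency matrix (see [relative_abundance()]),
#'   or an [otu_table] (converted internally).
#' @return A symmetric dissimilarity matrix with zero diagonal.
#' @export
spearman_dissimilarity <- function(freqs) {
  if (inherits(freqs, "otu_table")) freqs <- relative_abundance(freqs)
  if (ncol(freqs) < 2 || nrow(freqs) < 2)
    stop("need at least 2 samples and 2 OTUs")
  const <- apply(freqs, 2, function(x) diff(range(x)) == 0)
  if (any(const))
    stop("constant OTU frequency vector (rho undefined) in sample(s): ",
         paste(colnames(freqs)[const], collapse = ", "))
  d <- 1 - cor(freqs, method = "spearman")
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres `-D^2/2` and eigendecomposes it (via [stats::cmdscale()]);
#' axes with positive eigenvalues are kept, the variance explained by an axis
#' is its eigenvalue over the sum of positive eigenvalues, and each axis is
#' oriented so its first nonzero coordinate is positive (a deterministic sign
#' convention).
#'
#' @param D symmetric dissimilarity matrix (sample ids as dimnames).
#' @return A `pcoa_ordination`: list with `coordinates` (sample x axis),
#'   `eigenvalues`, `variance_explained`.
#' @export
pcoa_ordination <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (all(D == 0)) {
    coords <- matrix(0, n, 0, dimnames = list(rownames(D), NULL))
    return(structure(list(coordinates = coords, eigenvalues = numeric(0),
                          variance_explained = numeric(0)),
                     class = "pcoa_ordination"))
  }
  # negative eigenvalues are expected for non-Euclidean dissimilarities
  sc <- suppressWarnings(cmdscale(as.dist(D), k = n - 1, eig = TRUE))
  eig <- sc$eig
  tol <- max(abs(eig)) * 1e-8
  pos <- which(eig > tol)
  coords <- sc$points[, pos, drop = FALSE]
  for (ax in seq_len(ncol(coords))) {
    v <- coords[, ax]
    nz <- which(abs(v) > 1e-12)
    if (length(nz) > 0 && v[nz[1]] < 0) coords[, ax] <- -v
  }
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  rownames(coords) <- rownames(D)
  structure(list(coordinates = coords, eigenvalues = eig[pos],
                 variance_explained = eig[pos] / sum(eig[pos])),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  ve <- round(100 * x$variance_explained[seq_len(min(3, length(x$eigenvalues)))], 1)
  cat(sprintf("pcoa_ordination: %d samples, %d axes (PC1-%d explain %s%%)\n",
              nrow(x$coordinates), length(x$eigenvalues), length(ve),
              paste(ve, collapse = "/")))
  invisible(x)
}

#' Correlate an ordination axis with an environmental gradient
#'
#' Spearman correlation between an axis of a [pcoa_ordination()] and sample
#' salinity, with a seeded permutation p-value:
#' `p = (#{|rho_perm| >= |rho_obs|} + 1) / (nperm + 1)`.
#'
#' @param ordination a `pcoa_ordination`.
#' @param metadata data frame with `sample_id` and `salinity`.
#' @param axis axis number (default 1).
#' @param nperm number of permutations.
#' @param seed optional seed (`NULL` = current RNG stream).
#' @return A list with `rho`, `p` and `nperm`.
#' @export
correlate_axis_with_gradient <- function(ordination, metadata, axis = 1,
                                         nperm = 9999, seed = NULL) {
  coords <- ordination$coordinates[, axis]
  sal <- metadata$salinity[match(names(coords), metadata$sample_id)]
  if (anyNA(sal))
    stop("missing salinity for sample(s): ",
         paste(names(coords)[is.na(sal)], collapse = ", "))
  rho <- cor(coords, sal, method = "spearman")
  with_seed_(seed, {
    exceed <- sum(vapply(seq_len(nperm), function(i) {
      abs(cor(coords, sample(sal), method = "spearman")) >= abs(rho) - 1e-12
    }, logical(1)))
    list(rho = rho, p = (exceed + 1) / (nperm + 1), nperm = nperm)
  })
}

#' Average-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering of a dissimilarity matrix (default average
#' linkage), deterministic given `D`.  The dendrogram can be serialised as
#' newick with [as_newick()].
#'
#' @param D symmetric dissimilarity matrix (>= 2 samples).
#' @param linkage linkage criterion passed to [stats::hclust()].
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(D, linkage = "average") {
  D <- as.matrix(D)
  if (nrow(D) < 2) stop("need at least 2 samples to cluster")
  hclust(as.dist(D), method = linkage)
}

#' @rdname hierarchical_cluster
#' @param hc an `hclust` object.
#' @export
as_newick <- function(hc) ape::write.tree(ape::as.phylo(hc))

#' Mantel test between two dissimilarity matrices
#'
#' Spearman correlation over the lower triangles, with a one-sided seeded
#' permutation p-value obtained by relabelling the samples of `D2`:
#' `p = (#{rho_perm >= rho_obs} + 1) / (nperm + 1)`.
#'
#' @param D1,D2 symmetric dissimilarity matrices over the same samples in the
#'   same order.
#' @param nperm number of permutations.
#' @param seed optional seed (`NULL` = current RNG stream).
#' @return A list with `rho`, `p` and `nperm`.
#' @export
mantel_test <- function(D1, D2, nperm = 999, seed = NULL) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2)))
    stop("dissimilarity matrices have different dimensions")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    stop("dissimilarity matrices cover different samples")
  lt <- lower.tri(D1)
  rho <- cor(D1[lt], D2[lt], method = "spearman")
  n <- nrow(D1)
  with_seed_(seed, {
    exceed <- sum(vapply(seq_len(nperm), function(i) {
      p <- sample(n)
      cor(D1[lt], D2[p, p][lt], method = "spearman") >= rho - 1e-12
    }, logical(1)))
    list(rho = rho, p = (exceed + 1) / (nperm + 1), nperm = nperm)
  })
}

# One multivariate-hypergeometric draw of `n` reads per replicate, vectorised
# over replicates by sequential rhyper calls.
subsample_counts_ <- function(counts, n, reps) {
  k <- length(counts)
  out <- matrix(0L, k, reps)
  left <- rep(sum(counts), reps)
  need <- rep(n, reps)
  for (i in seq_len(k)) {
    ci <- counts[i]
    x <- rhyper(reps, ci, left - ci, need)
    out[i, ] <- x
    need <- need - x
    left <- left - ci
  }
  out
}

#' Rarefied alpha-diversity of one sample
#'
#' Draws `n` reads without replacement from the sample's OTU counts, `reps`
#' times (seeded), and reports the mean and standard deviation of observed
#' OTU richness and of the Shannon-Wiener index (natural log) over the
#' replicates.
#'
#' @param table an [otu_table] (or counts matrix).
#' @param sample_id which sample to subsample.
#' @param n subsampling depth (`<=` the sample's total reads).
#' @param reps number of repetitions (1000 in the study design).
#' @param seed optional seed (`NULL` = current RNG stream).
#' @return An `alpha_estimate`: list with `sample_id`, `n`, `reps`,
#'   `mean_richness`, `sd_richness`, `mean_shannon`, `sd_shannon`, and the
#'   per-replicate vectors in `replicates`.
#' @export
subsampled_alpha <- function(table, sample_id, n, reps = 1000, seed = NULL) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  if (!sample_id %in% colnames(counts)) stop("unknown sample: ", sample_id)
  x <- counts[, sample_id]
  if (n > sum(x))
    stop(sprintf("subsampling depth %d exceeds the %d reads of sample %s",
                 n, sum(x), sample_id))
  with_seed_(seed, {
    draws <- subsample_counts_(x[x > 0], n, reps)
    rich <- colSums(draws > 0)
    p <- sweep(draws, 2, colSums(draws), "/")
    sh <- -colSums(ifelse(p > 0, p * log(p), 0))
    structure(list(sample_id = sample_id, n = n, reps = reps,
                   mean_richness = mean(rich), sd_richness = sd(rich),
                   mean_shannon = mean(sh), sd_shannon = sd(sh),
                   replicates = list(richness = rich, shannon = sh)),
              class = "alpha_estimate")
  })
}

#' Rarefied alpha-diversity for every sample of a table
#'
#' Convenience wrapper around [subsampled_alpha()]: the depth defaults to the
#' lowest read count among the samples (the standard equal-depth comparison).
#'
#' @inheritParams subsampled_alpha
#' @param n depth; `NULL` uses the minimum sample total.
#' @return A data frame with one row per sample.
#' @export
alpha_diversity_table <- function(table, n = NULL, reps = 1000, seed = NULL) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  n <- n %||% min(colSums(counts))
  with_seed_(seed, {
    rows <- lapply(colnames(counts), function(s) {
      a <- subsampled_alpha(counts, s, n, reps)
      data.frame(sample_id = s, n = n, reps = reps,
                 mean_richness = a$mean_richness, sd_richness = a$sd_richness,
                 mean_shannon = a$mean_shannon, sd_shannon = a$sd_shannon,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Per-phylum rarefied alpha-diversity
#'
#' Restricts the table to OTUs of one phylum (lineage level 3), drops samples
#' with fewer than `min_reads` reads from that phylum, subsamples the
#' remaining samples to their common minimum depth, and reports rarefied
#' richness and Shannon diversity per sample.
#'
#' @param table an [otu_table] with lineages.
#' @param phylum phylum name (lineage level 3).
#' @param min_reads exclusion threshold (1000 in the study design).
#' @param reps,seed see [subsampled_alpha()].
#' @return A data frame as in [alpha_diversity_table()] with a `phylum`
#'   column; zero rows (with a warning) when no sample qualifies.
#' @export
per_phylum_alpha <- function(table, phylum, min_reads = 1000, reps = 1000,
                             seed = NULL) {
  if (is.null(table$lineages)) stop("table has no lineage annotations")
  lin <- strsplit(unname(table$lineages[rownames(table$counts)]), ";",
                  fixed = TRUE)
  phyla <- vapply(lin, function(x) if (length(x) >= 3) x[3] else "",
                  character(1))
  sub <- table$counts[phyla == phylum, , drop = FALSE]
  keep <- colSums(sub) >= min_reads
  if (!any(keep)) {
    warning(sprintf("no sample has >= %d reads of phylum %s",
                    min_reads, phylum))
    return(data.frame(phylum = character(0), sample_id = character(0),
                      n = integer(0), reps = integer(0),
                      mean_richness = numeric(0), sd_richness = numeric(0),
                      mean_shannon = numeric(0), sd_shannon = numeric(0)))
  }
  sub <- sub[, keep, drop = FALSE]
  out <- alpha_diversity_table(sub, n = min(colSums(sub)), reps = reps,
                               seed = seed)
  cbind(phylum = phylum, out, stringsAsFactors = FALSE)
}

#' Diversity contrast across the horohalinicum
#'
#' Compares rarefied richness and Shannon diversity between samples inside
#' the horohalinicum salinity band (5-8, bounds inclusive) and the remaining
#' samples, with a two-sided Wilcoxon rank-sum test per phylum and metric and
#' Benjamini-Hochberg adjustment across phyla within each metric.
#'
#' @param alpha a data frame of per-sample alpha estimates with columns
#'   `phylum` (optional; absent = whole community), `sample_id`,
#'   `mean_richness`, `mean_shannon`.
#' @param metadata data frame with `sample_id` and `salinity`.
#' @param range inclusive salinity bounds of the horohalinicum.
#' @return A data frame: `phylum`, `metric`, `W`, `p`, `q`.
#' @export
horohalinicum_test <- function(alpha, metadata, range = c(5, 8)) {
  sal <- metadata$salinity[match(alpha$sample_id, metadata$sample_id)]
  if (anyNA(sal)) stop("missing salinity for some samples")
  inside <- sal >= range[1] & sal <= range[2]
  if (!any(inside) || all(inside))
    stop(sprintf("one of the salinity groups [%g, %g] is empty",
                 range[1], range[2]))
  if (is.null(alpha$phylum)) alpha$phylum <- "community"
  rows <- list()
  for (ph in unique(alpha$phylum)) {
    sel <- alpha$phylum == ph
    for (metric in c("mean_richness", "mean_shannon")) {
      x <- alpha[[metric]][sel & inside]
      y <- alpha[[metric]][sel & !inside]
      if (length(x) == 0 || length(y) == 0) next
      if (diff(range(c(x, y))) == 0) {
        # every value tied: no evidence of a difference
        wt <- list(statistic = length(x) * length(y) / 2, p.value = 1)
      } else {
        wt <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        phylum = ph,
        metric = if (metric == "mean_richness") "richness" else "shannon",
        W = unname(wt$statistic), p = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (metric in unique(out$metric)) {
    sel <- out$metric == metric
    out$q[sel] <- p.adjust(out$p[sel], method = "BH")
  }
  out
}
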