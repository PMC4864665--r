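#' Correlate OTUs across the 16S and 18S tables
#'
#' Computes all pairwise Spearman correlations between the relative
#' abundances of 16S OTUs and 18S OTUs across the shared samples and
#' extracts pairs with `rho >= min_rho`.  OTUs with zero variance are
#' skipped (noted in `attr(, "skipped")`).  Each pair is annotated with the
#' 16S OTU's chloroplast flag (a `"Chloroplast"` rank anywhere in its
#' lineage) and the class-level names (lineage level 4) of both sides.
#'
#' @param table16,table18 [otu_table]s over identical sample sets.
#' @param min_rho extraction threshold (0.8 in the study design).
#' @param class_level lineage level used as "class" (4 in the PR2
#'   convention).
#' @return A `linked_pairs` data frame: `otu16`, `otu18`, `rho`,
#'   `chloroplast`, `class16`, `class18`.
#' @export
correlate_tables <- function(table16, table18, min_rho = 0.8,
                             class_level = 4L) {
  s16 <- colnames(table16$counts); s18 <- colnames(table18$counts)
  if (!setequal(s16, s18))
    stop("the two tables cover different sample sets")
  f16 <- relative_abundance(table16)
  f18 <- relative_abundance(table18)[, s16, drop = FALSE]
  var16 <- apply(f16, 1, function(x) diff(range(x)) > 0)
  var18 <- apply(f18, 1, function(x) diff(range(x)) > 0)
  skipped <- c(rownames(f16)[!var16], rownames(f18)[!var18])
  f16 <- f16[var16, , drop = FALSE]
  f18 <- f18[var18, , drop = FALSE]
  rho <- cor(t(f16), t(f18), method = "spearman")
  hits <- which(rho >= min_rho - 1e-12, arr.ind = TRUE)
  lin_at_ <- function(table, ids, level) {
    if (is.null(table$lineages)) return(rep("", length(ids)))
    vapply(strsplit(unname(table$lineages[ids]), ";", fixed = TRUE),
           function(x) if (length(x) >= level) x[level] else "",
           character(1))
  }
  chloro_ <- function(table, ids) {
    if (is.null(table$lineages)) return(rep(FALSE, length(ids)))
    vapply(strsplit(unname(table$lineages[ids]), ";", fixed = TRUE),
           function(x) "Chloroplast" %in% x, logical(1))
  }
  otu16 <- rownames(f16)[hits[, 1]]
  otu18 <- rownames(f18)[hits[, 2]]
  out <- data.frame(
    otu16 = otu16, otu18 = otu18,
    rho = rho[hits],
    chloroplast = chloro_(table16, otu16),
    class16 = lin_at_(table16, otu16, class_level),
    class18 = lin_at_(table18, otu18, class_level),
    stringsAsFactors = FALSE)
  out <- out[order(-out$rho, out$otu16, out$otu18), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("linked_pairs", "data.frame")
  out
}

#' Count class-level agreements among chloroplast pairs
#'
#' Restricts a pair list to pairs whose 16S OTU is flagged chloroplast,
#' drops (but counts) pairs lacking a class annotation on either side, and
#' counts how many of the evaluable pairs agree at the class level.
#'
#' @param pairs a `linked_pairs` data frame (see [correlate_tables()]).
#' @return A list: `k` (matches), `m` (evaluable chloroplast pairs),
#'   `dropped` (chloroplast pairs lacking annotation).
#' @export
count_class_matches <- function(pairs) {
  cp <- pairs[pairs$chloroplast, , drop = FALSE]
  evaluable <- nzchar(cp$class16) & nzchar(cp$class18)
  list(k = sum(cp$class16[evaluable] == cp$class18[evaluable]),
       m = sum(evaluable),
       dropped = sum(!evaluable))
}

# Shared setup of the shuffling test: the shuffle population is the set of
# distinct correlated 18S OTUs (annotated-only by default), each holding one
# class label; chloroplast pairs point into that population.
link_shuffle_setup_ <- function(pairs, population = c("annotated", "all")) {
  population <- match.arg(population)
  p18 <- pairs[!duplicated(pairs$otu18), c("otu18", "class18")]
  if (population == "annotated")
    p18 <- p18[nzchar(p18$class18), , drop = FALSE]
  cp <- pairs[pairs$chloroplast & nzchar(pairs$class16) &
                pairs$otu18 %in% p18$otu18, , drop = FALSE]
  labels <- factor(p18$class18)
  list(pop_labels = as.integer(labels),
       partner = match(cp$otu18, p18$otu18),
       class16 = as.integer(factor(cp$class16, levels = levels(labels))),
       m = nrow(cp))
}

#' Label-shuffling p-value for chloroplast/18S class matching
#'
#' Shuffles the class annotations among the correlated 18S OTUs `N` times
#' (seeded) and counts in how many shuffles `threshold_k` or more of the
#' chloroplast pairs land on a matching class; the p-value is `n / N`, the
#' empirical probability of the observed (or higher) level of matching
#' arising by chance.
#'
#' @param pairs a `linked_pairs` data frame; it must contain the full
#'   correlated pair set (the shuffle population), not only the chloroplast
#'   pairs.
#' @param threshold_k observed number of matches to meet or exceed.
#' @param n_shuffles number of shuffles `N` (10^6 in the study design).
#' @param seed optional seed (`NULL` = current RNG stream).
#' @param population `"annotated"` shuffles labels over 18S OTUs that carry a
#'   class annotation (default); `"all"` includes unannotated ones.
#' @return The p-value `n / N`.
#' @export
permutation_pvalue <- function(pairs, threshold_k, n_shuffles = 1e6,
                               seed = NULL, population = "annotated") {
  if (n_shuffles < 1) stop("need at least one shuffle")
  setup <- link_shuffle_setup_(pairs, population)
  if (threshold_k > setup$m) {
    warning("threshold_k exceeds the number of evaluable pairs; p = 0")
    return(0)
  }
  if (threshold_k <= 0) return(1)
  cls <- setup$class16
  cls[is.na(cls)] <- -1L  # classes absent from the population never match
  with_seed_(seed, {
    hits <- .shuffle_match_count_cpp(setup$pop_labels,
                                     setup$partner - 1L, cls,
                                     as.integer(threshold_k),
                                     as.numeric(n_shuffles))
    hits / n_shuffles
  })
}

#' Exact enumeration p-value for small shuffle populations
#'
#' The analytic oracle for [permutation_pvalue()]: for populations of at
#' most 10 correlated 18S OTUs, the probability of `threshold_k` or more
#' class matches under uniform label permutation is computed exactly by
#' recursion over the multiset of labels.
#'
#' @inheritParams permutation_pvalue
#' @return The exact p-value.
#' @export
exact_pvalue_small <- function(pairs, threshold_k, population = "annotated") {
  setup <- link_shuffle_setup_(pairs, population)
  if (length(setup$pop_labels) > 10)
    stop("population too large for enumeration; use permutation_pvalue()")
  if (threshold_k > setup$m) {
    warning("threshold_k exceeds the number of evaluable pairs; p = 0")
    return(0)
  }
  if (threshold_k <= 0) return(1)
  # positions = distinct partner OTUs; pairs sharing a partner share a label
  upos <- unique(setup$partner)
  targets <- lapply(upos, function(u) setup$class16[setup$partner == u])
  counts <- table(setup$pop_labels)
  labs <- as.integer(names(counts))
  cnt <- as.integer(counts)
  recurse <- function(i, cnt, matches) {
    if (matches >= threshold_k) return(1)
    if (i > length(targets)) return(0)
    remaining_max <- matches + sum(lengths(targets[i:length(targets)]))
    if (remaining_max < threshold_k) return(0)
    total <- sum(cnt)
    p <- 0
    for (li in seq_along(labs)) {
      if (cnt[li] == 0) next
      prob <- cnt[li] / total
      cnt2 <- cnt
      cnt2[li] <- cnt2[li] - 1L
      add <- sum(targets[[i]] == labs[li], na.rm = TRUE)
      p <- p + prob * recurse(i + 1, cnt2, matches + add)
    }
    p
  }
  recurse(1, cnt, 0L)
}
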