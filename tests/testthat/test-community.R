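test_that("relative abundances are per-sample fractions", {
  m <- matrix(c(2L, 2L, 1L, 0L), 2, 2,
              dimnames = list(c("o1", "o2"), c("s1", "s2")))
  f <- relative_abundance(m)
  expect_equal(unname(f[, "s1"]), c(0.5, 0.5))
  expect_equal(unname(f[, "s2"]), c(1, 0))
  expect_equal(unname(colSums(f)), c(1, 1))
  m[, 2] <- 0L
  expect_error(relative_abundance(m), "s2")
})

test_that("Spearman dissimilarity matches hand-computed rank correlations", {
  f <- cbind(s1 = c(1, 2, 3, 4), s2 = c(1, 3, 2, 4), s3 = c(4, 3, 2, 1))
  rownames(f) <- paste0("o", 1:4)
  d <- spearman_dissimilarity(f)
  expect_equal(d["s1", "s2"], 0.2)   # rho = 0.8 by hand
  expect_equal(d["s1", "s3"], 2)     # perfectly anti-ranked
  expect_equal(d["s1", "s1"], 0)
  expect_true(isSymmetric(d))

  fc <- cbind(s1 = c(1, 2, 3), s2 = c(1, 1, 1))
  expect_error(spearman_dissimilarity(fc), "s2")
})

test_that("PCoA reproduces known geometry", {
  # 3 collinear points: PC1 explains everything, coordinates (-1, 0, 1)
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  ord <- pcoa_ordination(d)
  expect_equal(length(ord$eigenvalues), 1)
  expect_equal(ord$variance_explained[1], 1)
  expect_equal(unname(ord$coordinates[, 1]) * sign(ord$coordinates[1, 1]),
               c(1, 0, -1), tolerance = 1e-9)  # collinear, up to global sign

  # Euclidean distances of known planar points are reproduced to 1e-9
  set.seed(41)
  pts <- matrix(rnorm(2 * 9), 9, 2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:9), paste0("s", 1:9))
  ord2 <- pcoa_ordination(D)
  Dhat <- as.matrix(dist(ord2$coordinates))
  expect_lt(max(abs(Dhat - D)), 1e-9)

  # a duplicated sample lands on identical coordinates
  D3 <- D[c(1:9, 1), c(1:9, 1)]
  dimnames(D3) <- list(paste0("s", 1:10), paste0("s", 1:10))
  ord3 <- pcoa_ordination(D3)
  expect_equal(unname(ord3$coordinates[10, ]), unname(ord3$coordinates[1, ]),
               tolerance = 1e-9)

  # degenerate all-zero matrix: one cloud, no axes
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(ncol(pcoa_ordination(z)$coordinates), 0)
})

test_that("axis-gradient correlation and its permutation p behave", {
  meta <- data.frame(sample_id = paste0("s", 1:10), salinity = 1:10)
  coords <- matrix(1:10, 10, 1, dimnames = list(paste0("s", 1:10), "PC1"))
  ord <- structure(list(coordinates = coords), class = "pcoa_ordination")
  res <- correlate_axis_with_gradient(ord, meta, nperm = 199, seed = 1)
  expect_equal(res$rho, 1)
  expect_equal(res$p, 1 / 200)

  # independent coordinates: |rho| small on average, p not extreme
  set.seed(42)
  ps <- replicate(20, {
    ordr <- structure(list(coordinates = matrix(rnorm(10), 10, 1,
                           dimnames = list(paste0("s", 1:10), "PC1"))),
                      class = "pcoa_ordination")
    correlate_axis_with_gradient(ordr, meta, nperm = 99)$p
  })
  expect_gt(mean(ps), 0.2)  # roughly uniform under the null

  meta2 <- meta; meta2$salinity[3] <- NA
  expect_error(correlate_axis_with_gradient(ord, meta2), "missing salinity")
})

test_that("average-linkage clustering merges as hand-computed", {
  d <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchical_cluster(d)
  expect_equal(hc$height, c(0.1, 1.0))
  nwk <- as_newick(hc)
  expect_match(nwk, "^\\(")
  expect_true(grepl("A", nwk) && grepl("C", nwk))

  # two samples: a single merge at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(hierarchical_cluster(d2)$height, 0.4)

  # duplicated sample merges at height 0
  d3 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(c("A", "A2", "C"), c("A", "A2", "C")))
  expect_equal(hierarchical_cluster(d3)$height[1], 0)

  expect_error(hierarchical_cluster(d2[1, 1, drop = FALSE]), "2 samples")
})

test_that("the Mantel test is rank-invariant and seeded", {
  set.seed(43)
  pts <- matrix(rnorm(16), 8, 2)
  D1 <- as.matrix(dist(pts))
  res <- mantel_test(D1, D1, nperm = 99, seed = 2)
  expect_equal(res$rho, 1)
  expect_equal(res$p, 1 / 100)
  # monotone rescaling leaves the statistic unchanged
  expect_equal(mantel_test(D1, 2 * D1, nperm = 9, seed = 2)$rho, 1)
  # reproducible under the same seed
  D2 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  expect_equal(mantel_test(D1, D2, nperm = 99, seed = 3)$p,
               mantel_test(D1, D2, nperm = 99, seed = 3)$p)
  expect_error(mantel_test(D1, D2[1:5, 1:5]), "dimensions")
})

test_that("Mantel agrees with the vegan implementation on the statistic", {
  skip_if_not_installed("vegan")
  set.seed(44)
  D1 <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  D2 <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  ours <- mantel_test(D1, D2, nperm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(D1), as.dist(D2), method = "spearman",
                       permutations = 99)
  expect_equal(ours$rho, unname(ref$statistic))
})

test_that("Mantel p-values under the null are super-uniform at 5%", {
  set.seed(45)
  hits <- 0
  for (i in 1:200) {
    D1 <- as.matrix(dist(rnorm(7)))
    D2 <- as.matrix(dist(rnorm(7)))
    p <- mantel_test(D1, D2, nperm = 39)$p
    if (p <= 0.05) hits <- hits + 1
  }
  # 200 replicates at level 0.05: expect <= ~10 + 3 SE
  expect_lte(hits, 10 + 3 * sqrt(200 * 0.05 * 0.95))
})

test_that("subsampling reproduces exact and hypergeometric expectations", {
  counts <- matrix(c(5L, 5L), 2, 1, dimnames = list(c("o1", "o2"), "s1"))
  # full depth: the draw is exhaustive
  a <- subsampled_alpha(counts, "s1", n = 10, reps = 200, seed = 1)
  expect_equal(a$mean_richness, 2)
  expect_equal(a$sd_richness, 0)
  expect_equal(a$mean_shannon, log(2), tolerance = 1e-12)

  # n = 1: richness is always 1
  b <- subsampled_alpha(counts, "s1", n = 1, reps = 100, seed = 2)
  expect_equal(b$mean_richness, 1)

  # n = 5 on counts [5,5]: E[richness] = 2(1 - 1/252) by hypergeometric
  exact <- 2 * (1 - choose(5, 5) / choose(10, 5))
  cc <- subsampled_alpha(counts, "s1", n = 5, reps = 1000, seed = 3)
  se <- cc$sd_richness / sqrt(1000)
  expect_lt(abs(cc$mean_richness - exact), 3 * max(se, 1e-3))

  expect_error(subsampled_alpha(counts, "s1", n = 11), "exceeds")
})

test_that("mean subsampled richness is monotone in depth (property)", {
  set.seed(46)
  counts <- matrix(rpois(8, 20) + 1L, 8, 1,
                   dimnames = list(paste0("o", 1:8), "s1"))
  depths <- c(5, 20, 60, sum(counts))
  means <- vapply(depths, function(n)
    subsampled_alpha(counts, "s1", n, reps = 400)$mean_richness, numeric(1))
  expect_true(all(diff(means) > -0.05))
  expect_equal(means[length(means)], sum(counts > 0))
})

test_that("rarefied Shannon agrees with vegan at full depth", {
  skip_if_not_installed("vegan")
  set.seed(47)
  counts <- matrix(rpois(10, 30) + 1L, 10, 1,
                   dimnames = list(paste0("o", 1:10), "s1"))
  a <- subsampled_alpha(counts, "s1", n = sum(counts), reps = 5, seed = 1)
  expect_equal(a$mean_shannon, unname(vegan::diversity(counts[, 1])),
               tolerance = 1e-12)
})

test_that("per-phylum alpha applies the 1000-read exclusion rule", {
  set.seed(48)
  counts <- rbind(
    matrix(c(600L, 1500L, 2000L), 1, 3),   # phylum A OTU 1
    matrix(c(399L, 800L, 1200L), 1, 3),    # phylum A OTU 2
    matrix(c(5000L, 5000L, 5000L), 1, 3))  # phylum B
  dimnames(counts) <- list(paste0("o", 1:3), paste0("s", 1:3))
  lin <- setNames(c("k;sg;phyA;cl", "k;sg;phyA;cl", "k;sg;phyB;cl"),
                  rownames(counts))
  tab <- make_otu_table(counts, lineages = lin)
  # s1 has 999 phylum-A reads -> excluded; s2, s3 kept at n = min = 2300
  out <- per_phylum_alpha(tab, "phyA", min_reads = 1000, reps = 50)
  expect_equal(out$sample_id, c("s2", "s3"))
  expect_equal(unique(out$n), 2300)

  # single-OTU phylum: richness 1, Shannon 0
  out_b <- per_phylum_alpha(tab, "phyB", min_reads = 1000, reps = 20)
  expect_equal(out_b$mean_richness, rep(1, 3))
  expect_equal(out_b$mean_shannon, rep(0, 3))

  expect_warning(per_phylum_alpha(tab, "phyC", reps = 5), "no sample")
})

test_that("the horohalinicum contrast uses exact Wilcoxon and BH", {
  meta <- data.frame(sample_id = paste0("s", 1:10),
                     salinity = c(5.5, 6, 6.5, 7, 7.5, 2, 3, 11, 15, 20))
  # completely separated groups, n1 = n2 = 5: exact two-sided p = 2/252
  alpha <- data.frame(phylum = "A", sample_id = paste0("s", 1:10),
                      mean_richness = c(1:5, 11:15),
                      mean_shannon = c(1:5, 11:15) / 10)
  res <- horohalinicum_test(alpha, meta)
  expect_equal(res$p, rep(2 / choose(10, 5), 2), tolerance = 1e-12)

  # identical values: p = 1
  alpha2 <- alpha; alpha2$mean_richness <- 3; alpha2$mean_shannon <- 3
  res2 <- horohalinicum_test(alpha2, meta)
  expect_equal(res2$p, rep(1, 2))

  # BH with one tiny p among m: q = p * m for the smallest
  alpha3 <- rbind(
    cbind(alpha, stringsAsFactors = FALSE),
    within(alpha, {phylum <- "B"; mean_richness <- rep(3, 10)
                   mean_shannon <- rep(3, 10)}),
    within(alpha, {phylum <- "C"; mean_richness <- rep(3, 10)
                   mean_shannon <- rep(3, 10)}))
  res3 <- horohalinicum_test(alpha3, meta)
  rich <- res3[res3$metric == "richness", ]
  expect_equal(min(rich$q), min(rich$p) * 3, tolerance = 1e-12)

  badmeta <- meta; badmeta$salinity <- rep(6, 10)
  expect_error(horohalinicum_test(alpha, badmeta), "empty")
})
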