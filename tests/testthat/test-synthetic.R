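test_that("simulated references hit their per-rank divergence targets", {
  cfg <- sim_config("16S", children = c(1, 2, 2, 2, 2, 2, 2, 2))
  db <- simulate_reference_taxonomy(cfg, seed = 91)
  expect_equal(length(db$ids), 128)
  lin <- db$lineage
  set.seed(911)
  for (r in c(2, 4, 6, 8)) {
    vals <- c()
    for (draw in 1:30) {
      i <- sample(length(db$ids), 1)
      same_upper <- apply(lin[, seq_len(r - 1), drop = FALSE], 1,
                          function(x) all(x == lin[i, seq_len(r - 1)]))
      js <- which(same_upper & lin[, r] != lin[i, r])
      if (length(js) == 0) next
      vals <- c(vals, pairwise_identity(db$seq[i],
                                        db$seq[js[sample.int(length(js), 1)]]))
    }
    expect_lt(abs(mean(vals) - cfg$sibling_identity[r]), 0.01)
  }
})

test_that("reference simulation is deterministic and validates its targets", {
  cfg <- sim_config("18S")
  db1 <- simulate_reference_taxonomy(cfg, seed = 92)
  db2 <- simulate_reference_taxonomy(cfg, seed = 92)
  expect_identical(db1$seq, db2$seq)
  expect_identical(db1$lineage, db2$lineage)

  # one child per rank: a single-leaf database
  cfg1 <- sim_config("18S", children = rep(1L, 8))
  expect_equal(length(simulate_reference_taxonomy(cfg1, seed = 93)$ids), 1)

  # non-increasing targets are rejected
  expect_error(sim_config("18S", sibling_identity = c(0.9, rep(0.8, 7))),
               "strictly increasing")
  expect_error(sim_config("18S", sibling_identity = seq(0.1, 0.8, 0.1)),
               "0.25")
})

test_that("every simulated leaf retains intact primer sites", {
  cfg <- sim_config("16S", children = c(1, 1, 2, 2, 2, 2, 2, 2))
  db <- simulate_reference_taxonomy(cfg, seed = 94)
  fpat <- paste0("^", halocline:::iupac_regex_(cfg$fwd_primer))
  rpat <- paste0(halocline:::iupac_regex_(
    reverse_complement(cfg$rev_primer)), "$")
  expect_true(all(grepl(fpat, db$seq)))
  expect_true(all(grepl(rpat, db$seq)))
})

test_that("gradient communities turn over smoothly along salinity", {
  # noise off: the deterministic Gaussian-response properties are exact
  cfg <- sim_config("18S", children = c(1, 1, 2, 2, 2, 2, 2, 2),
                    env_noise_sdlog = 0)
  db <- simulate_reference_taxonomy(cfg, seed = 95)
  comm <- simulate_gradient_communities(db, cfg, seed = 95)
  expect_equal(dim(comm$abundance), c(64, 21))
  expect_true(all(colSums(comm$abundance) > 0))
  expect_equal(comm$metadata$salinity, seq(2, 30, length.out = 21))

  # determinism
  comm2 <- simulate_gradient_communities(db, cfg, seed = 95)
  expect_identical(comm$abundance, comm2$abundance)

  # two taxa with optima at the range ends: their ratio is monotone
  n <- comm$niches
  lo <- which.min(n$optimum); hi <- which.max(n$optimum)
  ratio <- comm$abundance[hi, ] / comm$abundance[lo, ]
  expect_true(all(diff(ratio) > 0))

  # very wide tolerance flattens the response
  cfg_flat <- sim_config("18S", children = c(1, 1, 2, 2, 2, 2, 2, 2),
                         tolerance_range = c(1e6, 1.1e6),
                         env_noise_sdlog = 0)
  flat <- simulate_gradient_communities(db, cfg_flat, seed = 96)
  rel_range <- apply(flat$abundance, 1, function(x) diff(range(x)) / max(x))
  expect_true(all(rel_range < 1e-6))
})

test_that("plastid linkage couples 16S and 18S abundance profiles", {
  cfg18 <- sim_config("18S", children = c(1, 1, 2, 2, 2, 2, 2, 2))
  cfg16 <- sim_config("16S", children = c(1, 1, 2, 2, 2, 2, 2, 2),
                      chloro_fraction = 1)
  db18 <- simulate_reference_taxonomy(cfg18, seed = 97)
  db16 <- simulate_reference_taxonomy(cfg16, seed = 98)
  comm18 <- simulate_gradient_communities(db18, cfg18, seed = 97)
  linked <- simulate_linked_marker_communities(comm18, db16, cfg16, db18,
                                               seed = 99)
  # linkage fraction 1: every chloroplast profile is proportional to its
  # partner, so the rank correlation is exactly 1
  expect_equal(nrow(linked$links), 64)
  for (i in sample(64, 8)) {
    rho <- cor(linked$community16$abundance[linked$links$taxon16[i], ],
               comm18$abundance[linked$links$taxon18[i], ],
               method = "spearman")
    expect_equal(rho, 1)
  }
  # chloroplast lineages carry the partner's class at level 4
  l16 <- linked$refdb16$lineage
  expect_true(all(l16[linked$links$taxon16, 3] == "Chloroplast"))
  expect_equal(unname(l16[linked$links$taxon16, 4]),
               unname(db18$lineage[linked$links$taxon18, 4]))

  # linkage fraction 0: nothing is linked
  cfg0 <- sim_config("16S", children = c(1, 1, 2, 2, 2, 2, 2, 2),
                     chloro_fraction = 0)
  linked0 <- simulate_linked_marker_communities(comm18, db16, cfg0, db18,
                                                seed = 99)
  expect_equal(nrow(linked0$links), 0)

  # deliberate class mislabelling for the matching-test scenario
  cfgm <- sim_config("16S", children = c(1, 1, 2, 2, 2, 2, 2, 2),
                     chloro_fraction = 1, n_class_mismatch = 1)
  linkedm <- simulate_linked_marker_communities(comm18, db16, cfgm, db18,
                                                seed = 99)
  expect_equal(sum(!linkedm$links$class_matched), 1)
})

test_that("read simulation conserves counts and respects the error model", {
  cfg <- sim_config("18S", children = c(1, 1, 2, 2, 2, 2, 2, 2),
                    reads_per_sample = 2000L)
  db <- simulate_reference_taxonomy(cfg, seed = 101)
  comm <- simulate_gradient_communities(db, cfg, seed = 101)
  rd <- simulate_paired_reads(comm, db, cfg, seed = 102,
                              stations = c("st_01", "st_11"))
  expect_equal(nrow(rd$fwd), 4000)
  expect_equal(as.integer(table(rd$fwd$sample_id)[c("st_01", "st_11")]),
               c(2000L, 2000L))
  expect_equal(rd$fwd$id, rd$rev$id)
  expect_equal(nrow(rd$truth), 4000)

  # error-free reads are exact substrings of their source references
  cfg0 <- cfg; cfg0$error_scale <- 0
  rd0 <- simulate_paired_reads(comm, db, cfg0, seed = 103,
                               stations = "st_05")
  src <- unname(db$seq[rd0$truth$taxon])
  expect_true(all(substr(src, 1, cfg$read_length) == rd0$fwd$seq))
  expect_true(all(reverse_complement(
    substr(src, nchar(src) - cfg$read_length + 1, nchar(src))) ==
      rd0$rev$seq))

  # measured per-read mismatch counts match the quality-implied rates
  prof <- halocline:::sim_quality_profile(cfg)
  expected <- sum(10^(-prof$fwd / 10))
  mism <- mapply(function(r, s) {
    sum(strsplit(r, "")[[1]] != strsplit(substr(s, 1, cfg$read_length),
                                         "")[[1]])
  }, rd$fwd$seq[1:800], unname(db$seq[rd$truth$taxon[1:800]]))
  se <- sqrt(expected / 800)  # Poisson-ish
  expect_lt(abs(mean(mism) - expected), 4 * se)

  # reads must fit inside the reference
  cfg_long <- cfg; cfg_long$read_length <- 10000L
  expect_error(simulate_paired_reads(comm, db, cfg_long, seed = 1),
               "read length exceeds")
})

test_that("read simulation is byte-identical under a fixed seed", {
  cfg <- sim_config("16S", children = c(1, 1, 2, 2, 2, 2, 2, 2),
                    reads_per_sample = 500L)
  db <- simulate_reference_taxonomy(cfg, seed = 104)
  comm <- simulate_gradient_communities(db, cfg, seed = 104)
  a <- simulate_paired_reads(comm, db, cfg, seed = 105, stations = "st_02")
  b <- simulate_paired_reads(comm, db, cfg, seed = 105, stations = "st_02")
  expect_identical(a$fwd$seq, b$fwd$seq)
  expect_identical(a$rev$seq, b$rev$seq)
  expect_identical(a$truth, b$truth)
})
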