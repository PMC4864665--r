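test_that("cutoff schemes enforce monotonicity", {
  expect_silent(cutoff_scheme(c(rep(0.9, 6), 0.97, 0.99)))
  expect_error(cutoff_scheme(c(0.99, rep(0.9, 7))), "non-decreasing")
  expect_error(cutoff_scheme(c(0.9, 0.9)), "8 ranks")
})

test_that("local alignment finds substrings and filters by length", {
  set.seed(31)
  ref <- random_seq(300)
  refdb <- make_refdb(c(ref, random_seq(300)))
  q <- substr(ref, 20, 280)  # 261-nt exact substring
  hits <- align_query_to_refs(q, refdb, min_aln_len = 250, band = NULL)
  expect_equal(hits$ref_id, "ref_1")
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$aln_len, 261L)

  # alignment shorter than the floor is dropped (and counted)
  hits2 <- align_query_to_refs(substr(ref, 20, 259), refdb,
                               min_aln_len = 250, band = NULL)
  expect_equal(nrow(hits2), 0)
  expect_gte(attr(hits2, "n_filtered"), 1)

  # reverse-strand query gives the same hit as its forward control
  fh <- align_query_to_refs(q, refdb, min_aln_len = 100, band = NULL)
  rh <- align_query_to_refs(reverse_complement(q), refdb,
                            min_aln_len = 100, band = NULL)
  expect_equal(rh$identity[rh$ref_id == "ref_1"],
               fh$identity[fh$ref_id == "ref_1"])
  expect_equal(rh$bitscore[rh$ref_id == "ref_1"],
               fh$bitscore[fh$ref_id == "ref_1"])
  expect_equal(rh$strand[rh$ref_id == "ref_1"], -1L)

  expect_error(align_query_to_refs(q, refdb, min_aln_len = 0), ">= 1")
})

test_that("banded seeded alignment agrees with the full matrix for near hits", {
  set.seed(32)
  ref <- random_seq(400)
  refdb <- make_refdb(c(ref, random_seq(400)))
  q <- mutate_at(substr(ref, 50, 350), 6)
  full <- align_query_to_refs(q, refdb, min_aln_len = 250, band = NULL)
  banded <- align_query_to_refs(q, refdb, min_aln_len = 250, band = 48)
  expect_equal(banded$identity[banded$ref_id == "ref_1"],
               full$identity[full$ref_id == "ref_1"])
})

test_that("paired assignment follows the rank-specific identity cutoffs", {
  refdb <- make_refdb(replicate(3, random_seq(50)))
  cuts <- default_cutoffs()
  # single shared ref, min(fwd, rev) identity 0.992 >= 0.99 -> species
  a <- assign_paired(make_hits("ref_1", 0.995, 200),
                     make_hits("ref_1", 0.992, 180), refdb, cuts)
  expect_equal(a$lineage$depth, 8L)
  expect_equal(a$reason, "none")

  # min identity 0.975: genus (>= 0.97) but not species (< 0.99)
  b <- assign_paired(make_hits("ref_1", 0.98, 200),
                     make_hits("ref_1", 0.975, 180), refdb, cuts)
  expect_equal(b$lineage$depth, 7L)
  expect_equal(b$reason, "identity_cutoff")

  # below the kingdom cutoff: unclassified
  c <- assign_paired(make_hits("ref_1", 0.85, 200),
                     make_hits("ref_1", 0.80, 180), refdb, cuts)
  expect_equal(c$lineage$depth, 0L)

  # no shared reference: no_hits
  d <- assign_paired(make_hits("ref_1", 0.99, 200),
                     make_hits("ref_2", 0.99, 180), refdb, cuts)
  expect_equal(d$lineage$depth, 0L)
  expect_equal(d$reason, "no_hits")
})

test_that("the 95% bit-score rule builds a consensus over retained refs", {
  # two refs sharing the genus, differing at species
  lin <- c("k;sg;dv;cl;or;fa;ge;sp_A", "k;sg;dv;cl;or;fa;ge;sp_B",
           "k2;sg2;dv2;cl2;or2;fa2;ge2;sp2")
  refdb <- make_refdb(replicate(3, random_seq(50)), lin)
  cuts <- default_cutoffs()
  # bit-score sums 200 and 195: both within 95% of the best -> genus consensus
  a <- assign_paired(make_hits(c("ref_1", "ref_2"), c(0.995, 0.992), c(110, 105)),
                     make_hits(c("ref_1", "ref_2"), c(0.993, 0.994), c(90, 90)),
                     refdb, cuts)
  expect_equal(a$lineage$depth, 7L)
  expect_equal(a$reason, "consensus_conflict")
  expect_setequal(a$evidence, c("ref_1", "ref_2"))

  # second ref below 95% of the best sum: dropped, species assigned
  b <- assign_paired(make_hits(c("ref_1", "ref_2"), c(0.995, 0.992), c(110, 94)),
                     make_hits(c("ref_1", "ref_2"), c(0.993, 0.994), c(90, 90)),
                     refdb, cuts)
  expect_equal(b$lineage$depth, 8L)
  expect_equal(b$lineage$ranks[8], "sp_A")

  # total conflict at kingdom level with equal scores: unclassified
  c <- assign_single(make_hits(c("ref_1", "ref_3"), c(0.99, 0.99), c(100, 100)),
                     refdb, cuts)
  expect_equal(c$lineage$depth, 0L)
  expect_equal(c$reason, "consensus_conflict")
})

test_that("assign_single mirrors the paired rules for one read", {
  refdb <- make_refdb(replicate(2, random_seq(50)))
  a <- assign_single(make_hits("ref_1", 1.0, 150), refdb, default_cutoffs())
  expect_equal(a$lineage$depth, 8L)
  b <- assign_single(make_hits(character(0), numeric(0), numeric(0)),
                     refdb, default_cutoffs())
  expect_equal(b$lineage$depth, 0L)
  expect_equal(b$reason, "no_hits")
})

test_that("paired assignment equals the brute-force oracle on random instances", {
  set.seed(33)
  for (i in 1:100) {
    inst <- random_paired_instance()
    got <- assign_paired(inst$fwd, inst$rev, inst$refdb, inst$cutoffs)
    want <- oracle_assign_paired(inst$fwd, inst$rev, inst$refdb, inst$cutoffs)
    expect_equal(got$lineage$depth, want$depth,
                 info = sprintf("instance %d depth", i))
    expect_equal(got$lineage$ranks, want$ranks,
                 info = sprintf("instance %d ranks", i))
  }
})

test_that("raising cutoffs never deepens an assignment (monotonicity)", {
  set.seed(34)
  for (i in 1:40) {
    inst <- random_paired_instance()
    base <- assign_paired(inst$fwd, inst$rev, inst$refdb, inst$cutoffs)
    raised <- unclass(inst$cutoffs)
    r <- sample(8, 1)
    raised[r:8] <- pmax(raised[r:8], min(raised[r] + 0.02, 1))
    deeper <- assign_paired(inst$fwd, inst$rev, inst$refdb,
                            cutoff_scheme(raised))
    expect_lte(deeper$lineage$depth, base$lineage$depth)
  }
})

test_that("an error-free amplicon from a database entry gets its full lineage", {
  set.seed(35)
  cfg <- sim_config("18S", children = c(1, 2, 2, 2, 2, 2, 1, 2))
  refdb <- simulate_reference_taxonomy(cfg, seed = 351)
  amps <- truth_amplicons(refdb, cfg, qmin = 25)
  pick <- sample(nrow(amps), 6)
  for (i in pick) {
    fwd <- substr(amps$seq[i], 1, amps$junction[i])
    rev <- substr(amps$seq[i], amps$junction[i] + 1, nchar(amps$seq[i]))
    fh <- align_query_to_refs(fwd, refdb, min_aln_len = 250)
    rh <- align_query_to_refs(rev, refdb, min_aln_len = 210)
    a <- assign_paired(fh, rh, refdb, default_cutoffs())
    expect_equal(a$lineage$depth, 8L)
    expect_equal(unname(a$lineage$ranks),
                 unname(refdb$lineage[amps$taxon[i], ]))
  }
})

test_that("removing the true reference never deepens an assignment", {
  set.seed(36)
  cfg <- sim_config("18S")
  refdb <- simulate_reference_taxonomy(cfg, seed = 361)
  amps <- truth_amplicons(refdb, cfg, qmin = 25)
  pick <- sample(nrow(amps), 5)
  for (i in pick) {
    fwd <- substr(amps$seq[i], 1, amps$junction[i])
    rev <- substr(amps$seq[i], amps$junction[i] + 1, nchar(amps$seq[i]))
    full <- assign_paired(align_query_to_refs(fwd, refdb, 250),
                          align_query_to_refs(rev, refdb, 210),
                          refdb, default_cutoffs())
    reduced_db <- drop_reference_entries(refdb, amps$taxon[i])
    red <- assign_paired(align_query_to_refs(fwd, reduced_db, 250),
                         align_query_to_refs(rev, reduced_db, 210),
                         reduced_db, default_cutoffs())
    expect_lte(red$lineage$depth, full$lineage$depth)
  }
})

test_that("manual overrides apply only above 99% coverage and identity", {
  asg <- data.frame(otu_id = c("OTU_1", "OTU_2"),
                    kingdom = "k", supergroup = "sg", division = "dv",
                    class = "cl", order = "or", family = "fa",
                    genus = "", species = "",
                    depth = 6L, reason = "identity_cutoff", evidence = "",
                    stringsAsFactors = FALSE)
  ov <- data.frame(otu_id = "OTU_1", lineage = "K;SG;DV;CL;OR;FA;GE;SP",
                   coverage = 0.999, identity = 0.995,
                   stringsAsFactors = FALSE)
  out <- apply_manual_overrides(asg, ov)
  expect_equal(out$depth[1], 8L)
  expect_equal(out$species[1], "SP")
  expect_equal(out$depth[2], 6L)

  weak <- data.frame(otu_id = "OTU_2", lineage = "K;SG;DV;CL;OR;FA;GE;SP",
                     coverage = 0.999, identity = 0.98,
                     stringsAsFactors = FALSE)
  expect_warning(out2 <- apply_manual_overrides(asg, weak), "ignored")
  expect_equal(out2$depth[2], 6L)

  expect_error(apply_manual_overrides(asg, data.frame(
    otu_id = "OTU_9", lineage = "a", coverage = 1, identity = 1)),
    "unknown OTU")
  expect_identical(apply_manual_overrides(asg, ov[0, ])$depth, asg$depth)
})
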