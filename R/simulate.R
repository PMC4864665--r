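#' Configuration of the synthetic gradient study
#'
#' Bundles every knob of the synthetic-data generator: the shape and
#' divergence structure of the reference taxonomy, the amplicon geometry of
#' the marker, the community model along the salinity gradient, and the
#' sequencing error model.  Defaults emulate the study conditions: 21
#' stations spanning salinity 2-30, 5x10^4 read pairs per sample and marker,
#' an eight-rank reference of 128 taxa, Illumina-like 2x300 nt reads whose 3'
#' quality decays (so the Q25 centroid pass trims more than the Q20 mapping
#' pass), a 16S geometry whose mates overlap and an 18S geometry whose mates
#' do not (forcing concatenation), and plastid linkage for half of the
#' eukaryotic taxa.
#'
#' @param marker `"16S"` or `"18S"`; sets the primer pair, amplicon length,
#'   fixed tail trim, and merge-vs-concatenate geometry.
#' @param n_stations number of stations along the gradient.
#' @param salinity_range gradient end points (practical salinity).
#' @param children children per rank below the root (8 values; the product
#'   is the number of reference leaves).
#' @param sibling_identity expected sequence identity between leaves whose
#'   lineages first diverge at each rank (strictly increasing, kingdom to
#'   species).
#' @param read_length raw read length of both mates.
#' @param reads_per_sample read pairs drawn per station.
#' @param baseline_sdlog log-SD of the lognormal taxon baselines.
#' @param tolerance_range uniform range of the Gaussian niche tolerances
#'   (salinity units).
#' @param copy_sdlog log-SD of per-taxon rRNA copy-number multipliers (they
#'   distort read counts, not the underlying community).
#' @param env_noise_sdlog log-SD of station-by-taxon environmental noise
#'   (bloom patchiness) multiplying the niche response; 0 gives the pure
#'   Gaussian gradient response.  Plastid-linked 16S taxa inherit their
#'   partner's noise, so true cross-marker pairs stay perfectly correlated
#'   while unrelated taxa decorrelate, as in field data.
#' @param metazoan_spike number of taxa given `spike_factor`-fold copy
#'   numbers (emulating multicellular rRNA load); 0 disables it.
#' @param spike_factor copy-number multiplier of spiked taxa.
#' @param chloro_fraction fraction of eukaryotic taxa that get a linked
#'   chloroplast 16S taxon (used when pairing markers).
#' @param chloro_ratio_meanlog log-mean of the chloroplast:nuclear abundance
#'   ratio.
#' @param n_class_mismatch number of linked taxa whose chloroplast class
#'   label is deliberately mislabelled (to exercise the matching test).
#' @param error_scale multiplier on the per-base substitution rates implied
#'   by the quality profile (`10^(-Q/10)` at each position); 0 gives
#'   error-free reads.
#' @param seed unused here (pass seeds to the simulation functions); kept so
#'   a config can document the intended seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(marker = c("16S", "18S"),
                       n_stations = 21L,
                       salinity_range = c(2, 30),
                       children = c(1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
                       sibling_identity = c(0.70, 0.76, 0.80, 0.84,
                                            0.87, 0.90, 0.92, 0.95),
                       read_length = 300L,
                       reads_per_sample = 50000L,
                       baseline_sdlog = 1,
                       tolerance_range = c(3, 10),
                       copy_sdlog = 0.5,
                       env_noise_sdlog = 0.5,
                       metazoan_spike = 0L,
                       spike_factor = 50,
                       chloro_fraction = 0.5,
                       chloro_ratio_meanlog = log(0.1),
                       n_class_mismatch = 0L,
                       error_scale = 1,
                       seed = NULL) {
  marker <- match.arg(marker)
  if (length(children) != 8) stop("children must give 8 rank widths")
  if (length(sibling_identity) != 8)
    stop("sibling_identity must give 8 rank targets")
  if (any(diff(sibling_identity) <= 0))
    stop("sibling_identity must be strictly increasing from kingdom to species")
  if (any(sibling_identity <= 0.25 | sibling_identity > 1))
    stop("sibling identities must lie in (0.25, 1]")
  if (error_scale < 0) stop("error_scale must be >= 0")
  geom <- if (marker == "16S") {
    list(fwd_primer = "CCTACGGGNGGCWGCAG",
         rev_primer = "GACTACHVGGGTATCTAATCC",
         inner_length = 370L, tail_trim = 40L, mode = "merge")
  } else {
    list(fwd_primer = "CGGTAAYTCCAGCTCYV",
         rev_primer = "CCGTCAATTHCTTYAAR",
         inner_length = 576L, tail_trim = 44L, mode = "concatenate")
  }
  cfg <- c(list(marker = marker, n_stations = as.integer(n_stations),
                salinity_range = salinity_range, children = as.integer(children),
                sibling_identity = sibling_identity,
                read_length = as.integer(read_length),
                reads_per_sample = as.integer(reads_per_sample),
                baseline_sdlog = baseline_sdlog,
                tolerance_range = tolerance_range,
                copy_sdlog = copy_sdlog,
                env_noise_sdlog = env_noise_sdlog,
                metazoan_spike = as.integer(metazoan_spike),
                spike_factor = spike_factor,
                chloro_fraction = chloro_fraction,
                chloro_ratio_meanlog = chloro_ratio_meanlog,
                n_class_mismatch = as.integer(n_class_mismatch),
                error_scale = error_scale, seed = seed),
           geom)
  cfg$ref_length <- cfg$inner_length + nchar(cfg$fwd_primer) +
    nchar(cfg$rev_primer)
  structure(cfg, class = "sim_config")
}

# Phred score at each raw read position: high plateau with a decaying 3'
# tail, the reverse mate noisier than the forward (typical paired-end
# behaviour, and what makes the Q25/Q20 two-pass design meaningful).
sim_quality_profile <- function(config) {
  pos <- seq_len(config$read_length)
  fwd <- as.integer(round(pmax(22, 38 - pmax(0, pos - 240) * 16 / 60)))
  rev <- as.integer(round(pmax(18, 36 - pmax(0, pos - 150) * 18 / 150)))
  list(fwd = fwd, rev = rev)
}

rank_prefixes_ <- c("k", "sg", "dv", "cl", "or", "fa", "ge", "sp")

random_dna_ <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

instantiate_iupac_ <- function(primer) {
  pp <- strsplit(toupper(primer), "")[[1]]
  paste(vapply(pp, function(ch) {
    set <- setdiff(iupac_sets_[[ch]], "N")
    set[sample.int(length(set), 1)]
  }, character(1)), collapse = "")
}

#' Simulate a rank-structured reference database
#'
#' Grows an eight-rank taxonomy from a random root sequence: at each rank
#' every node spawns `children[rank]` children, each mutated at a per-branch
#' substitution probability chosen (with a Jukes-Cantor correction for
#' multiple hits) so that the realised identity between leaves first
#' diverging at rank r matches `sibling_identity[r]`.  Forward and reverse
#' primer sites are implanted at the amplicon ends and masked from mutation,
#' so every leaf remains amplifiable.
#'
#' @param config a [sim_config].
#' @param seed optional seed (`NULL` = current RNG stream).
#' @return A [reference_db] whose entries are the tree's leaves, with the
#'   node table attached as `attr(, "tree")`.
#' @export
simulate_reference_taxonomy <- function(config, seed = NULL) {
  with_seed_(seed, {
    t <- config$sibling_identity
    L <- config$ref_length
    lf <- nchar(config$fwd_primer); lr <- nchar(config$rev_primer)
    # identities are measured over the whole sequence, but the primer sites
    # are conserved (masked); rescale the divergence to the mutable fraction
    t_free <- 1 - (1 - t) * L / (L - lf - lr)
    excess <- 1 - 4 / 3 * (1 - t_free)
    if (any(excess <= 0))
      stop("divergence target(s) unreachable under a substitution model")
    S <- -3 / 4 * log(excess)          # JC path length for rank-r splits
    mu <- (S - c(S[-1], 0)) / 2        # per-branch substitution probability
    if (any(mu <= 0))
      stop("divergence targets must be strictly increasing in identity")
    fwd <- instantiate_iupac_(config$fwd_primer)
    rev_site <- reverse_complement(instantiate_iupac_(config$rev_primer))
    root <- random_dna_(L)
    substr(root, 1, lf) <- fwd
    substr(root, L - lr + 1, L) <- rev_site
    free <- setdiff(seq_len(L), c(seq_len(lf), (L - lr + 1):L))
    bases <- c("A", "C", "G", "T")

    nodes <- list(list(seq = root, path = integer(0)))
    tree <- list()
    for (r in 1:8) {
      nxt <- vector("list", length(nodes) * config$children[r])
      k <- 0
      for (nd in nodes) {
        for (ch in seq_len(config$children[r])) {
          s <- nd$seq
          hit <- free[runif(length(free)) < mu[r]]
          if (length(hit) > 0) {
            cur <- strsplit(s, "")[[1]]
            cur[hit] <- vapply(cur[hit], function(b)
              sample(setdiff(bases, b), 1), character(1))
            s <- paste(cur, collapse = "")
          }
          k <- k + 1
          path <- c(nd$path, ch)
          nxt[[k]] <- list(seq = s, path = path)
          tree[[length(tree) + 1L]] <- data.frame(
            level = r,
            label = paste0(rank_prefixes_[r], "_",
                           paste(path, collapse = ".")),
            parent = if (r == 1) "root"
                     else paste0(rank_prefixes_[r - 1], "_",
                                 paste(nd$path, collapse = ".")),
            stringsAsFactors = FALSE)
        }
      }
      nodes <- nxt
    }
    ids <- sprintf("%s_ref_%03d", tolower(config$marker), seq_along(nodes))
    seqs <- vapply(nodes, `[[`, character(1), "seq")
    lineages <- t(vapply(nodes, function(nd) {
      vapply(1:8, function(r)
        paste0(rank_prefixes_[r], "_",
               paste(nd$path[seq_len(r)], collapse = ".")), character(1))
    }, character(8)))
    db <- reference_db(ids, seqs, lineages)
    attr(db, "tree") <- do.call(rbind, tree)
    db
  })
}

#' Simulate community turnover along a salinity gradient
#'
#' Every taxon receives a lognormal abundance baseline, a niche optimum
#' drawn uniformly over the salinity range, and a Gaussian niche tolerance;
#' its abundance at a station is the baseline times the Gaussian response to
#' the distance between the station's salinity and its optimum, times
#' station-level lognormal patchiness noise (`env_noise_sdlog`).  Stations
#' are evenly spaced along the gradient, so composition turns over smoothly
#' -- the structure the beta-diversity statistics are designed to detect --
#' while the noise keeps unrelated taxa from correlating spuriously.
#'
#' @param refdb a [reference_db]; its leaves become the community's taxa.
#' @param config a [sim_config].
#' @param seed optional seed (`NULL` = current RNG stream).
#' @return A `true_community`: list with `metadata` (station data frame),
#'   `abundance` (taxon x station matrix), `niches` (per-taxon parameters).
#' @export
simulate_gradient_communities <- function(refdb, config, seed = NULL) {
  with_seed_(seed, {
    n <- config$n_stations
    sal <- seq(config$salinity_range[1], config$salinity_range[2],
               length.out = n)
    meta <- data.frame(
      sample_id = sprintf("st_%02d", seq_len(n)),
      station = sprintf("station_%02d", seq_len(n)),
      salinity = sal,
      temperature = round(14 + 0.25 * sal + rnorm(n, 0, 0.8), 2),
      stringsAsFactors = FALSE)
    taxa <- refdb$ids
    niches <- data.frame(
      taxon = taxa,
      baseline = rlnorm(length(taxa), 0, config$baseline_sdlog),
      optimum = runif(length(taxa), config$salinity_range[1],
                      config$salinity_range[2]),
      tolerance = runif(length(taxa), config$tolerance_range[1],
                        config$tolerance_range[2]),
      stringsAsFactors = FALSE)
    ab <- outer(seq_along(taxa), seq_len(n), function(i, j)
      niches$baseline[i] *
        exp(-(sal[j] - niches$optimum[i])^2 / (2 * niches$tolerance[i]^2)))
    if ((config$env_noise_sdlog %||% 0) > 0)
      ab <- ab * matrix(rlnorm(length(ab), 0, config$env_noise_sdlog),
                        nrow(ab), ncol(ab))
    dimnames(ab) <- list(taxa, meta$sample_id)
    structure(list(metadata = meta, abundance = ab, niches = niches),
              class = "true_community")
  })
}

#' Pair a 16S community to an 18S community through plastid linkage
#'
#' A fraction of the eukaryotic (18S) taxa are designated
#' chloroplast-linked: each takes over one 16S reference leaf, whose lineage
#' is rewritten as a chloroplast lineage carrying the partner's class name,
#' and whose abundance profile becomes a fixed per-taxon multiple of the
#' partner's 18S profile (so the pair correlates perfectly before sequencing
#' noise).  Remaining 16S taxa get independent gradient niches.  Optionally,
#' `n_class_mismatch` linked taxa are mislabelled with a different class, to
#' emulate imperfect annotations when exercising the matching test.
#'
#' @param community18 a `true_community` for the 18S marker.
#' @param refdb16 the 16S [reference_db] (its lineages are modified for the
#'   chloroplast leaves).
#' @param config the 16S [sim_config] (supplies `chloro_fraction`,
#'   `chloro_ratio_meanlog`, `n_class_mismatch`, community parameters).
#' @param refdb18 the 18S [reference_db] (source of partner class names).
#' @param seed optional seed (`NULL` = current RNG stream).
#' @return A list: `community16` (`true_community` on the same stations),
#'   `refdb16` (lineages updated), `links` (data frame `taxon16`, `taxon18`,
#'   `ratio`, `class16`, `class18`, `class_matched`).
#' @export
simulate_linked_marker_communities <- function(community18, refdb16, config,
                                               refdb18, seed = NULL) {
  if (config$chloro_fraction < 0 || config$chloro_fraction > 1)
    stop("chloro_fraction must be in [0, 1]")
  with_seed_(seed, {
    taxa18 <- rownames(community18$abundance)
    n_linked <- round(config$chloro_fraction * length(taxa18))
    n_linked <- min(n_linked, length(refdb16$ids))
    meta <- community18$metadata

    # independent gradient community over all 16S leaves first
    comm16 <- simulate_gradient_communities(refdb16, config)
    comm16$metadata <- meta  # same stations as the 18S survey
    links <- data.frame(taxon16 = character(0), taxon18 = character(0),
                        ratio = numeric(0), class16 = character(0),
                        class18 = character(0), class_matched = logical(0),
                        stringsAsFactors = FALSE)
    if (n_linked > 0) {
      taxon16 <- sample(refdb16$ids, n_linked)
      taxon18 <- sample(taxa18, n_linked)
      ratio <- rlnorm(n_linked, config$chloro_ratio_meanlog, 0.5)
      class18 <- refdb18$lineage[taxon18, 4]
      class16 <- class18
      if (config$n_class_mismatch > 0) {
        k <- min(config$n_class_mismatch, n_linked)
        all_classes <- unique(refdb18$lineage[, 4])
        for (i in seq_len(k)) {
          alt <- setdiff(all_classes, class18[i])
          class16[i] <- if (length(alt) > 0) alt[1] else "cl_other"
        }
      }
      for (i in seq_len(n_linked)) {
        part <- refdb18$lineage[taxon18[i], ]
        refdb16$lineage[taxon16[i], ] <- c(
          refdb16$lineage[taxon16[i], 1], "Cyanobacteria_pl", "Chloroplast",
          class16[i], paste0("cp_", part[5:8]))
        comm16$abundance[taxon16[i], ] <-
          ratio[i] * community18$abundance[taxon18[i], ]
      }
      comm16$niches$baseline[match(taxon16, comm16$niches$taxon)] <- NA
      links <- data.frame(taxon16 = taxon16, taxon18 = taxon18,
                          ratio = ratio, class16 = class16,
                          class18 = class18,
                          class_matched = class16 == class18,
                          stringsAsFactors = FALSE)
    }
    list(community16 = comm16, refdb16 = refdb16, links = links)
  })
}

#' Simulate paired amplicon reads from a community
#'
#' Reads are drawn multinomially per station from the community's taxon
#' abundances (distorted by lognormal rRNA copy-number multipliers and an
#' optional metazoan-like spike), excised from the reference sequences at
#' the primer coordinates with the marker's 2 x `read_length` geometry, and
#' mutated per base at `error_scale * 10^(-Q/10)` where Q follows the
#' position-dependent quality profile -- so the emitted Phred strings are
#' consistent with the injected error rates by construction.
#'
#' @param community a `true_community`.
#' @param refdb the matching [reference_db].
#' @param config a [sim_config].
#' @param seed optional seed (`NULL` = current RNG stream).
#' @param stations optional subset of station sample_ids to simulate (the
#'   pipeline streams one station at a time to bound memory).
#' @return A list: `fwd` and `rev` ([qual_reads] with `sample_id` set) and
#'   `truth` (data frame `read_id`, `sample_id`, `taxon`).
#' @export
simulate_paired_reads <- function(community, refdb, config, seed = NULL,
                                  stations = NULL) {
  reflen <- nchar(refdb$seq)
  if (config$read_length > min(reflen))
    stop("read length exceeds the amplicon length")
  with_seed_(seed, {
    prof <- sim_quality_profile(config)
    rate_f <- config$error_scale * 10^(-prof$fwd / 10)
    rate_r <- config$error_scale * 10^(-prof$rev / 10)
    qf <- phred_encode(prof$fwd)
    qr <- phred_encode(prof$rev)
    taxa <- rownames(community$abundance)
    mult <- rlnorm(length(taxa), 0, config$copy_sdlog)
    if (config$metazoan_spike > 0) {
      sp <- sample(seq_along(taxa), min(config$metazoan_spike, length(taxa)))
      mult[sp] <- mult[sp] * config$spike_factor
    }
    fwd_t <- substr(unname(refdb$seq[taxa]), 1, config$read_length)
    rev_t <- reverse_complement(
      substr(unname(refdb$seq[taxa]),
             nchar(refdb$seq[taxa]) - config$read_length + 1,
             nchar(refdb$seq[taxa])))
    use <- stations %||% community$metadata$sample_id
    out_f <- list(); out_r <- list(); out_truth <- list()
    for (s in use) {
      w <- community$abundance[, s] * mult
      counts <- as.integer(rmultinom(1, config$reads_per_sample, w))
      idx <- rep.int(seq_along(taxa), counts)
      f <- fwd_t[idx]; r <- rev_t[idx]
      if (config$error_scale > 0) {
        f <- .mutate_seqs_cpp(f, rate_f)
        r <- .mutate_seqs_cpp(r, rate_r)
      }
      ids <- sprintf("%s_read_%06d", s, seq_along(idx))
      out_f[[s]] <- qual_reads(ids, f, rep(qf, length(f)),
                               orientation = "forward", sample_id = s)
      out_r[[s]] <- qual_reads(ids, r, rep(qr, length(r)),
                               orientation = "reverse", sample_id = s)
      out_truth[[s]] <- data.frame(read_id = ids, sample_id = s,
                                   taxon = taxa[idx],
                                   stringsAsFactors = FALSE)
    }
    fwd <- do.call(rbind, out_f); class(fwd) <- c("qual_reads", "data.frame")
    rev <- do.call(rbind, out_r); class(rev) <- c("qual_reads", "data.frame")
    list(fwd = fwd, rev = rev, truth = do.call(rbind, out_truth))
  })
}

#' Error-free prepared amplicons of every reference taxon
#'
#' Runs the read-preparation chain on one error-free read pair per reference
#' entry, giving the exact sequence an OTU centroid founded by that taxon
#' will carry -- the ground truth used to audit clustering and
#' classification.
#'
#' @param refdb a [reference_db].
#' @param config a [sim_config].
#' @param qmin preparation profile (25 = centroid pass, 20 = mapping pass).
#' @return A data frame: `taxon`, `seq`, `junction`.
#' @export
truth_amplicons <- function(refdb, config, qmin = 25) {
  prof <- sim_quality_profile(config)
  qf <- phred_encode(prof$fwd); qr <- phred_encode(prof$rev)
  taxa <- refdb$ids
  fwd_t <- substr(unname(refdb$seq[taxa]), 1, config$read_length)
  rev_t <- reverse_complement(
    substr(unname(refdb$seq[taxa]),
           nchar(refdb$seq[taxa]) - config$read_length + 1,
           nchar(refdb$seq[taxa])))
  fwd <- qual_reads(taxa, fwd_t, rep(qf, length(taxa)), sample_id = "truth")
  rev <- qual_reads(taxa, rev_t, rep(qr, length(taxa)), sample_id = "truth")
  prep <- prepare_reads(fwd, rev, config$fwd_primer, config$rev_primer,
                        config$tail_trim, qmin,
                        mode = if (config$mode == "merge") "merge"
                               else "concatenate")
  data.frame(taxon = taxa, seq = prep$seq, junction = prep$junction,
             stringsAsFactors = FALSE)
}
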