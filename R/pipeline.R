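#' Run the OTU pipeline for one marker
#'
#' Orchestrates the per-marker chain end to end: read preparation in two
#' passes (stringent Q25 centroid pass, lenient Q20 mapping pass, both from
#' the same raw reads), dereplication, greedy 99% clustering, mapping-pass
#' counting, and consensus classification.  Deterministic given the config
#' and seed; all randomised stages draw from one seeded stream.
#'
#' @param config a list naming the inputs:
#'   \describe{
#'     \item{reads}{in-memory input: list with `fwd`/`rev` [qual_reads]
#'       (with `sample_id` set); or}
#'     \item{fastq}{data frame/list with `fwd`, `rev` FASTQ paths and
#'       `sample_id` per sample; or}
#'     \item{sim}{a [sim_config] -- the reads (and, if no reference is
#'       given, the reference itself) are simulated.}
#'     \item{reference}{a [reference_db], or list with `fasta` and
#'       `taxonomy` paths.  Required unless `sim` is given.}
#'     \item{marker}{`"16S"` (merge geometry) or `"18S"` (concatenate).}
#'     \item{fwd_primer, rev_primer, tail_trim}{read-prep parameters
#'       (defaulted from `sim` when present).}
#'     \item{cluster_threshold, map_threshold}{identity thresholds (0.99).}
#'     \item{cutoffs}{a [cutoff_scheme] for classification.}
#'     \item{seed}{integer seed for the whole run.}
#'   }
#' @param output_dir optional directory: OTU table, centroid FASTA,
#'   assignment TSV, rejection audit and a run log are written there.
#' @param verbose print stage progress.
#' @return A result bundle: list with `otu_table` (lineages attached),
#'   `assignments`, `clusters`, `audit` (per-pass read fate counts),
#'   `refdb`, `truth` (when simulated), and `params`.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = FALSE) {
  # fail on an incomplete config before any compute
  if (is.null(config$reference) && is.null(config$sim))
    stop("config must name a reference (or a sim config that generates one)")
  if (is.null(config$reads) && is.null(config$fastq) && is.null(config$sim))
    stop("config must provide reads: 'reads', 'fastq' or 'sim'")
  marker <- config$marker %||% config$sim$marker %||%
    stop("config must name the marker")
  say <- function(...) if (verbose) message(sprintf(...))

  run <- function() {
    # --- reference -------------------------------------------------------
    refdb <- config$reference
    truth <- NULL
    community <- NULL
    if (is.null(refdb) || (is.list(refdb) && !inherits(refdb, "reference_db"))) {
      if (!is.null(refdb)) {
        refdb <- parse_reference_db(refdb$fasta, refdb$taxonomy)
      } else {
        say("simulating reference taxonomy")
        refdb <- simulate_reference_taxonomy(config$sim)
      }
    }
    # --- reads -----------------------------------------------------------
    if (!is.null(config$reads)) {
      reads <- config$reads
    } else if (!is.null(config$fastq)) {
      fq <- config$fastq
      fwd <- do.call(rbind, Map(function(p, s) parse_fastq(p, s, "forward"),
                                fq$fwd, fq$sample_id))
      rev <- do.call(rbind, Map(function(p, s) parse_fastq(p, s, "reverse"),
                                fq$rev, fq$sample_id))
      class(fwd) <- class(rev) <- c("qual_reads", "data.frame")
      reads <- list(fwd = fwd, rev = rev)
    } else {
      say("simulating gradient community and reads")
      community <- config$community %||%
        simulate_gradient_communities(refdb, config$sim)
      sim <- simulate_paired_reads(community, refdb, config$sim)
      reads <- sim[c("fwd", "rev")]
      truth <- sim$truth
    }
    prep_par <- list(
      fwd_primer = config$fwd_primer %||% config$sim$fwd_primer,
      rev_primer = config$rev_primer %||% config$sim$rev_primer,
      tail_trim = config$tail_trim %||% config$sim$tail_trim,
      mode = config$mode %||% config$sim$mode %||%
        if (marker == "16S") "merge" else "concatenate")
    if (is.null(prep_par$fwd_primer) || is.null(prep_par$rev_primer) ||
        is.null(prep_par$tail_trim))
      stop("config must provide fwd_primer, rev_primer and tail_trim")

    # --- two-pass preparation + dereplication, streamed per sample -------
    samples <- unique(reads$fwd$sample_id)
    cent_parts <- list(); map_parts <- list()
    audit <- list()
    for (s in samples) {
      i <- reads$fwd$sample_id == s
      fwd_s <- reads$fwd[i, , drop = FALSE]
      rev_s <- reads$rev[reads$rev$sample_id == s, , drop = FALSE]
      cent <- prepare_reads(fwd_s, rev_s, prep_par$fwd_primer,
                            prep_par$rev_primer, prep_par$tail_trim,
                            qmin = 25, mode = prep_par$mode)
      mapp <- prepare_reads(fwd_s, rev_s, prep_par$fwd_primer,
                            prep_par$rev_primer, prep_par$tail_trim,
                            qmin = 20, mode = prep_par$mode)
      audit[[s]] <- list(centroid = attr(cent, "audit"),
                         mapping = attr(mapp, "audit"))
      cent_parts[[s]] <- derep_table_(cent)
      map_parts[[s]] <- derep_table_(mapp)
      say("prepared %s: %d/%d centroid-pass, %d/%d mapping-pass pairs kept",
          s, sum(cent$accepted), nrow(cent), sum(mapp$accepted), nrow(mapp))
    }
    cent_uniq <- combine_derep_(cent_parts, samples)
    map_uniq <- combine_derep_(map_parts, samples)
    say("dereplicated: %d centroid-pass / %d mapping-pass unique sequences",
        length(cent_uniq$seq), length(map_uniq$seq))

    # --- clustering + mapping -------------------------------------------
    thr_c <- config$cluster_threshold %||% 0.99
    thr_m <- config$map_threshold %||% 0.99
    clusters <- greedy_cluster(cent_uniq, threshold = thr_c)
    say("clustered into %d OTUs at %.0f%% identity",
        nrow(clusters$centroids), 100 * thr_c)
    tab <- map_uniques_to_table_(map_uniq, clusters, thr_m, marker)
    say("mapped reads: %s assigned, %s unassigned",
        format(sum(tab$counts), big.mark = ","),
        format(sum(tab$unassigned), big.mark = ","))

    # --- classification --------------------------------------------------
    cutoffs <- config$cutoffs %||% default_cutoffs()
    assignments <- classify_otus(tab, refdb, cutoffs)
    tab <- set_lineages(tab, assignments)
    say("classified: %d/%d OTUs at depth >= 1",
        sum(assignments$depth >= 1), nrow(assignments))

    params <- list(marker = marker, cluster_threshold = thr_c,
                   map_threshold = thr_m, cutoffs = unclass(cutoffs),
                   prep = prep_par, seed = config$seed,
                   n_samples = length(samples))
    list(otu_table = tab, assignments = assignments, clusters = clusters,
         audit = audit, refdb = refdb, truth = truth,
         community = community, params = params)
  }
  res <- with_seed_(config$seed, run())

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_otu_table(res$otu_table, file.path(output_dir, "otu_table.tsv"))
    export_centroids_fasta(res$otu_table,
                           file.path(output_dir, "centroids.fasta"))
    write.table(res$assignments, file.path(output_dir, "assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log <- c(sprintf("run_pipeline marker=%s", res$params$marker),
             sprintf("seed=%s", deparse(res$params$seed)),
             sprintf("cluster_threshold=%g map_threshold=%g",
                     res$params$cluster_threshold, res$params$map_threshold),
             sprintf("cutoffs=%s",
                     paste(res$params$cutoffs, collapse = ",")),
             vapply(names(res$audit), function(s)
               sprintf("audit %s centroid: %s | mapping: %s", s,
                       paste(res$audit[[s]]$centroid, collapse = "/"),
                       paste(res$audit[[s]]$mapping, collapse = "/")),
               character(1)))
    writeLines(log, file.path(output_dir, "run_log.txt"))
  }
  res
}

# Compact per-sample dereplication table (seq, junction, count).
derep_table_ <- function(prepared) {
  keep <- prepared[prepared$accepted, c("seq", "junction", "sample_id")]
  dt <- data.table::data.table(seq = keep$seq, junction = keep$junction,
                               sample = keep$sample_id)
  dt[, list(N = .N), by = c("seq", "junction", "sample")]
}

# Merge per-sample derep tables into a unique_seqs object (abundance order).
combine_derep_ <- function(parts, samples) {
  dt <- data.table::rbindlist(parts)
  tot <- dt[, list(total = sum(N)), by = c("seq", "junction")]
  data.table::setorder(tot, -total, seq)
  counts <- matrix(0L, nrow(tot), length(samples),
                   dimnames = list(NULL, samples))
  ri <- match(paste(dt$seq, dt$junction), paste(tot$seq, tot$junction))
  ci <- match(dt$sample, samples)
  counts[cbind(ri, ci)] <- dt$N
  structure(list(seq = tot$seq, junction = tot$junction,
                 total = tot$total, counts = counts),
            class = "unique_seqs")
}

# map_reads_to_centroids for an already-dereplicated unique_seqs object.
map_uniques_to_table_ <- function(uniq, clusters, threshold, marker,
                                  band = 16L, kmer = 10L, screen_from = 8L) {
  cent <- clusters$centroids
  cj <- ifelse(is.na(cent$junction), 0L, as.integer(cent$junction))
  qj <- ifelse(is.na(uniq$junction), 0L, as.integer(uniq$junction))
  res <- .map_to_centroids_cpp(uniq$seq, qj, cent$seq, cj, threshold,
                               as.integer(band), as.integer(kmer),
                               as.integer(screen_from))
  k <- nrow(cent)
  counts <- matrix(0L, k, ncol(uniq$counts),
                   dimnames = list(cent$otu_id, colnames(uniq$counts)))
  hit <- res$centroid
  for (c_idx in seq_len(k)) {
    rows <- which(hit == c_idx)
    if (length(rows) > 0)
      counts[c_idx, ] <- as.integer(colSums(uniq$counts[rows, , drop = FALSE]))
  }
  otu_table(counts, centroids = setNames(cent$seq, cent$otu_id),
            junctions = setNames(cent$junction, cent$otu_id),
            marker = marker,
            unassigned = colSums(uniq$counts[hit == 0, , drop = FALSE]))
}

#' Run the full two-marker gradient study on synthetic data
#'
#' The end-to-end driver: simulates linked 16S/18S reference databases,
#' communities and reads, runs the OTU pipeline for both markers, and
#' computes the study's statistics -- PCoA of the Spearman dissimilarities
#' with the PC1-salinity correlation, the Mantel test between the two
#' markers' dissimilarity matrices, rarefied alpha-diversity, and the
#' chloroplast/18S linking analysis with its label-shuffling p-value.
#'
#' @param seed integer seed governing every random stage.
#' @param sim16,sim18 [sim_config]s for the two markers.
#' @param cutoffs classification [cutoff_scheme].
#' @param nperm permutations for the PC1-salinity and Mantel tests.
#' @param alpha_reps subsampling repetitions for alpha-diversity.
#' @param link_shuffles shuffles for the linking p-value.
#' @param min_rho extraction threshold for cross-marker OTU pairs.
#' @param verbose print stage progress.
#' @return A list bundling both per-marker pipeline results (`pipeline16`,
#'   `pipeline18`), `metadata`, `beta` (dissimilarities, ordinations,
#'   gradient correlations, Mantel), `alpha` (per-marker tables), `linking`
#'   (pair list, match counts, p-value) and `links_truth`.
#' @export
run_gradient_study <- function(seed, sim16 = sim_config("16S"),
                               sim18 = sim_config("18S"),
                               cutoffs = default_cutoffs(),
                               nperm = 999, alpha_reps = 100,
                               link_shuffles = 1e5, min_rho = 0.8,
                               verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  with_seed_(seed, {
    say("simulating 18S reference and community")
    refdb18 <- simulate_reference_taxonomy(sim18)
    comm18 <- simulate_gradient_communities(refdb18, sim18)
    say("simulating linked 16S community")
    refdb16 <- simulate_reference_taxonomy(sim16)
    linked <- simulate_linked_marker_communities(comm18, refdb16, sim16,
                                                 refdb18)
    say("running 16S pipeline")
    res16 <- run_pipeline(list(marker = "16S", sim = sim16,
                               reference = linked$refdb16,
                               community = linked$community16,
                               cutoffs = cutoffs), verbose = verbose)
    say("running 18S pipeline")
    res18 <- run_pipeline(list(marker = "18S", sim = sim18,
                               reference = refdb18, community = comm18,
                               cutoffs = cutoffs), verbose = verbose)
    meta <- comm18$metadata

    say("beta-diversity")
    d16 <- spearman_dissimilarity(relative_abundance(res16$otu_table))
    d18 <- spearman_dissimilarity(relative_abundance(res18$otu_table))
    ord16 <- pcoa_ordination(d16)
    ord18 <- pcoa_ordination(d18)
    grad16 <- correlate_axis_with_gradient(ord16, meta, nperm = nperm)
    grad18 <- correlate_axis_with_gradient(ord18, meta, nperm = nperm)
    mant <- mantel_test(d16, d18, nperm = nperm)

    say("alpha-diversity")
    alpha16 <- alpha_diversity_table(res16$otu_table, reps = alpha_reps)
    alpha18 <- alpha_diversity_table(res18$otu_table, reps = alpha_reps)

    say("cross-marker linking")
    pairs <- correlate_tables(res16$otu_table, res18$otu_table,
                              min_rho = min_rho)
    matches <- count_class_matches(pairs)
    link_p <- if (matches$m > 0 && matches$k > 0)
      permutation_pvalue(pairs, matches$k, n_shuffles = link_shuffles)
    else NA_real_

    list(pipeline16 = res16, pipeline18 = res18, metadata = meta,
         beta = list(d16 = d16, d18 = d18, ordination16 = ord16,
                     ordination18 = ord18, gradient16 = grad16,
                     gradient18 = grad18, mantel = mant),
         alpha = list(alpha16 = alpha16, alpha18 = alpha18),
         linking = list(pairs = pairs, matches = matches, p = link_p),
         links_truth = linked$links,
         params = list(seed = seed, nperm = nperm, alpha_reps = alpha_reps,
                       link_shuffles = link_shuffles, min_rho = min_rho))
  })
}
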