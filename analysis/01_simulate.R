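#!/usr/bin/env Rscript
# Stage 1: simulate the study's raw material -- linked 16S/18S reference
# databases, gradient-structured communities over 21 stations (salinity
# 2-30), and paired reads -- and write them to results/simulated/ in the
# standard formats (FASTA + taxonomy TSV, metadata TSV, per-sample FASTQ).
#
# Everything downstream (02-06) can equally run from run_gradient_study();
# this stage exists so each step of the workflow can be inspected on disk.

library(halocline)

seed <- 1
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(seed)

# the on-disk artefact is kept modest (5000 pairs/sample); the full-scale
# 5e4 pairs/sample runs happen in memory in stages 02-06
sim16 <- sim_config("16S", reads_per_sample = 5000L)
sim18 <- sim_config("18S", reads_per_sample = 5000L)

refdb18 <- simulate_reference_taxonomy(sim18)
comm18 <- simulate_gradient_communities(refdb18, sim18)
refdb16 <- simulate_reference_taxonomy(sim16)
linked <- simulate_linked_marker_communities(comm18, refdb16, sim16, refdb18)

export_reference_db(refdb18, file.path(out, "ref18.fasta"),
                    file.path(out, "ref18.tax.tsv"))
export_reference_db(linked$refdb16, file.path(out, "ref16.fasta"),
                    file.path(out, "ref16.tax.tsv"))
write.table(comm18$metadata, file.path(out, "metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(linked$links, file.path(out, "links_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("simulated references: ", length(refdb16$ids), " (16S), ",
        length(refdb18$ids), " (18S); ", nrow(linked$links),
        " plastid-linked taxa")

# reads are large; write one station per file pair, per marker
for (cfg in list(list(sim = sim16, comm = linked$community16,
                      db = linked$refdb16, tag = "16S"),
                 list(sim = sim18, comm = comm18,
                      db = refdb18, tag = "18S"))) {
  for (s in cfg$comm$metadata$sample_id) {
    rd <- simulate_paired_reads(cfg$comm, cfg$db, cfg$sim, stations = s)
    write_fastq(rd$fwd, file.path(out, sprintf("%s_%s_R1.fastq", cfg$tag, s)))
    write_fastq(rd$rev, file.path(out, sprintf("%s_%s_R2.fastq", cfg$tag, s)))
  }
  message(cfg$tag, ": wrote ", nrow(cfg$comm$metadata), " stations x ",
          cfg$sim$reads_per_sample, " read pairs")
}
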