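# halocline

Paired-end amplicon OTU inference and diversity trends along salinity
gradients.

## What this is for

Brackish seas sit on steep salinity gradients that structure both bacterial
and eukaryotic plankton. Metabarcoding surveys of such systems sequence 16S
(V3–V4) and 18S (V4–V5) rRNA amplicons from the same stations and ask three
questions: does community composition turn over with salinity
(beta-diversity), does within-sample diversity dip in the critical 5–8
salinity band, the *horohalinicum* (alpha-diversity), and can the
plastid-encoded 16S signal of phytoplankton be tied to its nuclear 18S
counterpart? `halocline` implements the full analysis chain for such
surveys as a tested R package:

- **Read preparation** — IUPAC primer trimming, fixed 3′-tail and
  quality-threshold truncation, exact overlap merging (with the
  300 bp / >3 mismatches / <100 bp overlap rejection rules) or
  concatenation for amplicons whose mates cannot overlap.
- **Two-pass OTU construction** — a stringent Q25 pass builds centroids by
  greedy first-fit clustering at 99% identity; a lenient Q20 pass maps
  reads onto them, so few artefactual OTUs are founded while most reads
  are still counted. Identity is matches over columns of a semi-global
  alignment in which the shorter sequence aligns end to end.
- **Paired consensus taxonomy** — concatenated centroids are split at the
  junction, both halves aligned to a reference with an 8-rank (PR2-style)
  taxonomy, alignments under 250/210 columns dropped; candidates hit by
  both halves are bounded by rank-specific identity cutoffs
  (90% kingdom–family, 97% genus, 99% species), filtered to within 95% of
  the best summed bit-score, and the deepest agreed rank is assigned.
- **Cutoff calibration** — hold out reference entries, excise artificial
  read pairs at the primer coordinates, scan a cutoff grid per rank, and
  report precision and sensitivity.
- **Gradient statistics** — Spearman-correlation dissimilarity (`1 − ρ`),
  PCoA, PC1–salinity correlation with a permutation p-value, average-link
  dendrograms, Mantel tests, seeded rarefaction (richness and
  Shannon–Wiener), per-phylum rarefaction with a 1000-read rule, and the
  horohalinicum Wilcoxon contrast with FDR correction.
- **Cross-marker linking** — all-vs-all 16S×18S Spearman correlation,
  extraction of pairs at ρ ≥ 0.8, class-level agreement counts among
  chloroplast pairs, and a label-shuffling test (`p = n/N`) with an exact
  enumeration oracle.
- **Synthetic data** — a generator for rank-structured reference
  databases with controlled per-rank divergence, gradient-structured
  communities with plastid linkage, and Phred-modelled paired reads, so
  the whole pipeline runs end to end without any downloads.

The alignment kernels (semi-global identity, banded Smith–Waterman,
bit-parallel overlap merging) are implemented in C++ via Rcpp; a
two-marker study of 21 stations × 50,000 read pairs per sample runs in
about two and a half minutes on one core.

## Worked example

A reduced synthetic survey — 6 stations, 600 read pairs per sample — from
simulation to classified OTU table:

```r
library(halocline)

cfg <- sim_config("18S", n_stations = 6L, reads_per_sample = 600L,
                  children = c(1, 1, 2, 2, 2, 2, 2, 2))
res <- run_pipeline(list(sim = cfg, seed = 42), verbose = TRUE)
#> simulating reference taxonomy
#> simulating gradient community and reads
#> prepared st_01: 594/600 centroid-pass, 594/600 mapping-pass pairs kept
#> ...
#> dereplicated: 801 centroid-pass / 1055 mapping-pass unique sequences
#> clustered into 64 OTUs at 99% identity
#> mapped reads: 3,575 assigned, 0 unassigned
#> classified: 64/64 OTUs at depth >= 1

res$otu_table
#> otu_table (18S): 64 OTUs x 6 samples, 3,575 reads assigned
head(res$assignments[, c("otu_id", "genus", "species", "depth", "reason")], 3)
#>   otu_id            genus            species depth reason
#> 1  OTU_1 ge_1.1.2.1.2.2.1 sp_1.1.2.1.2.2.1.2     8   none
#> 2  OTU_2 ge_1.1.1.2.1.2.1 sp_1.1.1.2.1.2.1.2     8   none
#> 3  OTU_3 ge_1.1.1.1.2.1.1 sp_1.1.1.1.2.1.1.1     8   none
```

Every read maps back and every one of the 64 simulated taxa becomes an OTU
assigned its full species-level lineage — the reads are drawn from the same
reference the classifier searches, so this run is the package's own
positive control. The full study — both markers, beta/alpha-diversity and
linking — is one call:

```r
study <- run_gradient_study(seed = 1)
abs(study$beta$gradient16$rho)  # |Spearman rho| between PC1 and salinity, 16S
#> [1] 0.9974026
study$beta$mantel$rho           # coupling of the two markers' beta-diversity
#> [1] 0.993718
```

The sign of the PC1 correlation is arbitrary (ordination axes have no
inherent direction); its magnitude near 1 is the planted gradient being
recovered.

The numbered scripts under `analysis/` run the same stages as an inspectable
workflow (simulate → OTU pipeline → calibration → beta-diversity →
alpha-diversity → linking), each writing its tables under `results/`.

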