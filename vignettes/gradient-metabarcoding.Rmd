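---
title: "Amplicon metabarcoding along a salinity gradient: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplicon metabarcoding along a salinity gradient: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`halocline` reimplements, as tested and reusable code, the analysis chain of
a two-marker (bacterial 16S V3-V4, eukaryotic 18S V4-V5) amplicon survey of
plankton communities along a strong environmental gradient: paired-read
processing, two-pass OTU construction at 99% identity, a paired consensus
taxonomy classifier with calibrated rank-specific identity cutoffs,
gradient beta/alpha-diversity statistics, and a label-shuffling test that
links plastid 16S OTUs to their nuclear 18S counterparts.  Because the
original raw reads and reference snapshots are external resources, the
package ships a first-class synthetic-data module that generates the
statistical structure the analysis assumes, so every stage can be exercised
end to end and checked against ground truth.

This vignette records the models, the parameters that matter, the numerical
choices, and the limits of what the synthetic experiments demonstrate.

## Read preparation

Reads carry per-base Sanger Phred+33 qualities.  Preparation is a fixed
chain: 5'-anchored primer removal under IUPAC degeneracy (0 mismatches
beyond degeneracy by default, configurable -- the protocol gives no
allowance); a fixed 3' trim of the reverse mate (40 bases for 16S, 44 for
18S, whose reverse reads are noisier); and quality truncation at the first
base below a threshold.  "Cut at the first failing base" is the only
deterministic rule that guarantees every remaining base meets the
threshold, which is the property the downstream identity threshold relies
on.

Two preparation profiles are produced from the same raw reads:

* a **centroid pass** at Q >= 25, feeding OTU clustering (stringent, so
  sequencing noise founds as few spurious OTUs as possible), and
* a **mapping pass** at Q >= 20, feeding read-to-centroid counting
  (lenient, so as many reads as possible are assigned).

For the 16S geometry the mates overlap and are merged: every overlap offset
is scored exactly (bit-parallel mismatch counting), the offset maximising
matching bases is chosen, and the pair is rejected if the best overlap is
shorter than 100 bases, carries more than 3 mismatches, or yields a merged
sequence shorter than 300 bases -- each rejection tagged with its reason so
the three rules are separately auditable.  Within the overlap the
higher-quality base wins and the merged quality is the maximum of the two
(the protocol is silent here; this is common practice).  The search space
includes overlaps below the minimum so that a pair whose true overlap is,
say, 95 bases is rejected for its overlap -- not misattributed to
mismatches at some wrong offset.

For the 18S geometry the amplicon is longer than the mates can span, so
trimmed pairs are concatenated: forward read plus reverse-complemented
reverse read, with the junction index recorded.  Whether the original
protocol reverse-complemented before joining is not documented; this
package does, the choice is isolated in `concatenate_pairs()`, and the
junction makes the decision recoverable downstream.

## Sequence identity

All clustering and mapping decisions rest on one identity definition:
matching columns divided by total alignment columns of an optimal
semi-global alignment in which the shorter sequence aligns end to end and
terminal gaps are free only on the longer one (match +1, mismatch -1, gap
-2; gaps heavier than mismatches, as in the standard identity-clustering
tools).  Freeing the longer sequence's ends means reads shortened by
quality trimming are not penalised against longer centroids; requiring the
shorter sequence to align fully means two unrelated sequences cannot score
a perfect micro-overlap and report identity 1 -- a failure mode of fully
end-free scoring that the package's brute-force clustering oracle exposed
during development.

A banded variant (default half-width 16, widened by the length difference)
is used on the pipeline's substitution-dominated reads; the full matrix is
the reference behaviour and the band is validated against it in the tests.

## OTU construction

Centroid-pass sequences are dereplicated exactly (counts conserved, sorted
by total abundance, ties broken lexicographically) and clustered greedily
at 99% identity: scanning in abundance order, a sequence joins the *first*
centroid at or above the threshold, else founds a new OTU.  First-fit in
abundance order -- rather than best-fit -- is the documented behaviour of
the classic greedy centroid clusterers and is deterministic given the
input order.  Clustering happens once per marker across all samples
jointly, so one OTU table results.

Mapping-pass reads are then assigned to the centroid of *maximal* identity
when that identity reaches the threshold (ties toward the earlier, more
abundant centroid), else counted as unassigned; assigned plus unassigned
reads equal the input count per sample, an invariant the tests assert.
For concatenated amplicons the mapping identity is pooled over the two
halves using both junctions: the lenient pass trims less, so its junction
sits elsewhere than the centroid's, and a full-concatenation alignment
would charge that offset as internal gaps and unassign everything.
Clustering itself compares full concatenations -- all centroid-pass
sequences share one trim geometry, so no such offset arises there.

A k-mer prescreen (10-mers, active from 8 centroids) limits which
centroids are aligned.  The screen's bound is conservative for the
threshold in use -- a sequence within the identity threshold of a centroid
cannot lose enough shared k-mers to be screened out -- and below the
activation count every centroid is aligned, which the oracle-equivalence
tests rely on.

## Consensus taxonomy

Concatenated centroids are split at the junction and each half is aligned
locally (Smith-Waterman; match +1, mismatch -2, gap -2.5 per column, both
strands, seeded diagonal banding) against every reference sequence.
Alignments shorter than 250 (forward half) / 210 (reverse half) columns --
about 90% of the trimmed read lengths -- are discarded.  Bit-scores are
`(lambda * raw - ln K) / ln 2` with lambda = 1.28, K = 0.46; only ratios to
the best score matter downstream, so these constants are configurable and
non-critical.

Assignment then proceeds on references hit by **both** halves:

1. per candidate, the paired identity is the *minimum* of the two halves'
   identities -- the conservative reading of "both identities exceed the
   cutoff" (the mean is the obvious alternative; the choice is isolated in
   one function);
2. the deepest rank whose cutoff that identity meets bounds the candidate
   ("meets" is inclusive, `>=`: the published cutoffs are round percentages
   applied to discretised identities); candidates failing the kingdom-level
   cutoff are dropped;
3. a single surviving candidate donates its lineage, truncated to its
   bound;
4. with several, their forward+reverse bit-score sums are compared and only
   candidates within 95% of the best sum are retained; the lineage is the
   deepest rank at which all retained candidates agree, further truncated
   by the identity bound.

Merged (one-read) centroids use the same rules with the single hit identity
and bit-score.  Every assignment records why it stopped where it did
(`identity_cutoff`, `consensus_conflict`, `no_hits`, `length_filter`),
and manual curated overrides replace an automatic lineage only when their
reported coverage and identity both exceed 99%.

The default cutoffs are 90% for kingdom-family (levels 1-6), 97% at genus
and 99% at species, the scheme the calibration experiment below supports.

## Cutoff calibration

`make_holdout_testset()` removes a random sample of reference entries,
excises an error-free read pair from each at the primer-binding
coordinates, and `evaluate_cutoff_grid()` classifies them against the
remaining reference while scanning a range of identity cutoffs **at each
taxonomic level**: the row for rank r and cutoff c uses c at ranks r..8 and
the grid floor above.  This per-level scan keeps the candidate set fixed
along the scan, which makes sensitivity (fraction of reads assigned at the
rank) non-increasing in the cutoff *by construction*.  A scan that moved
all eight cutoffs together would not have this property: raising the
kingdom-level cutoff can drop a conflicting consensus candidate and
thereby *deepen* assignments -- a behaviour we observed and deliberately
designed out.

Definitions, recorded because the usual wording admits alternatives:
**sensitivity** at rank r = reads assigned at depth >= r over all test
reads; **precision** = the fraction of those whose rank-r name matches the
truth.  A rank-cutoff cell with no assignments reports precision `NA`
(undefined), deliberately distinct from 0.  `select_cutoffs()` picks, per
rank, the lowest cutoff whose precision meets a floor (lowest = maximal
sensitivity subject to the floor) and forces the scheme monotone
non-decreasing across ranks.

## The synthetic gradient study

The generator produces the structure the analysis assumes, each piece
checked by its own tests:

* **Reference taxonomy.**  An eight-rank tree grown from a random root;
  per-branch substitution probabilities are set by a Jukes-Cantor
  correction so that leaves first diverging at rank r show the configured
  identity (defaults, kingdom to species: 0.70, 0.76, 0.80, 0.84, 0.87,
  0.90, 0.92, 0.95), realised within one percentage point.  Primer sites
  are implanted at the amplicon ends and masked from mutation, and the
  masking is compensated in the rates so whole-sequence identities still
  hit the targets.  The species-level default of 95% leaves a clear margin
  on both sides of the 99% OTU threshold: distinct species do not
  co-cluster, and the 95%-of-best bit-score rule cleanly excludes a
  species sibling when the true reference is present.
* **Communities.**  Each taxon gets a lognormal baseline (sdlog 1), a
  niche optimum uniform over salinity 2-30 and a Gaussian tolerance
  uniform on 3-10 salinity units, over 21 evenly spaced stations --
  smooth compositional turnover, the signature the beta-diversity
  statistics detect.  Station-by-taxon lognormal patchiness noise (sdlog
  0.5 by default) is multiplied on top: without it the response curves
  are so clean that thousands of OTU pairs exceed a rank correlation of
  0.8 purely through shared niches, which would make the cross-marker
  matching test powerless.  Deterministic-response properties (monotone
  abundance ratios, flat wide-tolerance limits) are tested with the noise
  off.
* **Plastid linkage.**  A configurable fraction of eukaryotic taxa take
  over one 16S reference leaf each: its lineage is rewritten as a
  chloroplast lineage carrying the partner's class name, and its abundance
  becomes a fixed multiple of the partner's noisy profile -- so true
  chloroplast/18S pairs correlate perfectly before sequencing noise, while
  unlinked taxa decorrelate.  An option mislabels a chosen number of
  linked taxa at the class level to exercise the matching statistics.
* **Reads.**  Multinomial draws per station from abundances distorted by
  lognormal rRNA copy-number multipliers (sdlog 0.5; an optional
  "metazoan spike" multiplies a few taxa heavily), excised at the primer
  coordinates in a 2 x 300 nt geometry, and mutated per base at
  `10^(-Q/10)` under a position-dependent quality profile whose 3' decay
  makes the Q25/Q20 two-pass design meaningful (16S mates overlap by
  ~120 bases after trimming; 18S mates leave a gap, forcing
  concatenation).  The emitted Phred strings are consistent with the
  injected error rates by construction.

### Problem sizes

The end-to-end study runs 21 stations x 50,000 read pairs per sample and
marker over 128-taxon references -- about 2.1 million read pairs per run --
in roughly two and a half minutes on one core, with permutation tests at
999 permutations, alpha-diversity at 100 subsampling repetitions (1000 in
the standalone analysis scripts) and the label-shuffling test at 10^5
shuffles (the design value is 10^6; the p-values of interest here are
orders of magnitude from the decision boundary).  Unit and property tests
use references of 64-128 leaves and reads in the hundreds to thousands.

### What the synthetic experiments do and do not show

They show the machinery is correct: the classifier equals a brute-force
enumerator, clustering equals a first-fit oracle, rarefaction matches
hypergeometric expectations, the shuffling p-value matches exact
enumeration, and the full chain recovers a planted gradient
(|rho(PC1, salinity)| > 0.99 for both markers) and planted plastid links.
They do not show field performance: real communities are not Gaussian
niches on one axis, real references are phylogenetically uneven with
variable amplicon lengths and chimeras (chimera handling is deliberately
out of scope), and real error profiles include indels, which the
substitution-only error model omits -- though the alignment machinery
itself handles indels.

## Statistics

* **Beta-diversity** is `1 - rho` over per-sample OTU frequency vectors
  (Spearman, ties mid-ranked), range [0, 2]; the constant offset does not
  change the ordering of samples along principal coordinates.  PCoA is
  classical scaling (double-centred `-D^2/2`), axes with positive
  eigenvalues kept, variance explained relative to the positive spectrum,
  and each axis oriented so its first nonzero coordinate is positive -- a
  deterministic sign convention.  Hierarchical clustering is
  average-linkage by default (the linkage is exposed), exported as newick.
* **Permutation p-values** for the PC1-salinity correlation and the Mantel
  test use the add-one rule `(exceedances + 1) / (nperm + 1)`, so p is
  never zero; the axis test is two-sided on |rho|, the Mantel test
  one-sided.  The label-shuffling test reports the plain ratio `n / N`,
  following its published definition.
* **Alpha-diversity** subsamples without replacement (multivariate
  hypergeometric, drawn by sequential binomial conditioning, vectorised
  over repetitions), reporting means and SDs of observed richness and of
  the Shannon-Wiener index in natural log (the convention of the standard
  ecology toolkit).  Per-phylum rarefaction (phylum = lineage level 3,
  class = level 4) drops samples with fewer than 1000 reads of the phylum
  and subsamples the rest to their common minimum.  The horohalinicum
  contrast (salinity 5-8, bounds inclusive) is a two-sided exact Wilcoxon
  rank-sum per phylum and metric with Benjamini-Hochberg correction across
  phyla within a metric; fully tied groups report p = 1 directly rather
  than an undefined statistic.
* **Cross-marker linking** correlates all 16S against all 18S OTU relative
  abundances, extracts pairs at rho >= 0.8, counts class-level agreement
  among chloroplast-flagged pairs (pairs lacking a class annotation on
  either side are dropped but counted), and shuffles the class labels over
  the correlated 18S OTUs -- annotated ones by default, each distinct OTU
  keeping one label per shuffle -- to estimate the chance probability of
  the observed agreement.  An exact enumeration over the label multiset
  serves as the oracle for populations of up to ten OTUs.

## Known limitations

Single-threaded by design (the run fits in minutes); no chimera detection,
no denoising, no demultiplexing, and one FASTQ dialect (Phred+33).  The
identity prescreen is conservative for thresholds near 1 but could prune
legitimate matches at thresholds far below the defaults combined with very
short sequences; below its activation count it is exact.  The classifier's
bit-score constants are fixed rather than fitted; only their ratio enters
any decision.
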