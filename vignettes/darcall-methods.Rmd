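---
title: "Methods: calling and characterising DHS-associated repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and characterising DHS-associated repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`darcall` tests whether repeat (transposable-element) subfamilies
contribute open chromatin beyond chance, and characterises the subfamilies
that do. This vignette documents the statistical model, the tunable
parameters, the synthetic-data generator used for validation, and the
design decisions taken where the methodology was genuinely open.

## The enrichment model

The unit of testing is the (repeat subfamily, DHS dataset) pair. DHS peaks
are reduced to fixed 200 bp windows centred on their midpoints (the
informative part of a hypersensitive site is its centre; a fixed width
removes peak-calling width artefacts). The observed statistic is the
number of **distinct** subfamily instances overlapping at least one
window by one or more bases.

Chance overlap depends strongly on where peaks sit relative to genes:
repeats are depleted near promoters while many peaks concentrate there. A
uniform-genome null would therefore be badly miscalibrated. Instead, every
region is assigned one of six gene-proximity categories — TSS (within
1 kb of a TSS), promoter (up to 5 kb upstream of a TSS, strand-aware),
intragenic, proximal (≤ 10 kb from a gene boundary), distal (≤ 100 kb) and
desert — with precedence in that order, distances measured from the
region midpoint. A random background of `n_random` regions (default
200,000) reproduces the peak set's category distribution exactly:
per-category counts come from largest-remainder apportionment, and every
sampled region is verified to re-annotate to its assigned category
(rejection sampling within category-eligible tiles laid at
`region_width/4` steps).

The expected count for a subfamily is the number of background overlap
*events* (region × instance pairs) scaled by
`n_peaks / n_random`. Events rather than distinct instances keep the
estimator linear in the background size: with 200,000 background regions
against a few tens of thousands of peaks, distinct-instance counting
saturates (nearly every instance of a common subfamily is hit at least
once) and deflates the expectation many-fold; event counting recovers
observed/expected ≈ 1 on null subfamilies, which we verify on synthetic
null studies.

The test is a one-sided binomial: trials = the subfamily's instance
count, success probability = expected fraction, p-value = P(X ≥ observed)
computed via `pbinom(..., log.p = TRUE)` so that values far below
double-precision underflow stay exact (the strongest real enrichments
reach 10^-1000 and below). This parameterisation (instances as trials)
matches how results are naturally reported — fractions of a subfamily's
instances open — and is the one that reproduces published worked examples.
Pairs with p < `alpha` (default 1e-5) are DHS-associated repeats (DARs);
Benjamini–Hochberg q-values are reported per dataset as an extra column
but do not drive the calls, keeping the fixed cutoff comparable across
datasets of different sizes.

Expected counts are kept real-valued (no rounding), and each dataset's
background is seeded by the master seed combined with a hash of the
dataset identifier, so runs are reproducible dataset-by-dataset.

## Downstream characterisations

**Age.** Subfamily age uses the mean per-mil divergence of instances from
their consensus (milliDiv): p = milliDiv/1000, Jukes–Cantor distance
d = −(3/4)·ln(1 − 4p/3), age = d / rate with rate 2.2e-9
substitutions/site/year. The divergence from the ancestral consensus
accrues on a single lineage, so age = d/rate (15% divergence ≈ 76 Myr);
subfamilies younger than 95 Myr are classified primate-specific. The mean
is taken over all instances; no divergence filtering is applied.

**Mappability.** Short reads cannot always be placed uniquely inside
young repeats, deflating observed counts. The simulation samples reads
uniformly from the genome (both strands), calls a read uniquely mapped iff
its sequence occurs at exactly one genomic position under the mismatch
budget (reverse-complement occurrences count), and reports per subfamily
the unique fraction among reads wholly contained in its instances. Full
containment (rather than any overlap) is deliberate: reads straddling a
repeat boundary carry unique flanking sequence and would mask the
repeat's own ambiguity. Matching uses exact string search (a `PDict`
fast path at zero mismatches); read lengths 36 and 20 with budgets 2 and 1
mirror the two common production read lengths. Ratios are estimates with
binomial sampling error; the read count is recorded alongside.

**Specificity.** Observed open-instance counts are normalised by each
dataset's peak count, and each (subfamily, dataset) value is divided by
the median normalised count across datasets of the same lab group —
medians are computed separately per lab group because read length (and
hence mappability) differs systematically between them. The focal dataset
is included in its own group median; with ≥ 7 datasets per group the
difference from exclusion is negligible and inclusion keeps the statistic
well-defined for small groups. Folds above 3 on a DAR flag a cell-type
specific DAR.

**TF and motif association.** ChIP co-occurrence is a hypergeometric
upper-tail test on the subfamily's instances: universe = instances,
successes = ChIP-bound instances, draw = DHS-contributing instances,
observed = both (cutoff p < 0.001). Instance flags use the same
200 bp-window any-overlap rule as DAR calling. The PWM scanner scores
log-odds in bits against a 0-order background on a discretised grid (bin
1e-3 bits) and computes exact p-values by position-wise convolution of the
score distribution on the same grid, so scan thresholds and p-values are
mutually consistent and match exhaustive word enumeration for short
motifs. `N` bases contribute zero log-odds. The five classifier features
per (motif, subfamily) pair are: fraction of instances with a hit;
fraction of genome-wide hits inside the subfamily; bound/unbound best-hit
score ratio; a binomial enrichment of the subfamily hit count against the
genome-wide per-position hit rate (log10 p); and the observed hit count
against first-order-Markov resamples of the instance sequences
(composition-preserving null for motif-generation potential, regularised
as (obs+½)/(sim+½)). The last two realise deliberately configurable
choices — the enrichment test's exact form and the shuffle model are not
standardised anywhere, so both are parameters; the Markov resample
preserves expected dinucleotide composition rather than exact counts.
Features combine by a weighted rank average (ranks normalised to [0, 1],
ties sharing mean rank, missing features dropping out of a pair's weight
mass); weights default to equal because no trained weighting is published,
and the top decile by rank score is flagged. A motif supports a specific
DAR when present in > 25 instances and in > 20% of DHS-contributing
instances (strict inequalities).

**Expression.** A gene is up-regulated in a cell type when its z-score —
focal dataset value against mean/SD over datasets outside the cell type —
exceeds 2 in at least one focal dataset; zero outside-spread genes get no
call. Genes associate with a DAR when their body overlaps a 50 kb window
centred on any open instance midpoint; the window mirrors the package's
tag-density analysis so both expression routes use one proximity rule.
The significance of the up-regulated count among associated genes comes
from 10,000 permutation draws of equally many genes from the array
universe (without replacement within a draw), standardised by the
permutation mean and population SD (at 10,000 draws the n−1 correction is
irrelevant; the population form matches the closed-form hypergeometric
moments the draw converges to). The tag-density variant segments the
genome into non-overlapping 50 kb windows, computes per-dataset densities,
calls windows up-regulated by the same z > 2 rule and permutes background
windows instead of gene names.

**Auxiliary enrichments.** Chromatin-state assignment requires a state to
cover strictly more than half the region (a 50/50 tie assigns nothing);
raising the threshold can only withdraw an assignment, never switch it.
The 15 raw states map to 7 combined states through a required
configuration mapping. Conservation: instances overlapping a conserved
non-exonic element are "conserved"; the open set is tested against the
all-instance fraction with the same one-sided binomial kernel as DAR
calling. dsQTL enrichment is hypergeometric over DHS clusters (each dsQTL
assigned to at most one cluster — largest overlap, ties leftmost); both
the upper tail and the point probability are reported, because legacy
analyses of this design have published the point mass as "the
hypergeometric p" and the two differ several-fold at typical counts.

## The synthetic-study generator

Validation needs data where the truth is known. `generate_study()` builds
a complete study from one seed: a first-order Markov background genome
(GC 41%, mild autocorrelation), 40 subfamilies of 100–500 non-overlapping
instances (150–450 bp) created by mutating per-subfamily consensus
sequences at per-instance milliDiv rates; 600 genes; 12 DHS datasets
spanning 8 tissue groups and both lab groups (7 + 5), each with ~500
peaks over the 2 × 5 Mb genome — that peak density yields a ~2.5%
background instance-hit rate, matching the expected fractions seen in
real studies of this design. Open-chromatin enrichment is planted by
directing `round(fold × expected_hits)` peaks onto randomly chosen
instances of the target subfamily in the target cell type (defaults: folds
10, 8, 6 and 5 into four subfamilies); ChIP peaks land on a configurable
fraction of the active instances; motif consensus sequences are written
into a fraction of planted subfamilies' instances (both strands);
expression of genes within 50 kb of active instances is shifted by 3
noise-SD units in the matching cell type; CNEEs and dsQTLs are placed
preferentially on active instances/clusters at configurable rates.

The generator emulates the *structure* of such a study, not its noise
processes: peaks are placed directly (no read-level noise or peak-caller
behaviour), instances do not overlap, divergence is uniform along an
instance, and the genome has no large-scale composition domains. Passing
recovery tests therefore demonstrates that the statistics are calibrated
and sensitive under the design assumptions — not that every real-data
artefact (copy-number variation, blacklist regions, GC-coverage bias) is
handled.

Desk-scale problem sizes were fixed once: the default study above for the
end-to-end recovery checks (a full run of generation, DAR calling at
n_random = 200,000 × 12 datasets, specificity, motif classification and
expression takes a few minutes on one CPU), a 12-subfamily 2 × 0.4 Mb
study for module tests, and a 50-subfamily × 6-dataset null study for
false-positive calibration. Mappability simulations in tests use toy
genomes where the exhaustive answer is computable.

## Numerical and degenerate-input conventions

* Coordinates: 1-based closed `GRanges` in memory, 0-based half-open in
  all files (UCSC convention), converted only at the I/O boundary.
* Midpoints use floor((start + end)/2) in 0-based coordinates; resized
  windows crossing a chromosome end are shifted back inside (clipped, not
  discarded).
* Clustering merges regions at gap strictly less than `max_gap`; overlap
  counts as gap 0; clustering is idempotent.
* Zero expected count with positive observed yields an infinite fold with
  a warning (1.0 when both are zero); zero permutation SD yields a signed
  infinite z with a warning; subfamilies with no sampled reads get an NA
  mappability ratio.
* p-values are carried as log10 throughout; "p < 1e-100" is printable
  exactly.
* All randomness flows from explicit integer seeds; per-dataset and
  per-stage seeds are derived from the master seed with a deterministic
  string hash, and seeded code restores the caller's RNG state.

## Known limitations

* Genome-scale published totals (fractions of all DHS in TEs, counts of
  DARs across 75 datasets) require the original consortium inputs and are
  out of scope; the package validates against worked examples with
  printed inputs and against planted synthetic truth instead.
* Cross-species projection (lineage assignment by alignment chains) is
  not implemented; `lineage_partition()` consumes caller-provided labels.
* The motif classifier's feature weights are configuration, not learned;
  ranking quality on real data depends on the supplied weights.
* The annotation-matched background matches gene proximity only — not GC,
  chromosome balance or mappability of the sampled regions.
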