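---
title: "Methods: caste-differential H3K4me1 and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: caste-differential H3K4me1 and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casteChIP)
```

## The analysis

Honey bee queens and workers develop from genetically identical female
larvae; their divergence is driven by differential gene regulation, and
histone marks such as H3K4me1 (a chromatin mark of primed and active
enhancers) are candidates for carrying that regulatory difference.
casteChIP implements the desk-scale statistical core of a
caste-comparison study that profiles H3K4me1 by ChIP-seq and expression
by RNA-seq in both castes, with three biological replicates per caste,
and verifies selected genes by qPCR.

The package deliberately starts downstream of alignment and peak
calling: its inputs are per-replicate peak calls (BED), gene models
(GFF3), a gene-by-sample count table (TSV), optional per-base signal
(bedGraph), and a qPCR Ct table (TSV). Everything upstream (read QC,
alignment, peak calling, motif discovery) is out of scope.

## Peak comparison

**Consensus and presence.** All replicate intervals from both castes are
merged wherever they overlap by at least 1 bp (book-ended intervals stay
separate), and a replicate is *present* on a consensus interval when at
least one of its peaks overlaps it by 1 bp or more. Presence is
deliberately binary and strict — it operationalizes "detected" without a
minimum-overlap fraction, which keeps the rule faithful to how
replicate-consistent peak lists are described in this field.

**Unique peaks.** A consensus peak is unique to a caste when it is
present in *all* replicates of that caste and in *no* replicate of the
other. With three replicates this is a 64-row truth table, and the test
suite checks all of it.

**Differential peaks.** Peaks that are not caste-unique are tested for a
fold-change difference: per-replicate signal (summed read counts over
the consensus interval) is library-normalized (each replicate's total
peak signal scaled to the median library), and Welch's two-sided t-test
is applied to `log2(signal + 1)`. A peak is differential when `p < 0.05`
and the linear fold change `(mean_A + 1)/(mean_B + 1)` exceeds 2 in
either direction. The underlying study names only the thresholds, not
the test; Welch-on-logs at n = 3 is simple, standard, and fully
self-contained. Raw p-values are used, matching the printed rule; this
is anti-conservative across hundreds of peaks and the output keeps the
p-values so users can re-threshold. Peaks with fewer than two detected
replicates in either caste are `unresolved`, never silently dropped, and
unique classification runs first, so a peak absent from one caste is
never also counted as differential.

**Annotation and distribution tests.** Each peak is assigned the feature
category of its midpoint — promoter, exon, intron, or intergenic, in
that precedence — with ties broken by nearest TSS and then gene id, so
the assignment is deterministic and order-independent. The promoter is
2000 bp upstream to 200 bp downstream of the TSS by default; no promoter
definition is universal, so both extents are arguments everywhere.
Caste differences in the category distribution are tested with Pearson's
chi-squared (no continuity correction) on the 2 x 3 table of promoter /
exon / intron counts; intergenic peaks are excluded because the three
gene-linked categories are reported as an exclusive split. Zero margins
raise an error naming the margin rather than producing NaN statistics.

## Differential expression

The NB model `Var = mu + alpha * mu^2` is used throughout.
Normalization is median-of-ratios: `factor_j = median_g(count_gj /
geomean_g)` over genes with no zero counts. Dispersion is estimated per
gene by within-group moments pooled across the two castes, floored at
1e-8 — and then *moderated*: the per-gene estimate (2(n-1) df at n
replicates) is shrunk toward the across-gene median with a prior weight
of 20 pseudo-df. The Wald statistic `z = log2FC / SE` (delta-method SE
of the log2 group means) is referenced against a Student t distribution
with the combined degrees of freedom rather than a normal.

These two choices are deliberate and coupled. At n = 3 the raw moment
estimator is so noisy that a normal-reference Wald test rejects ~12% of
null genes at alpha = 0.05, while a t(4) reference fixes the level but
leaves effect genes with p-values too large for Benjamini-Hochberg to
find at 2000-gene scale. Moderation restores power and the matching t
reference restores the level: measured on simulated null data (2000
genes, 3 vs 3, alpha = 0.05 dispersion) the type-I fraction is ~0.05,
and planted 1.5-log2FC genes are recovered with sensitivity ~0.99 at
empirical FDR ~0.04 (both measured in the acceptance tests). Setting
`prior_df = 0` gives the unmoderated estimator for users who want it.

DEGs are genes with BH-adjusted p <= 0.05; no fold-change filter is
applied on top. FPKM is `count * 1e9 / (length * total)`. When a group
mean is zero, 0.5 per sample is added to both group means (flagged in
the output) so fold changes stay finite.

## Integration

Peaks link to at most one gene: promoter-window containment of the
midpoint wins, then gene-body containment, with nearest-TSS tie-breaks;
intergenic midpoints link nowhere. Genes linked to differential peaks
are DPGs; DEG/DPG overlaps are exact set intersections. The correlation
between chromatin and expression change is Spearman's rho between
per-gene peak log2FC and expression log2FC (both oriented caste A over
caste B, so positive rho means co-directional change), reported for all
linked genes and for the DEG-restricted subset, with the large-sample
t approximation for p. Over-representation of user-supplied gene sets
(GMT) is the upper-tail hypergeometric test with BH adjustment across
sets; the universe defaults to all annotated genes and is configurable,
since the universe choice dominates ORA results. TSS metaprofiles
average per-base coverage in 50-bp bins over +/-2 kb around every TSS,
strand-flipped so negative offsets are always upstream; bins crossing a
chromosome edge are dropped for that gene only.

## qPCR

Relative expression uses the 2^-ddCt method: technical replicates are
averaged per (sample, gene); `dCt = Ct_target - Ct_reference`;
`ddCt` subtracts the control-group mean dCt; `RQ = 2^-ddCt`. Group
comparison is Welch's t-test on the dCt scale — the approximately
normal scale — while fold changes are reported as RQ; a flag switches
the test to the RQ scale. The control group (which caste anchors the
baseline) is an explicit argument, since either orientation is
defensible.

## The synthetic-data generator

Every stage is testable against planted truth without downloads. The
generator emulates the structure of a two-caste, three-replicate larval
study on a single chromosome:

* **Genome.** 500 non-overlapping genes (2-10 kb, 2-6 exons, random
  strand) on a 5-Mb chromosome. A 2-Mb default cannot hold 500 genes of
  this length distribution, so 5 Mb is the package default; placement is
  a stick-breaking allocation of the intergenic space, which is
  deterministic per seed and fails with an explicit "genome too dense"
  error when the genes cannot fit.
* **Peaks.** 1-kb peaks with <=50 bp per-replicate jitter; midpoints at
  least 1200 bp apart so consensus merging can never fuse two planted
  peaks and planted classes stay mutually exclusive. 400 background
  peaks (both castes, equal NB means), 60 caste-unique peaks per caste
  (60% of worker-unique peaks in promoters, 60% of queen-unique peaks
  in introns, mirroring the 4th-instar contrast this design emulates),
  and 80 differential peaks (NB means split symmetrically by a planted
  log2FC of magnitude 2 +/- 20%, signs split evenly; half in
  promoters). Promoter-planted peaks are centred within 150 bp of the
  TSS; aggregate read density within a peak is modelled as a triangular
  pile-up around the summit, so the TSS metaprofile genuinely peaks at
  the TSS. No public peak-width, concordance or depth conventions exist
  for this design; these defaults are the package's own and are echoed
  into the truth manifest.
* **Counts.** NB counts (dispersion 0.05) at mean 200 with a lognormal
  gene-level spread (sd 0.5 on log2); 100 planted DE genes at
  +/-1.5 log2FC. Genes owning planted promoter differential peaks
  instead receive an expression effect correlated with the peak's
  planted log2FC.
* **Correlation planting.** The peak-expression correlation is planted
  through a latent Gaussian copula on the peak fold changes' normal
  scores. NB measurement noise at n = 3 attenuates the *measured*
  Spearman correlation well below the latent one, so the generator
  inverts an empirically fitted response curve (measured rho ~=
  0.659 r + 0.230 r^2 at the reference depths, fitted by simulation
  with 500 linked genes) and scales analytically for configurations
  with different noise. The attainable measured correlation ceiling at
  the default depths is ~0.88; a target of 0.9 therefore reads ~0.88,
  which the acceptance band accounts for. The realized latent
  correlation is recorded in the truth manifest.
* **qPCR.** `Ct = baseline - log2(relative expression) + N(0, 0.2)`,
  with a constant-mean reference gene (GAPDH), so the noiseless case
  inverts exactly through the 2^-ddCt arithmetic.

What the generator does *not* emulate: read-level artifacts
(mappability, GC bias), multi-chromosome genomes, overlapping genes,
chromatin-state autocorrelation along the genome, and peak-caller
idiosyncrasies. Passing tests therefore demonstrate the correctness and
calibration of the statistical rules on data satisfying the model's
assumptions, not robustness to upstream artifacts in real data.

## Numerical choices and degenerate inputs

* Canonical coordinates are 0-based half-open everywhere inside the
  package; GFF3's 1-based closed convention is converted only in the
  readers and writers.
* A zero-width promoter request returns a minimal 1-base window at the
  TSS rather than erroring, keeping window-size sweeps total.
* Welch tests on constant data resolve by comparing means (p = 1 when
  equal, 0 otherwise) instead of erroring.
* Pseudo-counts: +1 on normalized peak signal (fold change and logs);
  0.5 per sample on normalized expression means only when a group mean
  is zero (flagged).
* BH adjustment preserves input order and passes NAs through.
* Dispersion floor 1e-8; zero-variance genes sit at the floor.
* All simulator stages draw from seeds derived deterministically from
  the master seed, and all writers format numbers independently of the
  session locale, so a seeded run is byte-reproducible.

## Problem sizes in the test suite

The unit and acceptance tests run the generator at reduced sizes chosen
to keep each statistical check well-powered while the whole suite stays
interactive: 120-gene genomes for round trips, 2000 genes x 3 vs 3 for
null-calibration and recovery checks (10 seeds), 500 linked genes x 20
seeds for correlation calibration, 2000 draws for type-I rates of the
chi-squared test, and ten full pipeline runs at the default study
conditions for end-to-end recovery and determinism.

## Known limitations

* The differential-peak test uses raw p-values by design; treat the
  differential peak *count* as threshold-dependent.
* The moment-moderated dispersion has no mean-dispersion trend; data
  with a strong trend would be better served by trend-aware shrinkage.
* One peak links to one gene; distal enhancer-promoter pairing (e.g.,
  loop-based assignment) is out of scope.
* The Spearman p-value is a large-sample approximation; at n < 10 it is
  indicative only.
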