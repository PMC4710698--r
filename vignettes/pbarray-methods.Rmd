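---
title: "Methods: cross-species microarray analysis of metal-responsive expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species microarray analysis of metal-responsive expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The experimental design this package analyzes

Cross-species hybridization (CSH) studies measure the transcriptome of a
non-model species — here a lead-tolerant pseudometallophyte — by hybridizing
its RNA to arrays designed for a sensitive model relative. Because coding
sequences between such Brassicaceae relatives share only about 89% nucleotide
identity, a fraction of probes fails outright for the non-model species: both
conditions sit at the array's background floor. The analysis therefore has to
(i) remove scale differences between arrays, (ii) discard probes that never
rose above background, (iii) call differential expression within each species
and tissue, and (iv) use the sensitive species' response as a *filter*: its
reaction to the metal is taken as the standard plant response, and the
interesting candidates are the genes where the tolerant species responds when
the sensitive one does not (metal-*specific*), or responds with a clearly
different magnitude (metal-*common* but divergent).

The design is fixed at two species (`tolerant`, `sensitive`), two tissues
(`roots`, `shoots`), control vs. Pb-treated, with independent biological
replicates (three by default, matching the underlying hydroponic experiments).

## Normalization and differential expression

**Between-array normalization.** The default is *upper-quartile scaling*:
each array is multiplied by a constant so that its 75th-percentile intensity
equals the geometric mean of all arrays' 75th percentiles. We read
"quartile normalization" as this Agilent-standard percentile-shift rather
than full quantile normalization, because upper-quartile scaling is a pure
rescaling — it preserves within-array ratios exactly and is idempotent —
whereas forcing identical distributions is a far stronger transform than
a variance-minimizing chip correction requires. Full quantile normalization
remains available (`normalization_mode: "quantile"`, via limma) as a
sensitivity check. Percentiles use linear interpolation between order
statistics (`quantile()` type 7); on continuous intensities ties do not
arise, so the convention is innocuous but concrete and testable.

**Per-probe median centering.** Each probe is divided by its median across
*all* samples. Because one constant divides every sample of a probe, neither
fold changes (ratios of condition means) nor log-scale t-statistics change;
the step only places probes on a common scale for display and clustering.
The test suite asserts this invariance explicitly.

**Log transform.** Base 2, the microarray convention, used only as the scale
of the t-test; reported fold changes are always linear, and qPCR concordance
uses log10 (see below). Base 10 is available via `log_base`.

**Background retention.** A probe enters the analysis of a species × tissue
contrast only if there *exists* a condition (control or treated) in which
*all* replicates exceed the configured background intensity. A gene silenced
by treatment still qualifies through its control replicates; a probe that
fails to hybridize at all — the CSH dropout case — qualifies through
neither and is removed. The filter is applied to between-array-normalized
linear intensities, so an array's overall scale cannot push its probes over
the floor. The background is a single configured intensity (the synthetic
generator's floor by default); negative-control-derived backgrounds are out
of scope.

**Testing.** A classical pooled-variance two-sided Student t-test on the
log2 values, with the t-distribution ("asymptotic") p-value, followed by
Benjamini–Hochberg adjustment across all genes tested in the contrast. A
gene is *regulated* when its BH-adjusted q-value is below `fdr_threshold`
(default 0.1). The raw p < 0.05 level is recorded as `p_threshold` and
exposed for sensitivity analyses, but is not applied as a second filter by
default: we read the two published thresholds as the pre-adjustment test
level and the post-adjustment FDR call of a single procedure, not as two
stacked filters. Both knobs are configuration keys, so the other reading
costs one line. Zero within-group variance with unequal means yields p = 0
and a `degenerate` flag; with equal means, p = 1.

**Probe→gene collapse.** When several probes map to one gene, the probe with
the largest mean intensity across all samples represents the gene — the
brightest probe is the least likely to be degraded by cross-species sequence
divergence. Most users of gene-level 44k designs see ~1.6 probes per gene;
the synthetic generator defaults to one probe per gene.

## The candidate-selection cascade

Within a tissue, the regulated genes of the two species are compared on the
*shared* gene universe — the genes surviving background filtering in both
species. A gene untested in one species can be neither specific nor common;
it is excluded, because calling it "specific" would conflate biology with
hybridization failure. `venn_partition()` errors on mismatched universes
rather than silently guessing.

- **Specific genes** (regulated in the tolerant species only) pass if their
  fold change FC > 2.0 or FC < 0.5 — strict inequalities, so a gene at
  exactly 2.0 is discarded.
- **Common genes** (regulated in both) must first show a divergent
  magnitude: FC_tolerant / FC_sensitive > 2.0 or < 0.5, on linear fold
  changes and regardless of direction agreement (a gene up 3-fold in the
  tolerant species and down to 0.4 in the sensitive one has ratio 7.5 and
  passes — the published procedure states no direction handling, and a
  discordant response is exactly the kind of divergence the filter seeks).
  Survivors then pass the same twofold filter on the tolerant species' FC.
- Candidates are the union; counts are conserved at every stage
  (input = retained + discarded), and up/down candidate counts add to the
  candidate total because the specific and common sets are disjoint by
  construction of the Venn partition.

Common genes carry a sign category (`++`, `--`, `+-`, `-+`), first sign the
tolerant species. The published figure legend defines these categories as a
*species* comparison within a tissue; an adjacent paragraph of prose instead
sketches a roots/shoots reading. The legend definition is implemented — it
is the one consistent with a per-tissue Venn diagram. Relatedly, the
published text reports 331 shoot-specific retained genes while its own
selection table sums to 192 + 138 = 330; the package reports the sum (330,
hence 356 shoot candidates), and this discrepancy is simply documented
rather than reproduced.

## Functional-class enrichment

Candidate lists are scored against a gene→class annotation in which a gene
may carry several classes (MapMan-style bins). For a class \(c\),

\[
\mathrm{NF}_c \;=\; \frac{n_{c,\mathrm{input}} / n_{\mathrm{classified\ input}}}
                        {n_{c,\mathrm{ref}} / n_{\mathrm{classified\ ref}}}
\]

— the class's share of the classified input list over its share of the
classified reference (all classified genes on the array by default;
overridable). Unclassified genes drop out of both denominators. NF = 1 means
composition identical to the reference.

Stability is quantified by the bootstrap: the input list is resampled with
replacement at its original size B = 100 times (configurable), NF recomputed
per resample with duplicated genes counting multiply in numerator and
denominator, and the *standard deviation of the B resampled scores* reported
as the bootstrap SE of the class score — the usual bootstrap SE of a
statistic, not sd/√B, which would estimate the precision of the bootstrap
mean instead.

Significance is a two-sided hypergeometric (Fisher exact) test of the class
count in the classified input against the classified reference, at
α = 0.05. The upstream classification tool publishes no formula for its
significance, so the hypergeometric test is this package's documented
choice, and the published legend's "significant class (p > 0.05)" is treated
as a typo for p < 0.05. Classes with fewer than 5 input genes are flagged
(`o`) as too small to interpret; significant classes are starred (`*`). No
multiple-testing correction is applied across classes by default (raw class
scores are the convention for this statistic); `bh = TRUE` enables it.

## qRT-PCR concordance

Validation panels are compared as the Pearson correlation of log10 fold
changes between array and qPCR, pooling roots and shoots into a single
correlation (the published validation plots both tissues on one regression);
per-tissue correlations are reported alongside. Pairs missing a fold change
in either assay are dropped with a message. The reported \(r^2\) is the
squared correlation. Reproducing a specific published \(r^2\) requires that
study's supplementary fold-change table, which is external data; the package
verifies the statistic against a closed-form Pearson oracle and exact
special cases instead.

## The synthetic-data generator

`simulate_experiment()` exists so that every downstream stage is exercisable
with no downloads, under conditions that mirror the motivating design:

- **Baseline expression** is log-normal: per-gene log2 mean drawn from
  N(10, 1.5²), i.e. median intensity ≈ 1000 on an array whose background
  floor defaults to 50 — a typical dynamic range for one-color intensity
  data.
- **Planted regulation**: `n_up`/`n_down` genes per species × tissue
  (default 100 + 100) have their treated mean multiplied by `fc_planted`
  (default 4) or its reciprocal *on the linear scale, before noise*, so the
  pre-noise treated/control ratio equals the planted fold change exactly.
  Half of each planted set (`shared_fraction = 0.5`) is shared between the
  species with the same direction, so the Venn partition has non-trivial
  specific and common sectors.
- **Noise**: replicate noise is log-normal with sd 0.25 on the log2 scale —
  moderate biological-replicate scatter under which a 4-fold effect with
  three replicates is clearly but not trivially detectable; per-array scale
  jitter (log2 sd 0.1) is what the between-array normalization must remove.
- **Dropout**: a fraction (default 0.2) of probes is silenced for the
  tolerant species — both conditions drawn uniformly in (0, background] —
  as a per-probe Bernoulli surrogate for CSH sequence divergence at ~89%
  identity. Dropped probes are never planted as regulated, and the
  background-retention rule removes them by construction.
- **Annotation**: one probe per gene by default; functional classes drawn
  from a 10-label list with 15% multi-membership and 10% unclassified genes.
- All randomness flows through the single `seed`; a fixed configuration is
  byte-identical on re-run, down to the serialized TSVs.

What the generator does *not* emulate: probe-sequence effects and partial
(graded) hybridization loss, correlated gene modules, intensity-dependent
variance, dye or spatial artifacts, and outlier arrays. Passing the
validation suite therefore shows the pipeline's statistics are correct and
calibrated under a clean log-normal model — not that real CSH data meet
those assumptions.

## Validation conditions and numerical choices

The package's own validation (test suite and `scripts/acceptance.R`) uses:
null calibration on 50 simulated experiments of 1,000 genes (raw-p < 0.05
fraction compared to 0.05 within three Monte-Carlo standard errors, the SE
taken across runs so that within-run correlation is respected); recovery of
planted regulation over 10 simulated experiments of 1,000 genes with 50 + 50
planted genes per tissue at fold change 4 and noise sd 0.25 (recovery
through q < 0.1 plus the twofold filter, with the observed false-discovery
proportion); bootstrap convergence at B = 10,000 on a 50-gene input;
and brute-force oracles for the BH step-up, the two-sided hypergeometric
p-value (exhaustive pmf summation for reference sizes up to 60), the normed
frequency, upper-quartile equalization (75th percentiles equal to 1e-9), and
the textbook Pearson formula (agreement to 1e-12). These sizes are the
package's chosen validation conditions: large enough that the stochastic
checks are stable across seeds, small enough to run routinely.

Numerical conventions: strict inequalities at every fold-change threshold;
quantile type 7 percentiles; fold changes computed from linear condition
means of normalized intensities; p = 0 with a flag for degenerate
zero-variance contrasts; empty candidate lists propagate as empty tables,
never errors.

## Known limitations

- The recovery guarantee applies to the DE-plus-fold-change stage. The
  cross-species ratio filter *deliberately* discards genes whose planted
  response is shared with equal magnitude between species (ratio ≈ 1), so
  end-to-end "recovery of all planted genes" is not a meaningful target for
  the full cascade — the cascade's job is to remove exactly those genes.
- Upper-quartile scaling corrects a global per-array factor only;
  intensity-dependent (loess-type) bias is out of scope.
- The background value is a single dataset-wide intensity, not a
  per-probe negative-control estimate.
- Real annotation databases are not shipped; the enrichment module consumes
  any user-supplied gene→class table.
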