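---
title: "Methods: analysing error-corrected sequencing mutation data with ecstox"
author: "ecstox authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing error-corrected sequencing mutation data with ecstox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the data
model, the statistics, the numerical choices, and the points where the
design was genuinely open. The companion README shows a worked example;
here the emphasis is on *why* each piece works the way it does and what
the bundled tests do and do not establish.

## The record model

Error-corrected sequencing (ECS) pipelines emit either per-site records
(a row for every sequenced position, variant or not) or variant-only
calls plus separate depth summaries. `ecstox` normalizes both into one
record table inside a `MutationSet`:

* Coordinates are 1-based inclusive `start` with half-open `end`
  (`end = start + nchar(ref)` for sequence-resolved alleles). Importers
  shift declared 0-based input. BED region files are likewise converted
  on read.
* Alleles are parsed case-insensitively and stored uppercase. Insertions
  and deletions are expected in left-aligned, anchor-base (VCF) form;
  length changes that are not anchored that way are classified `complex`
  rather than re-normalized, because re-normalization against the
  reference is a variant-calling concern, not an analysis one.
* Categorization is a total function over (REF, ALT): `no_variant`
  (ALT absent, `"."`, or equal to REF), `snv`, `mnv` (equal lengths
  > 1), `insertion`/`deletion` (anchored extensions), `complex`
  (different lengths and compositions), `sv` (symbolic or breakend ALT),
  `ambiguous` (IUPAC codes in ALT), `uncategorized` (residual, e.g.
  non-ACGT REF). A property test drives randomized (REF, ALT) pairs
  through the classifier and asserts totality.
* The trinucleotide context is undefined at contig edges and wherever a
  flanking base is not A/C/G/T; no sequence is ever fabricated. Such
  SNVs keep their 6/12-base subtype but drop out of 96/192-channel
  tallies, and the affected counts are reported.
* VCF specifics: files must be single-sample; the sample identifier
  comes from the genotype column header first, then an INFO `sample`
  field, and a conflict between the two is an error rather than a silent
  preference. `total_depth` is the sum of the `AD` entries; multi-allelic
  rows split into one record per ALT sharing the site depth; `alt_depth`
  comes from `VD`. A variant row with no depth information at all is
  assumed to be supported by one read, following the tabular-dialect
  convention for variant-only files.
* Canonical sort order is (sample, contig, start, ref, alt); it decides
  which record "comes first" wherever that matters (depth
  deduplication).

## Filtering

`filterMut()` applies its rules in a fixed order — germline VAF, SNV in
germline MNV, custom column, region containment, depth adjustment — so
that the MNV rule can see the germline flags. Records are flagged, not
removed, because their `total_depth` still belongs in frequency
denominators; dropping them is an explicit option.

Choices worth noting:

* The germline VAF rule is strict (`vaf > cutoff`), so a record exactly
  at the cutoff is kept. The default cutoff 0.01 reflects deep panel
  data, where true heterozygous germline variants sit near VAF 0.5 and
  somatic mutations orders of magnitude lower.
* The SNV-in-germline-MNV rule uses the MNV's half-open span and applies
  within the same sample only.
* Region containment keeps 1-bp records whose start lies in a region;
  records spanning more than one base must start *and* end inside the
  same region. Boundary-straddling indels are removed, not clipped.
* Depth adjustment treats flagged non-germline reads as no-calls
  (`total_depth := total_depth − alt_depth`, `alt_depth := 0`);
  germline records keep their depths. Import sanitizes
  `alt_depth > total_depth` rows, so the subtraction cannot go negative
  in practice; a defensive clamp-and-warn remains.

## Min/Max counting and subtype frequencies

The same mutation observed in many reads of one sample is either one
clonally expanded event (Min) or many independent events (Max); the two
frequencies bracket the truth. `calculateMF()` always reports both:
`sum_min` counts records once, `sum_max` sums `alt_depth`.

Depth handling is where most subtlety lives:

* At a site with several variant records in one sample, only the first
  record (canonical order) contributes `total_depth` to depth sums —
  otherwise multi-allelic sites would double-count coverage.
* At subtype resolutions the denominator is the depth of sites where the
  subtype can occur: C:G sites for C-reference subtypes at 6-base
  resolution (2 classes), the reference base at 12-base (4), the
  pyrimidine-strand trinucleotide at 96-base (32 classes), the stranded
  trinucleotide at 192-base (64). These class counts follow directly
  from the 6 × 16 = 96 channel algebra.
* Depth classes are computed from reference base content alone,
  independent of which variants happen to be called — an indel's anchor
  base neither adds nor removes subtype-specific depth.
* Precalculated depth tables must match the requested grouping ×
  resolution exactly (a `context_class` column at subtype resolutions);
  mismatches are errors, never broadcasts. Zero-depth groups report
  undefined (NA) frequencies, never 0.
* Non-SNV mutations are tallied under their variation type alongside the
  SNV subtype rows, so a "spectrum" at any resolution partitions all
  counted mutations, and proportions sum to 1 per group.

Normalized proportions divide each subtype's frequency by the sum of
subtype frequencies in the group; when no depth exists, raw proportions
divide counts by the group total. With equal class depths the two
definitions coincide exactly, which the tests assert.

Counting is validated against an independent brute-force counter
(nested loops, no shared code) on 1000-record fixtures over ten random
groupings and four resolutions, exactly.

## Dose-effect modelling

Mutation counts out of sequenced bases are binomial under three
admittedly idealized assumptions: finitely many trials, equal per-base
mutation probability, independence. `fitMFModel()` fits a logit-link
GLM; since MF is ~1e-7, `logit(mu) ≈ log(mu)` and exponentiated
contrasts are rate ratios. Overdispersion is measured by the Pearson
statistic `phi = X²/(n − p)`; `phi > 1` switches inference to
quasibinomial (the coefficient estimates are identical, standard errors
scale by `sqrt(phi)`). With random effects a binomial GLMM (random
intercepts, Laplace approximation, lme4) is used, with no extra
dispersion scaling. Note that for genuinely binomial data the estimated
`phi` lands on either side of 1 with roughly equal probability, so the
selected family is data-driven by construction; what is stable is the
rule, and that is what the tests pin down.

Contrasts are supplied as vectors (or built by `contrastsVsControl()`);
`estimateContrast()` returns `theta = c'beta`, the fold change
`exp(theta)` with delta-method SE `exp(theta)·se(theta)`, Wald tests (t
with residual df for GLMs, z for GLMMs — the reference distribution is a
design choice, stated here because it is not forced by the model), and
Šidák-adjusted p-values `1 − (1 − p)^m` across the supplied family of
comparisons.

Constant fixed-effect factors (a single level) are dropped to the
intercept rather than erroring, so saturated means on homogeneous data
remain estimable.

## Benchmark dose

`bmdModelAverage()` fits four standard continuous dose-response families
to log-transformed individual responses with normal errors (the error SD
profiled out of the likelihood):

* exponential `y = a(c − (c−1)e^{−bx^d})`
* Hill `y = a(1 + (c−1)x^d/(b^d + x^d))`
* inverse exponential `y = a(1 + (c−1)e^{−bx^{−d}})`
* log-normal `y = a(1 + (c−1)Φ(d·log(x/b)))`

All are parameterized with `a > 0` (control response), `c ≥ 1` (maximum
fold change, so fitted curves are monotone non-decreasing), `b > 0`
(dose scale) and `d > 0` (shape), via unconstrained log transforms
optimized with Nelder–Mead from three data-driven starts (control mean,
top/bottom fold, dose-range-scaled `b`). The BMD solves
`f(BMD) = a(1 + BMR)` in closed form per family (verified against
bracketed root finding), `NA` with a reason when the fitted curve never
reaches the target (e.g. flat data). An SD-mode BMR
(`f(BMD) = a·e^{sd0}`, one control SD on the log scale) is also
available.

Model averaging is by parametric bootstrap: Akaike weights
`w ∝ exp(−ΔAIC/2)` from the full-data fits; each replicate draws a
generating family with probability `w`, simulates log-scale residuals at
that family's fitted SD, refits all four families (warm-started from the
full-data parameters, which stabilizes and speeds the bootstrap),
recomputes replicate weights, draws a family from them, and records its
BMD. The reported BMD is the median of draws; BMDL/BMDU are the 5th and
95th percentiles (a 90% interval). Everything is reproducible from one
seed; more than 20% failed replicates triggers a warning.

The recovery tests use an exponential truth (`a=1, b=1, c=3, d=1`,
analytic BMD50 `log(4/3)`). Two problem sizes appear: 50 observations
per dose group for point recovery — at 50 observations *in total* the
estimator's sampling dispersion is itself on the order of 20% relative,
so no point bound near 15% is meaningful there — and 50 total for
interval coverage, where the 90% bootstrap interval is asserted to cover
the truth in at least 80% of 20 replicates.

## Spectra comparison and clustering

`spectraComparison()` takes an R × 2 table of Min-based counts (Min so
that the counted events are independent), drops zero-margin rows,
computes `G² = 2 ΣΣ Y log(Y/E)` with the `0·log(0)` = 0 convention, and
refers it to chi-square on `(R−1)(T−1)` df — unless `N/(R−1) < 20`, in
which case `G²/df` is referred to `F(df, N − df)` (floor 1 on the
denominator df; the denominator choice is isolated in one place so it
can be re-pinned if a different small-sample convention is preferred).
The chi-square path is cross-checked against the deviance of the Poisson
log-linear independence model on 100 random tables.

`clusterSpectra()` is `dist()` + `hclust()` with Euclidean distance and
Ward's method in the `ward.D2` (squared-Euclidean) convention, followed
by `orderLeaves()`: at every internal node the subtree with the smaller
minimum merge height is placed first, with leaves treated as infinitely
high, ties keeping input order. Only the leaf permutation changes;
topology, heights and hence cophenetic distances are untouched.

## Signature refitting

`buildTrinucleotideMatrix()` sums defined-context SNVs (Min counting)
into the 96 canonical channels. `refitSignatures()` solves the
non-negative least-squares problem `min ‖obs − C·x‖, x ≥ 0` and then
prunes backwards: repeatedly drop the active signature whose removal
costs the least reconstruction cosine, refitting after each drop, while
the cost stays below 0.01 cosine per step. The threshold trades sparsity
against fidelity; 0.01 is small relative to the 0.9 robustness bar
reported with every fit. Exposures scale linearly with the observed
profile and the cosine is scale-free (both asserted).

The test catalog is synthetic (clearly labelled as such): each signature
concentrates most of its mass on a few dominant channels of one
substitution class over a low background, the shape real SBS signatures
have. The concentration is a deliberate design point: with 1000
multinomially sampled mutations, reconstruction cosine is limited by
sampling noise, and a flat catalog could not exceed 0.99 no matter how
exact the refit; the peaked catalog both resembles real signatures and
keeps the recovery bounds meaningful (measured on the bundled seeds:
minimum cosine 0.993, maximum exposure error 0.036 over 20 draws).

## The synthetic-data generator

`simulateDataset()` emulates the structure of a panel-style ECS study:
by default twenty 2.4 kb random-sequence targets at 10,000× fixed
per-site depth, mutations drawn binomially at each sample's design MF
with contexts drawn from a planted 96-channel spectrum (placed on
matching reference sites, reverse-complemented as needed), germline SNVs
and 3-bp MNVs at Beta(100, 100) VAF (centered on 0.5, concentrated
enough to exercise the 0.01 cutoff realistically), sub-clonal SNVs
planted inside germline MNV spans at VAF 0.005, labelled artifact rows,
clonal multiplets with a stated `alt_depth` at randomly chosen
mutations, and off-target records in a margin trimmed from the region
ends. Output is emitted as per-site tabular records and as variant-only
single-sample VCFs plus a depth table, and the two dialects import
identically (asserted). A single seeded stream drives everything; the
truth record carries the seed and every planted quantity, and downstream
tests read expectations only from it.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: sequencing depth is constant rather than
variable and positionally biased; mutations are independent across sites
and samples (no hotspots, no shared clonal lineages beyond single-site
multiplets); germline variants are unlinked; the reference is random
sequence, so context composition is near-uniform rather than
genome-like; and no read-level artifacts exist for the consensus caller
upstream to have missed. Results on real ECS data depend on an upstream
pipeline the package intentionally does not model.

## Problem sizes and runtime choices

Test fixtures are sized so the whole suite runs comfortably on one CPU:
classification/import fixtures of a few hundred to a few thousand
records; oracle-equivalence fixtures of 1000 records; GLM recovery at 10
samples/group with 5 × 10⁷ bases each; 200-replicate CI coverage; BMD
recovery with 200-replicate bootstraps and 20-replicate coverage; the
acceptance script simulates the full 24-sample, 48 kb, 10,000× study
(~1.1 million records) end to end. Optimizer tolerances (Nelder–Mead,
`reltol 1e-12`, three starts; warm starts inside the bootstrap) were
chosen so that noiseless self-consistency checks recover generating
parameters to four significant digits.

## Known limitations

* No upstream processing: alignment, consensus calling, variant calling
  and variant re-normalization are out of scope; inputs are trusted to
  be left-aligned and anchored.
* No dbSNP or population-database germline lookup; germline flagging is
  VAF-based only.
* Covariate support in the BMD module is limited to what the four-family
  parametric bootstrap supports; no quantal endpoints and no Bayesian
  averaging.
* Spectra comparison is defined for two groups; multi-group comparisons
  must be decomposed into pairs (with Šidák adjustment available for the
  family).
* The GLMM path reports Wald z statistics; small-sample refinements
  (Kenward–Roger-style corrections) are not implemented.
* Signature refitting assigns a fixed catalog; it does not extract
  de-novo signatures and does not model 192-channel or indel signatures.
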