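---
title: "Methods: clonality concordance and CNV-based tissue-of-origin inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality concordance and CNV-based tissue-of-origin inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrace)
```

# Overview

`clonotrace` implements two linked analyses for synchronous multifocal
tumors:

1. **Clonality concordance** — decide whether several lesions descend from
   one ancestral cell population by counting exactly matched somatic events
   between them, and order the lesions along a putative metastatic route.
2. **Tissue of origin** — assign a cancer-type label to lesions by
   comparing their whole-genome copy-number profile with cancer-type CNV
   signatures learned from a labelled multi-cancer cohort.

This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate. Every empirical statement here is computed by
the package's test suite or by `scripts/acceptance.R`; nothing is quoted
from external runs.

# Somatic call filtering

Candidate somatic calls are filtered per candidate, independently, by a
`filter_policy()`:

| parameter | default | meaning |
|---|---|---|
| `min_coverage` | 100 reads | calls with *less* coverage are excluded (boundary kept) |
| `min_alt_reads` | 5 reads | calls with *fewer* supporting reads are excluded |
| `exclude_dbsnp` | `TRUE` | drop catalogued germline polymorphisms |
| `exclude_germline` | `TRUE` | drop calls present in the patient's blood DNA |
| `low_af_cutoff` | 0.05 | threshold for the low-allele-frequency summary (strict `<`) |
| `cnv_log2_threshold` | 0.7 | gene CNV gain iff log2 ratio `> 0.7`, loss iff `< -0.7`, strict |

Two conventions are deliberately config-exposed rather than hard-coded.
First, whether the supporting-read rule counts variant-supporting reads or
total reads is ambiguous in common phrasing ("fewer than five reads"); the
default is variant-supporting reads (`support_reads = "alt"`), the reading
under which the rule adds information beyond the coverage rule, with
`"total"` available. Second, coverage summaries default to the sample
standard deviation (n−1 divisor), the common default in statistical
software, with the population convention available
(`sd_type = "population"`); published per-lesion summary tables rarely say
which was used, so neither is treated as ground truth.

There is no rescue of low-support calls that happen to be shared across
lesions: each lesion's evidence stands alone, which keeps the shared-event
counts conservative.

# Shared-event concordance

Matching is deliberately exact:

* **Mutations** match on gene + chromosome + position; by default the
  ref/alt alleles must also match (`match_alleles = TRUE`). Allele-blind
  matching (gene + coordinate only) is available because published
  shared-mutation counts are sometimes derived that way, but it can merge
  distinct substitutions at one site, so strict matching is the default.
* **Chromosome-level CNVs** match only on *identical* intervals — equal
  chromosome, start and end. An off-by-one end does not match. This is a
  very conservative overlap rule; a reciprocal-overlap mode
  (`min_reciprocal`) exists but is off by default because identical-interval
  matching is the convention the shipped published fixtures were counted
  under.
* **Gene-level CNVs** match on gene + direction.

`venn_counts()` reports per-lesion totals, all pairwise intersections, the
all-lesion intersection and the explicit union; for three lesions the
inclusion–exclusion identity is asserted internally. When only published
Venn counts are available (the underlying tables not being deposited),
`union_from_venn()` / `run_clonality(venn_tabulated = ...)` evaluate the
identity directly.

**Relatedness and route.** The pairwise relatedness score is the unweighted
count of matched events (weights are config-exposed, but the default
follows the qualitative argument from counts). The route heuristic assumes
that cells acquire alterations as they disseminate: the lesion with the
smallest total event burden (mutations + CNV intervals + gene CNVs) is
taken as sampling the ancestral population, and remaining lesions are
chained by descending relatedness to the current chain tail. Ties are
broken lexicographically by lesion id and flagged; an all-zero score matrix
is flagged `unresolved`. For a two-branch patient the within-branch order
is genuinely underdetermined by sister-lesion data; only the origin and the
branch membership are treated as recoverable truth in the tests.

# Region matrix construction

Segmented copy-number profiles (SEG dialect: sample, chromosome, 1-based
inclusive start/end, log2 segment value) are aligned by collecting, per
chromosome, the union of all samples' segment boundaries and emitting the
maximal disjoint intervals between consecutive breakpoints covered by at
least one sample (`GenomicRanges::disjoin` provides the partition).
Consequences, each tested against a per-base brute-force oracle on random
genomes ≤ 10 kb:

* every region is covered all-or-none by any segment, so the matrix fill is
  exact, and a partially covering segment is an internal-consistency error;
* total region length equals the union of segment footprints;
* boundaries are cohort-order invariant, and adding a sample refines but
  never coarsens them.

Two conventions are config-exposed: uncovered (region, sample) entries are
filled with 0 (log2-neutral — segment absence is read as "no detected
deviation", the natural reading for tumor profiles where neutral genome is
simply not segmented), and regions covered by *no* sample are not emitted
(footprint-union semantics; `emit_gaps = TRUE` with a genome emits them).
Values are the supplied segment means; no re-centering or integer-copy
conversion is applied (allele-specific integerization belongs upstream).

New lesions are *projected* onto an existing cohort region set
(`project_segments()`): each value is the coverage-weighted mean of the
lesion's segments over the region with fill for uncovered bases. Projection
reduces to the exact fill when segmentations align. Patient lesions never
contribute cohort breakpoints and never enter signature selection — the
model is frozen before the patient is scored.

# Signature selection

Each region is scored for association between its per-sample value and the
cancer-type label. The default scorer fits, per class, a one-vs-rest
binomial logistic regression of class membership on the region value and
computes a likelihood-ratio p-value against the intercept-only model. The
region-level p-value is the smallest per-class p-value with a Bonferroni
correction for the number of *distinct* one-vs-rest splits (for two
classes both splits are the same test, so the correction factor is 1; for
K ≥ 3 it is K). An uncorrected minimum is anti-conservative by up to a
factor K under the null; with the correction the fraction of null regions
with p < α concentrates at α, which the acceptance suite checks within 3σ
binomial bounds and a KS uniformity test. A one-way ANOVA F-test
(`method = "anova"`) is offered as a single-test alternative scorer.

Numerical choices:

* degenerate (constant-value) regions score p = 1 by convention and are
  flagged;
* perfectly or quasi-separated fits — routine for strong signatures, where
  the logistic MLE diverges — fall back to a Firth-penalized fit, with the
  penalized likelihood-ratio statistic, and are flagged. The internal IRLS
  fit is validated against `stats::glm` in the tests; it exists because a
  cohort-scale matrix requires tens of thousands of fits per selection
  pass and the Firth fallback is not part of base R;
* p-values are floored at 1e-320 to remain strictly positive;
* selection is strict: a region is selected iff p < α, default
  α = 1e-12, the conventional cutoff for this analysis at consortium scale.

One interaction deserves emphasis: the likelihood-ratio statistic is
bounded above by the null deviance, roughly 2·n·H(class proportions), so
the smallest achievable p-value is set by the cohort size. At the default
cohort size (120 samples) a clean signature region reaches p ≈ 1e-28 and
the 1e-12 cutoff is comfortable; a 30-sample cohort cannot reach 1e-12 at
all and must use a cutoff scaled to its size (the unit tests do exactly
this for their miniature cohorts).

# Discriminant classification

The classifier is a Gaussian discriminant with per-class means over the
selected regions and a single pooled per-feature variance floored at
ε = 1e-6 (diagonal covariance). The diagonal form is forced by the
geometry of the problem: signature selection routinely returns far more
regions than there are samples, where the full pooled covariance is
singular. A full-covariance mode is available and refuses to run when
features ≥ samples. Priors default to empirical class frequencies
(`"uniform"` and custom vectors available). Scores are
log prior + Σ per-feature Gaussian log-density; exact ties are broken by
class label order and flagged. On one feature and two classes the decision
boundary agrees with the closed-form LDA threshold to 1e-9 (acceptance
suite) and with `MASS::lda` predictions (unit tests).

**Accuracy protocol.** Published per-class accuracies for this kind of
model rarely state whether they are resubstitution or cross-validated.
The default here is stratified 5-fold cross-validation with signature
selection re-run *inside every training fold*, so no information from
held-out samples leaks into selection; resubstitution is available
(`mode = "resubstitution"`) and both can be reported side by side, clearly
labelled. Fold assignment is seeded and reproducible; a seed is mandatory.

# Synthetic cohorts and patients

The generator stands in for consortium training data and patient event
tables that are not publicly redistributable at usable resolution. Study
conditions are pinned in the defaults:

* **Cohort** (`cohort_spec()`): 3 classes (labelled with TCGA-style study
  codes CHOL / LIHC / PAAD) × 40 samples — a deliberate scale-down of the
  595-sample three-cancer setting this kind of model is built on, sized so
  the full pipeline (including ten-seed recovery runs and 5-fold CV with
  in-fold selection) completes in minutes on one CPU; an 8 × 10 Mb
  chromosome genome; 30 planted signature regions per class (disjoint
  across classes, fixed sign, mean |log2| shift 0.8 over Gaussian noise
  sd 0.1); 15 passenger segments per sample, 10% of which are inflated past
  the ±0.7 calling threshold. Region counts come out in the thousands,
  preserving the regions ≫ samples geometry of the real analysis at ~3% of
  its region count.
* **Patient** (`patient_spec()`): 3 lesions (pancreas, biliary duct,
  omentum), origin class PAAD; 29 truncal mutations, 1 truncal CNV
  interval, 5 truncal gene CNVs shared by all lesions; a biliary+omentum
  branch sharing 17 further mutations, 6 CNV intervals and 2 gene CNVs;
  private counts (34/38/42 mutations; 83/178/138 CNV intervals) chosen so
  the per-lesion totals match the published three-lesion case the
  concordance defaults mirror, with the pancreas lesion carrying the
  fewest alterations. Five artifact calls per lesion (dbSNP/germline
  flagged or low-coverage) exercise the filter. Allele frequencies are
  drawn from Beta(1, 20) clamped to ≥ 0.01, putting ~64% of calls below
  0.05 — deep-sequenced tumor tissue shows 60–76% — with read depth
  ~N(450, 150²) floored at 120 and supporting reads binomial in depth and
  AF. Truncal CNV intervals are drawn from the origin class's signature
  regions, so the patient is classifiable against the cohort.

Determinism: one seed per spec; per-sample sub-seeds derived from it make
generation reproducible and order-independent. Mutation coordinates are
drawn without replacement genome-wide and intervals are rejection-sampled
against overlap, so planted events never collide — the regime in which
recovery of the planted route and Venn bookkeeping can be asserted exactly.

**What the generator does not emulate** (and what passing tests therefore
do not show about real data): realistic CNV length and recurrence
distributions (passenger placement is uniform with rejection), focal
vs arm-level structure, sex-chromosome ploidy, tumor purity and subclonal
allele-frequency structure, trinucleotide mutational signatures, and
cross-class correlation of copy-number changes. Recovery results on
synthetic cohorts are a *verification* of the pipeline's statistics, not a
*validation* of classification accuracy on real tumors.

# Problem sizes and seeds used by the checks

The acceptance checks run the study-scale defaults: ten cohorts
(seeds 1–10) for selection recovery; 2 000 dense null regions × 120
shuffled labels for calibration; 100 random ≤ 10 kb genomes for the
per-base oracle; one default cohort for 5-fold CV; one default patient for
origin and route recovery. These sizes are the package's chosen study
conditions; they keep a full run in the minutes range while leaving the
features ≫ samples geometry intact.

# Known limitations

* The route heuristic is a greedy chain over an unweighted event-count
  score; it is not a phylogeny. Formal tree inference (parsimony or
  likelihood over lesion genotypes) is out of scope, as are calendar-time
  estimates of metastasis.
* Identical-interval CNV matching is brittle to segmentation jitter
  between platforms; the reciprocal-overlap mode exists for that case but
  changes the meaning of the counts.
* The one-vs-rest logistic scorer treats regions independently; correlated
  neighbouring regions yield correlated signatures, and the signature
  count should not be read as a count of independent loci.
* Genome builds are treated as opaque metadata; no liftover is attempted,
  so cohort and lesions must share a build.
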