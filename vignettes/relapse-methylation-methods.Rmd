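---
title: "Longitudinal methylation analysis of serially relapsing tumors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal methylation analysis of serially relapsing tumors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrelapse)
library(dplyr)
```

`methrelapse` analyzes CpG-level bisulfite methylation counts collected
longitudinally from patients whose tumors relapse repeatedly: a matched
normal tissue, the primary tumor at diagnosis, every resected relapse, and
(optionally) patient-derived orthotopic xenografts (PDOX) grown from those
samples. The setting it models is pediatric ependymoma, where the two major
molecular subtypes — supratentorial RELA-fusion tumors (referenced against
normal cerebrum) and posterior fossa group A tumors (referenced against
normal cerebellum) — relapse serially over many years, and where the
epigenome rather than the mutational landscape carries most of the
progression signal. Everything below applies equally to any cohort with the
same sample structure.

## The analysis model

**Differential methylation per site.** At each CpG covered by at least 5
reads in both the tumor and its matched normal (the canonical coverage
filter; inclusive), the methylated/unmethylated read counts form a 2x2
table. `call_dmcs()` tests it with a two-sided Fisher exact test, adjusts
p-values by Benjamini-Hochberg *within* the tumor-vs-normal comparison
(each comparison is an independent screen), and labels the site Hyper when
the tumor-minus-normal ratio difference is at least +0.2 with q <= 0.05,
Hypo symmetrically, and NoChange otherwise. The Fisher test replaces the
model-based caller used in the original RRBS processing with a transparent
criterion whose two-sided p is exact hypergeometric enumeration; equivalence
with any specific external caller is not claimed. The 0.2 default is
deliberately below the 0.3 cross-patient consistency filter so the stricter
published filter stays binding. Sites failing coverage in either sample are
not tested — there is no imputation. The test is implemented as a chunked,
vectorized enumeration (`fisher_p_2x2()`) so that the roughly 2.5 million
site tests of a full cohort take seconds; `stats::fisher.test()` is used as
the independent oracle in the test suite, never as the implementation.

**Trajectories.** For each patient, every timepoint (primary first, then
relapses in order) is compared against the *same* matched normal, and the
per-site direction sequence is classified (`classify_trajectory()`):

* **ConsistentHyper / ConsistentHypo** — the same polar state at every
  timepoint;
* **GainHyper / GainHypo** — a NoChange prefix then an all-polar suffix
  (one clean acquisition);
* **LossHyper / LossHypo** — a polar prefix then a NoChange suffix;
* **Switch** — anything else touching a polar state;
* **ExcludedPolaritySwitch** — any adjacent Hyper<->Hypo flip; such sites
  are rare biologically and are excluded from downstream discovery, but are
  tallied so the exclusion rate is visible;
* sites that are NoChange throughout are not DMCs and do not enter category
  fractions; sites below coverage at any timepoint are `Uncovered`.

Two genuinely open readings were settled as follows. *Gain* and *Loss* are
defined as single clean transitions (prefix/suffix form); any multi-toggle
or compound gain-then-loss pattern is Switch — the broadest reading of
"switch between a polar state and NoChange". And a patient lacking a primary
sample keeps its trajectory (earliest sample acts as timepoint 0, flagged
via `has_primary`), but is excluded from booster support because "absent in
the primary" cannot be certified.

**Discovery.** Three procedures, all per subtype and all deterministic:

* **Drivers** (`find_drivers()`): sites ConsistentX in *every* recurring
  patient, same polarity, then filtered to mean |delta| strictly greater
  than 0.3 across the supporting patients' tumor samples with uniform
  direction. The mean-over-samples reading (rather than per-sample) follows
  the usage for region-level averages; a `per_sample` flag offers the strict
  variant. Sites uncovered in any patient cannot be shared — documented, no
  imputation.
* **Boosters** (`find_boosters()`): NoChange in the primary and the same
  polar state at every relapse, in every patient.
* **Predictors** (`find_predictors()`): same-direction DMC in every
  recurring patient's primary, covered-but-NoChange in every non-recurrent
  reference primary (absence of the reference aborts the procedure:
  specificity cannot be established), and same-direction DMC in every
  relapse sample of the subtype. Sites with partial coverage across those
  samples are disqualified (strict reading). Ranking is the mean |delta|
  across recurring primaries, with the inclusive >= 0.8 top-candidate flag.

**Regions and genes.** Candidate sites are merged into regions
(`merge_dmrs()`): maximal same-direction runs with start-to-start gaps of at
most 300 bp and at least 3 members. The merge parameters are not published
for the original study (they were internal to its caller); 300 bp/3 sites
yields promoter-scale regions and both are exposed. Regions are assigned to
genes whose TSS lies within +/- 5 kb of the region (`assign_genes()`); the
window is strand-agnostic because "up/downstream" covers both sides, and
strand is retained only for interpretation.

**PDOX preservation.** A candidate is preserved iff it is a same-direction
DMC (against the same normal) in *every* available PDOX derived from its
supporting patients — the conservative reading, since the aggregation rule
is not stated in the source material. Candidates with no matched PDOX are
kept and flagged not-evaluated. `preservation_percent()` reports
`round(100 * preserved / total, 1)`, the arithmetic used for printed
percentages such as 479/529 = 90.5%.

**Expression integration.** DEGs are called by library-size CPM
normalization, a per-gene two-sided Welch t-test on log2(CPM + 1), BH across
genes, and the inclusive thresholds q <= 0.05 and |log2FC| >= 1 (fold change
of the group-mean CPMs). The t-test replaces a negative-binomial count model:
it is transparent, adequate at the simulated effect sizes, and a
pre-computed DEG table can be substituted. `integrate_expression()`
correlates each candidate gene's region-mean methylation with its
log2(CPM + 1) across all tumor *and* normal samples (the tumors-only variant
is a flag choice the caller can make by passing fewer columns); concordance
requires direction agreement (hyper-down or hypo-up) and strictly negative
Pearson r, with no magnitude cutoff by default (`max_r` tightens it).
Genes with fewer than 3 paired samples or zero variance are flagged
not-evaluated rather than forced.

**Cohort metrics.** `convergence_series()` correlates each tumor with its
immediately preceding timepoint, falling back to the nearest earlier
available sample when one is missing (flagged); pairs with fewer than 100
shared covered sites are flagged, a repository choice since the minimum
underlying the published correlations is unknown. `global_fidelity()` is the
same Pearson correlation between a patient sample and its PDOX.
`top_variable_cpgs()` ranks complete-case sites (covered in all samples) by
across-sample variance with position tie-breaks; the 1 - r distance matrix
for clustering is left to external tools.

## The synthetic cohort generator

`simulate_cohort()` is a first-class module, not a test fixture: it defines
the study conditions under which every guarantee is demonstrated.

* **Cohort shape.** Five recurring patients per subtype with relapse counts
  7, 2, 1, 4, 1 (RELA) and 3, 2, 1, 2, 3 (PFA) — mirroring the clinical
  table of the motivating study, whose per-patient recurrence counts are the
  concrete design — plus one non-recurrent primary per subtype and one PDOX
  per recurring patient (of the latest sample). Five normal samples per
  tissue are generated; the two-group expression test needs that many for
  reasonable power, and methylation calling uses the first of each tissue as
  the matched reference.
* **Baseline methylation** is a bimodal beta mixture, 0.55 Beta(1, 10) +
  0.45 Beta(10, 1), mimicking the low/high modes of CpG methylation (no
  distribution is published; this is the generator's choice). CpA sites
  (5% extra sites) are lowly methylated (Beta(2, 30)) and globally reduced
  in tumors by a factor 0.4, emulating the tumor-specific loss of non-CpG
  methylation.
* **Planted signals** come in clusters of 5 CpGs about 60 bp apart
  (isolated from neighbors by >300 bp so each cluster is one region), split
  evenly over subtype and direction: 300 driver, 300 booster, 200 predictor
  and 200 switch sites by default, with shifts of 0.5, 0.5, 0.8 (predictors
  must clear the >= 0.8 ranking) and 0.5. Baselines at planted sites are
  truncated so the shifted ratio stays inside [0, 1], making the design
  ratio exact. Switch sites toggle at a random half of timepoints — the
  source only reports that under 2% of DMCs flip polarity, so the toggling
  pattern is a design choice.
* **Convergence.** Background CpGs carry a patient-specific drift field
  `u_t`: independent Gaussian (sd 0.25) at the primary, then
  `u_t = (1 - rate) * u_(t-1) + rate * attractor` at each relapse, with a
  per-patient Gaussian attractor. Consecutive relapses therefore correlate
  increasingly strongly — the hallmark the convergence metrics measure.
  Planted sites carry no drift, so their design deltas are exact.
* **Reads.** Per site and sample, total reads are Poisson (mean 50 by
  default — RRBS-scale; fragment-based coverage is deliberately not modeled,
  Poisson suffices to exercise the >= 5-read filter) and methylated reads
  binomial. PDOX methylomes add truncated Gaussian noise (sd 0.05) to the
  matched sample's latent ratios before reads are redrawn.
* **Expression.** One gene is placed near each driver/booster/predictor
  cluster (TSS within +/- 3 kb, inside the +/- 5 kb window) and is
  methylation-coupled with probability 0.5; the rest of the 1000 genes are
  placed uniformly. A coupled gene's negative-binomial mean (size 10) is
  scaled by `exp(-2 * promoter methylation change)` per sample — a
  natural-log slope, so a 0.5 shift gives |log2FC| of about 1.44, clearly
  past the fold-change-2 threshold; only the *sign* of the coupling is
  established externally, the magnitude is the generator's choice.
* **Determinism.** A single seed drives one RNG stream in a fixed
  iteration order; identical config + seed reproduces byte-identical
  outputs.

What the generator does *not* emulate: sequence context and fragment
structure of real RRBS libraries, copy-number alterations, subclonal
mixtures, batch effects, and the very low tumor-vs-normal correlations of
real tumors (the shared bimodal baseline keeps simulated correlations high).
Passing tests therefore demonstrate the *logic* of the pipeline — error
control, classification, set algebra, recovery of planted structure — not
performance on real tumors.

## Evaluation conventions

Planted predictor sites *necessarily* satisfy the driver definition: they
are consistent same-direction DMCs in every recurring patient from primary
through all relapses, and driver discovery only sees the recurring patients.
Driver recovery is therefore scored against the union of planted driver and
predictor sites. The converse does not hold: planted drivers are shifted in
the non-recurrent primary too, so the predictor specificity rule excludes
them, and predictor recovery is scored against planted predictors alone.
Similarly, the delta-consistency filter of driver discovery averages over
the supporting (recurring) patients' samples: the non-recurrent reference
belongs to the predictor procedure, not the driver one.

DEG recall on coupled genes is asserted for driver- and predictor-linked
genes. Booster-linked genes are diluted by construction — their primaries
are unshifted, so the tumor-vs-normal mean effect can fall below the
two-fold threshold (for the PFA relapse mix it does) — which is a property
of the design, visible in the truth tables, not a defect of the caller.

## Problem sizes and numerical choices

The default study is about 50,000 CpGs (plus 2,500 CpA sites), 48 sample
comparisons, and runs end to end in roughly a minute on one core; the test
suite exercises the full default scale once and smaller cohorts (600-4,000
sites) elsewhere. The convergence trend is demonstrated on 20 independent
3,000-site single-patient cohorts with four relapses at convergence rate
0.6. Fisher p-values match exact enumeration to 1e-10 (relative error
convention 1 + 1e-7, the same as `stats::fisher.test`); Pearson correlations
are `stats::cor` and match the closed form to 1e-12. Ties in top-variable
selection break by genome position with natural chromosome order
(chr2 before chr10). Degenerate inputs are handled explicitly: empty
comparisons abort, zero-variance genes are not evaluated, all-zero genes are
excluded from testing, and zero-coverage sites never reach a test.

## A short tour

```{r tour, eval = FALSE}
co <- simulate_cohort(cohort_config(seed = 1))
pipe <- run_pipeline(co)

glance(pipe)                                  # headline counts
tidy(pipe)                                    # candidate table
planted_recovery(pipe$candidates, co$truth$sites)

autoplot(pipe$convergence)                    # rising relapse correlations
autoplot(pipe$category_fractions)             # 7-category mix per patient
autoplot(pipe$integration, pipe$degs$RELA)    # anticorrelation highlights

write_pipeline_outputs(pipe, "results/run1")  # TSV bundle + summary JSON
```

## Known limitations

The caller is single-replicate per comparison (no dispersion modeling or
smoothing), BH is per comparison rather than pooled, DMR construction is a
greedy gap rule rather than a statistical segmentation, the expression test
is a t-test on log2 CPM rather than a count model, and the generator's
realism limits are listed above. Counts reported by the original study
depend on its raw data and unpublished caller parameters and are not
reproduction targets for this package.
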