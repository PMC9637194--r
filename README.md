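# methrelapse

Longitudinal DNA-methylation analysis of serially relapsing tumors, in R.

## The problem

Some childhood brain tumors — ependymoma is the motivating case — relapse
again and again over many years while their mutational landscape stays
quiet; the progression signal lives in the epigenome. Given CpG-level
bisulfite methylation counts from matched normal tissue, the primary tumor,
every serial relapse, and (optionally) patient-derived orthotopic xenografts
(PDOX), the questions are:

* which CpGs are differentially methylated at each stage, and how does each
  site's state *travel* across relapses (consistent, gained, lost,
  switching)?
* which methylation marks behave like **drivers** (present from the primary
  through every relapse of every patient), **boosters** (newly acquired at
  relapse and persisting), or **predictors** (already present at diagnosis
  in patients who will eventually relapse, absent from non-recurrent
  primaries)?
* are those marks preserved in the matching PDOX models, do they sit in
  promoters and anticorrelate with gene expression, and do serial relapse
  methylomes *converge* (growing relapse-to-relapse correlation)?

`methrelapse` implements that whole analysis as composable, pipe-friendly
functions plus a one-call pipeline, together with a fully specified
synthetic cohort generator with planted ground truth, so every stage is
testable without any external data.

## The model in brief

* **DMC calling** (`call_dmcs`): per site covered by ≥ 5 reads in tumor and
  matched normal, a two-sided Fisher exact test on the
  (methylated, unmethylated) × (tumor, normal) table — computed by exact
  hypergeometric enumeration, vectorized over millions of sites —
  Benjamini–Hochberg adjustment per comparison, and direction
  Hyper / Hypo / NoChange at |Δ| ≥ 0.2 (Δ = tumor − normal methylation
  ratio) and q ≤ 0.05.
* **Trajectories** (`classify_trajectory`): each site's ordered state
  sequence per patient falls into consistent-Hyper/Hypo, gain-Hyper/Hypo,
  loss-Hyper/Hypo or switch; adjacent Hyper↔Hypo flips are excluded
  (and tallied).
* **Discovery** (`find_drivers`, `find_boosters`, `find_predictors`):
  cross-patient set intersection (UpSet-style exclusive tallies via
  `intersect_patients`), a strict mean-|Δ| > 0.3 consistency filter for
  drivers, and ranked predictors with an inclusive |Δ| ≥ 0.8 top flag.
* **Regions & genes** (`merge_dmrs`, `assign_genes`): same-direction DMC
  runs (gap ≤ 300 bp, ≥ 3 sites) assigned to genes whose TSS is within
  ± 5 kb.
* **PDOX preservation** (`pdox_filter`): a candidate is preserved iff it is
  a same-direction DMC in every matched xenograft sample.
* **Expression** (`call_degs`, `integrate_expression`): CPM-normalized
  Welch t-tests on log2(CPM+1) at FDR ≤ 0.05 and fold change ≥ 2, then
  Pearson anticorrelation of promoter methylation with expression.
* **Metrics** (`convergence_series`, `global_fidelity`,
  `top_variable_cpgs`): relapse-to-relapse Pearson correlation with a
  nearest-earlier-sample fallback for missing timepoints, patient-vs-PDOX
  global fidelity, and complete-case top-variable CpG selection.

The methods vignette
(`vignettes/relapse-methylation-methods.Rmd`) documents every assumption,
default and numerical choice.

## Worked example

```r
library(methrelapse)

co   <- simulate_cohort(cohort_config(n_sites = 4000, n_genes = 300,
                                      n_chroms = 8, seed = 101))
pipe <- run_pipeline(co)

glance(pipe)
#> # A tibble: 1 × 7
#>   n_sites_tested n_comparisons n_drivers n_boosters n_predictors mean_convergence_r mean_pdox_fidelity
#> 1           4000            48       493        290          200              0.936              0.979

planted_recovery(pipe$candidates, co$truth$sites)
#> # A tibble: 6 × 7
#>   kind      subtype n_recovered n_truth true_positive precision recall
#> 1 driver    PFA             247     250           247         1  0.988
#> 2 booster   PFA             144     150           144         1  0.96
#> 3 predictor PFA             100     100           100         1  1
#> 4 driver    RELA            246     250           246         1  0.984
#> 5 booster   RELA            146     150           146         1  0.973
#> 6 predictor RELA            100     100           100         1  1
```

48 tumor/PDOX samples were each tested against their matched normal; the
planted driver, booster and predictor sites are recovered with precision 1
and recall ≥ 0.96 (driver truth includes the planted predictors, which
satisfy the driver pattern by construction — see the vignette). Convergence
is visible per patient:

```r
dplyr::filter(pipe$convergence, patient_id == "RELA1")
#>   from_sample to_sample pearson_r fallback_used
#> 1 RELA1_P     RELA1_R1      0.885 FALSE
#> 2 RELA1_R1    RELA1_R2      0.965 FALSE
#> 3 RELA1_R2    RELA1_R3      0.975 FALSE
#> ...

autoplot(pipe$convergence)           # r vs relapse number, per patient
autoplot(pipe$category_fractions)    # 7-category trajectory mix
tidy(pipe)                           # full candidate table
write_pipeline_outputs(pipe, "out")  # TSVs + summary.json
```

The rising `pearson_r` along RELA1's seven relapses is the convergence
signature; `pipe$preservation` summarizes PDOX preservation per candidate
kind and direction (e.g. driver/PFA/Hyper 124/124 = 100%, driver/RELA/Hypo
122/124 = 98.4% in this run, where the PDOX noise is small).

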