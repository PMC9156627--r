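# semioloc

Probabilistic localizing values of epileptic seizure semiologies from
patient-level literature data.

## What problem this solves

During presurgical evaluation of drug-resistant focal epilepsy, the
symptoms and signs of a seizure (its *semiology*) point — imperfectly —
towards the brain regions that generate them. The published literature
linking semiology to verified localizations is dominated by temporal-lobe
surgical series: studies that preselected patients because the seizure
focus was already known (*topological* studies: resection cohorts and
cortical stimulation). Estimating `p(region | semiology)` from pooled
literature data therefore inflates temporal-lobe probabilities.

`semioloc` is for epileptologists and methodologists who want
localization probabilities with that selection bias made explicit and
mitigated. It provides:

* a canonical patient-semiology record schema with reading, validation and
  subset filtering (ground truths, study design, age);
* a regular-expression taxonomy that maps free-text descriptions to
  semiology categories, with negation and string-similarity safeguards
  (dystonic never fires the tonic rule, "without epigastric aura" does not
  count as an epigastric aura);
* a hierarchical brain-region tree (8 top-level regions, 5 temporal
  subregions) with equal-split redistribution of interlobar-junction
  allocations and ancestor roll-up;
* per-patient-semiology normalization: each unit's allocations sum to 1,
  so a semiology's total weight equals its patient count;
* conditional probabilities `p(R | S)` with 95% bootstrap percentile
  intervals (10,000 resamples of patient-semiology units), computed side
  by side on all data and on the bias-mitigated *non-topological* subset;
* the estimated unbiased distribution of localizations (EUD-Loc): the
  pooled regional prior from non-topological data only;
* relative localizing value as odds ratios `OR = ad/bc` from weighted 2x2
  tables (semiology vs all others, region vs rest), Haldane-Anscombe 0.5
  correction on zero cells, bootstrap CIs and significance at alpha 0.05;
* a seeded synthetic cohort generator with known ground truth (true
  conditional matrix, study mix, temporal-focused selection bias), so the
  whole pipeline is testable without any download;
* a command line (`inst/cli/semioloc`) with subcommands `validate`,
  `classify`, `forest`, `ors`, `eudloc`, `simulate`, `sensitivity`,
  `flows`.

## Worked example

Generate a literature-like cohort of about 5,000 patients, then contrast
the biased and bias-mitigated views:

```r
library(semioloc)

cohort <- generate_cohort(default_paper_like_config(seed = 1))
w <- cohort_weight_matrix(cohort$records)

eud_loc(w, subset_label = "non_topological")
#> Prior distribution of localizations (non_topological subset, 3097 units):
#>   Temporal         44.6%
#>   Frontal          31.1%
#>   Parietal          6.9%
#>   Occipital         6.2%
#>   Cingulate         4.4%
#>   Insula            2.6%
#>   Hypothalamus      3.8%
#>   Other             0.4%

eud_loc(w, subset_label = "all_data")
#> Prior distribution of localizations (all_data subset, 9825 units):
#>   Temporal         66.1%
#>   Frontal          14.6%
#>   ...
```

The non-topological prior (EUD-Loc) puts 44.6% of localizing mass on the
temporal lobe; pooling in the topological studies inflates it to 66.1% —
the publication bias the filtering is designed to remove (in this cohort
the generator planted exactly that contrast: 44% unbiased, 75% topological
focus, 71% topological share).

Conditional localizing value of a specific semiology, on the unbiased
subset:

```r
w_nt <- subset_units(w, "non_topological")
p  <- localizing_probability(w_nt, "Epigastric", "Temporal")
ci <- bootstrap_ci(w_nt, "Epigastric", "Temporal", n_boot = 10000, seed = 1)
sprintf("p(Temporal | Epigastric) = %.2f, 95%% CI (%.2f, %.2f)", p, ci[1], ci[2])
#> "p(Temporal | Epigastric) = 0.88, 95% CI (0.83, 0.92)"
```

An epigastric aura localizes to the temporal lobe with 88% probability in
this cohort (the generator's truth is 83%; the interval is the percentile
bootstrap over the 173 epigastric patient-semiology units). Its intrinsic
value relative to all other semiologies:

```r
or_with_ci(w, "Epigastric", "Temporal", n_boot = 10000, seed = 1)
#>    semiology   region odds_ratio   ci_low  ci_high significant
#> 1 Epigastric Temporal       6.66     5.22     8.89        TRUE
```

so knowing that a patient has epigastric auras multiplies the odds of a
temporal source several-fold over the baseline prior. `forest_table()`
assembles these cells for every semiology with at least 100 patients in
both study-design subsets, across 7 top-level regions and 5 temporal
subregions, in both the all-data and non-topological series;
`plot_forest()` renders the two-series forest plot.

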