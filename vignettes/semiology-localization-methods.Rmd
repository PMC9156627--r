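---
title: "Probabilistic localization of seizure semiologies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic localization of seizure semiologies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semioloc)
```

## The problem

Seizure semiology — the evolution of symptoms and signs during an epileptic
seizure — carries localizing information about the brain regions that
generate it, and is weighed during presurgical evaluation of drug-resistant
focal epilepsy. The literature reporting semiology-to-localization links is,
however, strongly biased towards temporal lobe epilepsy: resection and
stimulation series preselect patients by a known seizure focus, so temporal
regions are oversampled relative to their true prevalence. `semioloc`
implements a pipeline that (i) turns patient-level literature records into
normalized localizing weights over a hierarchical brain-region tree,
(ii) estimates conditional localization probabilities
$p(\text{region} \mid \text{semiology})$ with bootstrap confidence
intervals, (iii) mitigates the publication bias by contrasting the full
data with the subset of *non-topological* studies (those that selected
patients by semiology or consecutively, without region preselection), and
(iv) quantifies each semiology's intrinsic localizing value as an odds
ratio against all other semiologies.

## Data model

One record is one *patient-semiology* observation: free-text description,
assigned category, multi-one-hot localizing allocations over region nodes,
three ground-truth flags (postsurgical seizure-freedom; imaging and
neurophysiology concordance; invasive SEEG/stimulation — at least one must
hold for inclusion), a study-design label (`epilepsy_topology`,
`stimulation`, or `spontaneous`; the first two jointly form the
*topological* subset), an age label, and laterality fields (stored but not
analysed here).

The region tree has eight fixed top-level regions (temporal, frontal,
parietal, occipital, cingulate, insula, hypothalamus, cerebellum), five
temporal subregions (mesial, anterior, lateral, posterior, basal), eight
interlobar junction categories, and the standalone subcallosal cortex.
Junctions exist only as a data-entry convenience; `redistribute_junctions()`
splits a junction's weight *equally* among its constituent lobes. The split
proportions are a design choice: equal shares are the maximum-entropy
allocation and conserve total weight, and the perisylvian junction is
assigned the constituents {frontal, temporal, parietal}. Allocations are
stored at the most specific node only; ancestors are aggregated at query
time by `rollup()`, so a lobe total includes its subregions without ever
double-counting a hierarchy path.

## Normalization

`cohort_weight_matrix()` first redistributes junctions, then divides each
record's allocations by their total, so every patient-semiology unit sums
to one. A semiology reported to localize to $k$ regions therefore
contributes $1/k$ to each — penalizing multifocal reports — and the total
weight of a semiology equals the number of patients reported with it.
Normalization runs *after* junction redistribution so that a junction
counts as its constituent lobes rather than as a single region.

## Estimation

For a semiology $S$ with $n$ units and unit weight vectors $w_i$,

$$\hat p(R \mid S) \;=\; \frac{1}{n}\sum_{i=1}^n \mathrm{rollup}(w_i, R),$$

and 95% confidence intervals are percentile intervals (2.5/97.5) over
10,000 resamples of the units with replacement. The resampling unit is the
patient-semiology unit — not the article, not the raw data point — because
normalization defines it as the unit of analysis. All stochastic outputs
are seeded (default seed 0) and bit-identical across reruns.

Pooling all semiologies within a subset gives the prior distribution of
localizations over top-level regions (`eud_loc()`). Restricted to
non-topological data this is the *estimated unbiased distribution of
localizations* (EUD-Loc); computed on all data it is the
publication-biased prior. The seven forest-plot regions are reported
explicitly, with cerebellum and subcallosal cortex folded into an "Other"
remainder so the distribution sums to one.

A semiology is *eligible* for reporting when at least 100 patients carry it
in both the topological and the non-topological subsets (strict two-sided
threshold, `eligible_semiologies()`); `forest_table()` reports each
eligible semiology over the seven top-level regions plus five temporal
subregions, in both the all-data and non-topological series.

The intrinsic localizing value of $S$ for region $R$ is an odds ratio from
the weighted 2×2 table (`contingency_table()`): $a$ = rolled-up weight of
$S$'s units in $R$, $b = n_S - a$, and $c, d$ analogously over all other
semiologies — including those below the reporting threshold. Zero cells
receive the Haldane–Anscombe 0.5 correction. The bootstrap resamples all
units pooled (not within strata), and significance means the 95% interval
excludes 1.

## The synthetic cohort generator

Because the analyses are defined against a curated literature database,
the package ships a seeded generator (`generate_cohort()`) whose defaults
encode the literature-like study conditions, so that every stage is
testable with known ground truth:

* **Non-topological articles** draw each unit's category from the semiology
  marginal and its region from the true conditional row
  $P(\cdot \mid s)$; with probability 0.2 a second region is drawn from the
  same row and the unit is allocated half/half (multifocal reporting).
* **Topological articles** first draw a focus region from the focus
  distribution, then sample categories from the Bayes inversion
  $P(s \mid f) \propto P(f \mid s)\,P(s)$ of the same truth, and set every
  unit's region to the focus exactly. Sharp preselection is a design
  choice: resection and stimulation series know their region with
  certainty. The stimulation vs epilepsy-topology split inside the
  topological subset is 50/50 and pooled in all analyses.
* Temporal allocations are refined into undifferentiated temporal (30%)
  or one of the five subregions (mesial 35%, anterior 10%, lateral 10%,
  posterior 8%, basal 7%) — a choice reflecting the dominance of mesial
  temporal localizations in the surgical literature.

`default_paper_like_config()` fixes the shape constants: the unbiased
region marginal puts 44% of mass on temporal and 31% on frontal regions
(parietal 7%, occipital 6%, cingulate 4.5%, hypothalamus 4%, insula 3%,
cerebellum 0.5% complete it — our choice, descending in rough clinical
prevalence); the twelve named categories carry their reported shares of
non-topological data (tonic 9.8% down to somatosensory 2.9%, 65.5%
together) with the remaining 34.5% spread over 23 placeholder categories;
their shared conditional row is the unique residual making the mixture hit
the unbiased marginal exactly. Topological articles focus on the temporal
lobe 75% of the time, and the topological article share is 0.71, so the
pooled all-data temporal share is $0.71 \times 0.75 + 0.29 \times 0.44
\approx 0.66$ — reproducing the biased-vs-unbiased (66% vs 44%) contrast
that motivates the filtering. Articles carry 5–40 patients (uniform; the
literature gives no size distribution, so a generic small-series range is
used) and patients carry 1–3 distinct semiology categories. Ground-truth
flags are independent Bernoulli draws (seizure-freedom 0.55, concordance
0.45, invasive 0.25) with rejection so every record has at least one; ages
are adult 62% / under-7 8% / unknown 30%; laterality is generated as
unknown because lateralization analysis is out of scope.

The generator emulates the selection mechanism, not the texture of real
literature data: it does not simulate narrative free text (each category
carries a fixed template phrase), chronological seizure evolution,
correlated ground truths, inter-article heterogeneity in reporting style,
or regional practice differences. Passing tests therefore demonstrate that
the estimators are correct and the bias mechanism is handled as designed —
not that any particular clinical number is true of real cohorts.

## Taxonomy

Free text is classified by per-category rule sets: case-insensitive,
word-boundary include patterns; exclude patterns that mask longer terms
before matching (so "unforced head turn" can never fire the head-version
rule, and string-similar pairs like dystonic/tonic or myoclonic/clonic
cannot cross-trigger); and negation handling. The negation algorithm is a
design choice, since only the requirement to avoid misclassifying
negations is given: a fixed cue list ("no", "not", "without", "denies",
"absence of", ...) suppresses a match when a cue occurs within 3 tokens
before the matched span *and* no clause punctuation intervenes — so
"without epigastric aura, blank stare noted" loses the epigastric match
but keeps the dialeptic one. Multi-category texts expand into one analysis
unit per (patient, category) pair. The shipped taxonomy covers the twelve
most common ictal categories plus postictal and asymptomatic (both removed
before analysis); the full 35-category inventory loads from a user file in
the same YAML format.

## Numerical choices and degenerate inputs

* Normalized unit vectors must sum to 1 within 1e-9; all-zero allocation
  vectors raise a degenerate-input error naming the offending patient.
* Percentile CIs use the default type-7 quantile; a cohort of identical
  units yields a degenerate interval equal to the point estimate.
* Duplicate (patient, semiology) rows are merged by summing raw
  allocations (with a warning) before normalization, which generalizes the
  $1/k$ rule to raw counts above one.
* Records whose age is unknown are retained under the under-7 exclusion
  filter: exclusion applies only where the label is available.
* Unknown filter keys, enum values, region columns, taxonomy duplicates
  and malformed trees raise typed errors (`semioloc_*_error`) rather than
  warnings.
* Patients are treated as nested within articles; a patient reported in
  two articles is treated as two patients, since cross-article identity is
  unknowable from published tables.

## Problem sizes used in the test-suite

The shipped checks run on synthetic cohorts of about 5,000 patients
(10,000 units) for parameter recovery and bias direction; 500 replicate
cohorts of 200 units with 2,000 bootstrap resamples for CI calibration
(scaled down from the 10,000 used in production queries, which only
sharpens the quantile estimate, not the interval's location); 500
replicates for the null odds-ratio control; and 1,000 random micro-cohorts
(at most 20 units) for exhaustive cross-checking of the weighted
contingency tables against brute-force enumeration. These sizes were
chosen so each statistical property is measured with enough replicates to
be meaningful while the whole suite stays quick to run.

## Known limitations

* Max-cell recovery of the conditional matrix at a 5,000-patient cohort is
  noise-limited: the rarest reported categories then hold under ~130
  non-topological units, so single cells carry sampling SDs up to ~0.05
  and the maximum error across the 12×8 grid typically lands near 0.1 even
  though estimates are unbiased (the suite's 3-SE recovery check passes).
  Larger cohorts shrink this proportionally to $1/\sqrt{n}$.
* The equal junction split and the perisylvian constituent set are
  conventions; a different redistribution would shift lobar totals by at
  most the junction mass.
* Odds ratios are reported per cell without multiplicity correction,
  matching forest-plot practice of per-cell 95% CIs.
* The taxonomy is pattern-based by design; it does not attempt clinical
  NLP beyond regular expressions with negation and exclusion safeguards.
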