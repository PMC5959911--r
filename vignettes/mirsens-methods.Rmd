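---
title: "Methods: screen hit calling, dose-response and follow-up analyses in mirsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen hit calling, dose-response and follow-up analyses in mirsens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsens)
```

`mirsens` analyses plate-based microRNA mimic/inhibitor screens for taxane
sensitisers and the downstream characterisation of hits. This vignette
documents the models and procedures each stage implements, the parameters
that matter, the numerical conventions adopted where several were
defensible, and what the synthetic-data generators do and do not emulate.

## Screen normalization and hit calling

### Model

Each well's luminescence is proportional to viable cell mass. Within a
(plate, treatment) stratum the non-targeting control wells define 100%
viability; a perturbation's viability is the mean of its per-well
percentages of the stratum control mean (inside one stratum this equals the
ratio of mean raw signals). Normalization is strictly per plate and per
treatment: plates carry a multiplicative batch factor (instrument gain,
seeding density) that cancels only within a stratum, and the drug's own
effect cancels only against the control of the *same* treatment. A
consequence worth spelling out: under an IC20 drug dose the control wells
themselves sit at 80% of vehicle signal, so a perturbation with no
drug-conditional effect normalizes to 100% under both treatments, and the
sensitiser rule below measures killing *beyond* the drug's own effect.

### The dual-threshold rule

`call_sensitisers()` labels a perturbation

* **sensitiser** — drug viability `< sens_threshold` (default 80%) *and*
  vehicle viability `> vehicle_threshold` (default 80%);
* **toxic** — vehicle viability at or below the vehicle threshold, with
  drug viability within `sens_margin` (default 10 points) of vehicle
  viability;
* **toxic_sensitiser** — vehicle-toxic and at least `sens_margin` further
  points lost under drug;
* **none** — otherwise. `strong` flags drug viability `< 50%`.

Thresholds are strict inequalities: a perturbation at exactly 80% is not a
hit. The four categories partition the input by construction; a one-line
restatement of the rule is kept as an oracle in the test suite and checked
over randomized viability pairs including the 80.0 and 50.0 boundaries.

`classify_sirna()` applies the band logic used for follow-up knockdowns:
the sensitiser call requires the drug-treated knockdown to sit at least
`sens_margin` points below the drug-treated control (the lower bound of the
10–20-point band such effects typically occupy), since single-gene
knockdowns are weaker than mimics and a margin-free rule would promote
noise. The 20–40% toxic viability band is reported as an informational
flag, not used in the rule, because the classification boundary is the
vehicle threshold, not the band.

The lethal positive control (PLK1-style siRNA) is excluded from hit
statistics; `positive_control_qc()` reports its normalized viability as a
transfection-efficiency check (pass at ≤ 25%).

## Growth curves and dose-response

Doubling time is the log2-ratio formula
`(t_B − t_A) / log2(C_B / C_A)`, exact for exponential growth and
independent of the window chosen within the exponential phase (a property
the tests verify to 1e-9 relative). Because real confluency curves
saturate, `select_linear_phase()` picks the widest window of at least
`min_points = 3` observed timepoints whose straight-line fit to
`log2(confluency)` reaches `R² ≥ 0.99`, breaking width ties by R²; both
knobs are exposed, and a curve with no qualifying window errors with a
suggestion to select manually rather than silently fitting a plateau.

Dose-response curves use the 4-parameter log-logistic (Hill) model on log
dose — the standard viability-assay model; the screen literature reports
IC50 and maximum response without naming a curve family, and this choice
makes IC values analytic inversions rather than graphical reads. Fitting is
plain least squares via `minpack.lm::nlsLM` with data-driven starts (span
asymptotes, midpoint dose, unit slope). Zero doses are vehicle anchors,
never log-transformed. The reported *maximum response* is the empirical
minimum of per-dose mean viability, deliberately model-free, and is carried
on the error condition when the fit cannot converge (e.g. flat, effect-free
data) so a screening loop can keep the number.

`ic_value()` supports two IC conventions, both documented because the
field uses both: `"asymptote"` measures the reduction as a fraction of the
fitted span (so `ic_value(fit, 50)` *is* the fitted IC50, an exact
identity), while `"absolute"` solves for viability `100 − level` percent,
the convention under which an IC20 dose leaves cells at 80% of untreated
control; the latter errors when the requested viability lies outside the
fitted asymptotes.

## Expression follow-up

The differential-expression fit itself is consumed, not implemented: count
models belong to dedicated tools, and this package's contribution starts
after the DE table. `filter_low_signal()` removes a transcript only when
*both* clauses hold — mean abundance below 1 RPKM in both groups *and*
variance below the median per-gene variance — since either alone would
discard genuinely quiet but regulated transcripts. The median is computed
once, over all genes present before filtering, on samples of both groups
pooled; the phrase "median variance of the two groups" is ambiguous between
pooled and per-group, so pooled is the default and `variance = "per_group"`
the flag. With the median frozen this way the filter is idempotent.

`downregulated_set()` is strict (`adjusted p < 0.05`); reported set
percentages round half away from zero to integers, matching how such
fractions are conventionally printed. Target-evidence annotation gives
experimental support (TarBase-style) priority over prediction;
`aggregate_predictions()` combines per-source pair tables by union,
intersection or k-of-n, and the tests check the k-of-n result against a
brute-force membership-bitmap filter.

For synthetic matrices only, `de_from_expression()` provides a per-gene
Welch t-test on `log2(x + 0.5)` with BH adjustment, so planted-effect
recovery is testable end to end; it is a two-group location test for
simulated abundances, not a count-model DE method, and should not be
pointed at real sequencing counts.

## Gene-set over-representation

`enrich_collection()` tests the downregulated set against each set of a
GMT collection with the one-sided hypergeometric upper tail
`P(X ≥ k)`, the overlap statistic used by gene-set browsers. Two
conventions are explicit rather than silent: the query is first intersected
with the collection's namespace (only genes the collection can recognise
can overlap), and `universe_size` is a required argument because the
p-values depend on it and no portable default exists. The tail is evaluated
in log space via `phyper(..., log.p = TRUE)`; the tests compare it against
exhaustive enumeration of all `C(N, n)` draws for every parameter
combination with a universe up to 15, and BH adjustment against hand
step-up computations.

## Tumor-expression evaluation

`clean_matrix()` drops genes with strictly more than 50% missing values in
any single tissue group (exactly half is retained) and imputes the
remaining missing cells with the minimum observed value of the cleaned
dataset — a floor-imputation appropriate for intensity data where
missingness concentrates at the detection limit. The per-compared-group
reading of "tissue set" is the default; multi-site matrices can be cleaned
per site by passing site labels as the groups.

`two_group_de()` runs per-gene two-sided t-tests (Welch by default;
`var_equal = TRUE` gives the pooled spreadsheet-style variant), BH
adjustment across all tested genes, and linear fold changes of group
means — inputs flagged `log2_input` are exponentiated first because a
"fold ≥ 1.5" criterion is a linear-scale statement. The up-call is
`adjusted p ≤ 0.05` (inclusive) *and* fold ≥ 1.5, with the symmetric
down-call at fold ≤ 1/1.5. Genes with zero variance in both groups get
p = 1 with a warning rather than an error, so a few saturated probes cannot
abort a dataset. `zscore_matrix()` uses the population (divide-by-n) SD —
a heatmap-scaling convention that had to be fixed one way; constant rows
are emitted as zeros with a warning.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure each stage assumes:

* `simulate_screen()` — multiplicative log-normal signal noise (positive,
  heteroscedastic, like luminescence), per-plate base-signal factors
  (log-SD 0.15) that *force* per-plate normalization, fixed control wells
  on every plate, an IC20 drug contract (`control_drug_viability = 80`),
  and perturbation classes whose effects compose multiplicatively, with
  sensitisation an extra factor applied only under drug. Default effect
  ranges: sensitisers near-neutral under vehicle (0.90–1.05) with
  conditional factor 0.40–0.70; toxic perturbations at 20–40% vehicle
  viability with no conditional effect; dual effects 0.20–0.60 × 0.50–0.80.
  These place the classes inside the bands the rule is built for while
  leaving the boundaries to noise. Replicates default to 2 wells per
  treatment — a config choice, as screen replicate structure varies.
* `simulate_confluency()` — logistic growth whose early phase carries the
  requested doubling time.
* `simulate_dose_response()` — the exact Hill curve plus multiplicative
  noise; zero dose stored as the vehicle anchor.
* `simulate_expression()` / `simulate_tumor_matrix()` — log-normal
  abundances, planted multiplicative fold effects, forced low-signal genes
  (both filter clauses) and forced >50%-missingness genes, with
  missing-completely-at-random masks.

Every generator is byte-identical under a fixed seed, and noise-free runs
reproduce their generative means exactly.

What passing the recovery tests does **not** show about real data: no
spatial plate artifacts (edge effects, gradients — a B-score correction is
out of scope), no transfection-efficiency drift, no count-based
mean–variance relationship (planted DE recovery uses t-tests on simulated
abundances, not a count model), no missing-not-at-random structure, and no
correlation between genes. Recovery rates on this synthetic structure are
upper bounds on what identical settings achieve on real plates.

## Problem sizes and reproducibility

The shipped demo configuration and the test suite run every stage at small
scale — a 500-perturbation screen with 2 replicate wells per treatment,
50 seeded dose-response experiments with 8 doses × 4 replicates,
200–500-gene expression/tumor matrices with 4 or 20 samples per group, and
50 null tumor datasets of 1000 genes — sizes at which each stage's
behaviour (recovery above 90% sensitivity, null false-positive control
under BH) is already stable and a full pipeline run takes seconds. All
randomness descends from one top-level seed, expanded deterministically per
stage, so a config file pins an entire run; `run_pipeline()` reruns
byte-identically and writes the exact config beside its outputs.

## Known limitations

* Hit calling consumes per-perturbation viability summaries; it does not
  model well-level variance or provide p-values for hits — the rule is the
  published threshold rule, not an inferential test.
* The log-logistic fit assumes a monotone decreasing viability curve;
  biphasic responses will fit poorly and should be caught by inspecting
  residuals.
* `enrich_collection()` tests overlap only; no ranked/weighted (GSEA-style)
  statistics.
* The cardiotoxicity blacklist is user-supplied (`exclude_blacklist()`);
  the package ships none.
* Real tumor datasets are user-supplied files; there is no download client.
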