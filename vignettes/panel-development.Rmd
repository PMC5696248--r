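---
title: "Developing an MRM biomarker panel: model, assumptions, and defaults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing an MRM biomarker panel: model, assumptions, and defaults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mrmpanel)
library(dplyr)
```

# The problem

Pancreatic ductal adenocarcinoma (PDAC) is usually detected late. The
established blood marker, CA19-9, has two structural weaknesses as a
screening tool: its levels rise in benign biliary disease, and roughly
10–15% of the population (Lewis-antigen-negative individuals) do not
express it at all, so a subset of cancers is invisible to it. A standard
response is to *anchor* a multi-marker panel on CA19-9 and add a small
number of proteins, measured by targeted mass spectrometry, that carry
signal where CA19-9 does not.

`mrmpanel` implements that development pipeline end to end:

1. **Quantitation** of multiple-reaction-monitoring (MRM) data:
   transition-level peak areas → per-sample relative peptide levels.
2. **Verification QC**: reproducibility, dynamic-range, interference,
   and confounder filters that shrink a broad candidate list to markers
   worth combining.
3. **Anchored panel search**: exhaustive enumeration of CA19-9-anchored
   marker combinations, each classified by a support vector machine
   (SVM) under stratified cross-validation, selected by paired ROC
   statistics.
4. **Validation**: frozen-model, frozen-cutoff evaluation across
   clinically motivated comparison scenarios.
5. A **synthetic cohort generator** with ground-truth labels, so every
   step can be benchmarked against planted truth.

# Quantitation model

An MRM assay monitors a handful of *transitions* (precursor/product ion
pairs) per peptide, in a light (endogenous) and a heavy
(stable-isotope-labeled standard, SIS) channel. The quant unit is the
**relative peptide level**: the light:heavy peak-area ratio, which is
dimensionless and cancels instrument response. `quantify_transitions()`:

- picks one **signature transition** per peptide — the one with the
  largest total light area across all runs (lexicographic tie-break) —
  chosen once globally, so a peptide's series is internally comparable;
- ratios light to heavy (or to an external β-galactosidase standard
  with `mode = "external"`, for peptides without an SIS standard);
- averages technical replicates and reports the replicate CV
  (SD/mean of the raw ratios).

Zero or missing denominators yield flagged `NA`s; a zero light area is
flagged `below_detection`. Nothing is silently imputed.

# Verification filters

`run_qc()` applies five filters, each computed on the full input (so the
surviving set does not depend on rule order):

| Filter | Rule | Default |
|---|---|---|
| `cv_filter` | median triplicate CV ≤ threshold | 10% |
| `range_filter` | median relative level inside an open interval | (0.1, 10) |
| `audit_filter` | signature transition not interfered | see below |
| `confounder_filter` | no center/batch association in controls | BH-adjusted α = 0.05 |
| `single_marker_screen` | oriented normal-vs-PDAC AUC above threshold | 0.60 |

**Interference detection** (`audit_flag`) compares each transition's
fractional contribution to the summed *light* area against its
contribution to the summed *heavy* area, per sample. In a clean
measurement the two patterns match (both channels share fragmentation
chemistry); an interfering co-eluting ion adds area to one light
transition only. We test the per-replicate difference of contributions
with a **one-sided** paired t-test (light above heavy). The one-sided
choice is deliberate: an additive light-only contamination *inflates*
the hit transition's contribution and necessarily *depresses* its
siblings', so a two-sided rule would flag the innocent siblings too and
inflate the false-flag rate. A transition is also flagged when the
replicate CV of its light:heavy ratio exceeds 20%. A (peptide,
transition) pair is called interfered when flagged in more than half of
the samples; a peptide fails QC when its *signature* transition is
interfered. The intended workflow is two-pass: flag, then re-quantify
with `quantify_transitions(exclude_transitions = ...)` so quantitation
rests on interference-free transitions.

A known blind spot, by construction: if *every* transition of a peptide
carries the same relative contamination, the contribution patterns
match again and the discordance test cannot see it. This is inherent to
relative-pattern methods, not an implementation limit.

**Confounder screening** runs Kruskal–Wallis tests of the relative
level against clinical center and against preparation batch *within
the control group only* — disease-composition differences between
centers must not masquerade as nuisance effects — with
Benjamini–Hochberg correction across peptides per factor.

# Panel search and selection

`panel_search()` enumerates every marker subset of sizes 2–3 that
contains the anchor, deterministically (by size, then lexicographically).
Each candidate is evaluated with a two-class SVM:

- markers are log-transformed (plasma analyte levels are approximately
  log-normal) and standardized with training-fold constants only;
- linear kernel, regularization constant fixed at 1 — the smallest
  assumption consistent with the dual decision function
  `f(x) = Σ αᵢyᵢ⟨x, xᵢ⟩ + b`, and no tuning loop that could overfit the
  selection;
- the *continuous* decision value is kept for ROC work; the sign rule is
  applied only at the frozen cutoff;
- scores are oriented so cases score higher (a fitted orientation flag,
  since the SVM's internal label order is arbitrary);
- 5-fold cross-validation, stratified by class (and center when given),
  with the fold assignment **shared across all candidates** so every
  pairwise comparison is paired;
- all candidates are evaluated on the rows complete for every searched
  marker, again to keep paired tests valid (dropped-row count is
  recorded).

Selection is two-stage, against the anchor alone on the same
cross-validated scores:

1. **AUC stage**: AUC gain ≥ 0.07 *and* DeLong p < 0.05;
2. **sensitivity stage**: sensitivity gain > 0.10 at the 90%-specificity
   cutoff *and* McNemar p < 0.05 (cases-only scope — it is a comparison
   of sensitivities at matched specificity).

Survivors are ranked by cross-validated AUC, then sensitivity gain,
then panel name — all computable without touching a test set.

## Paired ROC statistics

`delong_test()` implements the structural-components (placement-value)
estimator of the covariance of two correlated AUCs, using a midrank
formulation that is O(n log n); it is validated in the test suite
against a naive double-loop implementation to 1e-12. `mcnemar_test()`
uses the exact two-sided binomial p when the discordant count is below
25 and the continuity-corrected χ² otherwise. Positive calls are
`score ≥ cutoff`; boundary conventions (≥ at the AUC gain, strict > at
the sensitivity gain) follow the selection rule's wording. PPV uses the
textbook formula with a default prevalence of 12.9 per 100,000.

## Cutoff transfer

`sensitivity_at_specificity()` freezes the smallest decision threshold
whose *training* specificity meets the target, choosing among midpoints
between observed scores (plus both extremes). The same frozen cutoff —
one global cutoff, not per-scenario cutoffs — is then applied to every
test scenario, which is why reported test specificities scatter around
the target rather than matching it exactly.

# The synthetic cohort generator

`cohort_config()` + `generate_cohort()` emulate a 1008-sample,
five-center validation cohort: 401 PDAC (stages I/II/III/IV =
20/228/31/122), 349 normal controls, 149 other cancers, 109 benign
pancreatic disease, with per-group demographics and blocked-randomized
preparation batches (round-robin within group, so per-batch group
composition deviates by at most one sample).

**CA19-9 channel.** Within each group-by-center stratum, CA19-9 is
log-normal with the log-location set by the configured median and the
spread calibrated from the configured MAD via `lnorm_sdlog_from_mad()`.
A log-normal cannot attain MAD/median ≥ 1 — yet heavy-tailed clinical
strata show exactly that — so calibration is two-branch: exact MAD
inversion when MAD/median < 0.95, otherwise a quantile fallback that
pins the 90th percentile at `median × (1 + MAD/median)`. A configured
fraction (default 12.5%) of PDAC cases are **non-expressors** whose
CA19-9 is drawn from the control distribution; their identities are in
the ground truth. Values are censored at assay bounds (1.2 and 10,000
U/mL) and a small fraction is flagged missing.

**MRM channel.** Each marker is log-normal with a disease effect set
either directly or from a target single-marker AUC via the binormal
identity `AUC = Φ(δ / (σ√2))` (`effect_for_auc()`). Transition-level
data add: fixed per-transition responses (heavy areas constant per
transition), multiplicative log-normal replicate noise at a configured
CV (default 8%, a typical triplicate MRM reproducibility target), and —
on a configured fraction of transitions — an additive light-only
interference. Optional per-marker batch/center fold changes feed the
confounder-recovery benchmarks. Everything is bit-reproducible from the
mandatory seed.

# A worked run

```{r pipeline, eval = FALSE}
config <- cohort_config(seed = 1)
cohort <- generate_cohort(config)
sim <- generate_transition_data(cohort$meta, config)

# two-pass quantitation: flag interference, then re-quantify without it
flags <- audit_flag(sim$transitions)$per_transition
quant <- quantify_transitions(
  sim$transitions,
  exclude_transitions = dplyr::filter(flags, interfered))

qc <- run_qc(quant, sim$transitions, cohort$meta)
tab <- assemble_analysis_table(quant_matrix(quant), cohort$meta)

sp <- split_train_test(cohort$meta, test_fraction = 0.2, seed = 1)
train <- dplyr::filter(tab, sample_id %in% sp$train)
test <- dplyr::filter(tab, sample_id %in% sp$test)

search <- panel_search(train, c("ca199", qc_survivors(qc)),
                       anchor = "ca199", seed = 1)
model <- train_panel(train, search$markers[[1]], seed = 1)
anchor_cut <- sensitivity_at_specificity(log10(train$ca199),
                                         train$is_case, 0.9)
run_scenarios(model, test, anchor_cutoff = anchor_cut$cutoff)
```

The scenario report contains, per comparison block (control vs PDAC,
control vs stage I/II, other cancers vs PDAC, benign vs PDAC, and each
restricted to CA19-9 < 37 U/mL): both AUCs with the paired DeLong test,
sensitivity/specificity at the transferred cutoffs with the paired
McNemar test, and PPVs.

# Numerical and design choices worth knowing

- **Positive rule** is `score ≥ cutoff`; the boundary convention is
  stated rather than standard.
- **Exact/asymptotic McNemar switch** at discordant count 25 is a common
  convention; both branches are conservative, which matters when
  auditing type-I error empirically.
- **Degenerate DeLong variance** (identical score vectors) returns
  p = 1 with a flag instead of dividing by zero.
- **Orientation**: single inverted markers (e.g. transthyretin, lower
  in disease) are handled by the fitted orientation sign, so users never
  pre-negate columns.
- **Leakage discipline**: standardization constants, fold assignments,
  the SVM, and both cutoffs derive from training data only; the test
  suite checks that deleting the test set yields byte-identical
  serialized models.
- **Missing data**: complete-case within the searched marker set,
  counted and reported; consistent with substantial real-world CA19-9
  missingness being dropped rather than imputed.

# Limitations

- The generator's markers are conditionally independent log-normals;
  real plasma proteins are correlated, so real panel gains are usually
  smaller than the independent-marker arithmetic suggests.
- Interference is modeled as an additive light-channel bias with a
  sample-independent magnitude; real interferences co-elute variably.
- The two-stage selection's default gates (7% AUC gain, 10% sensitivity
  gain) are demanding: with an anchor at AUC 0.82, two independent
  added markers need single-marker AUCs well above 0.70 before the
  *expected* gain clears 0.07 (the binormal combination of 0.82 with
  two 0.70 markers is ≈ 0.88–0.89). Panels that merely rank first will
  often, correctly, fail the gates.
- No survival analysis, cost-effectiveness, or clinical decision
  thresholds beyond the fixed-specificity rule.
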