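---
title: "Threshold panels and partial-AUC evaluation for TBI outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold panels and partial-AUC evaluation for TBI outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbipanel)
```

## The problem

After a traumatic brain injury (TBI) with visible lesions on head CT, the
clinical question is who will recover. Functional outcome is graded on the
Glasgow Outcome Scale—Extended (GOSE, 1–8) months after injury, dichotomized
as favorable (GOSE 5–8) vs. unfavorable (GOSE 1–4), or complete recovery
(GOSE 8) vs. incomplete (GOSE < 8). Two complementary sources of prognostic
signal are (i) the structural injury pattern on the admission CT, summarized
by the Helsinki CT score (HCTS), and (ii) admission plasma levels of
brain-derived protein biomarkers (Aβ40, Aβ42, GFAP, H-FABP, IL-10, NF-L,
S100B, t-tau, all in pg/ml).

A prognostic rule used for triage must miss almost no patient who will do
badly, so performance is evaluated *at fixed high sensitivity*: every
statistic in this package is computed under the constraint sensitivity
≥ 90%, and ROC curves are compared by the partial AUC (pAUC) over the
90–100% sensitivity band. The useful question is then how much *specificity*
a rule can achieve there — how many patients headed for a good recovery can
be spared an intensive-monitoring pathway.

## The Helsinki CT score

The HCTS sums integer weights over structured CT findings: subdural
hematoma (+2), intracerebral hematoma/contusion (+2), epidural hematoma
(−3), any mass lesion over 25 cm³ (+2), intraventricular hemorrhage (+3),
and the suprasellar cistern state (normal 0, compressed +1, obliterated +5).
The achievable range is exactly −3 to 14 (the package verifies this by
exhaustive enumeration of all 2⁵ × 3 findings combinations). The weight
table ships as a versioned JSON constant (`inst/extdata/hcts_weights.json`)
rather than hard-coded, so a revised or alternative CT score can be swapped
in; `score_hcts()` reads it at run time. Dichotomization is strictly
greater-than (`classify_hcts(score, threshold)` is `score > threshold`),
matching the conventional "HCTS > 1" notation. A recorded mass lesion > 25
cm³ without any mass-lesion type flag triggers a warning, not a rejection,
because lesion types and lesion size are tallied independently in practice.

## ROC machinery

`build_roc()` constructs the empirical ROC of a score with strict
comparisons (`> t`, or `< t` for markers whose *low* values flag the adverse
outcome, as happens for IL-10 inside panels). Every attained sensitivity is
a multiple of 1/n_events and every specificity a multiple of
1/n_non-events; with 33 events the grid explains reported values such as
97.0% (= 32/33) and 90.9% (= 30/33).

The partial AUC integrates specificity as a function of sensitivity over a
band (default 0.90–1.00), with linear interpolation between adjacent
operating points and exact partial trapezoids at the band edges. It is kept
on the unit-square scale and *not* renormalized: the ceiling for the
0.90–1.00 band is 0.10 (reported as 10%), a perfect classifier attains it,
and the chance diagonal contributes ∫₀.₉¹ (1 − s) ds = 0.005 (0.5%). Both
limits are checked to 1e−9 in the tests. On the full band the pAUC equals
the ordinary AUC, which the tests cross-check against an independent
implementation (pROC).

`operating_point_at_sensitivity()` returns, among attained points with
sensitivity ≥ the constraint, the one maximizing specificity (ties toward
higher sensitivity, then the more extreme threshold). Because the
(sensitivity 1, specificity 0) endpoint always qualifies, a marker that
cannot operate in the band is reported at that trivial point with threshold
"–" rather than dropped.

Confidence intervals use a stratified bootstrap: patients are resampled
with replacement within outcome classes (so replicates keep both classes
and the class sizes), the statistic is recomputed on each replicate, and
the 95% percentile interval is reported. The default is 2000 replicates
under a fixed seed recorded in the report metadata. The interval method and
replicate count are package choices — they are the community defaults, and
interval endpoints should be read as reproducible-but-conventional rather
than as canonical values.

## Threshold panels

A panel is a set of one to three marker rules — each a strict threshold
with a direction, e.g. `HCTS (>4) + IL-10 (<0.48 pg/ml) + Aβ40 (>7.38
pg/ml)` — combined through a minimum-positive-count cut: a patient is
panel-positive when at least `min_positive` rules are satisfied. The
panel's own ROC is built from the integer rule count (operating points at
every cut 1..size), so its pAUC, sensitivity and specificity are directly
comparable with single markers.

`optimize_panel()` searches exhaustively over marker subsets (size ≤ 3),
per-marker candidate thresholds, both directions, and all decision cuts.
Candidate thresholds come from `candidate_thresholds()`: midpoints between
consecutive distinct observed values (the exhaustive grid — any threshold
between the same two data points classifies identically), or a 19-point
equally spaced quantile grid for larger cohorts. The objective is
lexicographic: among candidates with sensitivity ≥ 90%, maximize
specificity, then pAUC, then prefer smaller panels, then a deterministic
lexicographic order over marker names, thresholds and the decision cut. The
specificity-first ordering reflects the clinical framing above: the
sensitivity floor is a constraint, specificity is the payoff, and pAUC
summarizes robustness of the neighborhood. If nothing attains the
constraint the sensitivity-maximizing panel is returned with
`constraint_met = FALSE` — never a silent fallback.

The search is exact, not heuristic: counting patients who satisfy ≥ m of
the rules reduces by inclusion–exclusion to single, pairwise and triple
rule-intersection counts, computed for all threshold combinations at once
as cross-products of 0/1 indicator matrices. Nine markers on a 19-point
grid with both directions is about 10⁷ candidate panels and runs in roughly
a second; the tests verify exact agreement with brute-force enumeration on
100 small cohorts and recovery of planted AND-rules.

Two handling choices are worth stating. Within `evaluate_panel()` records
missing any panel marker are excluded listwise per panel (the exclusion
count is reported). Within `optimize_panel()` exclusion is listwise across
the whole candidate pool instead, so that every candidate panel is scored
on the same patients — otherwise the search would compare specificities
computed on different denominators. Second, an integer severity score such
as the HCTS is conventionally restricted to `positive_if_greater` in the
search (`directions = c(hcts_sum = "positive_if_greater")`); biomarkers
search both directions, which is how a low-IL-10 rule can enter a panel.

## Group comparisons

`mann_whitney_u()` implements the two-sided Mann–Whitney U test with
midrank ties; for combined n ≤ 12 the null distribution is enumerated
exactly over all label assignments, otherwise a normal approximation with
tie-corrected variance and continuity correction is used (conventions match
the standard reference implementation, against which the tests check both
branches). `summarize_cohort()` emits the usual two-group table: Welch
t-tests for normally distributed demographics, Mann–Whitney for skewed or
ordinal variables, proportion tests for categoricals. The variable-to-test
mapping is *declared*, never inferred from normality screening, so the
table is deterministic; Welch rather than pooled-variance t is the default
and is surfaced in the output. No multiplicity correction is applied.

## The synthetic cohort generator

Patient-level data behind studies of this kind are typically available only
on request, so the package ships a generator that emulates the printed
statistical structure and makes the whole pipeline testable end to end:

* cohort split 137 = 82 CT-positive (49 favorable + 33 unfavorable) + 55
  CT-negative (51 + 4);
* biomarkers drawn from lognormal distributions fitted to per-group
  median/IQR pairs. The lognormal family is the deliberate choice here:
  strictly positive, right-skewed, two-parameter — identifiable from
  exactly the pair of summaries that gets printed.
  `fit_lognormal_from_median_iqr()` sets the log-location to log(median)
  and solves for the log-scale by bracketed monotone root-finding to an IQR
  residual below 1e−9 (a closed form via asinh exists and serves as the
  test oracle);
* CT findings sampled independently per feature at the per-outcome-group
  prevalences (26/33 unfavorable vs. 27/49 favorable subdural hematomas,
  etc.); CT-negative patients carry all-negative findings and score 0;
* GOSE sampled within the dichotomy, with the complete-recovery (GOSE 8)
  frequency matched to its published rate; an S100B value below the assay
  detection floor is replaced by 1 pg/ml, per the stated substitution rule;
* a sampling-delay covariate (truncated normal, 13.1 ± 10.4 h, floor 0) for
  interface completeness — it enters no statistic.

Only the NF-L and Aβ42 per-group distributions are published; those are
encoded as printed and flagged `provenance = "published"`. The remaining
marker distributions are documented placeholders flagged `"assumed"`:
realistic in scale and ordering, but not data. Tests and the acceptance
script treat only structural quantities (group sizes, the published
median/IQR pairs, score ranges) as reference values, never the assumed
ones.

What passing tests on synthetic cohorts do *not* show about real data: the
generator samples markers independently of each other and of the CT
findings given the outcome group, has no lesion–lesion correlation, no
informative missingness, and lognormal tails rather than whatever the true
assay distributions are. Panel performance numbers on synthetic cohorts
therefore validate the *machinery* (search exactness, constraint handling,
reproducibility), not the clinical effect sizes.

## Numerical conventions

* All threshold comparisons are strict (`>`/`<`); equal-to-threshold is
  negative, and the min-positive cut is inclusive.
* Reporting rounds half away from zero to one decimal in percent
  (`round_half_up()`), applied only at the formatting layer; every internal
  comparison uses exact fractions and tolerances of 1e−9 or tighter.
* Tie-breaks everywhere are deterministic and documented (ROC operating
  point: specificity, sensitivity, extreme threshold; panel search:
  specificity, pAUC, parsimony, lexicographic order).
* Degenerate inputs are explicit errors ("degenerate cohort" for
  single-class labels, empty confusion margins) or flagged rows (constant
  markers, infeasible constraints) — never silent.
* Every stochastic step (generator, bootstrap) takes a seed, runs under a
  preserved RNG state, and is byte-reproducible; identical seeds give
  byte-identical CSV and JSON outputs.

## Problem sizes used by the test suite

The suite keeps its heavier properties at deliberately modest sizes chosen
to make the checks sharp rather than slow: brute-force oracle comparisons
on 100 cohorts of ≤ 12 patients × 3 markers; planted-panel recovery over 20
seeded cohorts of 42 patients; Mann–Whitney type-I calibration over 2000
null simulations at the study's 49/33 group sizes; generator fidelity at
10⁵ oversampled draws (median/IQR within 5%). The full default pipeline —
generate, score, single-marker tables, panel optimization — runs in well
under a minute on one CPU.

## Known limitations

* The panel search is exhaustive by design and scales as (grid × 2)^3 per
  marker triple; beyond ~10 markers or very fine grids it needs a coarser
  quantile grid (the engine refuses grids past 5 × 10⁷ cells rather than
  degrade silently).
* Bootstrap percentile intervals can be degenerate at the extremes (e.g. a
  specificity of exactly 0 or 1 in nearly all replicates); the panel-level
  intervals also condition on the *fixed* panel definition and do not
  propagate search/selection optimism. With 82 patients, re-running the
  optimizer inside the bootstrap would mostly measure overfitting noise;
  external validation, not resampling, is the honest check for that.
* `min_positive` of a reported panel is a searched quantity; published
  panel descriptions often omit it, and a joint sensitivity/specificity
  pair generally cannot disambiguate it without patient-level data.
* The generator's assumed marker distributions make absolute synthetic
  panel performance arbitrary; only structure-driven quantities are stable
  across seeds.
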