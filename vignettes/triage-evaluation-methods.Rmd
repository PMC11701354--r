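---
title: "Methods: evaluating a two-stage SCS triage rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating a two-stage SCS triage rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scstriage)
```

## The pathway and its model

The package models a two-stage triage of chronic low-back-and-leg-pain
patients on an orthopaedic waiting list towards spinal-cord-stimulation
(SCS) consultation. Stage 1 is algorithmic: a strict conjunction of six
including indicators over patient-reported outcomes (prior back surgery;
leg/mixed pain location; DN4 > 3; pain duration ≥ 3 months; NPRS leg ≥
NPRS back; NPRS leg ≥ 5) and seven excluding indicators that must all be
absent. Stage 2 — the orthopaedic review of stage-1 positives — and the
final referral decision are *clinical* judgements the package deliberately
does not model: they enter as external labels, latent Bernoulli gates in
synthetic mode or a reference CSV in data mode.

Threshold semantics are taken literally from the rule as circulated: DN4 is
strictly greater than 3 (so 4 is the minimal satisfying integer), duration,
NPRS-leg and the leg-vs-back comparison are inclusive (3.0 months, 5, and
equality all satisfy), and age ≤ 18 excludes. `evaluate_boundaries()`
prints this so the semantics are inspectable rather than implicit. Two rule
profiles ship as YAML data: the full `"table1"` profile and an
`"abstract_5"` variant without the prior-surgery requirement — both
circulate in descriptions of the tool, and we surface the discrepancy
instead of silently resolving it.

Missing data: only the DN4 score may be missing (it was a late addition to
the PROM set in the pathway this emulates). A record whose only failures
are missing fields is negative; under the default
`missing_policy = "review"` it is additionally flagged for manual review.
Every indicator is always evaluated — no short-circuiting — so the
per-indicator satisfaction vector is complete for audit.

## The synthetic generator

`generate_cohort()` emulates a heterogeneous waiting-list cohort. Latent
stage-1 qualifying status is Bernoulli with the observed prevalence 90/1025;
qualifying records are drawn to satisfy every indicator, non-qualifying
records from marginal distributions with any accidental qualifier given one
randomly violated indicator. The stage-2 and referral gates are conditional
Bernoulli draws with probabilities 20/90 and 8/20, so the default
1025-patient cohort reproduces the funnel 1025 → 90 → 20 → 8 in
expectation, and the nesting referred ⊆ stage-2 ⊆ stage-1 holds in every
realisation.

The source pathway does not publish its PROM distributions (its
patient-characteristics table is supplementary and unavailable), so the
marginals are documented placeholders chosen once for plausibility: NPRS
scores uniform-discrete on their scales conditioned on qualifying status,
pain duration log-normal with median 24 months, DN4 binomial(10, p) with
p = 0.65 for qualifying (truncated to > 3) and 0.30 otherwise, age normal
(mean 55, SD 13) truncated to adulthood for qualifying patients, and small
per-flag exclusion probabilities. All are overridable via
`cohort_marginals()`. No correlation structure beyond what the rule forces
is modelled; passing tests therefore show the *evaluation machinery* is
correct under known conditions, not that real PROMs look like this.

DN4 missingness is missing-completely-at-random at `dn4_missing_rate`
(default 0 so accuracy analyses are clean); no imputation is attempted.

The rater simulator is a latent-class model: each rater calls a truly
eligible subject positive with probability `p_correct_positive` and a truly
ineligible one negative with `p_correct_negative`, conditionally
independently given the latent label. The default panel (0.97/0.97,
0.95/0.96, 0.88/0.92, 0.93/0.94) represents an experienced mixed clinical
panel — two pain specialists, a neurosurgeon, a nurse specialist — with
substantial but imperfect agreement; the exact values are scaffolding, not
estimates, and nothing downstream asserts the kappas they induce. The
rating subsample is stratified (up to half triage-qualifying) because at
the cohort's ~9% prevalence an unstratified 50-patient sample would leave
kappa dominated by a handful of positives.

`generate_sus_responses()` builds integer Likert sets whose item means hit
requested targets. Since printed item means are two-decimal roundings
(4.17 = 25/6), "achievable" is defined as a nearest integer column total
within `mean_tol = 0.005` of the target mean; unreachable targets error,
naming the item. A seeded sum-preserving perturbation spreads responses
across respondents without moving any item mean — consequently the
between-respondent SD is an artefact of that spread and is *not* calibrated
to any reported dispersion.

## The evaluation battery

**Accuracy.** The 2×2 table compares the stage-2 (fast-track) triage
indication with the referral decision — the convention of the reported
worked example, whose indication row totals 20, so stage-1-only patients
count as negatives. Se, Sp, PPV, NPV are exact ratios; a zero-denominator
metric is an explicit undefined marker, never NaN or 0. Three CI methods
are implemented: Clopper–Pearson (default), Wilson score, and the
rule-of-three 3/n bound for degenerate 0-of-n / n-of-n cells (requesting it
for interior counts is an error). The method is named in every report
because the worked example's printed intervals are not jointly consistent
with any single standard construction — only its NPV bound (1 − 3/1005 ≈
99.7%) is recoverable, via the rule of three. Percentages are rounded
half-up to one decimal for display; raw proportions are retained.

**Reliability.** Cohen's κ uses the two raters' own marginals; Fleiss' κ
pools category proportions across raters (and equals Scott's π for two
raters — a documented, tested identity, not an accident). Specific
agreement follows the standard paired-table decomposition positive =
2a/(2a+b+c), negative = 2d/(2d+b+c). Degenerate case: when expected
agreement is exactly 1 (a single shared category), κ is defined as 1 if
observed agreement is also perfect and undefined (`NA`) otherwise — a
documented convention, since the statistic is otherwise 0/0. Pairs are
flagged reliable at κ ≥ 0.70. Multi-rater positive/negative agreement is
pooled as the unweighted mean over the six rater pairs and labelled as
such, the pooling scheme being unspecified in the source reporting.
Kappas are displayed to two decimals; raw values retained. Weighted kappa,
>2 categories and kappa CIs are out of scope (the triage call is binary
and no kappa intervals are reported for it).

**Usability.** Standard SUS scoring; the transform is affine in the items,
so the mean of per-respondent scores equals the transform of the item
means — an exact identity the tests exploit and that justifies
reconstructing the reported mean (74.2) from printed item means. The SD
uses the sample (n − 1) convention; with one respondent it is an undefined
marker. Item benchmarks are the published per-item means, compared
strictly (> for odd, < for even items, exactly as printed; a mean exactly
at its benchmark fails). Grade bands are data, not code: the published
curved letter-grade edges and adjective anchors (a score maps to the
nearest anchor). Note the published letter bands place 74.2 in "B"
(74.1–77.1); some secondary reports of the same score say "B+" — we follow
the published band edges. The published all-study average of 68 is exposed
as `meets_average`.

## Numerical and design choices

- Determinism: every stochastic function requires an explicit seed and
  restores the caller's RNG state; identical config + seed yields a
  byte-identical JSON report (no timestamps are written).
- Exact integer arithmetic wherever possible (table counts, SUS totals);
  the only tolerances in the test suite are 1e-12 for algebraically exact
  identities and 3-binomial-SD / 0.02-kappa bands for Monte-Carlo checks.
- Problem sizes: law-of-large-numbers funnel checks use n = 10^5; rater
  Monte-Carlo checks n = 5 × 10^4; oracle sweeps 500–10^4 random
  instances. These sizes put Monte-Carlo error well below the assertion
  bands while keeping the default suite fast.
- CSV dialect: UTF-8, header row, comma separator, booleans "true"/"false",
  empty cell = missing — chosen so files are language-neutral.

## What the tests do and do not show

The oracle suite verifies the rule engine against an independent
brute-force evaluation (including the complete 2^13 satisfy/violate truth
table, of which exactly one pattern is positive), the kappas and agreement
against direct cross-tabulation arithmetic and closed-form expectations
under the simulator, the CIs against `binom.test`/`prop.test`, and the SUS
transform against per-respondent brute force. What they cannot show: the
original study's rater-level data are unpublished, so its specific kappas
(0.66–0.95 pairwise, 0.79 Fleiss, 0.89 intra-rater), agreement percentages
and score SD are not reproducible here — the machinery that would compute
them from raw ratings is what is validated. Likewise the synthetic cohort
demonstrates correct bookkeeping at the reported prevalences, not clinical
realism of the PROM marginals.
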