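---
title: "Three-source capture-recapture: models, linkage and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-source capture-recapture: models, linkage and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recap3)
```

# The estimation problem

A closed population — here, the general practitioners active in a
country in one reference year — is covered by three administrative
lists, each incomplete: a hospital survey (A), a ministry
human-resources bank (B), and a practice-licensing bank (C). Counting
the union of the lists undercounts the population by everyone on no
list. Capture-recapture treats list membership as three capture
events: cross-classifying individuals by their capture history gives an
incomplete 2^3 contingency table whose eighth cell (pattern 000) is
structurally missing, and a model fitted to the seven observed cells
projects it.

# The model family

We model the seven observed cell means with hierarchical Poisson
log-linear models: intercept, three main effects, and any subset of the
three pairwise interactions AB, AC, BC — eight models, with 4 to 7
parameters. The main effects absorb unequal list sizes; a pairwise
interaction absorbs dependence between two lists (for instance,
hospital-employed physicians being more likely to appear in the
ministry bank). The three-way interaction is never included: with seven
observations it would make the projection non-identifiable, so its
absence is the family's core assumption, alongside closure (no entry or
exit during the reference period) and perfect linkage (the table's
counts are the true overlap).

Under treatment (0/1) coding every non-intercept covariate is zero at
pattern 000, so each fitted model projects the unobserved cell as
`exp(intercept)` and estimates the total as `N = exp(intercept) +
n_obs`. Every model with at least one interaction also has a
closed-form maximum-likelihood estimator in the seven cells (for
example `n100 * n010 / n110` when AC and BC are present); the package
keeps both routes and the test suite requires them to agree to 1e-6
relative on hundreds of random tables — the closed forms act as an
independent oracle for the iterative fit.

## Fitting and numerical choices

* Fitting is IRLS with step-halving on the 7-cell Poisson likelihood
  (`stats::glm.fit`), converging when the relative deviance change
  falls below 1e-10, capped at 100 iterations. The design is tiny and
  fixed, so exactness is cheap.
* A parameter whose sufficient statistic is zero (for example the AB
  interaction when `n110 = n111 = 0`) is inestimable; the fit refuses
  with an error naming the offending cells rather than returning a
  divergent coefficient.
* Zero cells get no continuity correction by default; closed forms with
  a zero denominator raise an explicit infinite-estimate error. We
  prefer loud failure over silent smoothing on tables this small.
* Model selection minimises AIC, with ties broken by BIC and then by
  parsimony. AIC and BIC are deviance-based (`G2 + 2p`,
  `G2 + p log n_obs`); they differ from the full-likelihood versions by
  a model-independent constant, so ranking — the only thing selection
  uses — is unaffected.
* The confidence interval for N is log-normal on the projected cell:
  the delta-method standard error of `log x000` is the intercept entry
  of the inverse Fisher information, and the interval is
  `n_obs + x000 / C` to `n_obs + x000 * C` with
  `C = exp(z * se)`. A published interval for the physician study
  (51,578–55,899 around 53,630) is asymmetric in exactly the way this
  family produces, and the package reproduces its endpoints to within a
  few units, which is why this construction was adopted; the original
  report does not state its method.
* Estimates stay real-valued everywhere; rounding to whole persons
  happens only when a report is rendered.

# Record linkage

The linkage stage is deliberately deterministic: an exact-match cascade
over normalized keys with precedence council code > national ID >
name+surname. The council code is the profession's registry identifier
and the designated primary key; the lower tiers only act for records
the higher tiers could not key, so two records with distinct council
codes are never merged through a shared lower-tier key — such
cross-tier disagreements are logged as conflicts and the code-distinct
entities stay separate. Ambiguous lower-tier matches (an ID claimed by
two code-distinct entities) likewise form their own entity rather than
guessing; this keeps the result invariant to row order. Records with no
usable key at all are excluded from tabulation with a warning and
counted in the audit log. There is no phonetic or edit-distance
matching: the upstream study linked through a reference bank by exact
identifiers, and probabilistic linkage would add a tuning surface the
estimator cannot audit.

Missing council codes can be filled from a reference roster
(`enrich_from_reference()`), only when the reference yields exactly one
candidate code.

# The synthetic registry

`build_truth()` defines the generating model at the cell-probability
level: the eight pattern probabilities are the softmax of the same
log-linear predictor the fitted family uses. Generating at this level
(rather than through per-person latent heterogeneity) matches the
estimand exactly: a model fitted with the generating interaction set is
correctly specified, so parameter-recovery and coverage tests measure
the estimator, not a model-mismatch artefact.

Default coefficients are `lambda_main = (-0.551, -1.814, -1.197)` and
`lambda_pair = (0.855, -0.407, 0.286)`. They were set by solving the
saturated model on the reconstructed cell table of the physician study,
so the defaults emulate that study's conditions: list A the largest,
strong positive A–B dependence, negative A–C dependence, and about 40%
of the population on no list. The default simulated population is
53,630, the study-scale total.

`corrupt_and_write()` renders histories as roster CSVs with identifier
damage: council codes blanked at rate 0.10, national IDs at 0.05,
within-source duplicate rows at 0.02, and adjacent-character name
transpositions at 0.05. The study reports that missing codes had to be
sought through other identifiers but not how often; these defaults are
of the order an analyst of administrative registers would call a
moderately dirty extract, and they exercise every tier of the cascade
(at the defaults, linkage accuracy against the truth sidecar is about
0.99). Identifier tokens are synthetic zero-padded integers and names
are ASCII tokens; script-specific name handling is out of scope. All
randomness flows through explicit per-operation seeds, and outputs are
byte-identical across reruns.

What the generator does *not* emulate: per-person capture
heterogeneity, behavioural response, geography-correlated coverage, or
realistic name-frequency distributions. Passing tests therefore show
the estimator and linkage machinery are correct under the assumed
model, not that the model holds for any particular real registry.

# Reconstructing a published overlap table

The motivating study prints, for each model, only the projected cell X
and derived statistics — not the seven observed counts. Because seven
of the eight models have closed-form estimators, the seven printed X
values form a solvable system in the seven cells. `recover_cells()`
reduces it to three equations in (n100, n010, n001) — the other four
cells follow in closed form — and solves: a damped fixed-point
iteration is tried first (it diverges on the published values, whose
quotient map is not a contraction from any start we found), then
least-squares root-finding on the log scale, followed by a Newton
polish to machine precision. The recovered table has n_obs ≈ 32,201,
matching the constant N − X difference across the published
dependent-model rows, and refits reproduce every printed X within
rounding.

Two reconstruction findings are worth recording. First, the published
combined-list count after deduplication (27,048) is not the observed
total the models were fitted to (32,201 by the N − X identity); the
package reports both completeness ratios and does not attempt to
reconcile them. Second, the published AIC column equals `G2 + 2p` plus
a constant ≈ 69.9 on seven of the eight rows; the remaining row
(AC/BC) breaks the offset and prints BIC > AIC, consistent with a
misprint, so the tests check ranking and pairwise AIC differences
excluding that row, and absolute printed AIC/BIC are not reproduction
targets. The independence model, which never enters the inversion, is
the reconstruction's hold-out: its fit on the recovered table lands on
the printed X (16,353.43) and deviance (1,617.56) within 0.1%.

# Stratified estimation

`stratified_fit()` fits per stratum (for example per province) under
either a `"global"` policy — one model, selected on the pooled table,
fitted everywhere — or `"per-stratum"` selection. The source study does
not say which it used; the global policy is the default here because
31 small tables make per-stratum selection noisy, and a simulation test
checks that uniformly split strata re-add to the pooled estimate within
5%. Published per-province figures are not reproduction targets: the
per-province cell counts are not printed, and the published
"completeness" column there does not equal reported/estimated for any
row we checked (e.g. 179/217 = 82.5%, printed as 97), so its definition
is unknown and only the ratio definition is implemented.

# Problem sizes in the test suite

The suite validates estimator equivalence on 200 random tables × 7
models, parameter recovery over 200 replicates and interval coverage
over 500 replicates at a true population of 50,000, and
linkage round-trips at populations of 1,200–4,000 — sizes at which
multinomial noise is small relative to the tolerances being asserted
while the whole suite stays interactive (well under a minute).
Acceptance thresholds: median relative error of N below 2%, nominal-95%
coverage at least 90% (Monte-Carlo slack), closed-form agreement 1e-6.

# Known limitations

* Independence-model projections have no closed form and rely solely on
  the IRLS route (this is also why that model can serve as the
  reconstruction hold-out).
* The family cannot express three-way list dependence or per-person
  heterogeneity; if the saturated model is selected (as in the
  motivating study), its G2 is zero by construction and goodness of fit
  cannot arbitrate further.
* Deterministic linkage treats any surviving identifier corruption as
  genuine non-overlap, which biases overlap cells downward and the
  population estimate upward; the synthetic sidecar exists precisely to
  quantify that distortion under assumed corruption rates.
* Confidence intervals ignore linkage uncertainty; they are
  model-based, conditional on the table.
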