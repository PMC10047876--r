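---
title: "Models and methods behind schrothagree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind schrothagree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schrothagree)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the validation suite does and does not
demonstrate.

## 1. The classification rule engine

Schroth therapy distinguishes four curve patterns — `3c`, `3cp`
(thoracic-major) and `4c`, `4cp` (thoracolumbar/lumbar-major), with the
`p` suffix marking an imbalanced pelvis — from four boolean postural
judgements: whether the pelvis is balanced (not displaced relative to
midline), whether the lumbar and pelvis blocks deviate in the same
direction ("coupled"), whether a prominent hip is observed, and whether
the thoracic prominence is judged more significant than the lumbar one.

The decision tree evaluates pelvis balance first. An unbalanced pelvis
is resolved by the coupling check: coupled gives `3cp`, uncoupled
`4cp`. A balanced pelvis is resolved by the prominence comparison:
thoracic dominant gives `3c`, otherwise `4c`.

Two points of this tree were genuinely open and are resolved as
package design choices:

* **Totality of the balanced branch.** Clinical instructions for the
  balanced-pelvis branch also ask the assessor to confirm that the
  pelvis is uncoupled from the lumbar spine and to look for a prominent
  hip, without stating an alternative outcome when those checks fail.
  The engine records both findings in the decision trace as
  confirmatory observations but lets the prominence comparison decide
  `3c` versus `4c` unconditionally, making `classify_curve_type()` a
  total, deterministic function over all 16 feature combinations —
  a property the test suite asserts exhaustively.
* **Ties in prominence.** `3c` requires the thoracic prominence to be
  judged *more* significant; a tie therefore classifies as `4c`. The
  boolean `thoracic_dominant` must be set `FALSE` on ties by the
  caller; the engine has no tie state of its own.

Curve laterality (left/right convexity) is not part of the label; the
engine classifies pattern only. Features are human-supplied booleans —
there is deliberately no image or video analysis.

## 2. Agreement statistics

All reliability statistics operate on a subjects × raters
`rating_matrix` with `NA` for missing ratings and a fixed category
list. With `r_ik` the number of raters placing subject `i` in category
`k`, `r_i` the subject's non-missing rating count, and a symmetric
partial-credit weight matrix `w` (unit diagonal, entries in `[0, 1]`):

$$p_a = \frac{1}{n'} \sum_{i:\, r_i \ge 2} \sum_k
  \frac{r_{ik}\,(r^*_{ik} - 1)}{r_i (r_i - 1)},
  \qquad r^*_{ik} = \sum_l w_{kl}\, r_{il},$$

$$\pi_k = \frac{1}{n} \sum_i \frac{r_{ik}}{r_i}, \qquad
  p_e = \frac{T_w}{q(q-1)} \sum_k \pi_k (1 - \pi_k),
  \qquad T_w = \sum_{k,l} w_{kl},$$

and the coefficient is $(p_a - p_e)/(1 - p_e)$. Identity weights
reduce $p_a$ to the fraction of agreeing rater pairs and the
coefficient to the unweighted AC1; the weighted and unweighted paths
are literally the same code, so the reduction is exact by
construction. AC1's chance term is built from category marginals
rather than per-rater classification probabilities, which avoids the
well-known paradoxes of kappa when prevalence is skewed — relevant
here, since the four curve types are far from equiprevalent.

**Missing ratings.** Subjects with fewer than two ratings cannot
contribute an agreeing pair and are excluded from $p_a$ (its
denominator is $n'$, the count of subjects with $r_i \ge 2$), but
their available ratings still inform the marginals $\pi_k$. The
category count `q` stays fixed at the declared list even if a rater
never used a category.

**Why the partial-credit weights.** The shipped default
(`schroth_weights()`) encodes exercise-prescription similarity: 0.75
between patterns differing only in pelvis balance (`3c`/`3cp`,
`4c`/`4cp`), 0.50 between the two balanced-pelvis patterns
(`3c`/`4c`), and 0.00 for pairs whose corrective exercises act in
opposite directions or on different regions. Misclassifying within a
high-weight pair changes little of the prescribed programme, so it is
sensible for the headline clinical statistic to discount it.

**Variance and intervals.** The standard error is a subject-level
delete-one jackknife: the coefficient is recomputed with each subject
removed and the usual jackknife spread formula applied. It was chosen
over a closed-form linearisation because it is estimator-agnostic (the
same code serves the unweighted, weighted and percent-agreement
statistics), transparent, and cheap at these problem sizes (44
leave-one-out replicates). Confidence intervals are normal
approximations, truncated above at 1 and not truncated below, giving
symmetric intervals except at the ceiling. Degenerate inputs are
refused loudly: no subject with two ratings, or a weight matrix making
$p_e = 1$, are errors, not silent `NaN`s.

**Intra- versus inter-rater.** `intra_rater()` treats one rater's two
occasions as a two-"rater" matrix, so test-retest reliability reuses
the multi-rater machinery unchanged. `inter_rater()` runs over all (or
a subset of) raters at one occasion. Because a two-occasion study has
two equally valid inter-rater coefficients, `run_pipeline()` reports
both occasions *and* their Fisher-pooled value, rather than silently
choosing one.

## 3. Pooling, benchmarking, precision

Per-rater coefficients are averaged on the Fisher scale:
$z_j = \operatorname{atanh}(c_j)$, pooled value
$\tanh(\bar z)$. The pooled CI uses the standard error of the mean
transform, $\mathrm{sd}(z)/\sqrt{m}$, back-transformed — a CI for the
mean coefficient of the observed panel, not a prediction interval for
a new rater. Pooling a single coefficient returns it unchanged, and
the pooled value always lies within the input range.

Exact ±1 coefficients have an infinite transform, so `fisher_pool()`
refuses them. Inside `run_pipeline()`, where a perfect simulated rater
is legitimate, boundary values are clamped to $1 - 10^{-12}$ before
pooling; the pooled estimate is then 1 to well below reporting
precision while remaining defined.

Interpretation uses a subtractive critical value: the band label
(poor / slight / fair / moderate / substantial / almost perfect, with
Landis–Koch-style cut points at 0, 0.21, 0.41, 0.61, 0.81) is looked
up for `estimate − critical_value`, so only agreement confidently
above chance is interpreted. The critical value is a configurable
constant defaulting to 0.08, the tabulated value for a design with 44
subjects, 10 raters and 4 categories; deriving the critical-value
table itself is out of scope. The clinical-adequacy flag is separate
and applies to the raw estimate: adequate iff ≥ 0.61 (inclusive).

The study precision criteria operate on percent agreement: the
coefficient of variation (jackknife se over percent agreement) must be
≤ 0.15 and the relative error ≤ 0.20. "Width of the confidence
interval" is ambiguous between half- and full-width; the package
computes both (`relative_error`, `relative_error_full`) and flags the
half-width, erring on the transparent side rather than guessing.

## 4. The synthetic study generator

`simulate_study()` emulates a two-occasion, multi-rater classification
study. Its defaults *are* the reference study conditions: 44 subjects
whose true types are drawn with prevalence 9/44, 12/44, 6/44, 17/44
over (`3c`, `3cp`, `4c`, `4cp`), rated twice by a panel of ten raters,
with occasional missing ratings.

Each rater is three parameters:

| parameter | meaning | default tiers |
|---|---|---|
| `accuracy` *a* | P(assigning the true category) | 0.90 / 0.75 / 0.60 |
| `consistency` *c* | P(occasion-2 label copies occasion 1) | 0.30 / 0.25 / 0.20 |
| `missing_rate` | P(a rating is never recorded) | 0.01 |

The panel comprises two "experienced" raters (a = 0.90), four more
"well-trained" raters (0.75), and four less-trained raters (0.60); the
well-trained subgroup of six is defined as the experienced pair plus
the four — real rater pools do not state whether their subgroups nest,
so the simulator simply fixes a nesting. Consistency is deliberately
low: the two rating occasions are a blinded week apart, so test-retest
agreement should be driven by accuracy, not recall. With these values
the expected intra-rater percent agreement spans roughly 0.55–0.87
across the panel, matching the spread a heterogeneous therapist panel
shows in practice. The 1% missing rate reproduces the occasional
skipped video (a 43-of-44 denominator for one rater).

Misclassification is structured, not uniform: given truth `t`, the
confusion row puts mass `a` on `t` and spreads `1 − a` over the other
categories *in proportion to their partial-agreement weight with* `t`,
with zero weights floored at ε = 0.05 so every confusion remains
possible. This encodes the clinical reality that near categories
(`3c`↔`3cp`, `4c`↔`4cp`) are the confusable ones — and it is an
assumption: no empirical confusion table exists to calibrate against.
The occasion-2 model (copy with probability `c`, else a fresh
confusion draw) was chosen over correlated redraws because it has one
interpretable parameter and a closed-form expected test-retest
agreement,

$$\mathbb{E}[p_a^{\text{intra}}] = \sum_t \pi_t
  \Big[c + (1-c) \sum_k C_{tk}^2\Big],$$

implemented as `expected_intra_pa()` and used as the analytic oracle
in the validation suite.

**What the simulator does not model:** video/image quality, rater
errors at the level of individual algorithm branches (errors attack
the final label directly), learning effects between occasions, and
subject-specific difficulty. Passing the simulation-based checks
therefore demonstrates that the statistical machinery is correct under
a plausible generative model — not that any particular therapist panel
will achieve these coefficients on real patients.

## 5. Validation design and problem sizes

The test suite validates each layer against an independent oracle:
observed and chance agreement against brute-force rater-pair
enumeration on 1,000 random small matrices (≤ 5 subjects, ≤ 3 raters,
random missingness, tolerance 1e−12); hand-worked coefficient examples
against exact fractions (e.g. the four-subject, two-rater case equals
49/73); pooled headline means against the published per-rater values;
and the simulator against its own closed form, using 200 replicates of
the 44-subject default study and 3-Monte-Carlo-se tolerances, plus
monotonicity of the recovered coefficient in both `accuracy`
(over 0.5/0.7/0.9) and `consistency` (over 0.5/0.8/1.0) at 200
replicates per grid point, and the subgroup ordering experienced >
well-trained > all with weighted ≥ unweighted at 100 replicates.
These replicate counts keep every stochastic check comfortably
discriminating while the whole suite runs in well under a minute.

## 6. Known limitations

* The jackknife CI is a normal approximation; very small studies
  (under ~10 subjects) or near-ceiling coefficients would be better
  served by resampling on the Fisher scale.
* The pooled-CI construction (se of the mean transform) treats
  per-rater coefficients as independent; raters judging the same 44
  subjects are positively correlated, so pooled CIs are somewhat
  narrow.
* The error-topology assumption (confusion mass proportional to
  partial-credit weights) is untestable without an empirical confusion
  table; conclusions that depend on *which* categories are confused
  should be checked against alternative topologies via a custom
  `weights` argument to `study_config()`.
* The critical value is taken as a configurable input, not derived;
  designs other than (44 subjects, 10 raters, 4 categories) need their
  own tabulated value.
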