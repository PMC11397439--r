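---
title: "Methods: metabolic phenotyping and partial-correlation networks in mhonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic phenotyping and partial-correlation networks in mhonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Among young adults with overweight or obesity, a subgroup carries little
cardiometabolic risk ("metabolically healthy obesity", MHO) while another
accumulates risk factors ("metabolically unhealthy obesity", MUO).  Studies
of this phenotype typically collect anthropometry, fasting blood
biochemistry, blood pressure, a food-frequency questionnaire (FFQ), the
DASS-21 psychological scales and an activity questionnaire, then ask two
questions: which variables differ between MHO and MUO, and how the whole
variable system hangs together as a conditional-dependence network.

`mhonet` implements that analysis chain end to end: instrument scoring,
MHO/MUO classification, nonparametric group comparison, and Gaussian
graphical model (GGM) estimation with the graphical lasso.  Because
participant-level data from such studies are typically not deposited, the
package also ships a seeded cohort simulator with a *known* sparse
precision matrix, so every stage — including edge-support recovery by the
network estimator — can be tested against ground truth.

## Instrument scoring

**FFQ.** Each record (food, frequency unit, times, portion in grams)
converts to grams/day: daily records multiply directly, weekly divide by
7, monthly by 30 (month length is a documented convention, configurable
via `month_days`).  Nutrient totals sum `grams/day / 100 ×` the per-100 g
density over foods; energy is treated like any nutrient column.

**DASS-21.** Twenty-one items scored 0–3 split into three 7-item
subscales (depression, anxiety, stress); a subscale score is the plain
sum, so each ranges 0–21.  Raw sums are *not* doubled onto the 42-item
scale — the 0–21 range fixes that convention.  The item allocation is an
explicit argument (`dass21_mapping()` ships the standard allocation)
rather than a hard-coded constant.  Severity banding needs cutoffs that
vary between conventions, so it is off unless explicit breaks are given.

**IPAQ.** Scores at or above 3 are `active` and below 2 `sedentary`; the
middle band is taken as `[2, 3)`, the only reading compatible with the
two outer categories.  The three bands partition `[0, Inf)`.

## Metabolic classification

BMI is weight/height² with WHO cutoffs (25, 30, lower bounds inclusive).
HOMA-IR is `insulin (µIU/mL) × glucose (mg/dL) / 405`.  Risk factors
follow the modified IDF list for young adults with the inequality
directions as printed: triglycerides ≥ 150 mg/dL, fasting glucose
≥ 126 mg/dL, HDL < 45 mg/dL, and elevated blood pressure at 120/80 mmHg.
Two readings of the blood-pressure criterion are possible; the
disjunctive one (systolic ≥ 120 **or** diastolic ≥ 80) is the default and
the conjunctive one is a flag, because the disjunctive reading is how
such composite BP criteria are normally applied.

Two classification methods are provided.  Method `idf` labels MUO at two
or more risk factors.  Method `idf_homa` adds insulin resistance: MUO
requires HOMA-IR ≥ 3 *and* two or more risk factors, and HOMA-IR < 3 is
always MHO.  The cell "HOMA-IR ≥ 3 but fewer than two risk factors" is
covered by neither stated rule; since MUO requires both conditions, it
defaults to MHO, switchable via `ambiguous_homa`.  Note the literal
HOMA-rule reading means a participant with low HOMA-IR but several risk
factors is MHO under `idf_homa` yet MUO under `idf`; the two methods
genuinely disagree on such rows, which is why `classify_cohort()` always
reports both labels.  The pipeline's default grouping method is `idf`.

## Group statistics

Descriptives report median, sample SD, range and a Shapiro–Wilk normality
screen (a Kolmogorov–Smirnov variant is available by flag).  Shapiro–Wilk
accepts at most 5000 values; longer vectors are screened on a seeded
subsample of 5000.  Constant vectors have no defined normality statistic
and return `NA` with a warning.

Group contrasts use the Mann–Whitney U test, two-sided: U from rank sums
with average ranks for ties; an exact p (doubled tail of the exact U
distribution) when the pooled size is ≤ 12 without ties, otherwise the
normal approximation with tie correction and continuity correction.
q-values control FDR by Benjamini–Hochberg across the whole variable
family — the adjustment procedure is an assumption, chosen because the
step-up arithmetic reproduces the kind of p-to-q pattern such tables
show.  The significance flag uses p < 0.005, matching the convention of
the tables this machinery emulates.  Quartiles are linear-interpolation
(type 7) quantiles.

## Network estimation

The GGM core works on a correlation matrix `S`.  Spearman is the default
(the variables fail normality screens; rank correlations are the
nonparametric choice consistent with "Rho" terminology), Pearson by flag.
Rank-based matrices can be indefinite at small n; eigenvalues are clipped
at 1e-8 and the matrix rescaled to unit diagonal, with the repair
flagged.  No nonparanormal rescaling (2·sin(πρ/6)) is applied — deliberate,
as the workflow this emulates feeds rank correlations directly into the
estimator.

The estimator maximizes the penalized Gaussian likelihood

    log det Θ − tr(SΘ) − λ Σ_{i≠j} |Θ_ij|

with an unpenalized diagonal, by block coordinate descent over columns
with a coordinate-descent lasso inner solver (implemented in C++).
Convergence is declared when the largest element change of the working
covariance W in a sweep falls below `tol` (default 1e-4, at most 500
sweeps); each column update is an exact block step on the dual objective
`log det W`, which is recorded per sweep and never decreases.  KKT
stationarity residuals of the returned solution are reported on every
fit, and the test suite checks the solver against an independent ADMM
solver for the same convex program, plus closed forms (λ = 0 inversion,
saturation at λ ≥ max|S_ij| to Θ_ii = 1/S_ii).

λ is selected on a log-spaced grid of 100 values from just above
λ_max = max|S_ij| down to 0.01·λ_max (the small offset keeps the empty
model among the candidates despite floating-point drift at the
boundary), warm-starting along the path.  The criterion is the extended
BIC in the Foygel–Drton form

    EBIC(λ) = −2 ℓ(Θ̂) + E log n + 4 E γ log p,

with `ℓ(Θ) = (n/2)(log det Θ − tr(SΘ))`, E the number of estimated
edges, and γ = 0.5 as the conventional default; ties break toward the
larger λ (the sparser model).  γ = 0 recovers the classical BIC.

Partial correlations are `ρ_ij = −Θ_ij/√(Θ_ii Θ_jj)` (zero diagonal by
convention); they equal residual correlations after regressing out all
remaining variables, which the tests verify against a regression-route
oracle.  Display applies the strict rule `|ρ| < 0.1 is hidden`; the ρ
matrix itself is never modified.

**Rho bands.** Sub-networks are re-estimated after restricting to
variables whose pairwise *marginal* correlation falls in a closed band
(0.400–0.599, 0.600–0.799, 0.800–0.999).  Three semantic choices were
open: filter edges vs variables, open vs closed interval ends, marginal
vs partial correlations.  The implementation keeps every variable
participating in at least one in-band pair (variable semantics keep the
re-estimated sub-network interpretable as a GGM), uses closed intervals,
and applies the band to marginal correlations (the band is described as
a correlation Rho, not a partial correlation).  All three choices are
isolated inside `band_filter()` and configurable by replacing that step.
An empty band selection is a reported empty network, not an error.

**Reporting.** Sub-networks are the connected components of the displayed
graph; isolated nodes count as singletons.  Layout is Fruchterman–
Reingold with edge attraction weighted by |ρ|, seeded (default 0) and
centred, so figures reproduce run to run.  Rendering follows the usual
conventions: green positive edges, red negative, width growing linearly
from 0.5 pt at |ρ| = 0.1 to 6 pt at |ρ| = 1 (purely presentational).

## The synthetic cohort generator

The generator is the package's ground-truth source, not a fixture.  A
`ground_truth_graph` draws a sparse symmetric precision matrix: edges
uniform at the requested density, magnitudes uniform in `value_range`
with random sign, diagonal set to the absolute row sum plus one
(diagonal dominance guarantees positive definiteness).  The latent
sample is Gaussian with correlation `cov2cor(Θ*⁻¹)`; each column then
passes through a monotone quantile (copula) transform to its anchored
marginal, so latent rank structure survives into the observed table.

Marginal families follow the shape of the measurement blocks: lognormal
for nutrient intakes and biomarkers (right-skewed, positive), truncated
normal for anthropometry and blood pressure, discrete ordinal (a rounded
truncated normal) for questionnaire subscale totals.  Each family is
anchored so its median matches the target: lognormal takes
`meanlog = log(median)` and solves `sdlog` from the anchor SD; the
truncated normal solves its location so the *truncated* median matches;
anchors whose median sits on the range boundary are handled by clamping
the location search.  The default anchor table
(`cohort_anchors()`) encodes 48 variables of an overweight/obese
young-adult cohort — some of its printed SD anchors are internally
implausible (an SD equal to the maximum, for instance), and the
generator uses them as given; only medians are treated as calibration
targets.  BMI and HOMA-IR are derived downstream, never simulated.

Group structure is generated on a latent severity axis: rows above a
threshold receive per-variable latent shifts (SD units; risk markers up
in MUO, HDL/fiber/MUFA down, magnitudes 0.15–1.2 chosen once to mirror
the reported median separations).  When the classification variables are
present, the threshold is calibrated by bisection so the fraction
*classified* MUO matches the target (164/230 ≈ 0.713), the labels are
taken from the classifier itself — keeping it the single source of truth
— and the latent-vs-classified mismatch rate is reported rather than
hidden.  With these anchors most participants sit near several IDF
thresholds, so the mismatch rate is substantial; that is a property of
the anchored population, not a bug.  Companion instrument data are
generated consistently: DASS subscale totals decompose into 21 items
(base-plus-remainder, positions shuffled under the seed) that re-score
exactly, and FFQ records are emitted against a deliberately synthetic
one-carrier-food-per-nutrient composition table
(`synthetic_food_composition()`, diagonal densities at one third of the
anchored median per 100 g) so that scoring reproduces the intake columns
to float precision.

The default ground-truth graph for the 48-variable cohort uses edge
density 0.03 and magnitudes 0.6–0.9, giving true partial correlations of
roughly 0.2–0.45 — the strength range typical of reported cohort-scale
GGMs, and detectable at a few hundred participants.  What the simulator
does *not* emulate: real dietary collinearity (nutrients computed from
shared foods), missing data, measurement error in instruments, or any
joint structure beyond the sparse latent graph plus marginal anchors.
Passing tests therefore demonstrate the machinery recovers known
structure under its own assumptions — not that any particular real
cohort satisfies them.

## Numerical choices and degenerate inputs

- glasso: `tol` 1e-4 on W, max 500 outer sweeps, inner lasso tolerance
  `tol/10`; non-convergence returns the fit with `converged = FALSE` and
  a warning, and EBIC selection skips non-converged fits.
- EBIC edge counts use exact zeros of the coordinate-descent solution
  (soft-thresholding yields true zeros, no epsilon cutoff).
- Spearman PSD repair: eigenvalue floor 1e-8, then `cov2cor`.
- Empty-graph conventions in recovery metrics: no predicted edges gives
  precision 1, no true edges gives recall 1, so empty-vs-empty scores
  F1 = 1.
- Mann–Whitney: zero tie-corrected variance (all values identical)
  returns p = 1; `U = n1·n2/2` maps to z = 0.
- `simulate_cohort(n = 0)` returns structurally complete, zero-row
  containers; a non-positive-definite precision is refused with a
  diagnostic.

## Problem sizes

The test suite exercises the solver oracle battery at p ≤ 6 across
λ ∈ {0, 0.05, 0.1, 0.3}; support recovery at p = 15, density 0.1,
n = 2000; marginal anchoring at n = 10000–20000; the latent covariance
invariant at n = 50000, p = 10 (tolerance 0.02 element-wise); and the
full pipeline at n = 90–230 with 48 variables.  These sizes were chosen
so the whole chain, including the 3-groups × 4-bands network matrix, is
routinely re-runnable on a laptop core in a few minutes.

## Known limitations

- The anchors pin medians (and approximately SDs for well-specified
  rows); they do not reproduce any real cohort's joint distribution.
- Rho-band semantics in the literature are ambiguous; results for the
  banded sub-networks depend on the variable-participation reading
  chosen here.
- EBIC with γ = 0.5 is conservative at n ≈ 230: subgroup networks
  (especially the smaller MHO group) are often empty or very sparse.
  That is the expected behaviour of the criterion, not a failure of the
  solver.
- No bootstrap edge-stability analysis, no centrality indices, and no
  directed/causal interpretation of edges.
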