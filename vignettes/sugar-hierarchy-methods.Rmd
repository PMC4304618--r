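---
title: "Methods: modelling and measuring the E. coli sugar-utilization hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and measuring the E. coli sugar-utilization hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sugarhier)
```

## The scientific problem

When *E. coli* meets a mixture of two non-PTS sugars (here: lactose,
arabinose, xylose, sorbitol, rhamnose, ribose), it does not treat them
symmetrically. The promoter of the sugar system supporting the lower
growth rate is partially repressed, the dominant system is fully
expressed, and ranking the sugars by the growth rate each supports alone
produces a strict hierarchy. The quantitative explanation is differential
activation by the master regulator CRP-cAMP: each catabolic promoter
responds approximately linearly to CRP activity, with a slope that falls
with the sugar's position in the hierarchy, so a given CRP level — set by
the current growth rate — activates each system to a different degree.

`sugarhier` implements that analysis as a reusable pipeline: extraction
of growth rate and promoter activity from plate-reader time series,
construction of the pairwise hierarchy and cross-activation matrices,
fitting and leave-one-out prediction of CRP input functions, a
sequential-vs-simultaneous dynamics classifier, and the cost/benefit
allocation models that rationalize when bang-bang (sequential) or mixed
(simultaneous) expression is optimal. Because no raw plates are publicly
deposited, the package ships a mechanistic synthetic plate generator
calibrated to the published constants, so every stage of the pipeline is
testable end to end.

## The synthetic plate generator

### Growth and consumption

A well is a batch culture: OD grows exponentially at the rate of the
"best" sugar currently present (`mixture_rule = "max"`), and consumed
sugar depletes by mass balance \(dS_i/dt = -(\mu/Y_i)\,OD\). Two
consumption modes are available:

* **sequential** (default for saturating pairs): the higher-ranked sugar
  is consumed first; growth drops to the next sugar's rate at each
  depletion event and to zero when all sugars are gone;
* **co-consumption** (`"co"`, used for the sub-saturating simultaneous
  scenarios): consumption is split across sugars in proportion to their
  remaining stocks, so concentration ratios stay constant and all sugars
  exhaust together. We deliberately do not weight consumption by current
  expression: because the dominant system is the highly expressed one,
  expression weighting always exhausts the minor sugar first and makes
  sustained co-expression impossible, contradicting the phenotype this
  mode exists to emulate.

Integration is event-driven: within a phase all rates are constant, so
OD, sugar and GFP trajectories are evaluated in closed form at the
sampling grid (default: every 6 min for 20 h, 201 samples). This is what
lets the noiseless pipeline recover generator constants to better than
one part in \(10^3\); a fixed-step explicit scheme at 0.01 h would
already carry ~0.25% error.

### Regulation

CRP activity is affine in generation time,
\(C(\mu) = c_0 + c_1 \ln 2/\mu\), normalized so that the slowest
condition (ribose alone) has activity 1. The intercept \(c_0\) is derived
from the two printed anchor growth rates (0.53 h\(^{-1}\) on lactose,
0.29 h\(^{-1}\) on ribose) by requiring that the ribose system needs
exactly 3 times the CRP activity of the lactose system for full
activation; it is a consequence, not a tuning knob.

Each promoter's input function is affine in normalized CRP activity and
clamped at zero, anchored so the promoter reaches its own maximum
(normalized activity 1) at the CRP level of growth on its cognate sugar
alone. With its cognate sugar absent, a promoter runs at a constant
cross-activation fraction of that maximum (median 20% across the six
promoters). The CRP-site-mutant rhaB variant is the wild-type promoter
with a 1.3-fold slope, re-anchored to its own maximum.

### Why the intermediate growth rates are what they are

Only the two extreme growth rates are published. The four intermediate
defaults (0.524, 0.514, 0.49, 0.406 h\(^{-1}\)) are calibration anchors
chosen under three simultaneous constraints: (i) monotone between the
printed extremes, (ii) every repressed entry of the noiseless pair matrix
inside the 0.1–0.5 band, and (iii) affine input functions. Constraints
(ii)+(iii) couple the rates: for reporter \(i\), the entry with its
nearest faster partner must fall below 0.5 while the entry with lactose
stays above 0.1, which bounds the ratio of the CRP spans by
\(0.9/0.5 = 1.8\) per row. Evenly spaced rates violate that bound from
sorbitol downward (ratios 2.3–3.1), so the defaults follow a roughly
geometric spacing in normalized-CRP space that satisfies it with margin.
A side effect is that input-function slopes near the top of the hierarchy
are steep (the arabinose system spans its full dynamic range over ~1% of
the CRP scale); the ordering "higher in the hierarchy, steeper slope" is
preserved.

### Measurement model

Rendering samples the true curves on the grid and applies

* per-day multiplicative lognormal factors (mean 1) on growth dynamics
  (CV 5%) and on promoter-driven fluorescence (CV 11%), one draw per day
  per condition — these reproduce the published day-to-day relative
  errors;
* additive Gaussian read noise, OD truncated just above zero
  (defaults 0.001 OD, 1 au — typical plate-reader repeatabilities);
* a shared autofluorescence accumulation (30 au/OD/h) in every well;
  promoterless background wells carry only this term.

Day factors scale the dynamics and the reporter signal but not the
regulatory input: CRP is computed from the nominal phase growth rate.
With the calibrated steep input functions, propagating a 5% growth
perturbation through the CRP chain would swing some promoters' activity
by far more than the 11% day-to-day spread actually observed, so the day
factors are treated as assay-level nuisances, which is also how the
published error figures are quoted. Identical seed and configuration
give bit-identical plates; rendering restores the caller's RNG state.

What the generator does *not* emulate: lag phases, smooth
(Monod-type) slowdowns near depletion, single-cell heterogeneity
(population means only, consistent with the unimodal single-cell
distributions reported), mechanistic cAMP transport (external cAMP is
modelled as directly pinning CRP activity), and any growth advantage of
ribose mixtures unless the optional `ribose_boost` factor is enabled.
Passing tests on this generator therefore demonstrate the correctness of
the pipeline's computations under the stated statistical structure, not
robustness to every artefact of real plates.

## Kinetics extraction

Promoter activity is \(P(t) = (dG/dt)/OD\) after subtraction of the
matched promoterless background; growth rate is
\(\alpha(t) = d\ln OD/dt\). Both derivatives use a sliding local
polynomial (Savitzky–Golay) estimator with half-width 3 points at 6-min
sampling, but with different orders:

* \(\alpha\) uses **order 2** (linear weights). \(\ln OD\) is piecewise
  linear, for which this estimator is exact; at the concave kinks of
  diauxic and stationary transitions its output is a convex combination
  of neighbouring slopes, so it cannot overshoot. Order-3 estimators ring
  at kinks, which can relocate the growth-rate maximum onto a transition.
* \(P\) uses **order 3** (exact through degree 4). GFP grows
  exponentially mid-log, and the order-2 estimator's curvature bias
  (\(\approx \alpha^2 h^2 \cdot 7/6\), ~0.3% at 0.53 h\(^{-1}\)) would
  exceed the pipeline's 1e-3 closure tolerance; the cubic estimator's
  bias is ~\(10^{-5}\).

The mid-exponential window is two generations centered on the
growth-rate maximum: \([t_{peak} - \tau, t_{peak} + \tau]\) with
\(\tau = \ln 2 / \alpha_{max}\), clipped to the data. Two numerical
choices matter on synthetic data: the argmax takes the *earliest point
within a \(10^{-6}\) relative tolerance* of the maximum (on an exactly
flat plateau, a bare argmax is decided by \(10^{-16}\) float jitter and
can land next to the depletion kink), and points below an OD detection
floor (default 0.05) are masked first, because the relative read noise of
near-inoculum ODs makes the log-derivative there spurious. Replicate
handling follows the summaries-first convention: per-well windowed means,
averaged within day, then across days; the day-to-day relative error is
the across-day standard deviation (n−1) over the mean. Negative
activities are retained unclipped in summaries so error estimates stay
unbiased; clipping (with a flag) happens only in normalized matrix
rendering.

## Matrices and ranking

Sugars are ranked by descending cognate-alone growth rate (exact ties:
alphabetical, flagged). The pair matrix entry \((i,j)\) is reporter
\(i\)'s activity in the \(\{i, j\}\) mixture divided by its cognate-alone
activity (pooled across days; the noise model draws day factors
independently per condition, so day-matched normalization would cancel
nothing). The cross matrix divides each reporter's activity on each sole
sugar by its cognate value. The dominance score counts, over the 15
unordered pairs, how often the higher-ranked reporter is strictly more
active with the lower partner than vice versa; ties count against. An
optional `divide_by_growth` flag reproduces the growth-rate-normalized
control analysis.

## CRP input functions and leave-one-out prediction

The CRP dataset pools, per promoter, every condition in which its cognate
sugar is present: the cognate-alone condition, the five pairs, and the
external-cAMP titrations of lactose+ribose (lacZ, rbsD) and
arabinose+rhamnose (araB, rhaB). The titrations are not decorative: in a
noiseless generator every lactose-containing pair grows at the lactose
rate, so the lacZ promoter would otherwise contribute a single distinct
CRP level and its line would be unidentifiable (arabinose: two). Promoter
activity is normalized to cognate-alone; CRP-reporter activity to its
dataset-wide maximum.

Fits are ordinary least squares with intercept. Leave-one-out prediction
refits the promoter's line without the predicted point and evaluates it
at the point's measured CRP level; the global \(R^2\) pools all predicted
points as \(1 - SS_{res}/SS_{tot}\) (the squared Pearson correlation is
reported alongside). The CRP-requirement of a promoter is
\((1-\text{intercept})/\text{slope}\), the level at which its normalized
activity reaches 1.

## Dynamics classification

For a two-reporter mixture the classifier normalizes both
promoter-activity curves to their own maxima, restricts to the growth
phase (the span where \(\alpha\) exceeds 10% of its maximum), and scores
overlap as \(\int \min(p_1,p_2)\,dt / \int \max(p_1,p_2)\,dt\). Scores
below 0.25 are sequential, otherwise simultaneous; the threshold is a
package choice since only qualitative categories are published. On the
default scenarios the two classes are widely separated (overlap ~1.0 for
the co-consumed lactose/xylose/sorbitol partners versus ~0.2 for the
sequential rhamnose/ribose partners), so the call is insensitive to the
threshold over a broad range.

## Optimality models

Expressing \(E_i\) proteins of system \(i\) costs \(a_i E_i\) growth-rate
units; the benefit is \(\mu = \sum_i S_i E_i b_i\) (optionally
Michaelis–Menten in \(S\)). On the linear budget
\(a_1E_1 + a_2E_2 = C\) the optimum is analytic bang-bang: the entire
budget goes to \(\arg\max_i S_i b_i/a_i\), ties resolved to the lowest
index and flagged degenerate. The family \(\sum_i a_i E_i^p = C\)
realizes the outward-bulging constraint for \(p>1\) (solved by
parameterizing the curve and one-dimensional maximization, objective
tolerance ~1e-8; for \(p=2\), \(\mu^* = \sqrt{C\sum s_i^2/a_i}\) is used
as an independent check), and there co-expression is always optimal when
both sugars contribute.

In the optimal-control batch simulation the allocation is re-optimized at
every step, the expressed sugar is consumed, and corner changes are
recorded as switch events. Once consumption drives the per-budget gains
onto the tie surface \(S_1b_1/a_1 = S_2b_2/a_2\), the discrete-time
bang-bang policy chatters between corners — the discrete shadow of the
continuous-time singular arc — so corner flips within a one-step tie
band are not counted as further switches; the first arrival at the tie
surface is the switch. The Pareto variant sweeps the constraint curve
and returns allocations non-dominated in (current growth, preparedness),
with preparedness instantiated as the poorer system's expression level —
one reasonable concretization of an objective that is only conceptual in
the source analysis.

## Problem sizes and runtime

The reference dataset is 35 conditions / 170 wells / 201 samples per
well; the replicate-day calibration uses the six sole-sugar conditions
over 20 days; the optimality oracle checks 100 random two-system models
against an exhaustive 1001-point grid. These sizes keep the whole test
suite and the acceptance script in the tens of seconds while leaving all
estimators deep in their asymptotic regimes.

## Known limitations

* The calibration is a consistent instantiation of the published
  constants, not a fit to deposited raw data (none exists); absolute
  activity scales are arbitrary.
* The steep top-of-hierarchy input functions are a consequence of
  requiring affine regulation plus the repressed band; real input
  functions presumably achieve the band with saturating nonlinearity.
* The dynamics classifier compares population-average curves only.
* The maltose seventh-sugar observations and σ70-reporter normalization
  are out of scope; the data model merely permits N ≠ 6.
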