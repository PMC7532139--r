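---
title: "Measuring static, dynamic, and entropic functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring static, dynamic, and entropic functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fcpipe` analyses within-subject pharmacological imaging designs in which
each participant is scanned under placebo and under an acutely acting
drug, and each scan is split into a first and second half so that peak
drug effects (first half) can be separated from waning effects (second
half). This gives a 2×2 drug-by-time design with four cells per
participant. This vignette explains the models behind each stage, the
parameters that matter, and the choices made where the design was open.

## Static connectivity and its statistics

Static functional connectivity (sFC) between two nodes is the Pearson
correlation of their timeseries over a scan half. All analysis happens on
the Fisher scale, *z* = arctanh(*r*), which approximately stabilises the
sampling variance; `aggregate_networks()` refuses raw-*r* input so the
transform cannot be skipped accidentally. With N nodes there are
N(N−1)/2 edges (35,778 at the 268-node atlas scale the design targets;
780 at the package's default desk scale of N = 40).

Network-level inference averages edges into 8 within-network sets and 28
between-network pairs and tests each of the 36 resulting interaction
means with a 2×2 within-subject ANOVA. Because every effect in a 2×2
within-subject design has a single degree of freedom, each F statistic is
computed as the squared paired *t* of the per-participant contrast score
(for the interaction, `(drug.first − drug.second) − (placebo.first −
placebo.second)`); the test suite verifies this against base R's
`aov()` error-stratum decomposition to 1e−8. Partial η² is
F/(F + df_error). The 36 interaction p-values are corrected per effect
with the Holm step-down procedure (`stats::p.adjust`).

Edge-level mapping uses a deliberately conservative two-stage rule: a
Bonferroni-corrected one-sample *t* against zero across participants
(p < α/E in any of the four cells, two-sided, since the sign of an edge
is meaningful) selects edges unlikely to be noise, and only those are
contrasted between drug conditions with uncorrected paired *t*-tests per
scan half.

## Time-resolved correlation by DCC-GARCH

Dynamic and entropic connectivity both start from an estimate of each
edge's correlation *trajectory*. Sliding-window correlations require an
arbitrary window length; instead each edge is modelled with a bivariate
dynamic conditional correlation (DCC) model estimated in two stages:

1. Per node, a GARCH(1,1) conditional-variance model on the mean-centered
   series, h_t = ω + α ε²_{t−1} + β h_{t−1}, fit by Gaussian
   quasi-maximum likelihood. No ARMA mean model is used — mean-centering
   is the simplest defensible specification for nuisance-regressed BOLD
   signals.
2. On the standardized residuals z_t, the DCC(1,1) recursion
   Q_t = (1 − a − b) S̄ + a z_{t−1} z′_{t−1} + b Q_{t−1} with correlation
   targeting (S̄ is the residual sample correlation), giving
   R_t = Q_t[1,2] / √(Q_t[1,1] Q_t[2,2]) ∈ (−1, 1).

Edges are fit independently as bivariate models rather than as one
N-dimensional model: a whole-brain multivariate DCC at atlas scale is
computationally infeasible and would couple the per-edge estimates the
downstream measures treat as separate. Per scan, each node's GARCH model
is fit once and reused across its edges.

Numerical choices: both recursions are linear in their lagged term and
are evaluated with `stats::filter(method = "recursive")`, so likelihood
evaluations are vectorised; optimisation is Nelder-Mead from a fixed
multi-start grid (α₀ ∈ {0.05, 0.15} × β₀ ∈ {0.5, 0.85} with ω₀ implied by
variance targeting; (a, b) starts {0.02, 0.1} × {0.5, 0.85} plus the
constant-correlation corner (0, 0)), with stationarity enforced by
penalty (α + β < 0.999, a + b < 0.997). Ties in log-likelihood are broken
toward the smallest a + b, i.e. the least persistent model, which makes
the estimator deterministic: identical inputs always give identical
fits. With a = b = 0 the filter reduces exactly to the constant residual
correlation, a closed form the tests exercise. If either stage fails to
produce a finite optimum, the edge falls back to an
exponentially-weighted moving correlation (λ = 0.94) and is flagged; a
flagged edge still yields a variance but the pipeline reports the count,
and entropy failures propagate as missing values rather than aborting a
whole-brain run.

**dFC** is the sample variance (denominator T − 1) of R_t. **eFC** is the
histogram approximation to the differential entropy of R_t:

H(X) = −Σᵢ f(xᵢ) ln( f(xᵢ) / w(xᵢ) ),

with f the empirical bin proportions and w the bin width; empty bins
contribute zero (the x ln x → 0 limit). For uniform bins this equals the
Shannon entropy of the proportions plus ln(w), which is what makes it an
estimate on the differential (bin-width-corrected) scale; the tests
assert this identity exactly and check the estimator against the closed
forms for uniform (ln(b − a)) and Gaussian (½ ln 2πeσ²) distributions.
The log is natural (nats), the differential-entropy convention. The
default is 60 bins with per-edge data-range binning; a sweep helper
covers 15–120 bins in steps of 15 so stability to the binning choice can
be verified. Two open choices are configurable: the entropy is taken on
the raw correlation scale by default (a Fisher-z option exists), and the
bin range can be fixed to [−1, 1] instead of the per-edge data range.
Data-range binning makes the estimator location-invariant and keeps
resolution where the data are, at the cost of an undefined value for a
constant series — exactly the degenerate case the flagging handles.

Variance and entropy are deliberately different summaries: an edge that
jumps between two extreme states has high variance but low entropy,
while an edge drifting across many neighbouring states has high entropy
without necessarily high variance.

## Connectome-based classification

To ask *where* in the connectome a drug signature lives, each
(participant × cell) observation is the vectorised upper triangle of one
connectivity matrix. A PLS discriminant-analysis model (PLS2 regression
of the one-hot cell labels on the features, via mixOmics) is trained
under leave-two-participant-out cross-validation: for each of the
C(12, 2) = 66 participant pairs, the model trains on the other ten
participants and classifies the held-out pair's eight rows. Features are
standardized with training-fold statistics only and zero-variance
training columns are dropped, so no information can leak from the test
pair; the suite verifies that perturbing one participant's data leaves
the predictions of its co-tested partners unchanged.

The number of PLS components defaults to 3 and is fixed a priori — it is
never tuned on test folds, which would be leakage. Predicted labels are
the arg-max of the predicted one-hot responses, with ties resolved by
the fixed cell order (placebo.first, placebo.second, drug.first,
drug.second). Pooled-over-folds confusion matrices give the
discrimination score of the peak-effect cell,
d′ = Φ⁻¹(hit) − Φ⁻¹(false alarm), with the standard extreme-rate
correction (0 → 1/(2n), 1 → 1 − 1/(2n), n the rate's denominator).
Rates are pooled over folds rather than averaged per fold: with only
two target observations per fold, per-fold rates would be too coarse
for the inverse-normal transform. The 36-interaction sweep repeats the
procedure on each within- or between-network feature subset; for
display, below-chance d′ is floored at zero while raw values are kept
in the tidy output. Models are never trained on combinations of within-
and between-network connectomes; combining *measures* is supported as
simple column concatenation after per-measure rescaling.

## The synthetic-study generator

Real data for this class of study are rarely deposited, so validation
rests on a generator whose truth is known. It emulates the statistical
structure the analyses assume: 12 participants × 2 drug conditions × 2
scan halves; node timeseries built from Gaussian innovations with a
block (network) correlation structure passed through a node-wise AR(1)
filter. Defaults, chosen once as representative of resting-state data at
desk scale: N = 40 nodes in 8 networks of 5 (preserving the 8-network
topology at tractable DCC cost), T = 400 timepoints per half (scan
length in volumes is treated as a free parameter — at a typical ~1 s
sampling interval this is the right order for a 10-minute half),
within-network ρ = 0.40, between-network ρ = 0.10, AR coefficient
φ = 0.4 (BOLD-like smoothness; DCC behaviour depends on autocorrelation,
so a nonzero default matters), innovation SD 1. Because every node
shares the same φ, the stationary cross-correlation equals the
innovation correlation, so the generative targets are recovered by
sample correlations as T grows — the tests' convergence property.

Participant heterogeneity is a uniform(−0.05, 0.05) jitter on each block
correlation, drawn once per participant from a participant-specific
substream of the seed and shared across that participant's four cells:
large enough to make paired statistics realistic, small enough not to
swamp fixed effects, and cancelling exactly in within-participant
contrasts. Condition effects are injected as additive shifts on the
Fisher-z scale of named network blocks in named cells. Optional
regime-switching alternates the correlation matrix every `period`
timepoints between ±`amplitude` z-shifted states, creating genuinely
time-varying coupling that dynamic measures should (and in the tests,
do) detect. Block-filled matrices can be slightly indefinite, so every
target is repaired by eigenvalue clipping at 1e−8 followed by
re-normalisation to unit diagonal; a request whose post-repair block
means move by more than 0.1 is rejected as contradictory, naming the
offending blocks.

What the generator does **not** emulate: hemodynamic response shapes,
scanner drift and physiological noise spectra, head motion, spatial
structure within networks, and non-Gaussian innovations. Passing tests
therefore demonstrate that the estimators and pipeline are correct and
calibrated under the assumed generative structure, not that any specific
empirical finding would replicate on real scans.

## Problem sizes, determinism, and limitations

The shipped tests and the acceptance script run at reduced sizes chosen
as the package's validation scale: null-calibration studies use 30
nodes and T = 200 per half over 6–10 seeds; DCC recovery uses single
edges at T = 2000; effect-recovery studies use the full default design
(12 × 40 × 400) over 3 seeds. All randomness flows from explicit seeds
(scans use substreams derived as `seed + 7919·participant +
104729·cell`, kept below 2³¹), and every estimator is deterministic
given its inputs, so pipeline reruns are byte-identical.

Known limitations: GARCH/DCC quasi-likelihood estimation on short halves
(T ≲ 100) is noisy and the persistence parameters are weakly identified
— the multi-start grid and least-persistent tie-break keep estimates
stable but conservative; the histogram entropy estimator carries the
usual plug-in bias of order (bins − 1)/(2T), visible when sweeping to
120 bins on short series; the drug-strength AUC integrates only
observed ratings (no implicit (0, 0) point is prepended, since the
first rating is taken a minute after inhalation), interpolating at the
upper boundary only when ratings straddle it; and the repeated-measures
machinery covers the 2×2 single-observation-per-cell design only, not
larger factorial layouts.
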