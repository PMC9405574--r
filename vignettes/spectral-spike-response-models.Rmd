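---
title: "Spectral spike response models and parameter pruning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral spike response models and parameter pruning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rssrm)
```

## The problem

A spike response model (SRM) writes the membrane potential of a single
neuron as a linear function of its inputs: the injected current and its own
spike history,

$$\hat u(t) = u_\mathrm{rest} + \sum_{s=0}^{J}\kappa_s I_{t-s}
           + \sum_{q=1}^{Q}\eta_q S(t-q),$$

where $S(t)$ is the 0/1 spike indicator.  Fitting the filters
$\kappa, \eta$ by least squares is attractive because it needs no
hand-tuned kernels, but a faithful lagged model needs thousands of lag
coefficients.  The spectral variant (SSRM) replaces the lags with Fourier
features: every regressor is a basis column $\cos(i\omega t)$ or
$\sin(i\omega t)$ multiplied elementwise with one of just two channels,
$I(t)$ and $S(t-1)$.  The full basis gives $n-1$ regressors per channel
for an $n$-sample recording ($2(n-1)$ in total), enough to interpolate the
training signal wherever a channel is nonzero.  The scientific question
this package reproduces is how gracefully each model family degrades when
it is pruned to roughly one hundred coefficients — about 1% of its full
size — using L1 regularization, and how pruned spectral models compare to
principal-component (PCR) and raised-cosine (RCR) regressions of the same
size.

## Ground-truth data

All data are simulated: the twenty canonical firing behaviors of the
two-variable Izhikevich model,

$$\dot v = 0.04 v^2 + 5 v + 140 - u + I,\qquad \dot u = a(bv - u),$$

with the reset $v \ge 30\,\mathrm{mV} \Rightarrow v \leftarrow c,\;
u \leftarrow u + d$, integrated by forward Euler.  `behavior_catalog()`
carries the published hyperparameters and stimulus protocols for behaviors
(a) tonic spiking through (t) inhibition-induced bursting; two behaviors
(class 1 excitable, integrator) use the published quadratic variant
$0.04v^2 + 4.1v + 108$ and accommodation uses the leak-free recovery rule
$\dot u = a\,b\,(v+65)$, as in the original protocol set.

Numerical choices that needed a decision:

* **Update scheme.** Both state variables advance simultaneously from the
  previous state (classic forward Euler); at a firing step only, the
  recovery update sees the pre-clamp overshoot peak, which reproduces the
  reset bookkeeping of the original protocol scripts and is what keeps the
  depolarizing-after-potential behavior to its single canonical spike.
* **Step and duration.** Default `dt = 0.25` ms, with a fixed
  per-behavior sample count (tonic spiking: 20,000 samples, so its full
  two-channel Fourier design has 39,998 columns).  The resonator is the
  one short recording that needed lengthening: its default is 4,000
  samples so that the 40 ms resonant pulse pair still fits at
  `scale = 0.1`.
* **Stability.** Inhibition-induced bursting diverges under Euler at
  `dt <= 0.25` with the canonical after-spike increment ($d=-2$): each
  spike pushes the recovery variable down faster than the inter-burst
  interval restores it.  The catalog uses $d = 0$, which bursts cleanly
  (2 ms intra-burst intervals, ~80 ms gaps) and is stable at every step
  size tested.
* **Protocols under rescaling.** Stimulus positions are relative to the
  recording length $D$; pulse widths and dynamical gaps (the resonator's
  40 ms pair spacing, the integrator's 5 ms doublet) are absolute, so
  `scale` shortens recordings without changing any behavior's firing
  class.  Single-pulse events sit at $0.55 D$ so that they fall inside the
  evaluation window of the lagged models, which discard the first
  $\max(J,Q)$ samples.  The catalog enforces a per-behavior minimum
  duration so a protocol always fits.  With these choices the catalog
  yields exactly 9 one-spike and 11 multiple-spike behaviors at
  `scale` 1 and 0.1 and at `dt` 0.25 and 0.125.

What the generator does *not* emulate: measurement noise, trial-to-trial
variability, subthreshold channel noise, or electrode filtering.  Every
model is fitted and evaluated on the training recording itself (the study
design measures representational capacity under pruning, not
generalization), so results here say nothing about held-out prediction on
biological recordings.

## The six model families

| model | regressors | penalty |
|-------|-----------|---------|
| SRM   | current lags $0..J$, history lags $1..Q$, $J=Q=\lfloor n/4\rfloor$ | ridge 0.01 |
| SSRM  | full Fourier features of $I(t)$ and $S(t-1)$ | ridge 0.01 |
| RSRM  | SRM columns | L1-selected to target count, ridge refit |
| RSSRM | SSRM columns | L1-selected to target count, ridge refit |
| PCR   | first $k$ principal components of the SRM design | ridge 0.01 |
| RCR   | $k$ raised-cosine bumps per channel | ridge 0.01 |

All models share the small ridge term $\lambda_2 = 0.01$ (applied to the
internally standardized coefficients; the intercept, the resting
potential, is never penalized).  The L1 objective is

$$E = \tfrac12\sum_t\big(u(t)-\hat u(t)\big)^2
    + \lambda_1 \lVert w\rVert_1 + \lambda_2 \lVert w\rVert_2^2 .$$

`fit_penalized()` solves the $\lambda_1 = 0$ case in closed form (primal
or dual ridge, depending on the design shape) and the $\lambda_1 > 0$ case
by cyclic coordinate descent (glmnet), with the exact penalty pair
recovered through the mixing-parameter mapping.  `tune_l1_for_count()`
bisects on $\log\lambda_1$ until the nonzero count hits the behavior's
target (±2%), bracketing the search with a lasso path first.  Counts are
not always exactly reachable — correlated columns enter the path in
groups — in which case the closest achieved count is returned with a
warning and recorded as-is.

**Selection then refit.**  Pruning a 4,000-column design to ten survivors
requires a $\lambda_1$ so large that the surviving coefficients are
themselves shrunk toward zero, which flattens the predicted potential for
reasons unrelated to which columns survived.  The package therefore treats
L1 as a *selection* device: after the search, the surviving columns are
refitted by ridge alone.  This matches the comparison's logic — PCR and
RCR fit their $k$ columns by ridge with no L1 bias, so the pruned models
should carry the same number of *unbiased* coefficients — and it is the
standard reading of "pruning" a model to a smaller one.  `refit = FALSE`
recovers the raw elastic-net coefficients.

Per-behavior target counts ship with the catalog (95 for tonic spiking,
10 for the resonator, ...); at reduced scale they shrink proportionally,
floored at 2 so every family remains constructible.

## From potentials to spikes

Three steps turn a predicted potential trace into a spike forecast:

1. **Detection.** A sample is a predicted spike iff it exceeds the
   empirical $1 - r\beta$ quantile of $\hat u$ (with $r$ the true firing
   proportion and $\beta \ge 1$ an inflation coefficient) *and* is a local
   maximum — strictly above its left neighbour, at or above its right
   neighbour, so plateaus fire once and endpoints never fire.
2. **Maximum tolerance.** The smallest timing slack $\tau_{\max}$ (swept
   upward on the sample grid) at which every spike of the smaller set can
   be matched to the other set.  Matching is greedy closest-pair-first:
   candidate pairs within $\tau$ are admitted by increasing time
   difference.  This discipline was chosen over matching in time order
   because it makes the matched set grow monotonically with $\tau$, so the
   tolerance-adjusted F1 cannot decrease as the tolerance is relaxed (a
   property that time-ordered greedy matching violates).  PCR and RCR
   tolerances are capped at 30 ms.
3. **Substitution.** Matched predictions are replaced by their true times;
   unmatched predictions stay.  F1 is computed on the substituted train;
   the van Rossum distance is always computed on the *unsubstituted*
   train, since its exponential kernel already integrates timing error.

$\beta$ is searched on $[1, 1.5]$ (11 uniform points) for the full models
and $[1, 270]$ (60 log-spaced points) for the pruned ones, keeping the
$\beta$ with the best tolerance-adjusted F1; ties go to the smallest
$\beta$, then to the smaller $\tau_{\max}$.

## Metrics

RMSE on the membrane potential; the van Rossum distance in its closed
pairwise form with $\tau = 1$ ms (tested against numerical quadrature of
the filtered-train integral it equals); precision/recall/F1 on the common
sample grid, with the conventions that two empty trains score 1 and an
undefined ratio scores 0.

## A reduced-scale run

The full-length study takes hours; `scale = 0.1` preserves every firing
class and is what the package's acceptance checks use.  A small
illustration (three behaviors, three models):

```{r demo, eval = FALSE}
cfg <- benchmark_config(scale = 0.1, models = c("izhikevich", "ssrm", "rssrm"))
res <- run_benchmark(cfg, behaviors = c("a", "b", "q"), verbose = FALSE)
res$records[, c("behavior", "model", "n_params", "rmse", "vrd", "f1", "tau_max")]
```

Two structural results are worth understanding rather than just reading
off the tables:

* **Why the full spectral model interpolates.** With $2(n-1)$ columns the
  design spans (almost) the whole sample space *on the support of its
  channels*, so training RMSE collapses toward zero and F1 is exactly 1.
  For behaviors driven by brief pulses (spike latency, subthreshold
  oscillations, resonator, rebound spike/burst, threshold variability),
  every regressor is zero outside the pulse and the post-spike samples, so
  the fit is the constant intercept there and the RMSE is dominated by the
  unfittable subthreshold dynamics.  Mean training RMSE
  over the twenty behaviors is therefore a few mV, not near zero; this is
  a property of zero-baseline pulse protocols, not of the solver.
* **Why pruned lagged models are not catastrophic here.** With
  teacher-forced spike history, the first history lag alone pinpoints the
  post-spike reset, and L1 selection keeps exactly such lags.  The pruned
  lagged model (RSRM) is therefore not a weak baseline in this
  implementation: its average F1 sits close to — sometimes above — the
  pruned spectral model's, rather than collapsing.

## Limitations

* Free-running (closed-loop) generation is out of scope: spike-history
  regressors are always ground truth.
* Stimulus amplitudes, lag counts, the optimizer and the β-selection
  rule are package-level defaults, all configurable; what the test suite
  pins down are the structural results — exact worked examples, identity
  rows, design sizing, the interpolation property, and pruning robustness
  at reduced scale.
* Wall-time per record is collected for information only; it is
  hardware-dependent and not comparable across machines.
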