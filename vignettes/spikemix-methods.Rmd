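---
title: "Spike-triggered mixture models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-triggered mixture models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikemix)
```

This vignette is the package's own account of the models it implements, the
choices made where the design was genuinely open, and what its synthetic
benchmarks do and do not establish.

## The model family

All four families are Bernoulli-per-bin encoding models: the probability of
a spike in bin $t$ is $\sigma(f(x_t, s_t))$ with the logistic sigmoid
$\sigma$ and a family-specific predictor $f$ (see the README table). Three
facts organize the whole package:

1. **The generative view.** If the stimulus distribution in spike bins
   (spike-triggered) and in non-spike bins is Gaussian, Bayes' rule yields a
   quadratic predictor; equal covariances collapse it to a linear one. If
   the spike-triggered distribution is instead a mixture of $K$ Gaussians
   (and the non-spike-triggered one a single Gaussian), the predictor
   becomes a log-sum-exp — a soft maximum — of $K$ quadratics: the STM.
   `bayes_to_stm()` is this identity in closed form, and the package's
   tests hold it to $10^{-8}$ on random points, because it is an algebraic
   statement, not an approximation.
2. **Canonical parametrization.** The non-spike-triggered Gaussian's
   quadratic is absorbed into each component's $(A_k, w_k, a_k)$ (a
   difference of quadratics is quadratic), and the global bias into the
   per-component offsets $a_k$. Both choices remove redundancies — the
   class-conditional form is invariant to scaling both densities by a
   common factor — and make the parameter counts exact:
   `count_parameters()` agrees with the length of the flat vector the
   optimizer actually touches, for every family.
3. **The history term.** Intervals enter through a naive-Bayes log-ratio
   $\log g_1(\Delta t) - \log g_0(\Delta t)$ of time-since-last-spike
   histograms, which equals a linear filter $h$ applied to the one-hot
   most-recent-spike vector. The filter is shared across mixture
   components. Index 1 of $s_t$ is the most recent history bin (a spike
   one bin before $t$), time since the last spike growing with the index.

## Estimation

**Generative initialization.** The spike-triggered rows of the design are
fitted with a $K$-component Gaussian mixture by EM (kmeans++-style seeding,
5 restarts, best local optimum kept; covariances jittered by
$10^{-6}\times$ the mean diagonal whenever a Cholesky factorization fails).
The non-spike-triggered rows get a single maximum-likelihood Gaussian
($1/N$ normalization). Interval histograms receive a Laplace pseudo-count
of 0.5 per bin before normalization so empty bins produce finite filter
values. The prior log-odds of a spike is folded into the offsets $a_k$;
whether it should instead stay fixed during fine-tuning is not determined
by the model class, and folding it in lets the conditional likelihood
decide.

**Discriminative fine-tuning.** The mean Bernoulli negative log-likelihood
is minimized by L-BFGS-B with analytic gradients. Internally the objective
is in nats (cleaner gradients); everything reported to the user is in bits.
For the mixture families the stimulus-parameter gradients carry softmax
component responsibilities; every family's gradient is property-tested
against central finite differences. Probabilities are clipped to
$[10^{-12}, 1 - 10^{-12}]$ inside the likelihood, and bins saturated past
the clip contribute no gradient — this keeps the implemented gradient the
exact gradient of the implemented objective.

**Early stopping.** With `val_split` set, a trailing contiguous fraction of
bins is held out; the optimizer runs in chunks of `check_every = 5`
iterations, validation is evaluated after each chunk, and training stops
once `patience = 50` consecutive checks fail to improve on the best value
seen; the parameters at the best check are returned. A contiguous (rather
than random) split respects the serial dependence that spike history
induces between neighboring bins.

**The GLM pipeline.** Linear and quadratic models are fitted in three
stages: (1) the concave sigmoid-Bernoulli problem, which L-BFGS solves to
the global optimum (verified against an independent logistic solver to
$10^{-6}$ bits/bin); (2) joint alternating optimization of the filter and a
sum-of-Gaussian-blobs nonlinearity, $p(z) = \tanh(\sum_i \eta_i
\phi_i(z))$, whose $\tanh$ of a nonnegative blob sum keeps $p < 1$
(10 blobs by default, centers initialized on quantiles of the filter
response; 10 alternation rounds of at most 50 quasi-Newton iterations per
block — the alternation schedule is a free choice, and more rounds buy
little); (3) a 150-bin histogram estimate of $P(\mathrm{spike} \mid z)$,
which by construction reproduces the empirical bin frequencies on its own
training data. A held-out guard accepts a stage only if it does not degrade
validation cross-entropy by more than $10^{-3}$ bits/bin, so the flexible
stages can only help — the point of the multi-step procedure is to find a
linear-nonlinear description where one exists. The histogram stage needs a
few hundred samples per bin before its variance stops hurting; with less
data the guard simply rejects it.

**Factored STM.** Trained from small random initializations (entries with
standard deviation 0.1, offsets at the logit of the empirical spike rate so
the initial predictions match the mean rate); across seeds the final
held-out cross-entropy spreads by well under 0.03 bits/bin in the test
suite, so restarts are a robustness nicety rather than a necessity.

## Evaluation

`cross_entropy()` reports bits/bin and bits/s on held-out data.
`mi_lower_bound()` implements the spike-history decomposition: the
information rate about the stimulus is estimated as the cross-entropy drop
from a history-only model (the full model with stimulus terms dropped and
refitted) to the full model, divided by the bin width. The estimate can be
negative for models worse than the history baseline; that is a property of
the estimator, reported as-is.

The PSTH oracle predicts each frozen trial from the Gaussian-smoothed
average of the other $N-1$ trials plus a small offset, clipped just below
1. Kernel width (FWHM, converted to $\sigma$ via
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$, truncated at $\pm 4\sigma$) and
offset are chosen from log-spaced grids (0.05–5 ms, $10^{-4}$–$10^{-1}$ by
default) to minimize the mean leave-one-out cross-entropy, ties going to
the wider kernel and larger offset. Two conventions were open: the offset
is added *after* smoothing and before clipping, and smoothing is
edge-renormalized by the in-range kernel mass so a constant response stays
constant at the trial boundaries. Explained variance is the squared
Pearson correlation between smoothed rate vectors — affine-invariant and,
as with any PSTH-based $R^2$, strongly dependent on the kernel width used.

## The simulator and what the tests mean

The synthetic-data module emulates a low-pass-filtered (100 Hz) Gaussian
noise stimulation experiment: seeded white noise, 4th-order zero-phase
Butterworth low-pass, standardized to zero mean and unit variance; 10 ms
stimulus windows reduced to 10 principal components (PCA basis fitted on
training windows only, centered but *not* whitened); 25 ms of spike
history in 100 bins with all but the most recent spike removed; 50
unfrozen plus 50 frozen trials. The waveform runs at 4 kHz with 0.25 ms
spike bins, so one history bin equals one spike bin and no bin can hold
more than one spike. Windows end strictly before the bin they feed
(causality); bins without a full window are dropped and counted.

Ground-truth neurons are drawn per family with filters rescaled to a fixed
predictor dynamic range, a refractory-style history filter
($-5 e^{-(j-1)/4}$ in units of log-odds, strongly suppressing short
intervals), and the offset calibrated by bisection until the simulated
mean rate hits the requested value (20–120 Hz range, default 50 Hz, 3%
calibration tolerance averaged over four simulated trials). Spike sampling
is sequential with history feedback: the stimulus part of the predictor is
precomputed for all bins, then each bin's probability combines it with the
history term rebuilt from the spikes sampled so far.

What passing tests show — and what they do not: the synthetic benchmark
establishes *self-consistency* (a model fitted to data from its own family
recovers the generating model's held-out cross-entropy; richer families
order correctly on mixture-cell data; the PSTH behaves as an optimistic
history-free reference). Real afferent recordings differ in ways the
simulator does not emulate — non-Gaussian stimulus statistics after the
whisker/stimulator mechanics, adaptation on timescales beyond 25 ms,
nonstationarity across trials — so these tests validate the estimation
machinery, not the biological adequacy of any family.

**Problem sizes.** The test suite and the acceptance script run deliberately
desk-scale problems: recovery at 50,000 training bins ($D = 5$, $K = 3$,
$H = 20$), family ordering and data-efficiency curves at 10,000–20,000 bins
over 10 seeds, PSTH comparisons from 50 frozen trials of 4 s at 5
principal components. These sizes were chosen so that every claimed effect
is comfortably larger than its Monte-Carlo error at a few minutes of
compute; the same code runs the full 50-trial, 10-PC geometry unchanged.

## Numerical choices and degenerate inputs

* log-sum-exp uses max-subtraction; the sigmoid is computed in a
  saturation-stable form.
* Quadratic forms use the $\tfrac12 x^\top A x$ convention, $A$ stored
  symmetric and symmetrized on ingestion; the optimizer parametrizes the
  upper triangle so counts match free parameters.
* Repeated identical samples give a jittered covariance rather than an
  error; singular covariances in `bayes_to_stm()` raise an error
  suggesting jitter.
* Spike times bin by floor into half-open $[t\,dt, (t+1)\,dt)$ bins with a
  $10^{-9}$-bin guard, so written bin-start times re-bin exactly; two
  spikes in one bin collapse to one with a warning.
* Model containers are versioned JSON with numbers as full-precision
  decimal strings: round trips are bit-exact, truncated files and version
  mismatches fail loudly.
* The ridge penalty (off by default) exempts offsets; the reference
  protocol regularizes by early stopping only.

## Known limitations

* Output is Bernoulli per bin; Poisson counts and population coupling
  filters are out of scope.
* The mixture likelihood is non-concave: EM initialization plus
  quasi-Newton fine-tuning finds good optima in practice (and component
  permutations make many local optima equivalent), but there is no global
  guarantee.
* The MI estimate is a lower bound only in expectation; on finite test
  sets it fluctuates and can exceed the truth.
* History is limited to the most recent spike within the window —
  multi-spike history effects (bursting beyond the last interval) are not
  representable.
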