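---
title: "Dwell-time mixture analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dwell-time mixture analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwellmix)
```

## The measurement and its statistical model

In a single-molecule co-localization binding assay, a fluorescently
labelled RNA is flowed over surface-immobilized protein (here the RNA
chaperone Hfq, with or without the co-repressor Crc) and a camera records
fluorescence at fixed frame intervals. Each visit of a labelled RNA to an
immobilized protein produces a bright interval on that molecule's
intensity trace; the length of the interval is a *dwell time*. A
population of binding events with several distinct dissociation rates
produces dwell times distributed as a finite exponential mixture: with
probability $a_k$ an event has rate $1/\tau_k$, so

$$p(t) = \sum_{k=1}^{K} \frac{a_k}{\tau_k} e^{-t/\tau_k},
\qquad \sum_k a_k = 1 .$$

The amplitudes $a_k$ are the biologically interesting quantities — the
fraction of complexes in each kinetic class — and the $\tau_k$ are the
characteristic lifetimes of those classes.

Two instrument limits truncate what is observable. An event shorter than
the minimum resolvable interval $t_{min}$ (one camera frame by default,
0.1 s) is never seen, and no dwell can exceed the recording length
$t_{max}$ (180 s for a 3-minute movie). The likelihood therefore uses the
mixture density renormalized over $[t_{min}, t_{max}]$:

$$f(t) = \frac{\sum_k (a_k/\tau_k)\, e^{-t/\tau_k}}
{\sum_k a_k \left(e^{-t_{min}/\tau_k} - e^{-t_{max}/\tau_k}\right)} .$$

Because the normalizer carries the weights through the truncation, the
fitted $a_k$ keep their meaning as fractions of the *underlying* event
population, not of the observed subset. `truncated_pdf()` implements this
density, `neg_log_likelihood()` the corresponding objective over the
un-binned event durations.

Photobleaching of the dye is a competing first-order process: a bound
interval ends either by dissociation (rate $1/\tau$) or by bleaching
(rate $1/\tau_b$), so the observed rate is the sum $1/\tau + 1/\tau_b$.
With the canonical Cy5 bleaching lifetime of 173 s, a 60 s binding
lifetime is observed as $1/(1/60+1/173) \approx 44.5$ s; short lifetimes
are essentially unaffected. The simulator applies bleaching per event as
an independent exponential minimum, which is exactly the competing-risk
model above and reproduces the rate-addition property (verified in the
test suite by refitting simulated bleach-limited data).

## What the simulator emulates, and what it does not

`simulate_dwells()` draws events from a ground-truth mixture and pushes
them through the observation process in this order:

1. draw the binding duration from the mixture;
2. take the minimum with an exponential bleach time (when enabled);
3. discard events whose (raw) duration falls below $t_{min}$;
4. round surviving durations *up* to the next full frame — an event must
   occupy a frame to be detected;
5. drop (default) or cap events extending beyond $t_{max}$.

The discard step operates on the raw duration rather than the quantized
one so that the retained sample is exactly the left-truncated population
the likelihood describes; the discarded fraction then equals the mixture
CDF at $t_{min}$, which the test suite checks against its closed form.
Dropping right-censored events (`drop_incomplete`) matches a density
normalized over $[t_{min}, t_{max}]$; `cap_at_window` is retained for
sensitivity analysis only.

The default ground-truth parameters are the published operating points of
the assay, exposed by `study_models()`: the full-length substrate binds
Hfq in a 0.56/0.44 mixture of 2 s and 60 s complexes; 100 nM Crc shifts
the amplitudes to 0.30/0.70 without moving the lifetimes; the
downstream-motif mutant is a three-state 0.81/0.05/0.14 mixture with an
additional ~0.4 s transient class. Sample sizes in the workflow scripts
(5000 events per two-state condition, 8000 for the mutant, whose transient
events are heavily thinned by the one-frame resolution limit) give
parameter recovery comfortably inside the reported uncertainties while
each stage stays in the seconds-to-minutes range on one core.

The simulator reproduces the statistical structure of the measurement,
not its optics: no point-spread functions, drift, spot overlap, dye
blinking, or flow dead time. Passing recovery tests on these synthetic
data therefore demonstrates correctness of the estimators under the
assumed model; it cannot certify robustness to image-level artefacts that
real traces may carry.

Intensity traces (`simulate_traces()`) are a deliberately minimal additive
model — baseline, a fixed event amplitude, white Gaussian noise at a given
SNR — sufficient to exercise the event caller against planted ground
truth. `call_events()` binarizes at a threshold, bridges dark gaps up to a
tolerance (0 frames by default: one dark frame ends an event), and treats
runs touching the final frame as right-censored. The default threshold is
the baseline mean plus 3 standard deviations, with both moments estimated
from the lowest-intensity 20% of frames; since that subset is the lower
tail of the baseline noise, its mean and spread are corrected for the
truncation under a Gaussian assumption (the uncorrected tail statistics
would place the threshold *below* the baseline mean and flood the caller
with false events). At 3 standard deviations roughly 0.13% of baseline
frames still exceed the threshold, so long recordings produce occasional
one-frame spurious calls; raising `min_frames` suppresses them at the
cost of the shortest real events. A strict monotonicity of event counts
in the threshold holds only while the scanned thresholds stay above the
inter-event baseline — lowering the threshold into the baseline noise can
merge adjacent events and *reduce* the count — and the test suite states
the property in that regime.

## Fitting

`fit_mixture()` maximizes the truncated-mixture likelihood with the
weights mapped through a softmax (simplex constraint) and the lifetimes
on the log scale, giving an unconstrained $2K-1$-dimensional problem
solved by BFGS. Because the likelihood is multimodal in the label
ordering and can have minor local optima, the fit is multi-start: one
data-driven start (lifetimes at spread quantiles of the observed dwells,
equal weights) plus seed-derived random starts (lifetimes log-uniform
over the window, weights uniform on the simplex), 20 starts by default.
The best local optimum wins; ties go to the lowest start index, so
results are reproducible bit-for-bit given the data and seed. Lifetimes
are reported in ascending order with the weights permuted accordingly,
which makes the labelling permutation-invariant. Convergence uses a
relative log-likelihood tolerance of 1e-10 with up to 2000 iterations;
a fit in which two lifetimes land within 5% of each other is flagged as
exceeding the resolvable number of components.

One numerical point deserves mention: the window normalizer
$e^{-t_{min}/\tau} - e^{-t_{max}/\tau}$ loses all precision to
cancellation when $\tau$ far exceeds the window, and the resulting noise
creates a spurious direction of unbounded likelihood. The implementation
evaluates it as $e^{-t_{min}/\tau}\,(-\mathrm{expm1}(-(t_{max} -
t_{min})/\tau))$, which is exact in that limit (the truncated law tends
to the uniform density on the window).

The likelihood treats the frame-quantized durations as continuous. For
lifetimes of five frames or more the bias this introduces is below the
statistical noise at the sample sizes used; at two frames
(τ = 0.2 s at 0.1 s frames) the ~0.05 s round-up shift is a ~25% relative
effect on that component's lifetime, while the mixture *weights* remain
accurate — the three-state recovery tests document this regime.

`select_K()` fits each candidate $K$ and picks the smallest BIC,
$-2\log L + (2K-1)\log n$. The assay itself fixes $K$ per construct (two
states for the full-length substrate, three for the motif mutants); BIC
reproduces those choices on simulated data at the study's sample sizes,
and a forced-$K$ fit is always available via `fit_mixture()`.

## Uncertainty and condition comparison

`bootstrap_fit()` resamples the events with replacement (1000 replicates
by convention), refits each replicate warm-started from the base optimum
plus a few random restarts, and reports the standard deviation of each
parameter across replicates — numerically the same σ as fitting a normal
distribution to the bootstrap values. Replicates in which no start
converges are dropped and counted; a summary with more than 10% failures
is marked invalid. A per-molecule block bootstrap is available for data
with within-molecule correlation; the default resamples individual
events, matching the convention of bootstrapping the initial data.

For three-component fits the residual amplitude $a_3 = 1 - a_1 - a_2$ has
the propagated error $\sigma_{a_3} = \sqrt{\sigma_{a_1}^2 +
\sigma_{a_2}^2}$ (`propagate_residual_sigma()`). This assumes $a_1$ and
$a_2$ resample independently; simplex-constrained amplitudes are in fact
correlated, and the direct bootstrap σ of $a_3$ differs by exactly
$2\,\mathrm{cov}(a_1, a_2)$ in variance. The package reports both, and a
test verifies the variance identity on a correlated fit. Histogram error
bars use the binomial standard deviation $\sqrt{NP(1-P)}$
(`histogram_bar_sigma()`).

`compare_conditions()` forms $z = (A - B)/\sqrt{\sigma_A^2 + \sigma_B^2}$
and reports a two-tailed p value. The default reference distribution is
the standard normal, treating the bootstrap σ as the estimator's standard
error; it is not asserted that this reproduces the original analysis'
degrees-of-freedom choice, which is unstated, so a Welch-style t
reference with user-supplied df is provided for parity exploration. With
both σ zero the comparison is degenerate and flagged as such (p = 0 for
unequal estimates, p = 1 for equal ones).

## Half-life estimation

The rifampicin-chase analysis normalizes the target signal to a reference
RNA (16S rRNA) and sets time zero to 100%
(`normalize_to_reference()`; the result is invariant to rescaling either
signal). Two estimators are provided:

* **first-order** (`fit_first_order()`): ordinary least squares of
  $\ln(\%)$ on time — the spreadsheet "exponential trendline" convention,
  chosen over direct nonlinear exponential fitting to match how such
  trendlines are conventionally computed; $k = -$slope, $t_{1/2} = \ln
  2/k$, $R^2$ on the log scale. A direct comparison on noiseless data is
  part of the test suite (both recover the generating half-life exactly).
* **linear** (`fit_linear()`): OLS of % on time; $k^* = -$slope in %/min,
  $t_{1/2} = 50/k^*$, $R^2$ on the linear scale. This is the fallback for
  transcripts that do not decay with first-order kinetics.

`choose_method()` selects first-order when its log-scale $R^2$ is at
least 0.90 (a declared operationalization of the qualitative "followed /
did not follow first-order kinetics" judgement) and the series actually
decays; otherwise linear. One caveat is worth knowing: over a short
sampling span, a linear time course barely curves on the log scale — a
linear decay with a 10.4 min half-life sampled only to 8 min has log-scale
$R^2 \approx 0.996$ and would be classified first-order. The workflow
therefore samples slow, non-exponential decays far enough into the decay
(to ~20 min, reaching <40% remaining) for the distinction to be
identifiable. Degenerate inputs are handled explicitly: fewer than three
points is an error, non-positive percentages name the offending time
point, a non-negative slope yields a "no decay" result without a
half-life, and a normalized series rising above 100% is flagged as
non-decaying.

## Numerical and reproducibility choices

All stochastic operations take explicit integer seeds; derived sub-seeds
come from a seeded `sample.int()` stream, and every seeded helper
restores the caller's RNG state. Identical configuration and seed give
bit-identical datasets, fits and result documents (the pipeline test
compares files byte for byte; the provenance record echoes the
configuration without the run-specific output path for this reason).
Result documents are JSON with a human-readable block rounded to six
significant digits and a machine block at full precision.

Sizes used by the default test run — chosen to keep each recovery check
well-powered at realistic event counts — are 5000 events for two-state
fits, 8000 for three-state, bootstrap sizes of 150–250 replicates for
σ-scaling checks (the workflow scripts use the full 1000), and five
repeated seeds for the recovery criteria.

## Known limitations

* Lifetimes are fitted per condition; the assay's observation that Crc
  leaves the lifetimes unchanged suggests a shared-lifetime joint fit
  could gain precision, but such sharing is not implemented because the
  original analysis does not state it.
* The exact $t_{min}$ and $t_{max}$ of the original fits are not printed;
  both are parameters here, defaulting to one frame and the movie length.
* Whether the original dwell-time sets included right-censored events is
  unknown; `censoring_policy` makes the choice explicit and the default
  (`drop_incomplete`) is consistent with the windowed normalization.
* The continuous likelihood on quantized data biases sub-five-frame
  lifetimes (see above); an explicitly discretized likelihood would
  remove this at the cost of departing from the published form.
* Bootstrap σ values scale as $1/\sqrt{n}$, so comparisons against
  published σ are order-of-magnitude checks unless the original event
  counts are known.
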