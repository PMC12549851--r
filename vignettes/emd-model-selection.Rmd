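---
title: "Risk-based model selection with empirical model discrepancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-based model selection with empirical model discrepancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdselect)
```

## The problem

Suppose several probabilistic models have already been fitted — possibly
structurally identical, differing only in parameter values — and all of them
describe a held-out test dataset about equally well. Which should be
rejected? Ranking by empirical risk (the mean pointwise loss on the test
data) always produces a winner, even when the difference is far smaller than
what a replication of the experiment would reproduce. The quantity that is
missing is an *uncertainty on each model's risk* that reflects the
variability of the replication process itself, which is typically
non-stationary: tomorrow's dataset comes from a slightly different
data-generating process than today's.

`emdselect` implements a nonparametric answer. A model is only rejected when
a competitor is *reproducibly* better, in the sense that the tail
probability `P(R_A < R_B)` between two risk distributions clears a threshold
`epsilon`. The risk distributions are built from a single test dataset, with
no knowledge of the true process, by exploiting the self-consistency of each
model: how well its own synthetic data reproduce the statistics of its loss
on the real data.

The package needs only two capabilities per model, declared through
`candidate_model()`: evaluate a pointwise loss `Q(x, y)` (usually the
negative log likelihood) on records of a dataset, and sample synthetic
`(x, y)` pairs. The loss must be finite on every test record — a model that
assigns zero probability to an observation cannot be scored.

## From losses to quantile functions

The risk `R_A = E[Q]` depends on the loss distribution only through its
quantile function (PPF). Writing `q*_A(Phi)` for the quantile function of
the loss of model A evaluated on data from the true process (the *mixed*
PPF — loss under the model, distribution under the data),

    R_A = integral of q*_A(Phi) over Phi in [0, 1],

which `ppf_risk()` evaluates by the trapezoidal rule. Because the loss is
scalar, this holds in any data dimension.

`empirical_ppf()` estimates a PPF from `L` per-sample losses: sort, place
the order statistics at `Phi_i = i / (L + 1)`, and interpolate linearly onto
a uniform grid of `n_grid = 1024` interior points. Two conventions are worth
stating explicitly:

* **Endpoints.** The process construction below needs `q*(0)` and `q*(1)`,
  which order statistics do not define. The stored grid therefore carries
  explicit endpoints at `Phi = 0` and `Phi = 1` by constant extrapolation of
  the first and last ordinate. This is a choice; any extension consistent
  with monotonicity would do, and its influence is confined to the two
  endpoint draws.
* **Ties.** Tied losses produce flat PPF segments. All machinery only
  requires nondecreasing, not strictly increasing, curves.

The same loss evaluated on `l_synth = 4096` samples that the model generates
itself gives the *synthetic* PPF `q~_A`. Their pointwise gap

    delta_A(Phi) = | q~_A(Phi) - q*_A(Phi) |

is the *empirical model discrepancy* (`delta_emd()`). It vanishes
identically when the model reproduces the observations exactly, and grows
with misspecification — or with sampling noise when `L` is small, which is
the correct behaviour, since both effects limit what a replication will
reproduce.

## A stochastic process over quantile functions

The central assumption is a linear conversion from discrepancy to epistemic
uncertainty: across hypothetical replications, the loss PPF of model A is
treated as a random function centred on `q*_A` whose spread at `Phi` scales
with `sqrt(c) * delta_A(Phi)`. The dimensionless sensitivity factor `c` is a
property of the experiment, shared by all candidates, and is validated by
the calibration procedure described below.

Valid realisations must be monotone (they are quantile functions),
integrable, and *non-accumulating*: unlike Brownian-type processes, there is
no privileged direction in `Phi` along which variance should grow, because
loss samples arrive in no particular order. These constraints rule out
standard processes, and are met by the *hierarchical beta process*
implemented in `hb_process_spec()` / `sample_realisation()`:

1. Draw the endpoints `q(0) ~ N(q*(0), c delta(0)^2)` and
   `q(1) ~ N(q*(1), c delta(1)^2)` independently, redrawing until
   `q(0) < q(1)` (at most `max_endpoint_rejections = 1000` times; since the
   means are ordered each attempt succeeds with probability at least 1/2,
   so the cap is a safety valve, not a tuning knob).
2. For refinement levels `n = 1, ..., N`, split each increment over
   `[Phi, Phi + 2^(1-n)]` at its midpoint by a draw `x1 ~ Beta(alpha, beta)`
   and set `q(mid) = q(left) + x1 * (q(right) - q(left))`. Increments stay
   nonnegative, so monotonicity is automatic; sampled points are never
   revisited, which makes the process self-consistent under deeper
   refinement.

The beta parameters at each midpoint are chosen so that, in the Aitchison
geometry natural to compositional pairs `(x1, 1 - x1)`, the *centre* of the
split matches the split of `q*` and the *metric variance* matches the
discrepancy: with

    r = (q*(mid) - q*(left)) / (q*(right) - q*(mid)),
    v = 2 c delta(mid)^2,

solve `psi(alpha) - psi(beta) = log r` and
`psi_1(alpha) + psi_1(beta) = v` (`solve_beta_params()`), where `psi` and
`psi_1` are the digamma and trigamma functions. Ordinary beta moments would
couple the two equations badly near the boundary; the Aitchison metric
variance is unbounded, so the system is solvable for any requested spread.
The centre condition holds exactly (`E[log(x1/x2)] = psi(alpha) -
psi(beta)`); the variance condition is met at the level of increment pairs,
while the marginal spread of `q(Phi)` tracks `c delta(Phi)^2` only
approximately — the price of enforcing monotonicity exactly.

Numerical choices, all confined to degenerate corners:

* `(alpha, beta)` are solved by a damped Newton iteration in
  `(log alpha, log beta)` seeded from the large-argument asymptotics
  `psi(z) ~ log z`, `psi_1(z) ~ 1/z`, with a nested-bisection fallback
  that exploits the monotonicity of both functions. Residuals are driven
  below `1e-10` in the transformed equations except within a digamma
  cancellation floor (~`1e-8`) near the variance cap.
* Flat regions of `q*` carry no information about the split: one-sided flat
  increments clip `log r` to `±log(1e12)`; fully flat increments split
  deterministically at `x1 = 1/2`. The target `v` is floored at `1e-12` and
  capped at twice `psi_1(1e-8)` to keep the parameters representable.
* The `(r, v, alpha, beta)` table depends only on `(q*, delta, c)`, so it is
  computed once per process specification and shared by all realisations.
* `c = 0` (or `delta == 0`) bypasses sampling entirely and returns `q*` on
  the dyadic grid, avoiding zero-variance Gaussian edge cases.
* Midpoints are clamped into their bracket after assembly; a beta draw of
  exactly 0 or 1 could otherwise overshoot by one floating-point ulp.

`N = 8` refinement levels (a grid of 257 points) is the default; risk
integrals change negligibly under further refinement at the problem sizes
the package targets.

## Risk distributions, tail probabilities and the rejection rule

`sample_risk_distribution()` integrates realisations into risks, drawing in
batches of 16 (after a minimum of 32) until the relative standard error of
the mean risk falls below `2^-5` (about 3 %) or 4096 realisations are
reached; typical runs need on the order of a hundred. If the mean risk is
numerically zero the relative criterion is undefined and an absolute
standard-error criterion is used, flagged in the output.

`b_emd(A, B)` estimates `P(R_A < R_B)` as the fraction of ordered sample
pairs with `R_A[i] < R_B[j]`, computed by sorting and counting — identical
in value to the literal double sum. Ties count for neither direction; with
continuous risks the two ordered probabilities sum to exactly 1.

The ternary rejection rule (`emd_reject()`): reject model A when some B has
`P(R_B < R_A) > epsilon` **and** a lower empirical risk. The rule is
sometimes stated as "reject A when `B^EMD_AB < epsilon`", which for
`epsilon > 0.5` contradicts the ternary structure it is meant to implement
(it would reject at `B = 0.6` with `epsilon = 0.9`); the package follows
the ternary reading by default and keeps the literal one behind
`literal_threshold = TRUE`, documented, for comparison. The second condition keeps the rule consistent when risk
distributions are skewed. Raising `epsilon` can only shrink the rejected
set. For chains of comparisons, `transitivity_check()` certifies
`B_AC > epsilon` from `B_AB, B_BC > sqrt(epsilon)` whenever `epsilon`
exceeds the inverse squared golden ratio — a property of tail probabilities
between independent variables, exact also for the empirical estimates.

## Calibration of the sensitivity factor

`c` converts discrepancy into epistemic variance and cannot be validated
from one dataset. `run_calibration()` simulates the replication process: an
*epistemic distribution* (`epistemic_distribution()`) draws a concrete
data-generating process per experiment; a replicate dataset is generated;
per-replicate nuisance parameters of both candidates are refitted; `B^EMD`
is computed at the candidate `c`; and the ground truth `[R_A < R_B]` is
recorded from large-sample true risks under the drawn process. Sorting the
records by `B^EMD` and binning them into equal-count bins
(`bin_calibration()`) gives the conditional `B^epis` curve — equal counts
so each bin carries similar statistical power.

A usable `c` makes `B^EMD` correlated with `B^epis` while staying
conservative: `|B^EMD - 0.5|` should not exceed `|B^epis - 0.5|`.
`overconfidence_check()` operationalises the soft inequality by flagging a
bin when the `B^EMD` deviation exceeds the `B^epis` deviation by more than
one binomial standard error of the bin estimate (the slack is configurable;
one SE admits the "small violations" a soft bound intends), or when the two
deviations point to opposite sides of 1/2. With several epistemic
distributions, the per-bin minimum `|B^epis - 0.5|` across them is used, so
conclusions hold under every ensemble tested. Too small a `c` shows up as
saturated `B^EMD` values (overconfidence); too large a `c` weakens the
criterion — and because monotonicity caps the achievable metric variance,
very large `c` distorts realisations into step-like curves rather than
simply widening them, so comparisons degrade gradually and bin-level
association with the ground truth need not vanish entirely.

Experiment `j` of a run uses a child seed derived from `(seed, j)`, so runs
are reproducible record-for-record and could be parallelised
deterministically.

## The built-in black-body test bed

The package ships a fully offline example in which the data-generating
process and both candidates are known analytically. A simulated spectrometer
observes the spectral radiance of a black body at `T = 4000` K on a uniform
wavelength grid: photon counts are Poisson with mean `s * B(lambda; T)`,
rescaled by the gain `s = 1e5` (m^2 nm photons sr kW^-1) back to radiance
units, plus an optional sensor bias `b0`. The two candidate mean curves are
the Planck law and the classical Rayleigh-Jeans law, which agree at long
wavelengths and diverge catastrophically in the visible. Both candidates
assume additive Gaussian noise — deliberately wrong against Poisson data —
with the noise scale refitted per dataset by maximum likelihood
(`fit_sigma_mle()`: the root mean squared residual). Physical constants are
CODATA 2018; temperature is treated as known (refitting `T` per replicate
would add a second nuisance dimension orthogonal to what the example is
for). The default detection window, 6–20 µm, is the ambiguous regime where
both laws fit comparably; a visible window (e.g. 0.4–0.75 µm) makes the
comparison decisive.

The reference epistemic distribution (`blackbody_epistemic_dist()`) draws
the physical law uniformly from both candidates and the bias uniformly from
`[-1e-4, 1e-4]` radiance units, holding everything else fixed.

What the generator emulates: counting noise with variance tied to the mean,
mild structural misspecification (Gaussian vs Poisson), an adjustable
bias/misspecification axis, and an adjustable ambiguity axis (the window).
What it does not: wavelength-dependent detector response, correlated or
drifting noise, real calibration error in `T`, or any time-series structure
— losses are i.i.d. across records, which is also what the comparison
machinery assumes. Passing tests on this bed therefore exercise the full
pipeline under controlled misspecification, but say nothing about
correlated-sample data, for which losses would need thinning before use.

## Problem sizes and reproducibility

The test suite runs the pipeline at the sizes used throughout the package's
own studies: test datasets of 1024 points, synthetic PPFs from 4096 model
samples, 1024-point PPF grids, risk distributions of order 100 samples, and
a calibration of 256 simulated experiments of 1024 points aggregated into
16 equal-count bins at `c` in `{2^-12, 2^-1, 2^6}`. Every stochastic step
derives from an explicit seed; `run_compare()` / `run_calibrate()` write
full-precision CSVs plus a JSON manifest (seed, version, timing) so reruns
are byte-identical.

## Known limitations

* The linear discrepancy-to-uncertainty conversion is an approximation; it
  is most trustworthy when `delta` is not large relative to the PPF spread
  and `c` lies in the calibrated range (around `2^-4` to `2^0` in the
  shipped example).
* At very large `c` the monotonicity constraint bounds the achievable
  variance; realisations become step-like and the marginal-spread
  proportionality degrades, so calibration curves at such `c` should be
  read qualitatively.
* Ties in risk samples break exact complementarity of `b_emd` by the tie
  mass; continuous losses make this a measure-zero concern.
* No multiple-comparison correction is applied when many models are
  compared simultaneously; `epsilon` is a per-pair threshold.
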