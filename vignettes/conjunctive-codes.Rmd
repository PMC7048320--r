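---
title: "Conjunctive population codes: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conjunctive population codes: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjcode)
```

## The coding problem

A stimulus is a point on a discrete grid: `K` features, each taking one of
`n` values, for `M = n^K` stimuli in all. A population code assigns each
stimulus a binary activity pattern (codeword) across a set of units
("neurons"). The codes studied here are *conjunctive*: a unit of order `O`
fires only when a specific combination of `O` feature values is present.
`O = 1` is classical pure selectivity (one unit per single feature value);
`O = K` is full nonlinear mixed selectivity (one unit per stimulus, a
one-hot code); intermediate orders mix subsets of features. Every code has
complete coverage — one unit for every value combination within every
size-`O` feature subset — so every stimulus gets a unique codeword.

The scientific question is a channel-coding one: given a noisy readout,
which order is the most reliable and metabolically efficient way to
transmit the stimulus identity?

## Code geometry in closed form

For `rf_width = 1` the package's closed forms are exact and are
cross-checked against exhaustive enumeration in the test suite:

* population size `D_O = choose(K, O) * n^O` (`population_size()`);
* representation energy `P_O = choose(K, O)` under the squared-distance
  accounting (`representation_energy()`), i.e. one active unit per feature
  subset;
* minimum inter-codeword distance `Delta_O = sqrt(2 * choose(K-1, O-1))`
  (`min_distance()`), attained by stimulus pairs differing in one feature;
* the distance spectrum `d(K, O, v)` over the number `v` of differing
  features (`pairwise_distance()`), with `N_all(v) = choose(K, v) (n-1)^v`
  pairs per stimulus at each `v` (`count_at_distance()`).

The ratio `Delta_O^2 / P_O = 2 O / K` is exact and strictly increasing in
`O`: given the same spiking budget, more conjunctive codes place codewords
further apart. That single line is the geometric core of everything else
in the package.

Two energy accountings coexist. The *squared-distance* variant
(`P = choose(K, O)`) is what the closed forms above use. The *variance*
variant (`P = choose(K, O) (1 - n^-O)`) subtracts the squared mean rate,
which slightly favors pure codes (their units fire more often, so more is
subtracted). Simulations default to the variance variant — the
conservative choice when the claim under test is that mixing helps — and
analytic reports default to squared distance. When overlaying a
union-bound curve on simulated points, the bound must be computed under
the same variant that scaled the simulated codewords
(`ube_error(..., energy_variant = "variance")`); mixing the two
conventions inflates the pure code's apparent error by ~25% at `n = 5`.

A third accounting, `sum_of_spikes`, counts active units; for binary
codewords it coincides with squared distance.

## The linear transform

Codes of different orders are compared at equal representation energy `V`
and population size `N` by applying an `N x D_O` matrix `beta` with equal
column lengths `H = sqrt(V / P_O)` and (pseudo)orthonormal columns
(`make_transform()`, `verify_transform()`). Such transforms scale every
pairwise distance by exactly `H` and cannot change the relative geometry,
so decoding performance depends on `beta` only through `V`. The package
provides the exactly orthonormal styles (`identity_scaled`, used in all
simulations for speed and interpretability; `random_rotation`;
`random_embedding`) and a `gaussian` style with renormalized i.i.d. normal
columns, which satisfies the orthogonality constraints only approximately
at finite `N` — both are offered because either reading is consistent with
how such transforms are described in the literature. Monte-Carlo error
rates are invariant across styles at fixed `V` (tested within binomial
sampling error).

## Channel, decoder, and error metrics

The default channel adds independent Gaussian noise of variance `sigma2`
to every coordinate of the transformed codeword; the population
signal-to-noise ratio is `SNR = V / sigma2`, and only this ratio matters.
Maximum-likelihood decoding under isotropic Gaussian noise is
nearest-codeword decoding; ties (a measure-zero event, but reachable with
constructed inputs) resolve to the lowest stimulus index and are flagged.
Two Poisson channels are included: pure Poisson (rates equal to the
transformed activity, with *exact* zero-rate handling — a codeword with a
silent unit is impossible once that unit spikes; there is no epsilon
floor) and Poisson-with-baseline (rates shifted by `r_spont`, SNR defined
as `V / r_spont`).

Input noise is modeled two ways. *Local* noise moves each feature to an
adjacent value with probability `p_shift` (boundary values move inward
with the full probability mass — the model keeps the per-feature
perturbation rate constant rather than letting it vanish at the edges,
which is a choice the discrete geometry forces). Because such
perturbations land on valid nearby stimuli, they corrupt every code order
equally; the test suite verifies that the resulting error rate is
`1 - (1 - p_shift)^K` independent of `O`. *Bit-flip* noise corrupts the
order-1 input representation bit-by-bit; the corrupted bits can either
feed the conjunctive indicator products directly (`direct`) or be snapped
to the nearest valid stimulus first (`clean`). Both pipelines are exposed
because the generative description does not determine which is meant; they
differ only at second order in `p_flip`.

Two error metrics are reported per simulation: the error rate PE (any
mis-decoding) and the mean squared feature-space error MSE (squared
integer value distance summed over features; a circular variant serves
direction-like features). Every error moves at least one feature by at
least one step, so `MSE >= PE` under the linear metric.

## Union-bound error estimate

For ML decoding under Gaussian noise, the probability of preferring a
codeword at distance `d` is `Q(d / (2 sigma))`, with `Q` the
standard-normal upper tail (computed with `pnorm(lower.tail = FALSE)`;
naive `1 - pnorm` underflows at the SNRs of interest). Summing over all
error destinations grouped by `v` gives the full union bound; truncating
to minimum-distance neighbors gives
`PE ~ N_Delta(O) Q(sqrt(SNR * O / (2K)))`, which is strictly decreasing in
`O` for `O < K` — the headline reliability result. `N_Delta(O)` is
`K (n-1)` for `O < K` and `n^K - 1` for the fully mixed code (every other
stimulus is equidistant).

The bound's slack is worth knowing about. For `O < K` it converges to the
Monte-Carlo error rate at high SNR. For `O = K`, the error events toward
different destinations are positively correlated (every pair of one-hot
difference vectors shares the true stimulus's coordinate, correlation
1/2), so the union bound stays a factor of ~1.5–2 above the true rate even
when errors are rare; it is still an upper bound, and on the logarithmic
scales used to compare orders the gap is immaterial. The acceptance test
checks agreement at the highest SNR at which the simulation still records
errors.

An analogous truncated bound for decoding a *single* feature uses the
count of minimum-distance destinations that corrupt that feature:
`n - 1` for `O < K`, `(n - 1) n^(K-1)` for `O = K` (`feature_error()`).
Single-feature decoding is implemented as full-stimulus ML decoding
followed by projection, matching the way the neighbor counts are derived.

## Metabolic budgets and optimal order

Total energy is `E = eps * V + D_O`: each unit costs one maintenance unit
whether or not it spikes, and spiking costs `eps` per unit of
representation energy. `eps` defaults to 50, the midpoint of the
order-of-magnitude experimental range (10–100); the *relative* ordering of
code orders is provably independent of `eps`. A code is feasible iff
`E > D_O`, and then `delta^2 = (2 O / (K eps)) (E - D_O)`. Equating
consecutive orders gives the exact crossover
`E(O -> O+1) = (nK - (n+1) O) choose(K, O) n^O`; `optimal_order()`
reproduces these switch points exactly (ties resolve to the lower order),
and the threshold above which *some* mixed code beats the pure code is
`n^2 K^2 - n^2 K - n K < n^2 K^2`.

## Receptive-field widening

With `rf_width = s > 1`, units respond to intervals of `s` consecutive
values per feature. The construction tiles each axis with step-`s`
intervals at `s` lattice offsets (boundary intervals truncated), with the
`O` features of a unit sharing an offset; every stimulus then activates
exactly `s` units per feature subset (`P = choose(K, O) s`) and the joint
pattern remains unique. The supported geometry requires `s | n`. The
constructive unit count is `choose(K,O) ((n/s)^O + (s-1)(n/s+1)^O)`;
the commonly quoted closed form `choose(K,O) s (n/s + 1)^O` treats all
offsets as having `n/s + 1` intervals and so overcounts slightly (and does
not reduce to `n^O` at `s = 1`). `build_rf_codebook()` reports both values
and does not force agreement; all downstream budgeting uses the
constructive count, since those are the units actually maintained.
Minimum distance is independent of `s` (verified by brute force).

Widening RFs trades error *rate* for error *size*: errors become confined
to stimuli whose RFs overlap the true one, so they are small in feature
space, while the extra representation energy per codeword buys no extra
minimum distance, so errors become more frequent. Which effect wins at a
*fixed total energy* depends on the budget regime, and the package is
explicit about this because it is easy to mis-read:

* when spiking dominates the budget (`eps V >> D_O`), the classical
  pattern holds — PE rises and MSE falls with `s`;
* at low budgets, the *maintenance savings* of wider RFs (they need
  roughly `1/s^(O-1)` as many units) free enough energy that both PE and
  MSE improve with `s`.

The `fig3` sweep preset therefore uses `K = 3`, `n = 10`,
`sigma2 = 10` (the noise variance used in the reference energy analyses),
`eps = 50`, and `E = 19000`, which sits in the spiking-dominated,
non-saturated regime where both configurations make measurable errors at
2,000 trials per point. For the fully mixed code with `s = 1`, error
destinations are uniform over all wrong stimuli (checked by chi-square),
which is exactly the pathology that widening RFs repairs.

## Continuous stimuli

`continuous_simulate()` carries the construction to features on `[0, 1)`:
each axis is divided into `n_centers` base cells, boxcar RFs span
`rf_scale` cells at `rf_scale` offsets, and stimuli are drawn uniformly.
With boxcar tuning the response is piecewise constant on base cells, so
ML decoding on cell centers is exact and the MSE floor is the
quantization term `K w0^2 / 12` (`w0 = 1/n_centers`); a Gaussian-tuning
option gives graded responses decoded on a finer grid. At matched energy
and moderate SNR (the preset uses `SNR = 30`), mixed codes again beat pure
codes on MSE; unlike the discrete case, MSE *increases* with RF size
here, because wider boxcars add no information beyond the cell identity —
the energy they consume is pure redundancy at the same minimum distance.
The defaults (`K = 3`, 5–6 cells per axis, 2,000–3,000 draws) keep the
decode grid small; the qualitative pattern is insensitive to the lattice
resolution.

## Information-theoretic evaluation

`mutual_information()` is the uncorrected plug-in estimate from the
simulation's confusion matrix; at the trial counts used (≥ 5,000 per
point) and `M <= 125` the upward bias is a few hundredths of a bit and
does not affect the comparisons made. The reference curve is the
rate-distortion function of a uniform `M`-ary source under symbol-error
distortion, `R(D) = log2 M - Hb(D) - D log2(M - 1)`, computed in closed
form; an independent Blahut–Arimoto iteration in the test helpers
confirms the curve numerically, since no printed values exist to compare
against. A simulated code with error rate PE and information `I` is
feasible iff `I >= R(PE)`; the gap `I - R(PE)` measures how efficiently a
code converts channel information into correctness. Across matched SNRs
the fully mixed code's gap is consistently below the pure code's, and the
acceptance test asserts exactly that.

## Problem sizes and determinism

All simulation grids in the tests and presets are sized for a laptop-class
single core: the SNR sweep (`fig2a`) runs 3 orders x 10 SNRs x 2,000
trials in about a second; the RF sweep (`fig3`) and the rate-distortion
evaluation take a few seconds each. Every stochastic routine takes an
explicit seed, per-grid-point seeds are derived deterministically from a
master seed and recorded in the output manifest, and re-running a sweep
with the same config yields byte-identical CSV output.

## Known limitations

* Heterogeneous per-feature cardinalities (`n_i` varying across features)
  are not supported; the uniform-`n` assumption changes only population
  size, not distances or energies.
* Codes are exhaustive by construction; randomly subsampled conjunctive
  codes and learned codes are out of scope.
* Output noise is isotropic; correlated noise and non-ML decoders are not
  modeled.
* RF widths must divide `n`; heterogeneous widths within a code are not
  supported.
* The fully mixed code's union bound retains a constant-factor slack (see
  above); treat it as a bound, not an estimate, for `O = K` at moderate
  error rates.
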