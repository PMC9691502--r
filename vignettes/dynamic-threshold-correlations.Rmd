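---
title: "Dynamic-threshold spike trains with prescribed interval correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic-threshold spike trains with prescribed interval correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynthresh)
```

## The model and its assumptions

Many spontaneously active neurons fire with negatively correlated
interspike intervals (ISIs): a short interval is preferentially followed by
a long one. `dynthresh` implements a deliberately minimal encoder that
isolates the mechanism behind these correlations. A constant bias voltage
$v$ (volts) faces a dynamic threshold $r(t)$ that jumps by $A$ volts at
every spike and decays exponentially with time constant $\tau$ (ms),
*without resetting*; the running sum over past jumps is the memory of the
spike train. A spike fires when the coding error $e(t) = v - r(t)$ reaches
the spike threshold $\gamma$. There is no membrane integration, no voltage
reset, no refractory period, no adaptation current, and the input is
DC-valued: every simplification keeps the spike generator as the sole
nonlinearity so that the correlation structure is analytically traceable to
the noise.

Stochasticity enters through the spike threshold: $\gamma_i$ is redrawn
immediately after spike $i-1$ from a wide-sense stationary process with
mean $\gamma$, power $R_0$ and discrete autocorrelation $R_k$ (lags counted
in intervals), and held constant until spike $i$. At high firing rates the
exponential decay linearizes to slope $-m$, $m = (v-\gamma+A)/\tau$, and
the intervals obey

$$X_i = \frac{\gamma_i - \gamma_{i-1} + A}{m},$$

so the ISI sequence is the *first difference* of the noise plus a constant.
Two consequences drive everything in this package:

* the serial correlation coefficients (SCCs) are
  $\rho_k = -(R_{k-1} - 2R_k + R_{k+1}) / (2(R_0 - R_1))$ — independent of
  $v$, $A$, $\tau$ and $\gamma$ (the package tests this invariance
  exactly: with the same noise realization, different encoders produce
  identical SCCs);
* whenever the noise decorrelates ($R_N \to 0$), the SCCs sum to exactly
  $-1/2$, which by the spectral identity
  $P(0) = \tfrac{C^2}{2\pi T_1}(1 + 2\sum_k \rho_k)$ makes the spike train
  a perfect DC block.

A first-order autoregressive threshold noise
$\gamma_k = \pm a\,\gamma_{k-1} + w_k$ is the discretization (at the mean
ISI $T_1$) of an Ornstein–Uhlenbeck process with relaxation time
$\tau_\gamma = -T_1/\ln a$. Its sign selects the observed pattern families:
slow noise ($+a$) gives the monotone negative Type I family
$\rho_k = -a^{k-1}(1-a)/2$, fast noise ($-a$) the alternating Type II
family $\rho_k = -(-a)^{k-1}(1+a)/2$, and white noise the degenerate
Type III singleton ($\rho_1 = -1/2$, rest zero). The same machinery runs in
reverse: `acf_from_scc()` recovers the noise autocorrelation from a
prescribed SCC sequence, and `generate_from_acf()` turns that into
surrogate noise, so arbitrary decorrelating SCC patterns can be imposed on
surrogate spike trains.

An equivalent formulation perturbs the relaxation time instead of the
threshold: $\tau_i = (\tau/A)(\gamma_i - \gamma_{i-1} + A)$ with the spike
threshold fixed. `tau_sequence_from_threshold_noise()` performs the
transformation; the linearized interval is then $A/m_i$, a fixed multiple
of $\tau_i$, so the spike times coincide exactly with the noisy-threshold
train and the $\tau_i$ carry the same serial correlations as the ISIs.
(The slope is implemented as $m_i = (v-\gamma+A)/\tau_i$, the form
consistent with the deterministic definition of $m$.)

## EOD-grid firing

P-type electrosensory afferents fire at most once per cycle of the electric
organ discharge (EOD, period ~1–1.3 ms), which makes the EOD cycle a
natural integer time base. `simulate_exponential()` supports this
discipline: the event-driven simulator solves each threshold crossing in
closed form, $X_i = \tau\,\ln\frac{v-\gamma_{i-1}+A}{v-\gamma_i}$, and with
a grid enabled the spike is emitted at the first grid point **at or after**
the continuous crossing, never earlier than one period after the previous
spike; the jump $A$ is applied to the threshold value at the actual
emission time. When fast noise pushes the realized threshold below the
error at the start of an interval (no positive crossing), the grid rule
emits one period later — exactly the mechanism that produces the burst
peak at one EOD period in the bimodal, strongly bursting trains. On the
continuous base the same situation is a hard error, as is any nonpositive
interval under the linearized rule: linearization validity is never
silently patched by clipping.

Because the simulation discipline around the grid is a genuine design
choice, its influence was measured rather than assumed. Two disciplines
were compared on the matched configurations below: (i) threshold state
propagated through the quantized emission times (the implementation), and
(ii) continuous-time threshold dynamics with quantization applied only to
the reported spike times. On the matched non-bursting configuration the
estimated $\rho_1$ differs by well under 0.01 between disciplines (the test
suite asserts this against an independent re-implementation of discipline
(ii)) — the quantization itself, not its bookkeeping, is what moves the
correlations.

What quantization does move is substantial: rounding spike times to the
grid adds a differenced quantization error to every interval, which is
itself negatively lag-1 correlated and pushes $\rho_1$ below the linearized
closed form. For the matched non-bursting configuration ($v = 1.845$ V,
$A = 0.15$ V, $\tau = 30$ ms, $a = 0.4$, $R_0 = 1.07\times10^{-3}$ V²,
EOD 1.06 ms) the linearized prediction is $\rho_1 = -0.30$ and the
grid-locked simulation yields $\rho_1 \approx -0.36$; the moderately
bursting configuration ($A = 0.28$, $\tau = 26$ ms, $a = 0.29$ fast,
$R_0 = 9.22\times10^{-3}$ V², EOD 1.31 ms) moves from $-0.645$ (linearized)
to $\approx -0.58$; the strongly bursting one ($A = 0.19$, $\tau = 60$ ms,
$a = 0.69$ fast, EOD 1.04 ms) likewise lands between the linearized
$-0.845$ and the degenerate $-0.5$, with a bimodal ISI histogram peaked at
one EOD period. The 15-lag sums stay at $-0.49$ to $-0.50$ throughout.
These are the package's honest values under the stated discipline; they
bracket, but do not exactly coincide with, previously reported matched-model
values for these configurations, whose generating discipline is not
recoverable.

## Estimators

`estimate_sccs()` implements the blockwise estimator verbatim rather than a
standard biased ACF: within each non-overlapping block of $M$ intervals
(default 2000, sensible range 1000–3000) and for each lag $k$, deviations
are taken about the **global** mean $T_1$, the numerator sums
$(X_i-T_1)(X_{i+k}-T_1)$ over the $M-k$ available pairs, and the
denominator is the geometric mean of the two truncated sums of squares.
Block values are averaged with equal weights; the standard error is the
block standard deviation over $\sqrt{\lfloor N/M\rfloor}$. $\rho_0 = 1$
holds by construction and is not stored. Degenerate (zero-variance) blocks
and insufficient data are hard errors.

`pacf_durbin()` runs Durbin's recursion exactly, starting from
$\phi_{1,1} = \rho_1$, retaining the full coefficient triangle and the
denominators $1 - \sum_j \phi_{k,j}\rho_j$ for audit; a denominator within
$10^{-12}$ of zero aborts with the order at which the singularity occurs.
The test suite pins the recursion against brute-force Yule–Walker solves at
every order on random valid correlation sequences (agreement to
$10^{-10}$).

`spectrum_dc()` checks the DC-block prediction empirically: the train is
binned at the EOD period (or $T_1/4$ on a continuous base), the
mean-subtracted periodogram is averaged over the lowest 2% of frequencies
(DC bin excluded), and the result is compared against
$\tfrac{C^2}{2\pi T_1}(1+2\sum\hat\rho_k)$. When the correlation sum sits
near $-1/2$ both sides are close to zero, so the comparison is reported
against the renewal level $C^2/(2\pi T_1)$ rather than as a raw ratio.

## The inverse problem

The forward map is a second-difference recurrence, so inverting it needs a
boundary closure; none is canonical. The solver fixes $R_0 = 1$ and
$R_{K+1} = 0$ (the noise decorrelates at the horizon). Telescoping the
first differences $d_k = R_{k+1}-R_k$ gives
$d_k = d_0 + 2d_0\sum_{j\le k}\rho_j$ and the boundary condition becomes
*linear* in $d_0$, yielding the closed form
$R_1 = 1 - 1/(K+1+2\sum_{k=1}^K (K+1-k)\rho_k)$; the interior lags then
follow from the recurrence. The closure is therefore exact for any input —
inconsistency with $\sum\rho_k = -1/2$ never breaks the solve, it shows up
entirely in the diagnostic residual $|R_{K+2}| = |R_K|$ (continuing one
step past the horizon with $\rho_{K+1}=0$), which vanishes exactly when the
partial sum reaches $-1/2$. Recovered sequences violating $|R_k| \le R_0$
are returned with a warning: the input SCCs are not realizable by a
stationary threshold noise. Round trips through the forward map are exact
to the truncation tail; with AR(1) inputs truncated at lag 70 the
reconstruction error is below $10^{-8}$.

`generate_from_acf()` must extend a lag-limited ACF to arbitrarily long
sequences. Rather than appending a geometric tail and factorizing a
windowed Toeplitz matrix, the implementation uses the maximum-entropy
extension: the Yule–Walker AR($K$) process whose autocovariances equal the
input *exactly* at lags $0..K$ and decay by the AR recursion beyond. The
first $K$ samples come from the Cholesky factor of the Toeplitz covariance
(stationary start), the rest from the linear recursion, which is $O(n)$.
Near-singular covariances receive an escalating diagonal jitter (recorded
in the output); indefinite inputs are rejected against an eigenvalue
tolerance of $10^{-8} R_0$.

## Parameters, defaults, and numerical choices

* `gamma = A/2` by default — the coding-error-optimal threshold; SCCs are
  unaffected (verified in tests with $\gamma = 0$), so the choice matters
  only for interpretability.
* `v = 1.845` V in the fitting routines and canonical configurations —
  arbitrary for correlations, kept for reproducibility of the printed
  parameter sets.
* Noise power is specified either as $R_0$ (V²) or as
  $\mathrm{SNR} = 10\log_{10}(v^2/R_0)$ dB. The linearized rule requires
  $|\gamma_i - \gamma_{i-1}| < A$; at the canonical Type I parameters this
  makes SNR 35 dB marginal over $5\times10^5$ intervals (a few hundred
  boundary violations expected), so long white-noise runs in the tests and
  acceptance script use SNR 40 dB and the parameter-recovery suite 45 dB,
  where the violation probability is below $10^{-8}$ per interval. The
  grid-locked exponential simulator has no such restriction.
* Innovations are Gaussian (the discrete Ornstein–Uhlenbeck
  correspondence); the AR recursion is initialized from the stationary
  distribution.
* Initial condition: $t_0 = 0$ with the threshold at its post-spike value;
  the fixture generator and fitting loop discard 100 intervals as burn-in.
* Classification tolerance 0.02 (about the estimator noise at
  $2.5\times10^5$ spikes): Type III requires $|\rho_1 + 0.5| \le$ tol and
  all later lags within tol; Type I requires $-0.5 < \rho_1 < 0$ with
  $\rho_2$ below tol; Type II requires $\rho_1 < -0.5$ with $\rho_2 > 0$.
* `match_and_verify()` re-tunes only what must move: a bounded secant step
  on $a$ (initial slope $\pm 1/2$, the linearized derivative
  $d\rho_1/da$, bounds $(0, 0.98]$) against the achieved $\rho_1$, and a
  multiplicative rescaling of $R_0$ against the achieved CV — never both
  through one knob — for at most 20 rounds. Non-convergence returns the
  best candidate, flagged.

## What the synthetic data emulate — and what they do not

The fixture generator produces high-rate trains (150–400 spikes/s),
EOD-grid-locked firing with at most one spike per cycle, unimodal
(non-bursting) and bimodal (bursting) ISI distributions, and all three SCC
pattern types, using the canonical matched parameter sets. Problem sizes in
the tests are $10^4$–$5\times10^5$ intervals (the acceptance script uses
$5\times10^5$, where the blockwise estimator's standard error on $\rho_1$
is about 0.002); these were chosen so the Monte-Carlo error sits well below
every tolerance asserted against.

Passing tests on these surrogates show that the estimators and the
forward/inverse maps are mutually consistent and that the simulator
reproduces the closed-form families under quantization. They do **not**
show that real afferents are AR(1)-threshold encoders: real spike trains
have drifting rates, measurement jitter at the ADC rate, possible
higher-order dependencies (population data are at least second-order
Markov), and population-level regularities (e.g. the empirical
$\rho_1$–$\rho_2$ regression) that require the recordings themselves. The
model family implies $\rho_2 = \rho_1(1+2\rho_1)$ exactly; the
distance of real data from that curve is an empirical question outside the
package's scope.

## Known limitations

* SCCs are invariant under the mean firing rate by construction (lags are
  counted in intervals, not absolute time), whereas real correlations peak
  at intermediate rates.
* Only first-order AR noise is generated by the convenience constructors;
  positive ISI correlations (which require $R_0 < 2R_1 - R_2$, i.e.
  higher-order noise) are expressible through `generate_from_acf()` but no
  constructor builds them.
* The continuous-base exponential simulator requires a positive crossing
  in every interval; strongly bursting regimes need the grid (which is also
  where they occur in nature).
* The inverse solver's boundary closure ($R_{K+1} = 0$) is one defensible
  choice among several; for SCC inputs whose partial sum is far from
  $-1/2$ the recovered ACF depends on it, and the residual diagnostic
  should be inspected.
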