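---
title: "Testing circular uniformity: methods, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing circular uniformity: methods, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuniform)
```

## The problem

Angles, compass bearings and clock times live on a circle: 0 and $2\pi$ are
the same point, and the first inferential question is usually whether the
underlying distribution is uniform around that circle. This package
implements the seven tests of circular uniformity a biologist is likely to
meet or need, one shared Monte-Carlo calibration backend so that all seven
can be compared on identical terms, samplers for the alternatives against
which their power is usually studied, and the simulation engine that turns
those pieces into type-I-error and power estimates.

Throughout, a sample is stored in radians reduced to $[0, 2\pi)$; degrees
are accepted at every boundary (file readers, the CLI, `mu0_unit`) and
echoed back on output. Keeping one canonical internal unit is the cheapest
way to avoid modulus bugs.

## The tests and their null calibration

For $\theta_1,\dots,\theta_n$ write $\bar R e^{i\bar\theta} =
\frac1n\sum_j e^{i\theta_j}$, so $r = \bar R$ is the mean resultant length
and $\bar\theta$ the mean direction.

* **Rayleigh.** Statistic $r$; reject for large $nr$. The analytic p-value
  uses the standard second-order approximation
  $p = \exp\{\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n)\}$, $R = nr$. It is
  accurate from about $n = 4$; below that the implementation switches to the
  Monte-Carlo route by default. It is the most powerful invariant test
  against a von Mises alternative but close to blind against antipodally
  mirrored modes, whose first Fourier harmonic vanishes.
* **V-test.** $V = r\cos(\bar\theta - \mu_0)$ with $\mu_0$ fixed *before*
  data inspection; one-sided p from the standard normal tail of
  $u = V\sqrt{2n}$. Its alternative hypothesis is the Rayleigh test's, not
  "concentration at $\mu_0$": departures centred far from $\mu_0$ can still
  reject, which is why a significant V-test must be read together with a
  confidence interval for the mean direction (`mean_direction_ci()`).
* **Kuiper** ($V_n = D^+ + D^-$) and **Watson** ($U^2$), the
  rotation-invariant analogues of Kolmogorov–Smirnov and Cramér–von Mises.
  Analytic p-values apply the usual asymptotic series to the
  Stephens-modified statistics; both series are summed to convergence (60
  and 100 terms) with a closed escape to $p = 1$ for statistics far into
  the null bulk, and results clamped to $[0, 1]$.
* **Rao's spacing test.** $U = \frac12\sum_i |T_i - 2\pi/n|$ over the arc
  spacings $T_i$ between successive order statistics including the
  wrap-around arc. Published critical tables are coarse, so p-values are
  Monte-Carlo here; the null quantiles were cross-checked against an
  independent simulation (two implementations agree to the Monte-Carlo
  error, e.g. the 5% critical value at $n = 30$ is $\approx 157°$).
* **Hermans–Rasson.** A pairwise-difference statistic,
  $$T = \frac1n\sum_{i,j}\Big[\big(\tfrac{\pi}{2} - d(\theta_i,\theta_j)\big)
    + 2.895\big(\tfrac{2}{\pi} - |\sin(\theta_i-\theta_j)|\big)\Big],$$
  with $d$ the circular distance. In Fourier terms the distance part loads
  the odd harmonics and the $|\sin|$ part the even harmonics, with the
  constant $2.895$ balancing the two; both centring constants make the
  kernel mean-zero under uniformity and cancel in the Monte-Carlo
  calibration, so the test's validity does not depend on them. This is the
  test with the best worst-case behaviour across multimodal departures.
* **Data-driven smooth test (after Bogdan).** Fourier scores
  $c_j = \sqrt{2/n}\sum_i\cos(j\theta_i)$,
  $s_j = \sqrt{2/n}\sum_i\sin(j\theta_i)$, cumulative energies
  $N_k = \sum_{j\le k}(c_j^2 + s_j^2)$, and a Schwarz-type selection
  $k^* = \arg\max_k (N_k - 2k\log n)$, each harmonic counting its two scores
  as two parameters, ties resolved to the smallest $k$; the statistic is
  $N_{k^*}$ with $k \le 10$ by default. Because the selection is part of
  the statistic, it is re-run inside every null draw; calibrating $N_{k^*}$
  against a fixed-dimension null would be anti-conservative. One property
  worth knowing: the selected dimension tracks *every* informative
  harmonic, so strongly concentrated unimodal samples legitimately select
  $k \ge 2$ (higher von Mises harmonics are large when $\kappa$ is large);
  dimension 1 dominates only at moderate concentration.

**Monte-Carlo calibration.** Every statistic's null law depends only on
$n$, so `calibrate_null()` draws `reps` uniform samples once per (test,
$n$) and the table is reused across an entire sweep; this is what makes
10,000-replicate grids run in seconds. Empirical p-values use
$p = (1 + \#\{T_{\text{null}} \ge T_{\text{obs}}\})/(\text{reps}+1)$, which
cannot return zero and gives an exactly valid test at any table size.
Defaults: 9,999 null draws; analytic p-values for Rayleigh, V, Kuiper and
Watson (accurate at the sample sizes studied, and the route practitioners'
software uses), Monte-Carlo mandatory for Rao, Hermans–Rasson and the
smooth test. Every test also exposes the Monte-Carlo route so all seven can
be compared under identical calibration. Ties (zero spacings) are legal
everywhere.

## Samplers

* von Mises via the Best–Fisher (1979) wrapped-Cauchy-envelope rejection
  algorithm; $\kappa < 10^{-10}$ short-circuits to uniform.
* Wrapped Cauchy by inverting a linear Cauchy with scale $-\log\rho$ and
  wrapping; $\rho = 0$ is uniform by construction.
* Wrapped skew-normal as the linear skew-normal($\varepsilon, \omega,
  \alpha$) — drawn through its two-normal representation — reduced mod
  $2\pi$. Its density wraps the linear density over $|k| \le \lceil 8
  \max(1, \omega/2\pi)\rceil$ turns, far beyond where the Gaussian tail
  matters at any dispersion used here (verified by quadrature: all
  densities integrate to 1 within $10^{-6}$).
* Mixtures by categorical component choice, then a component draw.

Sampler correctness is established against an independent oracle: the
empirical CDF of $10^4$ draws must lie inside the 99% Kolmogorov band of
the CDF obtained by trapezoid quadrature of the density, for every family
and several parameter sets.

## The simulation scenarios

`scenario()` encodes the sweeps of the power study with their standard
conditions as defaults: type-I error on uniform samples at
$n \in \{10, 15, 20, 25, 30, 40, 80, 100\}$ with $10^5$ replicates;
$10^4$ replicates for power grids; $\alpha = 0.05$ as a parameter, never a
constant; bimodal $\kappa$ swept $0$–$6$ in $0.1$ steps at $n = 25$; mode
separation $\Delta$ swept $0°$–$180°$; mixing weight $0.05$–$0.5$ in $0.05$
steps at $\kappa \in \{2, 3\}$; a second-mode $\kappa_2$ swept $0$–$6$ with
the first mode's $\kappa_1$ fixed at 3; V-test directions at $0°$, $20°$
and $45°$ from the true mean. Mode layouts: symmetric placements put $f$
equal modes at $360°k/f$; asymmetric placements put two modes $90°$ apart,
and for $f \ge 3$ space the modes at $180°/(f-1)$ increments over half the
circle — the two-mode case is its own convention here because the even
half-circle rule would degenerate to the mirrored layout at $f = 2$.

Where the study conditions leave a grid unstated, the defaults are fixed
once as what brackets the interesting range: unimodal von Mises $\kappa \in
\{0, 0.5, \dots, 4\}$ (power saturates near 1 by $\kappa = 2$ at moderate
$n$), wrapped Cauchy $\rho \in \{0, 0.1, \dots, 0.8\}$, skew-normal
$\omega \in \{0.5, 1, \dots, 5\}$ with shape $\alpha = 30$ (a strong right
skew) and location $0$, and a $10°$ step for the $\Delta$ sweep.

Three engine choices matter for interpreting results. First, within a grid
cell all test configurations are evaluated on the *same* simulated samples,
so power differences between tests carry much less Monte-Carlo noise than
two independent estimates would. Second, each cell's RNG stream is derived
by hashing the master seed with the cell's sample size and generator
parameters, so a cell reproduces identically whether run alone, inside the
full grid, or through `estimate_rejection_rate()` (which *is* a one-cell
scenario). Third, null tables are built from their own derived streams
before any cell runs, so adding or removing cells never shifts another
cell's draws.

## The bootstrap confidence interval

The mean-direction interval is a percentile bootstrap on the circle:
resampled mean directions are centred on the observed mean direction with
deviations mapped to $(-\pi, \pi]$, the $\alpha/2$ and $1-\alpha/2$
quantiles of those deviations are taken, and the arc is shifted back.
A bootstrap was chosen over the dispersion-based analytic interval because
it needs no distributional assumption — consistent with using omnibus tests
in the first place — at the cost of requiring $r$ bounded away from zero
(the implementation refuses when $r < 10^{-12}$, the same tolerance used to
flag an undefined mean direction on exactly symmetric grids). Default
9,999 resamples. Coverage at the 95% level was verified by simulation on
von Mises data.

## What the generators do and do not emulate

The samplers produce independent, continuously distributed angles from
clean parametric laws. That matches the simulation design whose results
this package reproduces, and it is the right reference point for comparing
tests — but real orientation data often violate it: headings are recorded
to the nearest 5° or 10° (grouped data need different methods), animals
contribute repeated measures (independence fails), and empirical
multimodality rarely has exactly equal, exactly von Mises modes. Passing
the test suite therefore shows the tests are correctly calibrated and
powered *under these laws*; it does not license the tests for grouped or
dependent data.

## Numerical and scale choices

* Angle reduction is half-open $[0, 2\pi)$; $360° \equiv 0°$ in all mode
  lists.
* "Undefined mean direction" means $r < 10^{-12}$.
* Angle files print 15 significant digits, making write/read round trips
  exact to well below $10^{-12}$ radians in either unit.
* Rotation invariance of the Kuiper, Watson, Rao, Hermans–Rasson and
  smooth-test statistics holds to $10^{-9}$ and is asserted, not assumed.
* The test suite runs its simulations at deliberately modest sizes — null
  tables of 999–9,999 draws, power cells of 1,000–10,000 replicates,
  coverage checks over 400 datasets with 499 resamples — with tolerances
  widened to the matching binomial 3σ bands. These sizes were chosen so the
  whole suite completes in well under a minute per file while leaving every
  qualitative conclusion outside the noise; the preset scenario defaults
  keep the full study-scale replication counts.

## Known limitations

* Power comparisons against the smooth test depend on its selection
  penalty; other published penalties (lighter than $2k\log n$) would admit
  higher dimensions and shift its power profile. The penalty here is the
  Schwarz form stated above, fixed once.
* The Hermans–Rasson constant $2.895$ is taken as the literature's
  balancing value; the Monte-Carlo calibration keeps the test exactly valid
  for any constant, but power at specific alternatives would move with it.
* The analytic V-test p-value is a one-term normal approximation; at
  $n \le 10$ prefer `method = "monte_carlo"`.
* Grouped/aggregated circular data, circular–circular association, and
  parameter *estimation* (fitting mixtures, choosing mode counts by model
  selection) are out of scope.
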