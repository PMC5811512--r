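---
title: "Methods: peak open probability under open-channel block"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak open probability under open-channel block}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openblock)
```

## Model and assumptions

A voltage-gated channel with `m` identical, independent gates and an
open-channel blocker is modelled as the linear continuous-time Markov
chain

```
C_m <-> ... <-> C_1 <-> O <-> B
```

State `C_j` has `j` closed gates; each closed gate opens at rate `alpha`
and each open gate closes at rate `beta`, so the forward rate out of `C_j`
is `j * alpha` and the backward rate into it from `C_{j-1}` is
`(m - j + 1) * beta`. The blocker binds only the open state at rate
`gamma = kappa * concentration` (pseudo-first-order) and unbinds at the
dissociation rate `delta`. The blocked state conducts nothing but the gate
machinery is frozen while blocked (no closed-blocked states), which is the
defining assumption of *open-channel* block. All rates are in 1/ms,
potentials in mV, probabilities dimensionless.

The master equation is `x'(t) = A x(t)` with the tridiagonal column
generator built by `build_generator()`; columns sum to zero. The default
initial condition is all probability in `C_m` — a voltage step from a
strongly hyperpolarised holding potential.

## Exact solution and peak criterion

Because `A` is tridiagonal with nonnegative off-diagonals it is similar to
a symmetric matrix: the spectrum is real, and for an irreducible scheme
there is exactly one zero eigenvalue (the stationary mode).
`spectral_solve()` returns `x(t) = sum_i c_i V_i e^{r_i t}` with
eigenvalues sorted descending (0 first, then slowest).

The open probability peaks (exceeds its steady state transiently) exactly
when the slowest nonzero mode enters `O(t)` with a positive coefficient.
That coefficient has the closed form implemented in
`slowest_preexponential()`, and its sign reduces to the scalar test
`delta + r_slow < 0` used by `peak_exists_spectral()`. Two closed-form
specialisations are verified against it on thousands of random rate sets:

* `m = 1`: a peak exists iff `alpha > delta`.
* `m = 2`: iff `alpha > delta * (3 + b + sqrt(1 + 6b + b^2)) / 4` with
  `b = beta/alpha`; equivalently the boundary solves
  `delta^2 - delta*(3*alpha + beta) + 2*alpha^2 = 0`. At
  `alpha = beta = 1` the boundary is `delta = 2 - sqrt(2)`.

Neither involves `gamma`: peak *existence* is independent of blocker
concentration and affinity. Peak *time* and *height* for `m = 1` use the
closed forms in `peak_time_3state()` and `relative_peak_height()`; at the
dissociation-constant concentration (`gamma = delta`, `beta = 0`) the
height collapses to `(alpha/delta - 1)^(1/(1 - alpha/(2*delta)))`
(`relative_peak_height_kd()`).

## Numerical choices

All tolerances are relative to a problem scale, never absolute:

* **Zero eigenvalue**: `|r| < 1e-10 * max|A|`; exactly one is required,
  otherwise `spectral_solve()` errors (it never silently repairs).
* **Imaginary parts**: tolerated below `1e-10` times the spectral range,
  truncated; larger values raise an error.
* **Spectral degeneracy**: closed forms needing pairwise distinct
  eigenvalues (Putzer partial fractions, the slow-mode coefficient, the
  `m = 1` peak-time formula) refuse spectra with a gap below `1e-8` times
  the spectral range; `analyze_peak()` then falls back to the numerical
  path. A concrete degenerate line worth knowing: at `beta = 0` the
  three-state eigenvalues are `{0, -alpha, -(gamma + delta)}`, exactly
  repeated when `alpha = gamma + delta`. This is also why the
  `beta -> 0` limit of the peak height is exposed numerically
  (`relative_peak_height_limit()`) rather than as a closed form.
* **Existence boundary band**: `peak_exists_spectral()` treats
  `|delta + r_slow| < 1e-9 * max(rates)` as the undecidable boundary and
  reports no peak there (the conservative answer). `classify_point()`
  therefore uses the exact criterion `alpha(V) > delta` for `m = 1`, where
  hyperpolarised potentials (huge `beta`) push `delta + r_slow` inside
  that band even though the closed form decides cleanly.
* **Numerical argmax** (`find_peak_numeric()`): a 600-point logarithmic
  time grid spanning the fastest and slowest relaxation scales, golden
  section (`optimize()`) on the bracketing interval, then Newton
  refinement on `O'(t)` — `optimize()` alone is limited to ~`sqrt(eps)`
  relative precision in the abscissa. A peak is accepted when
  `O(t_p) > O_ss * (1 + 1e-12)`.
* **Steady state**: least-squares solve of the generator augmented with
  the normalisation row, after an SVD check that the null space is
  one-dimensional. Accuracy is ~`1e-16` absolute; components as small as
  `1e-10` (large `m`, `alpha << beta`) are therefore only accurate to
  ~`1e-6` relatively, which the tests acknowledge.

## Independent verification routes

Every result is computed at least twice by structurally different code:

1. spectral solution vs. hand-rolled scaling-and-squaring matrix
   exponential vs. Putzer recursion (and `Matrix::expm` as an external
   cross-check) — supremum disagreement below `1e-8` over hundreds of
   random rate sets, `m` from 1 to 4;
2. closed-form peak criteria vs. the spectral sign test vs. the slow-mode
   coefficient sign vs. brute-force waveform inspection, on thousands of
   random draws (rates `10^U(-1, 1)`), excluding a `1e-6`-wide band
   around the exact boundary where the decision is genuinely ill-posed;
3. closed-form `t_p` and peak height vs. the grid + Newton argmax
   (relative agreement `1e-6`);
4. the analytic `O(t)` vs. Gillespie ensembles (`N = 1e5`) within
   binomial standard errors, each channel on its own seeded RNG stream
   (`set.seed(base + channel)`), making ensembles reproducible and
   embarrassingly parallel.

Problem sizes throughout are tiny (`n = m + 2` states, `m <= 5`), so
dense linear algebra is the right tool; the whole suite runs in ~35 s on
one CPU.

## Design decisions and limitations

* Tidyverse-native surface: tibble outputs, `tidy()`/`glance()` on
  `peak_report`, `autoplot()` per result class.
* Region maps (`scan_delta_v_plane()`, `scan_beta_delta_plane()`) use
  deterministic grids; classification is reproducible by construction,
  and the `beta`-`delta` map re-verifies `gamma`-invariance at every call.
* Monotonicity in the `A2`/`A3` classification is judged by a central
  finite difference of width `2*dv` (default 1 mV); cells whose stencil
  straddles the no-peak border are labelled `A1`.
* Limitations: the scheme assumes identical independent gates and a
  single blocked state reachable only from `O`; no closed-state or
  inactivated-state block, no trapping, and rates are voltage-dependent
  only through the gating pair `alpha(V)`, `beta(V)`.
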