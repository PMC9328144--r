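---
title: "Reduced GUTS survival models, lethal profiles and species sensitivity distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced GUTS survival models, lethal profiles and species sensitivity distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsred)
```

## The problem

Standard aquatic toxicity tests expose organisms to constant concentrations,
but pesticide exposure in surface waters is pulsed and transient. Whether a
species is "sensitive" to a chemical then depends on the interplay between
its toxicokinetics/toxicodynamics and the exposure dynamics: a species whose
internal damage state tracks the water concentration almost instantaneously
is hit hardest by short sharp peaks, while a species that accumulates damage
slowly integrates long low tails. `gutsred` implements the model chain needed
to make that statement quantitative for survival data: reduced General
Unified Threshold models of Survival (GUTS-RED) calibrated to toxicity-test
counts, lethal-profile multiplication factors (LPx) for arbitrary exposure
time series, and species sensitivity distributions (SSD) over LP50 with the
5% hazard profile (HP5) endpoint.

## Model

The single state variable is the *scaled damage* $D_w(t)$ (in exposure
units, µg/L), driven by the external concentration $C_w(t)$ through the
dominant rate constant $k_D$ (1/d):

$$\frac{dD_w}{dt} = k_D \,(C_w(t) - D_w), \qquad D_w(0) = 0.$$

Two death mechanisms are supported.

**Stochastic death (SD).** All individuals share a threshold $z_w$ (µg/L);
damage above it adds hazard at the killing rate $b_w$ (L µg$^{-1}$
d$^{-1}$), on top of the background hazard $h_b$ (1/d):

$$h(t) = b_w \max(0,\, D_w(t) - z_w) + h_b, \qquad
S(t) = \exp\left(-\int_0^t h(u)\,du\right).$$

**Individual tolerance (IT).** Each individual has a fixed threshold drawn
from a log-logistic distribution with median $m_w$ (µg/L) and shape
$\beta$; death is immediate once the running maximum of damage exceeds it:

$$S(t) = \Big(1 - F\big(\max_{u \le t} D_w(u)\big)\Big) e^{-h_b t}, \qquad
F(d) = \left(1 + (d/m_w)^{-\beta}\right)^{-1}.$$

Exposure profiles are piecewise linear (hourly resolution is typical for
surface-water model output, and linear interpolation is the densest faithful
reconstruction of it; `read_exposure_profile()` converts TOXSWA-style
g/m³-and-hours input to µg/L-and-days). Constant-exposure test treatments
are two-node profiles, so one code path serves both laboratory tests and
field profiles. No extrapolation beyond the recorded window is permitted:
predictions are defined only on the profile's support.

## Numerical choices

* **Damage is solved exactly.** On a linear segment
  $C_w(t) = c_0 + s\,(t - t_0)$ the ODE has the closed solution
  $D_w = c_0 + s\tau - s/k_D + e^{-k_D \tau}(D_0 - c_0 + s/k_D)$, applied
  segment by segment. A generic Runge–Kutta integrator exists in the test
  suite purely as an independent oracle (agreement to $10^{-6}$ relative on
  randomized profiles).
* **Running maxima are exact.** The stationary point of $D_w$ inside a
  segment satisfies $e^{-k_D\tau^*} = s/(k_D A)$ and is therefore located
  in closed form, not on a grid; the running maximum is the cumulative
  maximum over nodes, stationary points and evaluation times.
* **SD hazard integration.** The excess hazard $\max(0, D_w - z_w)$ is
  integrated by the trapezoid rule on a grid that is refined (midpoint
  insertion, with the threshold-crossing times re-inserted at every pass)
  until the cumulative integral changes by less than $10^{-6}$ relative.
  This bounds the error without case analysis of the piecewise-smooth
  integrand. For constant-exposure treatments the integral is evaluated in
  closed form instead (the two paths are cross-checked in the tests); this
  is what makes calibration fast.
* **Interval probabilities are floored** at $10^{-30}$ before logs; the
  number of floored cells is recorded on every likelihood value and
  reported with fits, so a fit that leans on the guard is visible.

## Calibration

The likelihood is the interval-censored multinomial death model: per
treatment, deaths within each observation interval are multinomial with
probabilities $S(t_{i-1}) - S(t_i)$ and the final survivors carry
$S(t_{end})$. All four parameters, including background mortality, are
fitted jointly by default (a control-only pre-fit of $h_b$ is available via
`hb_control_only = TRUE`).

The search runs in log10 parameter space inside data-scaled bounds:
$k_D \in [\ln(20)/t_{end}/100,\ 1000]$ 1/d, thresholds
$z_w, m_w \in [c_{\min}/1000,\ 2\,c_{\max}]$ (lowest positive and highest
tested concentration), $b_w \in [10^{-4}, 10^{4}]$,
$h_b \in [10^{-6}, 0.1]$, and $\beta \in [0.5, 100]$ (no published
convention exists for the IT shape's search range; this covers the
concentration–response slopes seen in fish acute data). Data-scaled bounds
make "the estimate sits at the edge of the search space" a meaningful
diagnostic, and fits flag any estimate within 1% (log scale) of a bound.
The optimizer is a seeded Latin-hypercube screen (200 points by default)
followed by Nelder–Mead refinement of the best 10 — the same
coarse-grid-plus-simplex character as openGUTS without copying it.
Confidence intervals are likelihood-ratio profiles: each parameter is
stepped away from its estimate, re-optimizing the others, until the
profiled log-likelihood has dropped $\chi^2_{1,0.95}/2 = 1.921$, with the
crossing refined by bisection and bound-clipped intervals flagged.

Goodness of fit follows the usual screening metrics: NRMSE over all
treatment-by-time cells and the survival-probability prediction error
(SPPE) per treatment at the test end.

## LPx and its uncertainty

LPx is the factor by which a fixed exposure profile must be multiplied for
the model to predict x% mortality at the end of the profile window.
Background hazard is set to zero for this prediction — the factor measures
toxicant-attributable mortality only, independent of test-specific control
survival. Effect is evaluated at the end of the full window (profiles are
consumed as fixed windows; no moving-window assessment). Because damage is
linear in exposure, the factor-1 trajectory is computed once and rescaled:

* **IT** has the closed form
  $f = (m_w / D_{max,1}) \left(x/(100-x)\right)^{1/\beta}$.
* **SD** survival at the profile end is monotone in the factor, so the
  factor is found by bisection (relative tolerance $10^{-4}$) within
  $[10^{-6}, 10^{6}]$; the IT closed form doubles as an oracle for the
  generic root-finding in the tests.

Uncertainty is propagated from the likelihood region rather than by
bootstrap: parameter draws (log10-uniform over the profile-CI box, each interval
widened by a quarter of its own width) are accepted when their log-likelihood lies within 1.92 of
the maximum, and the LPx interval is the range over 200 accepted draws plus
the best fit. Fewer than 20 accepted draws flags the interval as
unreliable.

## SSD and ranking

One LP50 per species enters a log-normal (base-10) SSD fitted by maximum
likelihood ($\sigma$ with the $n$ denominator), and
$HP_5 = 10^{\mu - 1.6449\,\sigma}$ is the factor at which 5% of species
reach 50% mortality. A single distribution family is deliberate: with the
typical five fish species the family choice is weakly informed, and
multi-family model averaging is left as an extension. HP5 is computed from
LP50 point estimates only; propagating per-species LP50 uncertainty into
the SSD is out of scope. `rank_species()` orders species by LP50 within
each profile and variant and reports every pair whose order flips between
profiles.

## What the synthetic generators emulate — and what they do not

`generate_test()` simulates constant-exposure tests (default design: five
concentrations 1.8–18 µg/L plus control, 40 fish per treatment, daily
observation over 4 days — the scale of standard acute fish tests) with the
conditional-binomial death process, which matches the calibration
likelihood exactly. `generate_scenario()` produces three idealized
surface-water exposure shapes: a sharp 2-day triangular pulse, a rise to
peak followed by an exponential decline (half-life 10 d over 60 d), and
four evenly spaced pulses over 30 d. These are parametric stand-ins for
FOCUS-model output — real TOXSWA series carry baseline noise, asymmetric
recessions and seasonal structure that the generators do not emulate, so
passing tests demonstrate correctness of the model chain, not fidelity to
any particular catchment. The species panel spans $k_D$ from 0.25 to
100 d$^{-1}$ — the slow-to-fast range reported for fish — with the slow
species given a low threshold (long exposure accumulates damage) and the
fast species a higher threshold and killing rate (short pulses decisive).

One qualitative point is forced by the mathematics: when two scenarios
share the same peak concentration and the long-tailed one dominates the
pulse pointwise after its rise, every GUTS-RED parameter set yields
LP50(long-tail) ≤ LP50(pulse) *within* a species. The profile dependence of
sensitivity is therefore demonstrated where it is meaningful — *between*
species: the fast species is the more sensitive one on the pulse, the slow
species on the long tail, for both variants. This ranking reversal is the
mechanism the package exists to expose.

## Problem sizes and determinism

All randomness is seeded: simulated tests, the Latin-hypercube screen and
the likelihood-region draws reproduce exactly under a fixed seed. The test
suite works at desk scale — 100 parameter-recovery replicates at the
default acute design, 100 random profiles against the ODE oracle, a
two-species end-to-end ranking study — chosen so the whole chain, including
profile-likelihood intervals, is exercised in minutes on one core. The
bundled study driver (`run_study()`) runs the five-species,
three-scenario, two-variant chain in about two minutes.

## Known limitations

* Reduced GUTS only: no separate toxicokinetic compartment, no
  time-varying $k_D$, no sublethal endpoints, and no life-stage structure —
  early-life-stage tests are usable only after the prehatch phase is cut
  away (`prepare_els()`), and egg-stage effects are ignored by design.
* Frequentist calibration only; Bayesian posteriors (morse-style) are not
  replicated.
* Control and solvent-control pooling is applied on request, not gated on
  a similarity pretest; run your own Cox model or t-test first if in doubt.
* The SSD is single-family log-normal over point estimates; HP5 carries no
  uncertainty statement.
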