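---
title: "The DC model: exact solution, fixed-step schemes and their stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DC model: exact solution, fixed-step schemes and their stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmodel)
```

## The model and its assumptions

The diabetes-complications (DC) model tracks two stocks of diagnosed
diabetics: those with complications, $C(t)$, and those without, $D(t)$,
with $N = C + D$ the total. Flows are first-order with constant rates:
new cases arrive at a constant incidence $I$ into *both* balances (a
substantial share of patients already carry complications at diagnosis),
complications develop at rate $\lambda$, are brought under control at
rate $\gamma$, and patients exit through natural mortality $\mu$,
complication mortality $\delta$, or severe disability $\nu$. In the
$(C, N)$ variables:

$$C' = I - (\lambda + \theta)\,C + \lambda N, \qquad
  N' = 2I - (\nu + \delta)\,C - \mu N, \qquad
  \theta = \gamma + \mu + \nu + \delta .$$

The model is deliberately coarse: no age structure, no prediabetes
compartment, no stochastic demography, and a time-constant incidence.
Its value is that it is an *affine linear* system, so every quantity of
interest — equilibrium, spectrum, closed-form trajectory — is available
exactly, which makes it an ideal test bed for comparing numerical
integration schemes on an epidemiological problem.

## Parameters

All rates are per year; incidence is persons per year. The canonical set
(`dc_default_params()`) is $\lambda = 0.85$, $\delta = 0.05$,
$\mu = 0.02$, $\gamma = 0.5$, $\nu = 0.05$, $I = 6\times10^6$. Validation
requires all six non-negative and at least one of $\mu, \delta, \nu$
positive — without an outflow the system has no finite equilibrium. The
closed-form solution literature for this model writes the complication
transfer rate as $\rho$; it is the same quantity as $\lambda$ and the
package treats it as an alias. Swept values of $\lambda$ above 1 are
accepted as rates (with a warning) even though they lose their
interpretation as probabilities.

## Equilibrium and the two variants

`dc_equilibrium()` defaults to `variant = "ode_consistent"`, the exact
root of the $2\times2$ linear system, because that is the point the true
trajectories actually converge to. A closed-form pair for
$(C^*, N^*)$ circulates in the DC-model literature; its $C^*$ agrees
algebraically with the solved root (the denominator equals
$\beta = \rho(\nu+\delta) + \mu(\rho+\theta)$), but its $N^*$ does not
satisfy $N' = 0$ (it evaluates to $\approx 150.5$ M for the canonical
parameters, against the solved $\approx 148.95$ M). The literature form
is retained under `variant = "literature_formula"` for transparency, and the
discrepancy is asserted in the test suite rather than hidden.

## Exact solution and the truth oracle

With distinct decay rates $\eta_1 < \eta_2$ (the roots of
$x^2 - \sigma x + \beta$, $\sigma = \rho + \theta + \mu$ — the radicand
is $\sigma^2 - 4\beta$):

$$C(t) = K_1 e^{-\eta_1 t} + K_2 e^{-\eta_2 t} + \frac{\alpha}{\beta} I,
  \qquad \alpha = 2\rho + \mu,$$

with $K_1, K_2$ fixed by the anchor state so that $K_1 + K_2 +
(\alpha/\beta)I = C_0$ exactly. $N(t)$ is recovered by substituting
$C(t)$ into the first equation, $N = (C' + (\lambda+\theta)C - I)/\lambda$,
which guarantees both equations are satisfied jointly; this requires
$\lambda > 0$ (otherwise $C$ decouples and the propagator is used
instead). The `dc_propagate()` oracle takes a different route to the same
answer: it decomposes the deviation from equilibrium on the eigenbasis of
the system matrix and scales each mode by $e^{\chi\Delta t}$, handling a
repeated eigenvalue through $e^{At} = e^{\chi t}(I + (A-\chi I)t)$. Tests
assert the two routes agree to $10^{-10}$ relative wherever both are
defined, and that the propagator matches an independently coded fine-step
RK4 integration to $10^{-8}$ relative over 20 years.

For the canonical parameters $\eta_1 = 0.0812041$ and
$\eta_2 = 1.4087961$ per year: a slow mode with an 8.5-year half-life
that carries the epidemiologically meaningful relaxation, and a fast mode
that is gone within two years but controls the numerical stability limits
below.

## The five schemes and the discretization choices

All schemes are fixed-step by design — the object of study is the
behaviour of the basic discretizations themselves, so no adaptive
stepping is offered anywhere.

* **Explicit (forward) Euler** — the textbook first-order update.
* **Implicit (backward) Euler** — the update pair is mutually coupled
  (the new $C$ needs the new $N$ and vice versa), so the step solves
  $(I - \Delta t\,A)\,x_{i+1} = x_i + \Delta t\,b$ exactly; this is cheap
  for a $2\times2$ system and is the textbook backward Euler. A
  one-sweep sequential variant (`gauss_seidel = TRUE`; $C$ from the
  lagged $N$, then $N$ from the new $C$) is kept for fidelity
  experiments; the exact solve is the default and is what the fixed
  point of the sequential iteration converges to.
* **Heun** — forward-Euler predictor, then a trapezoidal corrector
  averaging the derivative at the current state and at the predictor.
  Both corrector derivative evaluations use known quantities only
  (current state and predictor) — the standard second-order Heun scheme.
* **Classical RK4** — half-increment stages 2 and 3, *full* previous
  increment in stage 4, and the $-\mu N$ sign of the $N$ balance in
  every stage. Both choices are forced by consistency: any deviation
  (a half increment in stage 4, or a $+\mu$ sign) destroys the scheme's
  fourth-order agreement with the exact solution, which the error tables
  verify at the $10^{-7}\,\%$ level.
* **ABM4** — four-step Adams–Bashforth predictor, derivative
  re-evaluation at the predictor, three-step Adams–Moulton corrector
  (PECE). Derivatives are right-hand-side values (never pre-multiplied
  by $\Delta t$; the step size enters only through the $\Delta t/24$
  Adams weights). The first three steps are bootstrapped with RK4 —
  itself fourth order, so the start-up does not degrade the scheme — and
  the four-state window then slides.

`dc_integrate()` flags a trajectory as diverged when $|C|$ or $|N|$
exceeds $10^{12}$ persons or goes non-finite: more than a thousand times
the population scale, unreachable by any stable run, so the guard never
triggers spuriously.

## Amplification factors and stability limits

For a linear system each one-step scheme multiplies the mode with decay
rate $\eta$ by its stability function at $x = \Delta t\,\eta$: $1-x$
(forward Euler), $1/(1+x)$ (backward Euler), $1-x+x^2/2$ (Heun), the
quartic Taylor polynomial of $e^{-x}$ (RK4). For the ABM4 PECE scheme the
factor is the largest-magnitude root of its characteristic quartic
$r^4 + (-1 + 28q - 495q^2)r^3 + (531q^2 - 5q)r^2 + (q - 333q^2)r + 81q^2$
with $q = x/24$, computed with `polyroot()` and cross-checked in the
tests against a direct simulation of the scalar recurrence. A scheme is
stable at $\Delta t$ when the spectral radius over both modes is at most
1 (a $10^{-12}$ slack absorbs round-off at the $x \to 0$ limit, where
all factors tend to 1).

The fast mode sets the limits: forward Euler requires
$\Delta t \le 2/\eta_2 \approx 1.42$ yr for the canonical parameters, so
on the standard sweep grid (0.1–1.5 yr) it first fails at 1.5 yr; the
ABM4 stability interval ends near $x \approx 1.25$, so it is flagged
unstable from $\Delta t = 1$ yr upward; backward Euler and (for this
spectrum) RK4 are stable throughout, and Heun fails only at 1.5 yr. This
reproduces the qualitative picture that the explicit and multistep
schemes are the fragile ones while the implicit scheme tolerates any
step.

## Experiments and the year-5 anchor

The error tables (`dc_error_table()`) launch each scheme from a reference
state at $t = 5$ years — C = 90,880,136.51, N = 150,047,685.76, shipped
with three later true-value pairs as a plain-CSV fixture — and score it
against the exact propagator at $t = 10, 15, 20$. The anchor is placed at
year 5 rather than year 0 because the reference tabulation this fixture
reproduces does not pin down a $t = 0$ state consistent with its own
later rows, while its year-5 row does pin a single exact trajectory: the
package's propagator reproduces all six later tabulated values to within
5 persons (the slack is the two-decimal rounding of the anchor itself).
All quantitative comparisons therefore run over $[5, 20]$, which at a
one-year step means 15 steps.

The parameter sweeps re-derive initial conditions from each swept
parameter set's *own* equilibrium (offset +500 persons), so each
trajectory reflects the swept dynamics rather than a foreign starting
point. The scenario grid defaults to the equilibrium (infinite) horizon;
finite horizons propagate exactly from each scenario's offset state.
Monotonicity of the equilibrium burden — $C^*$ decreasing in $\gamma,
\delta, \mu, \nu$ and increasing in $\lambda$, and both components
exactly linear in $I$ — follows from the closed form and is asserted
numerically across the study ranges.

## Numerical choices

* Convergence orders are estimated by one step-halving (error at
  $\Delta t$ vs $\Delta t/2$ against the exact propagator at $t = 20$).
  The one-step schemes are measured from $\Delta t = 1$; ABM4 from
  $\Delta t = 0.5$, because at a one-year step its start-up transient
  (the fast mode sits at $x = 1.41$, outside the PECE stability
  interval) still dominates the end-state error and masks the asymptotic
  order-4 ratio.
* Mode-rate identities ($\eta_1\eta_2 = \beta$,
  $\eta_1 + \eta_2 = \sigma$) are enforced to $10^{-10}$ relative over
  1,000 seeded random stable parameter draws; fixed-point and semigroup
  properties to $10^{-9}$–$10^{-10}$.
* Populations are stored as doubles throughout; only the `*_printed.csv`
  table variants round (persons to 2 decimals, percentage errors to 4
  significant figures, with values below $10^{-10}\,\%$ printed as
  0.0000 — below any precision the reference tables print).
* Degenerate cases are handled explicitly rather than approximately: a
  repeated eigenvalue switches the propagator to the
  $t e^{-\eta t}$ form, $\lambda = 0$ switches $N(t)$ recovery to direct
  propagation, and $\beta = 0$ (no outflow) is rejected at validation.

## The random-parameter generator

`dc_random_params()` draws the five rates log-uniformly on
$[10^{-3}, 1.5]$ and incidence uniformly on $[10^4, 10^7]$, seeded and
reproducible, optionally resampling into the real-distinct-eigenvalue
regime. It emulates the *mathematically admissible* parameter region, not
demographic realism: draws are independent across rates, carry no
country-specific calibration, and stay within the study's order of
magnitude. Passing the property suite on these draws shows the
implementation is correct across the stable region; it says nothing about
how well the DC model itself fits any real surveillance series, which
would require fitting $\lambda, \gamma, \delta, \nu$ jointly to data the
model does not ship.

## Problem sizes

The default study sizes keep every run at desk scale: 15 one-year steps
per error-table run, a seven-point step-size grid, 3–4 values per
parameter sweep, a $3\times3$ scenario grid, and 1,000 draws for the
property checks — the whole test suite and all analysis stages complete
in seconds.

## Known limitations

The exclusions mirror the model's purpose as a numerical test bed: no
nonlinear or global stability analysis (the system is linear, so none is
needed), no stiff-solver or adaptive integration, no figure-for-figure
plotting, and no fitting to real incidence or prevalence data. The
scenario grid reproduces the *structure* of long-run projections
(linearity in incidence, monotonicity in $\lambda$); published cell
values for such grids depend on unstated horizons and initial conditions
and are not targeted number-for-number.
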