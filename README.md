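# dcmodel

Population-level modelling of diabetes complications with a two-compartment
ordinary-differential-equation model, solved exactly and with five
fixed-step numerical schemes.

## The problem and the model

Public-health planners need to project how many diagnosed diabetics will
carry complications years ahead. The diabetes-complications (DC) model
splits the diabetic population into those with complications, `C(t)`, and
those without, `D(t)`, with `N(t) = C(t) + D(t)` the total stock, under a
constant incidence `I` of newly diagnosed cases (new cases enter both
compartments, since many patients already carry complications at
diagnosis). In the `(C, N)` variables the model is the affine linear
system

```
C'(t) = I − (λ + θ) C(t) + λ N(t)
N'(t) = 2I − (ν + δ) C(t) − μ N(t),      θ = γ + μ + ν + δ
```

with rates per year: `λ` the probability of developing a complication,
`γ` the rate at which complications are controlled, `δ` the mortality
rate due to complications, `μ` the natural mortality rate, and `ν` the
rate of becoming severely disabled. Because the system is linear it has a
closed-form solution `C(t) = K₁e^(−η₁t) + K₂e^(−η₂t) + (α/β)I` — the
package computes it, plus an exact eigendecomposition propagator used as
the truth oracle — and a unique equilibrium `(C*, N*)` that is always an
asymptotically stable node for positive rates.

On top of the model the package provides, from scratch, five fixed-step
schemes (explicit Euler, implicit Euler via an exact 2×2 solve, Heun's
predictor–corrector, classical 4th-order Runge–Kutta, and a 4-step
Adams–Bashforth–Moulton PECE scheme with RK4 start-up), per-scheme
amplification-factor stability diagnostics, eigenvalue classification of
the critical point, and experiment drivers: error tables against the
exact solution, step-size sweeps, per-parameter sweeps, and an
incidence-by-λ scenario grid.

## Worked example

```r
library(dcmodel)

params <- dc_default_params()     # λ=0.85, δ=0.05, μ=0.02, γ=0.5, ν=0.05, I=6e6
dc_stability(params)
#> DC model stability report
#>   characteristic: chi^2 + 1.49 chi + 0.1144 = 0
#>   discriminant:   1.7625
#>   eigenvalues:    chi1 = -0.0812041, chi2 = -1.4088 (1/yr)
#>   critical point: node, asymptotically_stable
```

Both eigenvalues are real and negative: every trajectory relaxes to the
equilibrium, the slow mode with a half-life of about 8.5 years. Scoring
RK4 with a one-year step from the year-5 reference state against the
exact propagator:

```r
fx <- dc_anchor_fixture()
dc_error_table("rk4", fx$anchor, params, dt = 1)
#>    t    C_num   C_true    err_C_pct     N_num    N_true    err_N_pct
#> 1  5 90880137 90880137 0.000000e+00 150047686 150047686 0.000000e+00
#> 2 10 90657024 90657025 7.955967e-07 149681776 149681776 3.877306e-08
#> 3 15 90507782 90507781 1.013533e-07 149437930 149437930 1.024850e-07
#> 4 20 90408341 90408341 1.037193e-07 149275456 149275456 1.026404e-07
#> 5 NA       NA       NA 2.501673e-07        NA        NA 6.097460e-08
```

The `err_*_pct` columns are percentage errors `|numeric − true|/true ×
100`; RK4 lands within a fraction of a person of the exact solution at
every report year, while forward Euler at the same step is off by about
0.011 % at year 20. The final row is the column average.

The full study is scripted as numbered stages under `analysis/`
(stability report, method comparison, step-size sweep, parameter sweeps,
incidence scenarios), each writing its tables under `results/`:

```sh
Rscript analysis/01_stability_analysis.R
Rscript analysis/02_method_comparison.R
# ...
```

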