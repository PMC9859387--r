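#!/usr/bin/env Rscript
# Stage 1: model setup and stability analysis.
# Computes the composite constants, equilibrium and eigenvalue
# classification of the DC model under the canonical parameters, and
# writes the report to results/stability.json.

library(dcmodel)

dir.create("results", showWarnings = FALSE)

params <- dc_default_params()
print(params)

d <- dc_derived(params)
cat(sprintf("\ncomposite constants: theta = %.4g, sigma = %.4g, beta = %.4g, alpha = %.4g\n",
            d$theta, d$sigma, d$beta, d$alpha))
cat(sprintf("modal decay rates:   eta1 = %.6f, eta2 = %.6f (1/yr)\n",
            d$eta1, d$eta2))
cat(sprintf("  -> slow mode half-life %.1f yr; fast mode dies within ~%.1f yr\n",
            log(2) / d$eta1, 3 / d$eta2))

eq <- dc_equilibrium(params, "ode_consistent")
cat(sprintf("\nequilibrium (root of the system): C* = %.2f, N* = %.2f persons\n",
            eq$C_star, eq$N_star))
eqp <- dc_equilibrium(params, "literature_formula")
cat(sprintf("closed-form literature N*:        %.2f persons (not a root; kept for transparency)\n",
            eqp$N_star))

st <- dc_stability(params)
cat("\n")
print(st)
cat(sprintf("forward-Euler stability limit: dt <= 2/eta2 = %.4f yr\n",
            2 / d$eta2))

jsonlite::write_json(
  list(parameters = unclass(params),
       derived = unclass(d),
       equilibrium = list(C_star = eq$C_star, N_star = eq$N_star),
       stability = list(trace_coeff = st$trace_coeff,
                        det_coeff = st$det_coeff,
                        discriminant = st$discriminant,
                        chi1 = Re(st$chi1), chi2 = Re(st$chi2),
                        critical_point_type = st$critical_point_type,
                        stability = st$stability),
       explicit_euler_dt_limit = 2 / d$eta2),
  "results/stability.json", auto_unbox = TRUE, digits = NA)
cat("\nwritten: results/stability.json\n")
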