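#' Characteristic equation of the DC model
#'
#' The linearization of the (C, N) system has the characteristic equation
#' \deqn{\chi^2 + (\lambda+\theta+\mu)\chi + \lambda(\nu+\delta) + \mu(\lambda+\theta) = 0,}
#' whose discriminant is
#' `Delta = (lambda+theta+mu)^2 - 4*(mu*(lambda+theta) + lambda*(nu+delta))`.
#' The coefficients are the negated trace and the determinant of the system
#' matrix, so the roots are its eigenvalues and equal `-eta1`, `-eta2` of
#' [dc_derived()] when real.
#'
#' @param params a [dc_params()] object.
#' @return list of class `dc_characteristic` with `trace_coeff` (1/yr),
#'   `det_coeff` (1/yr^2), `discriminant`.
#' @export
dc_characteristic <- function(params) {
  stopifnot(inherits(params, "dc_params"))
  theta <- params$gamma + params$mu + params$nu + params$delta
  trace_coeff <- params$lambda + theta + params$mu
  det_coeff <- params$lambda * (params$nu + params$delta) +
    params$mu * (params$lambda + theta)
  structure(list(trace_coeff = trace_coeff, det_coeff = det_coeff,
                 discriminant = trace_coeff^2 - 4 * det_coeff),
            class = "dc_characteristic")
}

#' Eigenvalues from the characteristic equation
#'
#' Roots of `chi^2 + trace_coeff*chi + det_coeff = 0` by the quadratic
#' formula; a complex-conjugate pair when the discriminant is negative.
#'
#' @param characteristic a [dc_characteristic()] object.
#' @return complex (or numeric, when real) vector `c(chi1, chi2)` with
#'   `chi1 >= chi2` for real roots.
#' @export
dc_eigenvalues <- function(characteristic) {
  stopifnot(inherits(characteristic, "dc_characteristic"))
  b <- characteristic$trace_coeff
  disc <- characteristic$discriminant
  if (disc >= 0) {
    s <- sqrt(disc)
    c(chi1 = (-b + s) / 2, chi2 = (-b - s) / 2)
  } else {
    s <- sqrt(as.complex(disc))
    c(chi1 = (-b + s) / 2, chi2 = (-b - s) / 2)
  }
}

#' Classify a pair of eigenvalues
#'
#' Standard phase-plane classification of the critical point of a 2x2
#' linear system from its eigenvalues: real pairs give nodes (stable or
#' unstable), mixed signs a saddle, equal real parts a proper/improper
#' node, complex pairs a spiral, and purely imaginary pairs a centre.
#'
#' @param chi1,chi2 eigenvalues (numeric or complex scalars).
#' @return list with `critical_point_type`, `stability` (tag
#'   `"asymptotically_stable"` or `"unstable"`) and `nonstandard_label`
#'   (logical): the centre row of the classification table used by this
#'   model's literature carries the label "asymptotically stable", which
#'   classical theory reserves for attracting points (a centre is only
#'   marginally stable); the table's label is reported and the flag marks
#'   the discrepancy.
#' @export
dc_classify <- function(chi1, chi2) {
  tol <- 1e-12
  re1 <- Re(chi1); re2 <- Re(chi2)
  im1 <- Im(chi1); im2 <- Im(chi2)
  nonstandard <- FALSE
  if (abs(im1) > tol || abs(im2) > tol) {
    if (abs(re1) <= tol && abs(re2) <= tol) {
      type <- "center"
      stab <- "asymptotically_stable"  # table's printed label
      nonstandard <- TRUE
    } else {
      type <- "spiral"
      stab <- if (re1 < 0 && re2 < 0) "asymptotically_stable" else "unstable"
    }
  } else if (re1 * re2 < 0) {
    type <- "saddle"
    stab <- "unstable"
  } else if (abs(re1 - re2) <= tol * max(1, abs(re1))) {
    type <- "proper_or_improper_node"
    stab <- if (re1 < 0) "asymptotically_stable" else "unstable"
  } else {
    type <- "node"
    stab <- if (re1 < 0 && re2 < 0) "asymptotically_stable" else "unstable"
  }
  list(critical_point_type = type, stability = stab,
       nonstandard_label = nonstandard)
}

#' Full stability report for a parameter set
#'
#' Convenience wrapper assembling the characteristic coefficients,
#' discriminant, eigenvalues and critical-point classification in one
#' object.
#'
#' @param params a [dc_params()] object.
#' @return list of class `dc_stability` with fields `trace_coeff`,
#'   `det_coeff`, `discriminant`, `chi1`, `chi2`, `critical_point_type`,
#'   `stability`, `nonstandard_label`.
#' @export
#' @examples
#' dc_stability(dc_default_params())
dc_stability <- function(params) {
  ch <- dc_characteristic(params)
  chi <- dc_eigenvalues(ch)
  cls <- dc_classify(chi[1], chi[2])
  structure(c(unclass(ch), list(chi1 = chi[[1]], chi2 = chi[[2]]), cls),
            class = "dc_stability")
}

#' @export
print.dc_stability <- function(x, ...) {
  fmt <- function(z) if (is.complex(z)) sprintf("%.6g%+.6gi", Re(z), Im(z))
  else sprintf("%.6g", z)
  cat("DC model stability report\n")
  cat(sprintf("  characteristic: chi^2 + %.6g chi + %.6g = 0\n",
              x$trace_coeff, x$det_coeff))
  cat(sprintf("  discriminant:   %.6g\n", x$discriminant))
  cat(sprintf("  eigenvalues:    chi1 = %s, chi2 = %s (1/yr)\n",
              fmt(x$chi1), fmt(x$chi2)))
  cat(sprintf("  critical point: %s, %s\n",
              x$critical_point_type, x$stability))
  invisible(x)
}
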