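# Shared numerical kernels: range-checked linear interpolation for sparse
# physical-property tables, the three-point Lagrange derivative on unequally
# spaced nodes, and monotone (shape-preserving) isotherm interpolants.

# Linear interpolation on a sparse table with hard range errors.
# `what` names the quantity in the error message.
interp_table <- function(x, y, xout, what = "value") {
  if (any(xout < min(x) - 1e-12) || any(xout > max(x) + 1e-12)) {
    stop(sprintf(
      "%s requested at %g outside the tabulated range [%g, %g]",
      what, xout[which(xout < min(x) | xout > max(x))[1]], min(x), max(x)
    ), call. = FALSE)
  }
  stats::approx(x, y, xout = xout, rule = 1, ties = "ordered")$y
}

# Derivative at x0 of the quadratic through three unequally spaced nodes
# (the classical Lagrange differentiation formula).  x0 need not coincide
# with a node, though in this package it always does (the central node).
lagrange3_deriv <- function(x, y, x0) {
  stopifnot(length(x) == 3L, length(y) == 3L)
  if (anyDuplicated(x)) stop("stencil nodes must be distinct", call. = FALSE)
  d1 <- (2 * x0 - x[2] - x[3]) / ((x[1] - x[2]) * (x[1] - x[3]))
  d2 <- (2 * x0 - x[1] - x[3]) / ((x[2] - x[1]) * (x[2] - x[3]))
  d3 <- (2 * x0 - x[1] - x[2]) / ((x[3] - x[1]) * (x[3] - x[2]))
  y[1] * d1 + y[2] * d2 + y[3] * d3
}

# Derivative of f (rows of `y`, one column per node) with respect to the
# electrolyte chemical potential mu_el at node `i` of the activity grid `a`
# [mol/L].  Differentiates in x = ln a when every stencil activity is
# positive (exact for the logarithmic mu_el dependence typical of surface
# equations of state); falls back to the activity variable itself when the
# stencil contains a = 0 (pure water), where ln a diverges but f(a) is
# smooth.  Interior nodes use the three-point Lagrange formula; terminal
# nodes a one-sided two-point difference, flagged low accuracy.
#
# Returns list(dfdmu = df/dmu_el [units of f per J/mol], low_accuracy, stencil)
mu_el_derivative <- function(a, y, i, RT) {
  n <- length(a)
  if (n < 3L) stop("need at least 3 concentrations to differentiate", call. = FALSE)
  interior <- i > 1L && i < n
  idx <- if (interior) (i - 1L):(i + 1L) else if (i == 1L) 1:2 else (n - 1L):n
  a_st <- a[idx]
  use_log <- all(a_st > 0)
  x <- if (use_log) log(a_st) else a_st
  x0 <- if (use_log) log(a[i]) else a[i]
  y <- as.matrix(y)
  dfdx <- if (interior) {
    apply(y[, idx, drop = FALSE], 1L, lagrange3_deriv, x = x, x0 = x0)
  } else {
    (y[, idx[2]] - y[, idx[1]]) / (x[2] - x[1])
  }
  dfdmu <- if (use_log) dfdx / RT else dfdx * a[i] / RT
  list(
    dfdmu = dfdmu,
    low_accuracy = !interior,
    stencil = list(indices = idx, variable = if (use_log) "log-activity" else "activity")
  )
}

# Shape-preserving cubic interpolant pi(S) for a validated isotherm:
# monotone Hermite (Fritsch-Carlson), no overshoot between nodes.
monotone_interpolant <- function(S, pi) {
  ord <- order(S)
  stats::splinefun(S[ord], pi[ord], method = "monoH.FC")
}
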