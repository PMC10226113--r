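# Parametric model of the monolayer-induced electrolyte adsorption,
# combining three mechanisms the data call for: ion-headgroup complexation
# (Langmuir-type in the activity), the osmotic effect of the hydrated polar
# headgroups that dilute surface water, and a squeeze-out term expelling
# ions at high monolayer density.  The form is deliberately the simplest
# smooth one exhibiting a maximum at intermediate density; it is isolated
# behind model_delta_gamma() so a different closure can be swapped in.

#' Model parameters for the induced-adsorption model
#'
#' @param K_assoc Ion-headgroup association constant, L/mol.
#' @param v_head Effective hydrated-headgroup volume per mole of lipid,
#'   L/mol (osmotic-dilution term).
#' @param b_excl Squeeze-out coefficient, (L/mol) x (m^2/umol): coefficient
#'   of the quadratic-in-density expulsion term.
#' @return An object of class `model_params`.
#' @export
model_params <- function(K_assoc, v_head, b_excl) {
  vals <- c(K_assoc = K_assoc, v_head = v_head, b_excl = b_excl)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("model parameters must be finite and >= 0", call. = FALSE)
  structure(as.list(vals), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> K_assoc = %g L/mol, v_head = %g L/mol, b_excl = %g (L/mol)(m^2/umol)\n",
              x$K_assoc, x$v_head, x$b_excl))
  invisible(x)
}

#' Induced electrolyte adsorption predicted by the model
#'
#' \deqn{\Delta\Gamma_{el} = \Gamma_s\,\nu\,\frac{K a}{1 + K a}
#'   + \nu\, C\, v_h\, \Gamma_s - \nu\, C\, b\, \Gamma_s^2,}
#' zero at \eqn{\Gamma_s = 0} and at zero electrolyte, with a unique
#' interior maximum in \eqn{\Gamma_s} whenever \eqn{b > 0}.
#'
#' @param params A [model_params()].
#' @param Gamma_s Lipid surface density (or vector), umol/m^2, \eqn{\ge 0}.
#' @param a_el Electrolyte activity, mol/L scale, \eqn{\ge 0}.
#' @param C_el Electrolyte concentration, mol/L, \eqn{\ge 0}.
#' @param spec An [electrolyte_spec()] (supplies \eqn{\nu}).
#' @return \eqn{\Delta\Gamma_{el}} in umol/m^2.
#' @export
model_delta_gamma <- function(params, Gamma_s, a_el, C_el, spec) {
  stopifnot(inherits(params, "model_params"), inherits(spec, "electrolyte_spec"))
  if (any(Gamma_s < 0) || any(a_el < 0) || any(C_el < 0))
    stop("Gamma_s, a_el and C_el must be >= 0", call. = FALSE)
  nu <- spec$nu
  binding <- params$K_assoc * a_el / (1 + params$K_assoc * a_el)
  nu * Gamma_s * (binding + C_el * params$v_head) -
    nu * C_el * params$b_excl * Gamma_s^2
}

# Density at which the model adsorption peaks (closed form; Inf when b = 0)
model_peak_density <- function(params, a_el, C_el, spec) {
  if (params$b_excl == 0 || C_el == 0) return(Inf)
  binding <- params$K_assoc * a_el / (1 + params$K_assoc * a_el)
  (binding + C_el * params$v_head) / (2 * C_el * params$b_excl)
}

#' Fit the induced-adsorption model to inversion output
#'
#' Non-negative least squares (Levenberg-Marquardt with zero lower bounds)
#' of [model_delta_gamma()] to one or several [route_constant_mu()] /
#' [route_constant_pi()] profiles.  Deterministic given the initial guess.
#' RMS relative errors are reported overall and, when an area threshold
#' `S_split` is given, separately for the expanded (\eqn{S >} threshold)
#' and condensed (\eqn{S \le} threshold) regions.
#'
#' @param profiles One `adsorption_profile` or a list of them (different
#'   target concentrations allowed; each profile's activity is taken from
#'   `spec`).
#' @param spec An [electrolyte_spec()].
#' @param init Initial [model_params()] (default K = 1, v = 0.1, b = 0.01).
#' @param S_split Optional area threshold (A^2/molecule) splitting the
#'   expanded/condensed error report.
#' @return A list of class `model_fit`: `params` ([model_params()]),
#'   `std_errors`, `residuals`, `rms_rel_error`, `rms_rel_by_region`,
#'   `n`, `converged`.
#' @export
fit_model <- function(profiles, spec, init = model_params(1, 0.1, 0.01),
                      S_split = NULL) {
  stopifnot(inherits(spec, "electrolyte_spec"), inherits(init, "model_params"))
  if (inherits(profiles, "adsorption_profile")) profiles <- list(profiles)
  dat <- do.call(rbind, lapply(profiles, function(p) {
    C <- attr(p, "C_el_target")
    data.frame(Gamma_s = p$Gamma_s, S = p$S, dGamma_el = p$dGamma_el,
               C_el = C, a_el = activity(spec, C))
  }))
  if (nrow(dat) < 6L) stop("need at least 6 data rows to fit", call. = FALSE)
  if (all(abs(dat$dGamma_el) < 1e-12) || !any(dat$dGamma_el > 0))
    stop("degenerate data: no positive induced adsorption to fit", call. = FALSE)

  nu <- spec$nu
  model_fn <- function(par)
    nu * dat$Gamma_s * (par[1] * dat$a_el / (1 + par[1] * dat$a_el) +
                          dat$C_el * par[2]) -
      nu * dat$C_el * par[3] * dat$Gamma_s^2
  # nls.lm rather than nlsLM: with data at a single concentration the
  # complexation and osmotic columns of the Jacobian are exactly collinear,
  # which Levenberg-Marquardt damping handles but nls-object construction
  # does not
  fit <- minpack.lm::nls.lm(
    par = c(K = init$K_assoc, v = init$v_head, b = init$b_excl),
    lower = c(0, 0, 0),
    fn = function(par) dat$dGamma_el - model_fn(par),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  est <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  resid <- fit$fvec
  rel <- abs(resid) / pmax(abs(dat$dGamma_el), 1e-9)

  by_region <- NULL
  if (!is.null(S_split)) {
    expanded <- dat$S > S_split
    by_region <- c(
      expanded = if (any(expanded)) sqrt(mean(rel[expanded]^2)) else NA_real_,
      condensed = if (any(!expanded)) sqrt(mean(rel[!expanded]^2)) else NA_real_)
  }
  structure(list(
    params = model_params(est[["K"]], est[["v"]], est[["b"]]),
    std_errors = stats::setNames(as.numeric(se), c("K_assoc", "v_head", "b_excl")),
    residuals = resid,
    rms_rel_error = sqrt(mean(rel^2)),
    rms_rel_by_region = by_region,
    n = nrow(dat),
    converged = fit$info %in% 1:4
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit>\n")
  print(x$params)
  cat(sprintf("  RMS relative error %.2f%% over %d points%s\n",
              100 * x$rms_rel_error, x$n,
              if (x$converged) "" else " [did not converge]"))
  if (!is.null(x$rms_rel_by_region))
    cat(sprintf("  expanded %.2f%% / condensed %.2f%%\n",
                100 * x$rms_rel_by_region[["expanded"]],
                100 * x$rms_rel_by_region[["condensed"]]))
  invisible(x)
}
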