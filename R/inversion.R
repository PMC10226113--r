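# Core thermodynamic inversion.  The surface Gibbs-Duhem relation for an
# insoluble monolayer on an electrolyte subphase,
#     d(sigma) = -Gamma_s d(mu_s) - nu * Gamma_el d(mu_el),
# gives, at fixed subphase composition, d(mu_s) = S d(pi).  Anchoring the
# integration at the equilibrium spreading point (whose amphiphile chemical
# potential is set by the bulk crystal and is therefore electrolyte
# independent) turns a family of compression isotherms at several
# concentrations into Delta(mu_s)(pi, C) on a common reference, from which
# the monolayer-induced electrolyte adsorption follows by differentiation
# with respect to the bulk electrolyte state, either at constant mu_s,
#     Delta(Gamma_el) = (1/nu) (d pi / d mu_el)|_{mu_s},
# or at constant pi,
#     Delta(Gamma_el) = -(Gamma_s/nu) (d mu_s / d mu_el)|_{pi}.
# Agreement of the two routes is a thermodynamic-compatibility test of the
# isotherm and spreading-pressure data sets.

#' Amphiphile chemical-potential change along a compression isotherm
#'
#' Integrates \eqn{\Delta\mu_s(\pi) = \int_{\pi_{sp}}^{\pi} S\, d\pi'} along
#' one isotherm, anchored to zero at the equilibrium spreading pressure.
#' The integral is evaluated by parts,
#' \deqn{\Delta\mu_s = S\pi - S_{sp}\pi_{sp} - \int_{S_{sp}}^{S} \pi\, dS',}
#' so LE-LC coexistence plateaus (\eqn{\pi} constant in \eqn{S}) are
#' integrable without inverting \eqn{\pi(S)}.  The isotherm is interpolated
#' with a shape-preserving monotone cubic and densified to `n_dense`
#' geometrically spaced areas before trapezoidal integration.  The spread
#' state's area \eqn{S_{sp}} is read off the isotherm at
#' \eqn{\pi = \pi_{sp}}; if the isotherm stops short of \eqn{\pi_{sp}} by at
#' most `gap_tolerance`, the final segment is extended linearly in
#' \eqn{(S,\pi)} with a warning, larger shortfalls are errors.
#'
#' @param iso A [compression_isotherm()].
#' @param sp A [spreading_point()] at the same concentration.
#' @param gap_tolerance Largest tolerated shortfall of the isotherm's
#'   maximum pressure below \eqn{\pi_{sp}}, mN/m (default 2).
#' @param n_dense Number of dense working-grid points (default 4000).
#' @return An object of class `chem_potential_curve`: a list with a `grid`
#'   data frame (`pi` mN/m, `S` A^2/molecule, `dmu` kJ/mol, ordered by
#'   increasing `pi`), plus `C_el`, `temperature`, `pi_sp`, `S_sp`.
#'   \eqn{\Delta\mu_s} is 0 at \eqn{\pi_{sp}}, negative below, and
#'   non-decreasing in \eqn{\pi} (strictly increasing except across
#'   plateaus).
#' @export
chem_potential_curve <- function(iso, sp, gap_tolerance = 2, n_dense = 4000) {
  stopifnot(inherits(iso, "compression_isotherm"), inherits(sp, "spreading_point"))
  if (abs(attr(iso, "C_el") - sp$C_el) > 1e-9)
    stop("isotherm and spreading point are at different concentrations", call. = FALSE)

  S_raw <- rev(iso$S); pi_raw <- rev(iso$pi)     # increasing S
  pi_max <- pi_raw[1]                            # pressure at smallest area
  gap <- sp$pi_sp - pi_max
  if (gap > gap_tolerance)
    stop(sprintf(
      "isotherm reaches only %.2f mN/m, %.2f mN/m short of pi_sp = %.2f (gap tolerance %.2f)",
      pi_max, gap, sp$pi_sp, gap_tolerance), call. = FALSE)

  S_lo <- S_raw[1]
  if (gap > 0) {
    # linear extension of the steep final segment down to pi_sp
    slope <- (pi_raw[1] - pi_raw[2]) / (S_raw[1] - S_raw[2])   # dpi/dS < 0
    if (!is.finite(slope) || slope >= 0)
      stop("cannot extend isotherm to pi_sp: final segment is not compressive",
           call. = FALSE)
    S_lo <- S_raw[1] + gap / slope
    warning(sprintf(
      "isotherm extended linearly from pi = %.2f to pi_sp = %.2f mN/m (S %.3f -> %.3f A^2)",
      pi_max, sp$pi_sp, S_raw[1], S_lo), call. = FALSE)
  }

  f_pi <- monotone_interpolant(S_raw, pi_raw)
  S_dense <- exp(seq(log(S_lo), log(max(S_raw)), length.out = n_dense))
  pi_dense <- numeric(n_dense)
  inside <- S_dense >= S_raw[1]
  pi_dense[inside] <- f_pi(S_dense[inside])
  if (any(!inside)) {
    slope <- (pi_raw[1] - pi_raw[2]) / (S_raw[1] - S_raw[2])
    pi_dense[!inside] <- pi_raw[1] + slope * (S_dense[!inside] - S_raw[1])
  }
  # guard against sub-mN/m interpolation wiggle at flat-run boundaries (the
  # Fritsch-Carlson filter can overshoot by ~1e-4 mN/m next to plateaus):
  # clamp to non-decreasing along compression, then floor at zero
  pi_dense <- rev(cummax(rev(pi_dense)))
  pi_dense <- pmax(pi_dense, 0)

  # spread-state area: first contact along compression, i.e. the largest S
  # at which pi attains pi_sp
  j <- suppressWarnings(max(which(pi_dense >= sp$pi_sp - 1e-12)))
  if (!is.finite(j) || j < 1L)
    stop("isotherm never attains pi_sp on the working grid", call. = FALSE)
  if (j >= n_dense) {
    S_sp <- S_dense[n_dense]
  } else {
    dpi <- pi_dense[j + 1L] - pi_dense[j]
    frac <- if (dpi == 0) 0 else (sp$pi_sp - pi_dense[j]) / dpi
    S_sp <- S_dense[j] + frac * (S_dense[j + 1L] - S_dense[j])
  }

  cum <- pracma::cumtrapz(S_dense, pi_dense)[, 1]   # int_{S_min}^{S} pi dS'
  pi_at_sp <- sp$pi_sp
  cum_sp <- if (j >= n_dense) cum[n_dense] else
    cum[j] + 0.5 * (pi_dense[j] + pi_at_sp) * (S_sp - S_dense[j])

  # Delta(mu_s) = S*pi - S_sp*pi_sp - int_{S_sp}^{S} pi dS'   [mN/m * A^2]
  dmu <- (S_dense * pi_dense - S_sp * sp$pi_sp - (cum - cum_sp)) *
    fp_constants$mNm_A2_to_kJ_mol

  grid <- data.frame(pi = rev(pi_dense), S = rev(S_dense), dmu = rev(dmu))
  if (any(diff(grid$dmu) < -1e-9))
    stop("non-monotone chemical potential along compression; check the isotherm",
         call. = FALSE)

  structure(list(grid = grid, C_el = attr(iso, "C_el"),
                 temperature = attr(iso, "temperature"),
                 pi_sp = sp$pi_sp, S_sp = S_sp, extended = gap > 0),
            class = "chem_potential_curve")
}

#' @export
print.chem_potential_curve <- function(x, ...) {
  cat(sprintf(
    "<chem_potential_curve> C_el = %g M, pi_sp = %.2f mN/m (S_sp = %.2f A^2)\n  pi in [%.2f, %.2f] mN/m, dmu_s in [%.3f, %.3f] kJ/mol\n",
    x$C_el, x$pi_sp, x$S_sp, min(x$grid$pi), max(x$grid$pi),
    min(x$grid$dmu), max(x$grid$dmu)))
  invisible(x)
}

# Evaluate a curve at given surface pressures.  At a coexistence plateau the
# area returned is the largest S attaining that pressure (first contact
# along compression).
curve_at_pi <- function(curve, pi) {
  g <- curve$grid
  if (any(pi < g$pi[1] - 1e-9) || any(pi > g$pi[nrow(g)] + 1e-9))
    stop(sprintf("pi outside curve range [%.3f, %.3f] mN/m",
                 g$pi[1], g$pi[nrow(g)]), call. = FALSE)
  keep <- !duplicated(g$pi)            # first row of a plateau has largest S
  list(dmu = stats::approx(g$pi[keep], g$dmu[keep], xout = pi, rule = 2)$y,
       S   = stats::approx(g$pi[keep], g$S[keep],   xout = pi, rule = 2)$y)
}

# Evaluate a curve at given chemical-potential changes (kJ/mol).
curve_at_dmu <- function(curve, dmu) {
  g <- curve$grid
  if (any(dmu < g$dmu[1] - 1e-9) || any(dmu > g$dmu[nrow(g)] + 1e-9))
    stop(sprintf("dmu outside curve range [%.4f, %.4f] kJ/mol",
                 g$dmu[1], g$dmu[nrow(g)]), call. = FALSE)
  keep <- !duplicated(g$dmu)
  list(pi = stats::approx(g$dmu[keep], g$pi[keep], xout = dmu, rule = 2)$y,
       S  = stats::approx(g$dmu[keep], g$S[keep],  xout = dmu, rule = 2)$y)
}

check_curve_family <- function(curves, spec, target_C) {
  if (length(curves) < 3L)
    stop("need chemical-potential curves at >= 3 concentrations", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, TRUE, "chem_potential_curve")))
  C <- vapply(curves, `[[`, numeric(1), "C_el")
  Tv <- vapply(curves, `[[`, numeric(1), "temperature")
  if (anyDuplicated(C)) stop("duplicate concentrations in curve family", call. = FALSE)
  if (max(Tv) - min(Tv) > 1e-6)
    stop("mixed temperatures in curve family", call. = FALSE)
  if (abs(Tv[1] - spec$temperature) > 1e-6)
    stop("curve temperature differs from electrolyte spec temperature", call. = FALSE)
  ord <- order(C)
  i <- which(abs(C[ord] - target_C) < 1e-9)
  if (length(i) != 1L)
    stop(sprintf("target concentration %g M is not in the curve family", target_C),
         call. = FALSE)
  list(curves = curves[ord], C = C[ord], i = i)
}

new_adsorption_profile <- function(df, target_C, route) {
  attr(df, "C_el_target") <- target_C
  attr(df, "route") <- route
  class(df) <- c("adsorption_profile", "data.frame")
  df
}

#' @export
print.adsorption_profile <- function(x, ...) {
  cat(sprintf(
    "<adsorption_profile> route %s at C_el = %g M, %d rows, dGamma_el in [%.4g, %.4g] umol/m^2%s\n",
    attr(x, "route"), attr(x, "C_el_target"), nrow(x),
    min(x$dGamma_el), max(x$dGamma_el),
    if (any(x$low_accuracy)) " [low accuracy: one-sided stencil]" else ""))
  invisible(x)
}

#' Electrolyte adsorption at constant amphiphile chemical potential
#'
#' The Frumkin route: on a grid of \eqn{\Delta\mu_s} values spanning the
#' common range of all curves, each curve is inverted to \eqn{\pi(C)} (the
#' inverse exists by monotonicity) and the monolayer-induced electrolyte
#' adsorption is
#' \deqn{\Delta\Gamma_{el} = \frac{1}{\nu}
#'   \left(\frac{\partial\pi}{\partial\mu_{el}}\right)_{\mu_s},}
#' with the derivative over the bulk electrolyte state taken by the
#' three-point Lagrange formula on the (unequally spaced) activity nodes —
#' in the \eqn{\ln a} variable when all stencil activities are positive, in
#' \eqn{a} itself when pure water is part of the stencil.  The derivative is
#' far more accurate at a central concentration than at terminal ones; at a
#' terminal concentration a one-sided two-point difference is used and the
#' rows are flagged `low_accuracy`.
#'
#' @param curves List of [chem_potential_curve()]s at \eqn{\ge 3} distinct
#'   concentrations (all anchored at the electrolyte-independent spread
#'   reference).
#' @param spec An [electrolyte_spec()].
#' @param target_C Concentration (present among the curves) at which the
#'   adsorption is reported.
#' @param n_grid Number of grid values (default 200).
#' @return An `adsorption_profile`: data frame with columns `S`
#'   (A^2/molecule, from the target-concentration curve), `Gamma_s`
#'   (umol/m^2), `dGamma_el` (umol/m^2) and `low_accuracy`, sorted by
#'   decreasing `S`.
#' @export
route_constant_mu <- function(curves, spec, target_C, n_grid = 200) {
  stopifnot(inherits(spec, "electrolyte_spec"))
  fam <- check_curve_family(curves, spec, target_C)
  lo <- max(vapply(fam$curves, function(cv) min(cv$grid$dmu), numeric(1)))
  hi <- min(vapply(fam$curves, function(cv) max(cv$grid$dmu), numeric(1)))
  if (lo >= hi)
    stop("curves have no common chemical-potential range", call. = FALSE)
  dmu_grid <- seq(lo, hi, length.out = n_grid)

  pi_mat <- vapply(fam$curves, function(cv) curve_at_dmu(cv, dmu_grid)$pi,
                   numeric(n_grid))
  a <- activity(spec, fam$C)
  RT <- fp_constants$R * spec$temperature
  der <- mu_el_derivative(a, pi_mat, fam$i, RT)     # mN/m per (J/mol)
  dGamma <- 1e3 * der$dfdmu / spec$nu               # umol/m^2

  S <- curve_at_dmu(fam$curves[[fam$i]], dmu_grid)$S
  df <- data.frame(S = S, Gamma_s = area_to_density(S), dGamma_el = dGamma,
                   low_accuracy = der$low_accuracy)
  df <- df[order(df$S, decreasing = TRUE), , drop = FALSE]
  rownames(df) <- NULL
  new_adsorption_profile(df, target_C, "constant_mu_s")
}

#' Electrolyte adsorption at constant surface pressure
#'
#' The complementary route: on a grid of \eqn{\pi} values spanning the
#' common pressure range, the chemical-potential change of each curve is
#' differentiated over the bulk electrolyte state at fixed \eqn{\pi},
#' \deqn{\Delta\Gamma_{el} = -\frac{\Gamma_s}{\nu}
#'   \left(\frac{\partial\mu_s}{\partial\mu_{el}}\right)_{\pi},}
#' with \eqn{\Gamma_s} taken from the target-concentration curve at that
#' pressure.  Stencils and accuracy flags as in [route_constant_mu()].
#'
#' @inheritParams route_constant_mu
#' @return An `adsorption_profile` with `route = "constant_pi"`.
#' @export
route_constant_pi <- function(curves, spec, target_C, n_grid = 200) {
  stopifnot(inherits(spec, "electrolyte_spec"))
  fam <- check_curve_family(curves, spec, target_C)
  lo <- max(vapply(fam$curves, function(cv) min(cv$grid$pi), numeric(1)))
  hi <- min(vapply(fam$curves, function(cv) max(cv$grid$pi), numeric(1)))
  if (lo >= hi)
    stop("curves have no common surface-pressure range", call. = FALSE)
  pi_grid <- seq(lo, hi, length.out = n_grid)

  dmu_mat <- vapply(fam$curves, function(cv) curve_at_pi(cv, pi_grid)$dmu,
                    numeric(n_grid)) * 1e3          # J/mol
  a <- activity(spec, fam$C)
  RT <- fp_constants$R * spec$temperature
  der <- mu_el_derivative(a, dmu_mat, fam$i, RT)    # dimensionless

  S <- curve_at_pi(fam$curves[[fam$i]], pi_grid)$S
  Gamma_s <- area_to_density(S)                     # umol/m^2
  dGamma <- -Gamma_s * der$dfdmu / spec$nu
  df <- data.frame(S = S, Gamma_s = Gamma_s, dGamma_el = dGamma,
                   low_accuracy = der$low_accuracy)
  df <- df[order(df$S, decreasing = TRUE), , drop = FALSE]
  rownames(df) <- NULL
  new_adsorption_profile(df, target_C, "constant_pi")
}

#' Electrolyte adsorption of the equilibrium spread monolayer
#'
#' Because the spread state sits at a fixed (electrolyte-independent)
#' amphiphile chemical potential, the concentration dependence of the
#' spreading pressure alone gives the adsorption there:
#' \deqn{\Delta\Gamma_{el,sp} = \frac{a}{\nu RT}\frac{d\pi_{sp}}{da},}
#' differentiated in the activity variable \eqn{a = \gamma_{el} C_{el}}
#' (which admits the pure-water point \eqn{a = 0}) by the three-point
#' Lagrange formula.
#'
#' @param sps List of [spreading_point()]s at \eqn{\ge 3} distinct
#'   concentrations (C = 0 allowed).
#' @param spec An [electrolyte_spec()].
#' @param target_C Concentration at which to evaluate, present among `sps`.
#' @param S_sp Optional area per molecule of the spread state
#'   (A^2/molecule), e.g. from [chem_potential_curve()]'s `S_sp`; `NA`
#'   otherwise.
#' @return A single-row `adsorption_profile` with
#'   `route = "spreading_point"`.
#' @export
spreading_point_adsorption <- function(sps, spec, target_C, S_sp = NA_real_) {
  stopifnot(inherits(spec, "electrolyte_spec"))
  if (length(sps) < 3L)
    stop("need spreading points at >= 3 concentrations", call. = FALSE)
  stopifnot(all(vapply(sps, inherits, TRUE, "spreading_point")))
  C <- vapply(sps, `[[`, numeric(1), "C_el")
  if (anyDuplicated(C)) stop("duplicate concentrations among spreading points",
                             call. = FALSE)
  ord <- order(C)
  C <- C[ord]
  pi_sp <- vapply(sps, `[[`, numeric(1), "pi_sp")[ord]
  i <- which(abs(C - target_C) < 1e-9)
  if (length(i) != 1L)
    stop(sprintf("target concentration %g M has no spreading point", target_C),
         call. = FALSE)

  a <- activity(spec, C)
  RT <- fp_constants$R * spec$temperature
  der <- mu_el_derivative(a, matrix(pi_sp, nrow = 1), i, RT)
  dGamma <- 1e3 * der$dfdmu / spec$nu
  df <- data.frame(S = S_sp,
                   Gamma_s = if (is.finite(S_sp)) area_to_density(S_sp) else NA_real_,
                   dGamma_el = dGamma, low_accuracy = der$low_accuracy)
  new_adsorption_profile(df, target_C, "spreading_point")
}

#' Thermodynamic-compatibility report between the two routes
#'
#' The constant-\eqn{\mu_s} and constant-\eqn{\pi} routes must agree if the
#' isotherm family and the spreading pressures are mutually consistent
#' (both follow from the same Gibbs-Duhem surface).  This report
#' interpolates one profile onto the other's area grid over the overlapping
#' \eqn{S} range and summarizes the pointwise deviation, relative to the
#' mean magnitude of the two values at each point.
#'
#' @param profile_mu,profile_pi `adsorption_profile`s at the same target
#'   concentration (typically from [route_constant_mu()] and
#'   [route_constant_pi()]).
#' @param tolerance PASS threshold on the maximum relative deviation
#'   (default 0.05).
#' @return An object of class `consistency_report` with elements
#'   `max_rel_dev`, `rms_rel_dev`, `n`, `S_range`, `tolerance`, `pass`.
#' @export
consistency_report <- function(profile_mu, profile_pi, tolerance = 0.05) {
  stopifnot(inherits(profile_mu, "adsorption_profile"),
            inherits(profile_pi, "adsorption_profile"))
  if (abs(attr(profile_mu, "C_el_target") - attr(profile_pi, "C_el_target")) > 1e-9)
    stop("profiles are at different target concentrations", call. = FALSE)
  lo <- max(min(profile_mu$S), min(profile_pi$S))
  hi <- min(max(profile_mu$S), max(profile_pi$S))
  if (lo >= hi) stop("profiles have disjoint area ranges", call. = FALSE)
  keep <- profile_mu$S >= lo & profile_mu$S <= hi
  S <- profile_mu$S[keep]
  A <- profile_mu$dGamma_el[keep]
  ordB <- order(profile_pi$S)
  B <- stats::approx(profile_pi$S[ordB], profile_pi$dGamma_el[ordB], xout = S,
                     rule = 2)$y
  denom <- pmax((abs(A) + abs(B)) / 2, 1e-9)
  dev <- abs(A - B) / denom
  res <- list(max_rel_dev = max(dev), rms_rel_dev = sqrt(mean(dev^2)),
              n = length(dev), S_range = c(lo, hi), tolerance = tolerance,
              pass = max(dev) <= tolerance)
  class(res) <- "consistency_report"
  res
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "<consistency_report> %s: max %.3f%%, RMS %.3f%% relative deviation over %d points, S in [%.2f, %.2f] A^2 (tolerance %.1f%%)\n",
    if (x$pass) "PASS" else "FAIL", 100 * x$max_rel_dev, 100 * x$rms_rel_dev,
    x$n, x$S_range[1], x$S_range[2], 100 * x$tolerance))
  invisible(x)
}
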