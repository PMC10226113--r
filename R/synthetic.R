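# Synthetic data generator.  An analytic Langmuir-type surface equation of
# state sigma(mu_s, mu_el) that satisfies the surface Gibbs-Duhem relation
# exactly, so that the lipid density and the monolayer-induced electrolyte
# adsorption are closed-form.  It produces isotherm families and spreading
# points in the same shapes the inversion consumes, making it an end-to-end
# oracle for the whole pipeline.

#' Analytic forward model for synthetic isotherm families
#'
#' Defines the surface equation of state
#' \deqn{\sigma(\mu_s,\mu_{el}) = \sigma_0(C) -
#'   RT\,\Gamma_\infty \ln\!\big(1 + b(\mu_{el})\,e^{\mu_s/RT}\big),\qquad
#'   b(\mu_{el}) = b_0\, e^{\beta\mu_{el}/RT},}
#' with \eqn{\mu_{el} = RT\ln a} (ideal activity, \eqn{a = C}) and
#' \eqn{\sigma_0(C) = \sigma_w + k_\sigma C}.  Differentiation gives the
#' exact fields
#' \deqn{\Gamma_s = \Gamma_\infty\theta,\quad
#'   \theta = \frac{b e^{\mu_s/RT}}{1 + b e^{\mu_s/RT}},\qquad
#'   \nu\,\Delta\Gamma_{el} = \beta\,\Gamma_s,}
#' so the generator carries its own adsorption oracle.  Spreading points are
#' produced at the fixed chemical potential `mu_s_sp`, mirroring the bulk
#' amphiphile phase acting as an electrolyte-independent reservoir.
#'
#' Defaults emulate a DPPC-like lipid on NaCl at 25 C: saturation density
#' 4 umol/m^2 (limiting area ~41.5 A^2/molecule), spreading pressures in
#' the low-to-mid 40s mN/m, and a monolayer-induced NaCl excess of a few
#' tenths of umol/m^2 at full coverage.
#'
#' @param Gamma_inf Saturation lipid density, umol/m^2.
#' @param b0 Adsorption-constant prefactor (dimensionless scale).
#' @param beta Electrolyte-coupling coefficient \eqn{\beta} (dimensionless);
#'   0 decouples the electrolyte entirely.
#' @param mu_s_sp Spread-state amphiphile chemical potential, kJ/mol
#'   (relative to the same standard state as `mu_s` arguments).
#' @param sigma0_slope Clean-surface tension slope \eqn{d\sigma_0/dC},
#'   mN/m per mol/L.
#' @param sigma_water Clean-surface tension of water, mN/m.
#' @param temperature Temperature, K.
#' @param nu Isotonic coefficient of the electrolyte.
#' @param a_floor Activity floor (mol/L) used for \eqn{\mu_{el}} at C = 0
#'   inside the generator only (the inversion never evaluates \eqn{\ln a}
#'   at 0).
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(Gamma_inf = 4, b0 = 1, beta = 0.12, mu_s_sp = 11.3,
                          sigma0_slope = 1.6, sigma_water = 71.97,
                          temperature = 298.15, nu = 2, a_floor = 1e-6) {
  stopifnot(Gamma_inf > 0, b0 > 0, sigma_water > 0, temperature > 0,
            nu >= 1, a_floor > 0)
  structure(list(Gamma_inf = Gamma_inf, b0 = b0, beta = beta,
                 mu_s_sp = mu_s_sp, sigma0_slope = sigma0_slope,
                 sigma_water = sigma_water, temperature = temperature,
                 nu = as.integer(nu), a_floor = a_floor),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf(
    "<forward_model> Gamma_inf = %g umol/m^2, b0 = %g, beta = %g, mu_s_sp = %g kJ/mol, T = %g K, nu = %d\n",
    x$Gamma_inf, x$b0, x$beta, x$mu_s_sp, x$temperature, x$nu))
  invisible(x)
}

fm_mu_el <- function(fm, C_el) {
  RT <- fp_constants$R * fm$temperature
  RT * log(pmax(C_el, fm$a_floor))
}

#' Evaluate the forward model at a surface state
#'
#' @param fm A [forward_model()].
#' @param mu_s Amphiphile chemical potential(s), kJ/mol.
#' @param C_el Electrolyte concentration, mol/L (single value).
#' @return Data frame with columns `mu_s` (kJ/mol), `sigma` and `pi` (mN/m),
#'   `Gamma_s` (umol/m^2), `S` (A^2/molecule) and the exact
#'   `dGamma_el` (umol/m^2).
#' @export
forward_surface_state <- function(fm, mu_s, C_el) {
  stopifnot(inherits(fm, "forward_model"), length(C_el) == 1L, C_el >= 0)
  RT <- fp_constants$R * fm$temperature               # J/mol
  b <- fm$b0 * exp(fm$beta * fm_mu_el(fm, C_el) / RT)
  x <- b * exp(mu_s * 1e3 / RT)
  theta <- x / (1 + x)
  Gamma_s <- fm$Gamma_inf * theta                     # umol/m^2
  # RT * Gamma_inf in mN/m: J/mol * mol/m^2 = N/m -> x1e3
  RTG <- RT * fm$Gamma_inf * 1e-6 * 1e3
  pi <- RTG * log1p(x)
  sigma <- fm$sigma_water + fm$sigma0_slope * C_el - pi
  if (any(sigma <= 0))
    stop("forward model yields non-positive surface tension in this range",
         call. = FALSE)
  data.frame(mu_s = mu_s, sigma = sigma, pi = pi, Gamma_s = Gamma_s,
             S = density_to_area(Gamma_s),
             dGamma_el = fm$beta * Gamma_s / fm$nu)
}

# Invert pi (mN/m) -> mu_s (kJ/mol) at concentration C_el.
fm_mu_s_at_pi <- function(fm, pi, C_el) {
  RT <- fp_constants$R * fm$temperature
  b <- fm$b0 * exp(fm$beta * fm_mu_el(fm, C_el) / RT)
  RTG <- RT * fm$Gamma_inf * 1e-3
  x <- expm1(pi / RTG)
  if (any(x <= 0)) stop("pi must be positive", call. = FALSE)
  RT * (log(x) - log(b)) / 1e3
}

#' Spreading pressure of the forward model
#'
#' \eqn{\pi_{sp}(C) = \sigma_0(C) - \sigma(\mu_{s,sp}, C)} at the fixed
#' spread-state chemical potential.
#'
#' @inheritParams forward_surface_state
#' @param C_el Concentration(s), mol/L.
#' @return Spreading pressure(s), mN/m.
#' @export
fm_spreading_pressure <- function(fm, C_el) {
  vapply(C_el, function(C) forward_surface_state(fm, fm$mu_s_sp, C)$pi,
         numeric(1))
}

#' Generate a synthetic isotherm family with its adsorption oracle
#'
#' Sweeps \eqn{\mu_s} at each concentration so that \eqn{\pi} covers
#' `pi_range` on `n_points` geometrically spaced pressures, and emits the
#' isotherm table, the spreading points (all at the common `mu_s_sp`), and
#' the exact monolayer-induced adsorption at every emitted state.
#'
#' @param fm A [forward_model()].
#' @param C_grid Concentrations, mol/L (\eqn{\ge 3}).
#' @param n_points Points per isotherm (\eqn{\ge 30}).
#' @param pi_range Pressure range c(lo, hi), mN/m.
#' @return A list with data frames `isotherms` (`C_el_M, S_A2, pi_mN_m`),
#'   `spreading` (`C_el_M, pi_sp_mN_m`) and `oracle`
#'   (`C_el_M, S_A2, dGamma_el_oracle_umol_m2`).
#' @export
generate_dataset <- function(fm, C_grid = c(0.05, 0.6, 2.0), n_points = 200,
                             pi_range = c(1, 50)) {
  stopifnot(inherits(fm, "forward_model"))
  if (length(C_grid) < 3L) stop("need at least 3 concentrations", call. = FALSE)
  if (anyDuplicated(C_grid)) stop("duplicate concentrations", call. = FALSE)
  if (n_points < 30L) stop("need at least 30 points per isotherm", call. = FALSE)
  stopifnot(length(pi_range) == 2L, pi_range[1] > 0, pi_range[2] > pi_range[1])

  pi_pts <- exp(seq(log(pi_range[1]), log(pi_range[2]), length.out = n_points))
  rows <- lapply(sort(C_grid), function(C) {
    st <- tryCatch(
      forward_surface_state(fm, fm_mu_s_at_pi(fm, pi_pts, C), C),
      error = function(e) stop(sprintf(
        "pressure range [%g, %g] mN/m unreachable at C_el = %g M: %s",
        pi_range[1], pi_range[2], C, conditionMessage(e)), call. = FALSE))
    data.frame(C_el_M = C, S_A2 = st$S, pi_mN_m = st$pi,
               dGamma = st$dGamma_el)
  })
  all <- do.call(rbind, rows)
  list(
    isotherms = data.frame(C_el_M = all$C_el_M, S_A2 = all$S_A2,
                           pi_mN_m = all$pi_mN_m),
    spreading = data.frame(C_el_M = sort(C_grid),
                           pi_sp_mN_m = fm_spreading_pressure(fm, sort(C_grid))),
    oracle = data.frame(C_el_M = all$C_el_M, S_A2 = all$S_A2,
                        dGamma_el_oracle_umol_m2 = all$dGamma)
  )
}

#' Add seeded Gaussian noise to isotherm pressures
#'
#' Reproducible measurement noise on the `pi_mN_m` column, at the scatter
#' typical of Wilhelmy-plate tensiometry (~0.3 mN/m standard error).
#' Pressures are floored at 0.  The caller's random-number state is left
#' untouched.
#'
#' @param rows Data frame with a `pi_mN_m` column (e.g.
#'   `generate_dataset()$isotherms`).
#' @param sigma_noise Noise standard deviation, mN/m (default 0.3).
#' @param seed Integer seed.
#' @return `rows` with perturbed `pi_mN_m`.
#' @export
add_noise <- function(rows, sigma_noise = 0.3, seed) {
  stopifnot(is.data.frame(rows), "pi_mN_m" %in% names(rows), sigma_noise >= 0)
  if (sigma_noise == 0) return(rows)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  rows$pi_mN_m <- pmax(rows$pi_mN_m + stats::rnorm(nrow(rows), 0, sigma_noise), 0)
  rows
}

#' Gibbs-Duhem self-test of the forward model
#'
#' Before the generator is trusted as an oracle it must prove its own
#' thermodynamic consistency: centered finite differences of
#' \eqn{\sigma(\mu_s,\mu_{el})} must reproduce the analytic fields,
#' \eqn{-\partial\sigma/\partial\mu_s = \Gamma_s} and
#' \eqn{(\partial\pi/\partial\mu_{el})_{\mu_s} = \nu\,\Delta\Gamma_{el}}.
#'
#' @param fm A [forward_model()].
#' @param mu_s Chemical potential at which to test, kJ/mol.
#' @param C_el Concentration at which to test, mol/L (> 0).
#' @param rel_step Finite-difference step as a fraction of RT (default 1e-4).
#' @return Named numeric vector of relative errors,
#'   `c(gamma_s = ..., electrolyte_coupling = ...)`.
#' @export
gibbs_duhem_check <- function(fm, mu_s, C_el, rel_step = 1e-4) {
  stopifnot(inherits(fm, "forward_model"), C_el > 0)
  RT <- fp_constants$R * fm$temperature
  h <- rel_step * RT                                    # J/mol
  st <- forward_surface_state(fm, mu_s, C_el)

  # -d(sigma)/d(mu_s) at fixed mu_el, in mol/m^2
  sig <- function(m) forward_surface_state(fm, m, C_el)$sigma
  dsig_dmus <- (sig(mu_s + h / 1e3) - sig(mu_s - h / 1e3)) / (2 * h) * 1e-3
  gamma_num <- -dsig_dmus * 1e6                         # umol/m^2
  err_gamma <- abs(gamma_num - st$Gamma_s) / st$Gamma_s

  # d(pi)/d(mu_el) at fixed mu_s: perturb mu_el via C = exp(mu/RT)
  mu_el <- fm_mu_el(fm, C_el)
  pi_at <- function(mu) forward_surface_state(fm, mu_s, exp(mu / RT))$pi
  dpi_dmuel <- (pi_at(mu_el + h) - pi_at(mu_el - h)) / (2 * h) * 1e-3  # N/m per J/mol
  coupling_num <- dpi_dmuel * 1e6                       # umol/m^2
  coupling_ana <- fm$nu * st$dGamma_el
  err_coupling <- if (coupling_ana == 0) abs(coupling_num) else
    abs(coupling_num - coupling_ana) / abs(coupling_ana)

  c(gamma_s = err_gamma, electrolyte_coupling = err_coupling)
}
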