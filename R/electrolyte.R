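# Bulk electrolyte thermodynamics: activities, chemical-potential
# differences, clean-surface tension, and the monolayer-free (baseline)
# electrolyte adsorption obtained from the Gibbs isotherm of the bare
# solution surface.

#' Define an electrolyte subphase
#'
#' Bundles the properties of the aqueous electrolyte subphase needed by the
#' monolayer thermodynamics: the isotonic coefficient \eqn{\nu} (number of
#' osmotically active species per formula unit; 2 for NaCl), a table of mean
#' activity coefficients \eqn{\gamma_{el}(C_{el})}, and a table of
#' clean-surface tensions \eqn{\sigma_0(C_{el})} used to convert between
#' surface tension and surface pressure \eqn{\pi = \sigma_0 - \sigma}.
#'
#' The electrolyte chemical potential is
#' \eqn{\mu_{el} = \mu_{el}^\circ + RT \ln \gamma_{el} C_{el}}, so the
#' molar-scale activity \eqn{a = \gamma_{el} C_{el}} is the natural bulk
#' state variable; both tables are interpolated piecewise linearly (they are
#' sparse, typically 3-10 points).
#'
#' @param name Electrolyte name (e.g. `"NaCl"`).
#' @param nu Isotonic coefficient \eqn{\nu}, an integer \eqn{\ge 1}.
#' @param temperature Absolute temperature in K (default 298.15).
#' @param activity_table Data frame or two-column matrix with columns
#'   `C` (mol/L, strictly increasing, \eqn{\ge 0}) and `gamma`
#'   (dimensionless, \eqn{> 0}).  `NULL` means ideal behaviour
#'   (\eqn{\gamma \equiv 1}), which is accepted with a warning.
#' @param sigma0_table Data frame or two-column matrix with columns `C`
#'   (mol/L) and `sigma0` (mN/m, \eqn{> 0}): surface tension of the clean
#'   (monolayer-free) solutions.
#'
#' @return An object of class `electrolyte_spec`.
#' @examples
#' nacl <- electrolyte_spec("NaCl", nu = 2,
#'   activity_table = data.frame(C = c(0, 0.6, 2.0), gamma = c(1, 0.673, 0.668)),
#'   sigma0_table  = data.frame(C = c(0, 0.6, 2.0), sigma0 = c(71.97, 72.93, 75.17)))
#' activity(nacl, 0.6)
#' @export
electrolyte_spec <- function(name, nu, temperature = 298.15,
                             activity_table = NULL, sigma0_table = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.numeric(nu) && length(nu) == 1L && nu >= 1 && nu == round(nu)))
    stop("`nu` must be an integer >= 1", call. = FALSE)
  if (!(is.numeric(temperature) && temperature > 0))
    stop("`temperature` must be positive (K)", call. = FALSE)

  if (is.null(activity_table)) {
    warning("no activity-coefficient table supplied; assuming ideal behaviour (gamma = 1)",
            call. = FALSE)
    activity_table <- data.frame(C = c(0, 100), gamma = c(1, 1))
  }
  activity_table <- as.data.frame(activity_table)
  names(activity_table)[1:2] <- c("C", "gamma")
  check_property_table(activity_table$C, activity_table$gamma, "gamma")

  if (!is.null(sigma0_table)) {
    sigma0_table <- as.data.frame(sigma0_table)
    names(sigma0_table)[1:2] <- c("C", "sigma0")
    check_property_table(sigma0_table$C, sigma0_table$sigma0, "sigma0")
  }

  spec <- list(name = name, nu = as.integer(nu), temperature = temperature,
               activity_table = activity_table, sigma0_table = sigma0_table)
  class(spec) <- "electrolyte_spec"
  # activity must be strictly increasing in C (gamma*C monotone on the table)
  a_nodes <- activity_table$gamma * activity_table$C
  if (any(diff(a_nodes) <= 0))
    stop("activity gamma*C must be strictly increasing in C on the table", call. = FALSE)
  spec
}

check_property_table <- function(C, val, what) {
  if (any(!is.finite(C)) || any(!is.finite(val)))
    stop(sprintf("non-finite entries in %s table", what), call. = FALSE)
  if (any(C < 0)) stop(sprintf("%s table: concentrations must be >= 0", what), call. = FALSE)
  if (any(diff(C) <= 0))
    stop(sprintf("%s table: concentrations must be strictly increasing", what), call. = FALSE)
  if (any(val <= 0)) stop(sprintf("%s table: values must be > 0", what), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.electrolyte_spec <- function(x, ...) {
  cat(sprintf("<electrolyte_spec> %s (nu = %d, T = %.2f K)\n",
              x$name, x$nu, x$temperature))
  cat(sprintf("  activity table: %d points on C in [%g, %g] M\n",
              nrow(x$activity_table), min(x$activity_table$C), max(x$activity_table$C)))
  if (!is.null(x$sigma0_table))
    cat(sprintf("  sigma0 table:   %d points on C in [%g, %g] M\n",
                nrow(x$sigma0_table), min(x$sigma0_table$C), max(x$sigma0_table$C)))
  invisible(x)
}

#' Electrolyte activity a = gamma * C
#'
#' Molar-scale activity with the activity coefficient linearly interpolated
#' on the spec's table.  `activity(spec, 0)` is exactly 0.
#'
#' @param spec An [electrolyte_spec()].
#' @param C_el Concentration(s), mol/L, within the tabulated range.
#' @return Activity (mol/L scale), same length as `C_el`.
#' @export
activity <- function(spec, C_el) {
  stopifnot(inherits(spec, "electrolyte_spec"))
  if (any(C_el < 0)) stop("concentration must be >= 0", call. = FALSE)
  gamma <- interp_table(spec$activity_table$C, spec$activity_table$gamma,
                        C_el, "activity coefficient")
  gamma * C_el
}

#' Electrolyte chemical-potential difference
#'
#' \eqn{\Delta\mu_{el} = RT \ln(a_{to}/a_{from})} between two bulk
#' concentrations, in J/mol.  Antisymmetric under argument exchange and
#' additive along concentration paths.
#'
#' @inheritParams activity
#' @param C_from,C_to Concentrations, mol/L, both strictly positive (the
#'   logarithm diverges at zero concentration; differentiate in the activity
#'   variable instead when a pure-water state is involved).
#' @return \eqn{\Delta\mu_{el}} in J/mol.
#' @export
mu_el_difference <- function(spec, C_from, C_to) {
  stopifnot(inherits(spec, "electrolyte_spec"))
  if (any(C_from <= 0) || any(C_to <= 0))
    stop(paste("chemical-potential differences require strictly positive",
               "concentrations; for states involving pure water differentiate",
               "in the activity variable (see spreading_point_adsorption)"),
         call. = FALSE)
  RT <- fp_constants$R * spec$temperature
  RT * log(activity(spec, C_to) / activity(spec, C_from))
}

#' Clean-surface tension sigma_0(C)
#'
#' Surface tension of the monolayer-free electrolyte solution, linearly
#' interpolated on the spec's table; used to convert surface pressure to
#' tension, \eqn{\sigma = \sigma_0 - \pi}.
#'
#' @inheritParams activity
#' @return \eqn{\sigma_0} in mN/m.
#' @export
sigma0 <- function(spec, C_el) {
  stopifnot(inherits(spec, "electrolyte_spec"))
  if (is.null(spec$sigma0_table))
    stop("spec has no sigma0 table", call. = FALSE)
  interp_table(spec$sigma0_table$C, spec$sigma0_table$sigma0,
               C_el, "clean-surface tension")
}

#' Monolayer-free electrolyte adsorption
#'
#' Baseline surface excess of the electrolyte on the bare solution|air
#' interface, from the two-component Gibbs isotherm:
#' \deqn{\Gamma_{el}(0) = -\frac{a}{\nu RT}\,\frac{d\sigma_0}{da}.}
#' The slope is evaluated by the three-point Lagrange formula on the
#' activity nodes of the \eqn{\sigma_0} table nearest to `C_el`.  Negative
#' for salting-out electrolytes such as NaCl (tension increases with
#' concentration).
#'
#' @inheritParams activity
#' @param C_el A single concentration, mol/L, strictly inside the table range.
#' @return \eqn{\Gamma_{el}(0)} in \eqn{\mu}mol/m^2.
#' @export
baseline_adsorption <- function(spec, C_el) {
  stopifnot(inherits(spec, "electrolyte_spec"), length(C_el) == 1L)
  if (is.null(spec$sigma0_table))
    stop("spec has no sigma0 table", call. = FALSE)
  tab <- spec$sigma0_table
  if (nrow(tab) < 3L)
    stop("baseline adsorption needs at least 3 sigma0 table points", call. = FALSE)
  if (C_el <= min(tab$C) || C_el > max(tab$C))
    stop("C_el must lie strictly inside the sigma0 table range (and be > 0)",
         call. = FALSE)
  a_nodes <- activity(spec, tab$C)
  a0 <- activity(spec, C_el)
  # centre the 3-point stencil on the node interval containing C_el
  j <- findInterval(C_el, tab$C, rightmost.closed = TRUE)
  lo <- min(max(j - 1L, 1L), nrow(tab) - 2L)
  idx <- lo:(lo + 2L)
  dsig_da <- lagrange3_deriv(a_nodes[idx], tab$sigma0[idx], a0)  # mN/m per M
  RT <- fp_constants$R * spec$temperature
  # mN/m -> N/m (1e-3), mol/m^2 -> umol/m^2 (1e6)
  -(a0 / (spec$nu * RT)) * dsig_da * 1e3
}
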