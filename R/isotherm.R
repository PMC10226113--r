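# Experimental data objects: compression isotherms (pi vs area per
# molecule at one subphase concentration) and equilibrium spreading points.

#' Construct and validate a compression isotherm
#'
#' One surface-pressure / area-per-molecule table \eqn{\pi(S)} measured at a
#' fixed electrolyte concentration and temperature.  Points are stored in
#' compression order (decreasing \eqn{S}); along compression \eqn{\pi} must
#' be non-decreasing up to a small tolerance (LE-LC coexistence plateaus are
#' allowed; genuine decreases indicate collapse or bad data and are
#' rejected).  The lipid surface density is \eqn{\Gamma_s = 1/S}.
#'
#' @param C_el Electrolyte concentration of the subphase, mol/L.
#' @param S Areas per molecule, \eqn{\mathrm{\AA}^2}/molecule, all positive.
#' @param pi Surface pressures, mN/m, all \eqn{\ge 0}.
#' @param temperature Temperature, K.
#' @param decrease_tol Largest tolerated decrease of \eqn{\pi} along
#'   compression, mN/m (default 0.05).  Raw noisy traces can be admitted
#'   with a larger tolerance and then regularized with [smooth_isotherm()].
#' @return An object of class `compression_isotherm`: a data frame with
#'   columns `S`, `pi` sorted by decreasing `S`, with attributes `C_el` and
#'   `temperature`.
#' @seealso [smooth_isotherm()], [chem_potential_curve()]
#' @export
compression_isotherm <- function(C_el, S, pi, temperature = 298.15,
                                 decrease_tol = 0.05) {
  stopifnot(length(C_el) == 1L, length(temperature) == 1L)
  if (C_el < 0) stop("C_el must be >= 0", call. = FALSE)
  if (length(S) != length(pi))
    stop("S and pi must have equal length", call. = FALSE)
  if (length(S) < 8L)
    stop("an isotherm needs at least 8 points", call. = FALSE)
  if (any(!is.finite(S)) || any(!is.finite(pi)))
    stop("non-finite isotherm values", call. = FALSE)
  if (any(S <= 0)) stop("areas per molecule must be positive", call. = FALSE)
  if (any(pi < 0)) stop("surface pressures must be >= 0", call. = FALSE)

  ord <- order(S, decreasing = TRUE)
  S <- S[ord]; pi <- pi[ord]
  if (anyDuplicated(S))
    stop("duplicate areas per molecule in isotherm", call. = FALSE)
  drops <- -diff(pi)                       # positive where pi decreases
  bad <- which(drops > decrease_tol)
  if (length(bad))
    stop(sprintf(
      "pi decreases by %.3f mN/m along compression at row %d (S = %.3f A^2); tolerance %.3f mN/m",
      drops[bad[1]], bad[1] + 1L, S[bad[1] + 1L], decrease_tol), call. = FALSE)

  out <- data.frame(S = S, pi = pi)
  attr(out, "C_el") <- C_el
  attr(out, "temperature") <- temperature
  class(out) <- c("compression_isotherm", "data.frame")
  out
}

#' @export
print.compression_isotherm <- function(x, ...) {
  cat(sprintf(
    "<compression_isotherm> C_el = %g M, T = %.2f K, %d points, S in [%.2f, %.2f] A^2, pi in [%.2f, %.2f] mN/m\n",
    attr(x, "C_el"), attr(x, "temperature"), nrow(x),
    min(x$S), max(x$S), min(x$pi), max(x$pi)))
  invisible(x)
}

#' Monotone (isotonic) smoothing of a noisy isotherm
#'
#' Replaces \eqn{\pi} by its isotonic regression along the compression
#' direction — the closest (least-squares) non-decreasing sequence.  This is
#' the recommended regularization for traces whose scatter exceeds the
#' monotonicity tolerance of [compression_isotherm()]; it preserves genuine
#' plateaus and introduces no parametric shape assumptions.
#'
#' @param iso A `compression_isotherm` (possibly built with a relaxed
#'   `decrease_tol`).
#' @return A `compression_isotherm` with monotone \eqn{\pi}.
#' @export
smooth_isotherm <- function(iso) {
  stopifnot(inherits(iso, "compression_isotherm"))
  # compression order is decreasing S; isoreg needs increasing x
  fit <- stats::isoreg(x = -iso$S, y = iso$pi)
  compression_isotherm(attr(iso, "C_el"), iso$S, pmax(fit$yf, 0),
                       temperature = attr(iso, "temperature"),
                       decrease_tol = 0)
}

#' Equilibrium spreading point
#'
#' The spreading pressure \eqn{\pi_{sp} = \sigma_0 - \sigma_{sp}} of the
#' amphiphile's bulk phase (crystals) in equilibrium with its spread
#' monolayer on a subphase of concentration `C_el`.  Because the electrolyte
#' cannot enter the bulk amphiphile phase, the amphiphile chemical potential
#' at this point is electrolyte independent — the reference state of the
#' whole method.
#'
#' @param C_el Subphase electrolyte concentration, mol/L.
#' @param pi_sp Spreading pressure, mN/m, positive.
#' @param uncertainty Optional standard error of `pi_sp`, mN/m.
#' @return An object of class `spreading_point`.
#' @export
spreading_point <- function(C_el, pi_sp, uncertainty = NA_real_) {
  stopifnot(length(C_el) == 1L, length(pi_sp) == 1L)
  if (C_el < 0) stop("C_el must be >= 0", call. = FALSE)
  if (!is.finite(pi_sp) || pi_sp <= 0)
    stop("pi_sp must be a positive pressure (mN/m)", call. = FALSE)
  structure(list(C_el = C_el, pi_sp = pi_sp, uncertainty = uncertainty),
            class = "spreading_point")
}

#' @export
print.spreading_point <- function(x, ...) {
  cat(sprintf("<spreading_point> C_el = %g M, pi_sp = %.2f mN/m%s\n",
              x$C_el, x$pi_sp,
              if (is.finite(x$uncertainty)) sprintf(" (+/- %.2f)", x$uncertainty) else ""))
  invisible(x)
}
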