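# End-to-end orchestration: validate inputs, integrate each isotherm to a
# chemical-potential curve, run both adsorption routes plus the
# spreading-point estimate, check route consistency, optionally fit the
# complexation/excluded-volume model, and write all results.

#' Configuration for [run_pipeline()]
#'
#' @param isotherm_csv Path to the isotherm CSV (`C_el_M, S_A2, pi_mN_m`).
#' @param spreading_csv Path to the spreading-point CSV
#'   (`C_el_M, pi_sp_mN_m[, err_mN_m]`).
#' @param electrolyte Either an [electrolyte_spec()] or a path to its YAML
#'   config.
#' @param target_C Concentration (mol/L) at which adsorption is reported;
#'   must be present in the isotherm file (a central concentration gives the
#'   most accurate derivative).
#' @param n_grid Grid size for the routes (default 200, minimum 50).
#' @param gap_tolerance Extension tolerance for [chem_potential_curve()],
#'   mN/m.
#' @param routes Which estimates to compute: subset of
#'   `c("constant_mu_s", "constant_pi", "spreading_point")`.
#' @param smooth Apply [smooth_isotherm()] to every isotherm before
#'   inversion (use for noisy traces).
#' @param decrease_tol Monotonicity tolerance when reading isotherms, mN/m.
#' @param consistency_tol PASS threshold for the route-consistency report.
#' @param temperature Temperature, K.
#' @param outdir Output directory (`NULL` = write nothing, return results).
#' @return A `run_config` list.
#' @export
fp_config <- function(isotherm_csv, spreading_csv, electrolyte, target_C,
                      n_grid = 200, gap_tolerance = 2,
                      routes = c("constant_mu_s", "constant_pi", "spreading_point"),
                      smooth = FALSE, decrease_tol = 0.05,
                      consistency_tol = 0.05, temperature = 298.15,
                      outdir = NULL) {
  if (n_grid < 50) stop("n_grid must be >= 50", call. = FALSE)
  routes <- match.arg(routes,
                      c("constant_mu_s", "constant_pi", "spreading_point"),
                      several.ok = TRUE)
  structure(list(isotherm_csv = isotherm_csv, spreading_csv = spreading_csv,
                 electrolyte = electrolyte, target_C = target_C,
                 n_grid = n_grid, gap_tolerance = gap_tolerance,
                 routes = routes, smooth = smooth, decrease_tol = decrease_tol,
                 consistency_tol = consistency_tol, temperature = temperature,
                 outdir = outdir),
            class = "run_config")
}

#' Run the full adsorption pipeline
#'
#' Reads and validates the inputs, anchors every isotherm at its spreading
#' point ([chem_potential_curve()]), computes the requested adsorption
#' estimates at `target_C`, reports route consistency when both routes were
#' requested, and (if `outdir` is set) writes `chem_potential_curves.csv`,
#' `adsorption_profiles.csv` and `consistency.txt`.  Deterministic given
#' its inputs.
#'
#' @param config A [fp_config()].
#' @return Invisibly, a list with `curves`, `profiles`, `consistency`
#'   (or `NULL`), and `spec`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- if (inherits(config$electrolyte, "electrolyte_spec"))
    config$electrolyte else read_electrolyte(config$electrolyte)
  if (abs(spec$temperature - config$temperature) > 1e-6)
    stop("electrolyte spec temperature differs from run temperature", call. = FALSE)

  isos <- read_isotherms(config$isotherm_csv, temperature = config$temperature,
                         decrease_tol = if (config$smooth) Inf else config$decrease_tol)
  if (config$smooth) isos <- lapply(isos, smooth_isotherm)
  sps <- read_spreading_points(config$spreading_csv)
  C_iso <- vapply(isos, function(x) attr(x, "C_el"), numeric(1))
  C_sp <- vapply(sps, `[[`, numeric(1), "C_el")
  if (!any(abs(C_iso - config$target_C) < 1e-9))
    stop(sprintf("target concentration %g M is not among the isotherms (%s)",
                 config$target_C, paste(C_iso, collapse = ", ")), call. = FALSE)

  message(sprintf("pipeline: %d isotherms (C = %s M), target %g M, n_grid %d",
                  length(isos), paste(C_iso, collapse = ", "),
                  config$target_C, config$n_grid))

  curves <- lapply(isos, function(iso) {
    C <- attr(iso, "C_el")
    k <- which(abs(C_sp - C) < 1e-9)
    if (length(k) != 1L)
      stop(sprintf("no spreading point at C_el = %g M", C), call. = FALSE)
    chem_potential_curve(iso, sps[[k]], gap_tolerance = config$gap_tolerance)
  })

  profiles <- list()
  if ("constant_mu_s" %in% config$routes)
    profiles$constant_mu_s <-
      route_constant_mu(curves, spec, config$target_C, config$n_grid)
  if ("constant_pi" %in% config$routes)
    profiles$constant_pi <-
      route_constant_pi(curves, spec, config$target_C, config$n_grid)
  if ("spreading_point" %in% config$routes) {
    i <- which(abs(C_iso - config$target_C) < 1e-9)
    profiles$spreading_point <-
      spreading_point_adsorption(sps, spec, config$target_C,
                                 S_sp = curves[[i]]$S_sp)
  }

  consistency <- NULL
  if (all(c("constant_mu_s", "constant_pi") %in% names(profiles))) {
    consistency <- consistency_report(profiles$constant_mu_s,
                                      profiles$constant_pi,
                                      tolerance = config$consistency_tol)
    message(utils::capture.output(print(consistency)))
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    curve_df <- do.call(rbind, lapply(curves, function(cv)
      data.frame(C_el_M = cv$C_el, pi_mN_m = cv$grid$pi, S_A2 = cv$grid$S,
                 dmu_s_kJ_mol = cv$grid$dmu)))
    utils::write.csv(curve_df,
                     file.path(config$outdir, "chem_potential_curves.csv"),
                     row.names = FALSE, quote = FALSE)
    write_profiles(profiles,
                   file.path(config$outdir, "adsorption_profiles.csv"))
    if (!is.null(consistency))
      writeLines(utils::capture.output(print(consistency)),
                 file.path(config$outdir, "consistency.txt"))
  }

  invisible(list(curves = curves, profiles = profiles,
                 consistency = consistency, spec = spec))
}
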