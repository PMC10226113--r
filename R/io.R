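# CSV and YAML interfaces.  The CSV dialects match Langmuir-trough export
# conventions: comma-separated, dot decimal, mandatory header, UTF-8.

# Write numerics at full double precision ("%.17g") so that a write/read
# round trip is value-identical.
write_csv_full <- function(df, path) {
  df[] <- lapply(df, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Read compression isotherms from CSV
#'
#' Expects columns `C_el_M, S_A2, pi_mN_m`; one file may hold several
#' concentrations, grouped by `C_el_M`.  Each group is validated as a
#' [compression_isotherm()].
#'
#' @param path CSV file path.
#' @param temperature Temperature of the measurements, K.
#' @param decrease_tol Monotonicity tolerance passed to
#'   [compression_isotherm()], mN/m.
#' @return Named list of `compression_isotherm`s (names are the
#'   concentrations), sorted by concentration.
#' @export
read_isotherms <- function(path, temperature = 298.15, decrease_tol = 0.05) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("C_el_M", "S_A2", "pi_mN_m"), path)
  if (anyDuplicated(df[, c("C_el_M", "S_A2")]))
    stop(sprintf("%s: duplicate (C_el, S) rows", path), call. = FALSE)
  Cs <- sort(unique(df$C_el_M))
  isos <- lapply(Cs, function(C) {
    sub <- df[df$C_el_M == C, ]
    tryCatch(
      compression_isotherm(C, sub$S_A2, sub$pi_mN_m,
                           temperature = temperature,
                           decrease_tol = decrease_tol),
      error = function(e) stop(sprintf("%s (C_el = %g M): %s", path, C,
                                       conditionMessage(e)), call. = FALSE))
  })
  stats::setNames(isos, as.character(Cs))
}

#' Write compression isotherms to CSV
#'
#' @param isotherms List of [compression_isotherm()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_isotherms <- function(isotherms, path) {
  df <- do.call(rbind, lapply(isotherms, function(iso)
    data.frame(C_el_M = attr(iso, "C_el"), S_A2 = iso$S, pi_mN_m = iso$pi)))
  write_csv_full(df, path)
}

#' Read equilibrium spreading points from CSV
#'
#' Expects columns `C_el_M, pi_sp_mN_m` and optionally `err_mN_m`.
#'
#' @param path CSV file path.
#' @return List of [spreading_point()]s sorted by concentration.
#' @export
read_spreading_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("C_el_M", "pi_sp_mN_m"), path)
  if (anyDuplicated(df$C_el_M))
    stop(sprintf("%s: duplicate concentrations", path), call. = FALSE)
  df <- df[order(df$C_el_M), ]
  lapply(seq_len(nrow(df)), function(k)
    spreading_point(df$C_el_M[k], df$pi_sp_mN_m[k],
                    if ("err_mN_m" %in% names(df)) df$err_mN_m[k] else NA_real_))
}

#' Write spreading points to CSV
#'
#' @param sps List of [spreading_point()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spreading_points <- function(sps, path) {
  df <- data.frame(C_el_M = vapply(sps, `[[`, numeric(1), "C_el"),
                   pi_sp_mN_m = vapply(sps, `[[`, numeric(1), "pi_sp"),
                   err_mN_m = vapply(sps, `[[`, numeric(1), "uncertainty"))
  write_csv_full(df, path)
}

#' Read an electrolyte specification from a YAML config
#'
#' Keys: `name`, `nu`, `temperature_K`, `activity_table` (list of
#' `[C_molar, gamma]` pairs), `sigma0_table` (list of
#' `[C_molar, sigma0_mN_per_m]` pairs).
#'
#' @param path YAML file path.
#' @return An [electrolyte_spec()].
#' @export
read_electrolyte <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("name", "nu"))
    if (is.null(cfg[[key]]))
      stop(sprintf("%s: missing key '%s'", path, key), call. = FALSE)
  to_table <- function(x, cols) {
    if (is.null(x)) return(NULL)
    m <- do.call(rbind, lapply(x, as.numeric))
    stats::setNames(as.data.frame(m), cols)
  }
  electrolyte_spec(
    name = cfg$name, nu = cfg$nu,
    temperature = if (is.null(cfg$temperature_K)) 298.15 else cfg$temperature_K,
    activity_table = to_table(cfg$activity_table, c("C", "gamma")),
    sigma0_table = to_table(cfg$sigma0_table, c("C", "sigma0")))
}

#' Write adsorption profiles to CSV
#'
#' Columns `C_el_M, S_A2, Gamma_s_umol_m2, dGamma_el_umol_m2, route,
#' low_accuracy`, rows sorted by route then decreasing area.
#'
#' @param profiles One `adsorption_profile` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "adsorption_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(C_el_M = attr(p, "C_el_target"), S_A2 = p$S,
               Gamma_s_umol_m2 = p$Gamma_s, dGamma_el_umol_m2 = p$dGamma_el,
               route = attr(p, "route"), low_accuracy = p$low_accuracy)))
  df <- df[order(df$route, -df$S_A2), ]
  write_csv_full(df, path)
}
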