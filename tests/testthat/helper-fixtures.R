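# Shared fixtures: an ideal NaCl spec, synthetic dataset -> object builders,
# and the generator's closed-form adsorption oracle.

nacl_ideal_spec <- function(nu = 2, temperature = 298.15, Cmax = 3) {
  electrolyte_spec("NaCl", nu, temperature,
    activity_table = data.frame(C = c(0, Cmax), gamma = c(1, 1)),
    sigma0_table = data.frame(C = c(0, 1, Cmax),
                              sigma0 = 71.97 + 1.6 * c(0, 1, Cmax)))
}

isotherms_from_df <- function(df, temperature = 298.15, decrease_tol = 0.05) {
  Cs <- sort(unique(df$C_el_M))
  lapply(Cs, function(C) {
    s <- df[df$C_el_M == C, ]
    compression_isotherm(C, s$S_A2, s$pi_mN_m, temperature = temperature,
                         decrease_tol = decrease_tol)
  })
}

sps_from_df <- function(df) {
  df <- df[order(df$C_el_M), ]
  lapply(seq_len(nrow(df)), function(i)
    spreading_point(df$C_el_M[i], df$pi_sp_mN_m[i]))
}

# Exact monolayer-induced adsorption of the forward model at area S
oracle_dgamma <- function(fm, S) {
  Gamma_s <- fp_constants$A2_to_umol_m2 / S
  fm$beta * Gamma_s / fm$nu
}

# Curves for a generated dataset (noise-free path)
synthetic_curves <- function(fm = forward_model(), ...) {
  ds <- generate_dataset(fm, ...)
  isos <- isotherms_from_df(ds$isotherms)
  sps <- sps_from_df(ds$spreading)
  list(curves = Map(chem_potential_curve, isos, sps),
       sps = sps, ds = ds, fm = fm)
}
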