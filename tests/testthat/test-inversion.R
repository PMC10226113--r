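RT_kJ <- fp_constants$R * 298.15 / 1e3
RT_A2 <- fp_constants$R * 298.15 / (fp_constants$mNm_A2_to_kJ_mol * 1e3)  # mN/m * A^2

ideal_gas_isotherm <- function(C = 0.6, n = 200, pi_range = c(1, 50)) {
  pi <- exp(seq(log(pi_range[1]), log(pi_range[2]), length.out = n))
  compression_isotherm(C, S = RT_A2 / pi, pi = pi)
}

test_that("2D ideal-gas isotherm reproduces Delta mu_s = RT ln(pi/pi_sp)", {
  iso <- ideal_gas_isotherm()
  cv <- chem_potential_curve(iso, spreading_point(0.6, 44.1))
  q <- seq(1, 44, length.out = 400)
  got <- fpmono:::curve_at_pi(cv, q)$dmu
  want <- RT_kJ * log(q / 44.1)
  expect_lt(max(abs(got - want) / abs(want)), 1e-3)
  # anchor: exactly zero at the spreading pressure
  expect_equal(fpmono:::curve_at_pi(cv, 44.1)$dmu, 0, tolerance = 1e-5)
  expect_equal(fpmono:::curve_at_pi(cv, 20)$dmu, RT_kJ * log(20 / 44.1),
               tolerance = 1e-3 * abs(RT_kJ * log(20 / 44.1)))
  # below the spreading pressure the chemical potential is negative
  expect_true(all(fpmono:::curve_at_pi(cv, c(5, 20, 40))$dmu < 0))
})

test_that("chemical potential is monotone in pi and matches the generator analytically", {
  fx <- synthetic_curves()
  for (cv in fx$curves) expect_true(all(diff(cv$grid$dmu) >= -1e-12))
  # generator oracle: Delta mu_s = mu_s(pi) - mu_s_sp, closed form
  fm <- fx$fm
  cv <- fx$curves[[2]]
  q <- seq(2, 45, length.out = 50)
  want <- fpmono:::fm_mu_s_at_pi(fm, q, cv$C_el) - fm$mu_s_sp
  got <- fpmono:::curve_at_pi(cv, q)$dmu
  expect_lt(max(abs(got - want) / pmax(abs(want), 1e-6)), 1e-3)
})

test_that("anchoring fails loudly when the isotherm stops short of pi_sp", {
  iso <- ideal_gas_isotherm(pi_range = c(1, 40))
  expect_error(chem_potential_curve(iso, spreading_point(0.6, 44.1)), "short")
  # within the gap tolerance: linear extension with a warning
  expect_warning(
    cv <- chem_potential_curve(iso, spreading_point(0.6, 41.5)),
    "extended")
  expect_equal(max(cv$grid$pi), 41.5, tolerance = 1e-6)
})

test_that("a piecewise-linear isotherm with an LE-LC plateau integrates exactly", {
  # pi(S): 10 -> 20 on S 120 -> 80, plateau at 20 on S 80 -> 60, 20 -> 50 on S 60 -> 30
  S <- seq(120, 30, by = -1)
  pi <- ifelse(S >= 80, 10 + 0.25 * (120 - S),
        ifelse(S >= 60, 20, 20 + (60 - S)))
  iso <- compression_isotherm(0.6, S, pi)
  cv <- chem_potential_curve(iso, spreading_point(0.6, 45))
  # independent oracle: exact integral of S dpi over the piecewise-linear path
  # from pi_sp = 45 (S = 35): at pi = 30, int = -637.5 mN/m A^2
  expect_equal(fpmono:::curve_at_pi(cv, 30)$dmu,
               -637.5 * fp_constants$mNm_A2_to_kJ_mol, tolerance = 5e-3)
  # crossing the plateau (which contributes zero): at pi = 15, int = -1637.5
  expect_equal(fpmono:::curve_at_pi(cv, 15)$dmu,
               -1637.5 * fp_constants$mNm_A2_to_kJ_mol, tolerance = 5e-3)
  expect_equal(cv$S_sp, 35, tolerance = 0.1)
  # inverse lookup at the plateau pressure: first contact = largest S
  expect_equal(fpmono:::curve_at_pi(cv, 20)$S, 80, tolerance = 1)
})

test_that("identical curves at different concentrations give zero adsorption", {
  spec <- nacl_ideal_spec()
  iso_pts <- ideal_gas_isotherm()
  curves <- lapply(c(0.05, 0.6, 2.0), function(C) {
    iso <- compression_isotherm(C, iso_pts$S, iso_pts$pi)
    chem_potential_curve(iso, spreading_point(C, 44.1))
  })
  pm <- route_constant_mu(curves, spec, 0.6)
  pp <- route_constant_pi(curves, spec, 0.6)
  expect_lt(max(abs(pm$dGamma_el)), 1e-6)
  expect_lt(max(abs(pp$dGamma_el)), 1e-6)
})

test_that("both routes recover the synthetic oracle and halve when nu doubles", {
  fx <- synthetic_curves()
  spec2 <- nacl_ideal_spec(nu = 2)
  pm <- route_constant_mu(fx$curves, spec2, 0.6)
  pp <- route_constant_pi(fx$curves, spec2, 0.6)
  expect_false(any(pm$low_accuracy))
  em <- abs(pm$dGamma_el - oracle_dgamma(fx$fm, pm$S)) / oracle_dgamma(fx$fm, pm$S)
  ep <- abs(pp$dGamma_el - oracle_dgamma(fx$fm, pp$S)) / oracle_dgamma(fx$fm, pp$S)
  expect_lt(max(em), 0.02)
  expect_lt(max(ep), 0.02)
  # Gamma_s column is 1/S in conventional units
  expect_equal(pm$Gamma_s, fp_constants$A2_to_umol_m2 / pm$S, tolerance = 1e-12)
  # rows sorted by decreasing S
  expect_true(all(diff(pm$S) < 0))
  # 1/nu prefactor
  spec4 <- nacl_ideal_spec(nu = 4)
  pm4 <- route_constant_mu(fx$curves, spec4, 0.6)
  expect_equal(pm4$dGamma_el, pm$dGamma_el / 2, tolerance = 1e-10)
})

test_that("downsampled isotherms (30 points) still recover the oracle within 5%", {
  fx <- synthetic_curves(n_points = 30)
  spec <- nacl_ideal_spec()
  for (p in list(route_constant_mu(fx$curves, spec, 0.6),
                 route_constant_pi(fx$curves, spec, 0.6))) {
    err <- abs(p$dGamma_el - oracle_dgamma(fx$fm, p$S)) / oracle_dgamma(fx$fm, p$S)
    expect_lt(max(err), 0.05)
  }
})

test_that("a terminal target concentration uses a one-sided stencil and is flagged", {
  fx <- synthetic_curves()
  spec <- nacl_ideal_spec()
  edge <- route_constant_mu(fx$curves, spec, 0.05)
  expect_true(all(edge$low_accuracy))
  central <- route_constant_mu(fx$curves, spec, 0.6)
  # central-point accuracy is far better than the terminal one
  err_edge <- abs(edge$dGamma_el - oracle_dgamma(fx$fm, edge$S)) /
    oracle_dgamma(fx$fm, edge$S)
  err_central <- abs(central$dGamma_el - oracle_dgamma(fx$fm, central$S)) /
    oracle_dgamma(fx$fm, central$S)
  expect_gt(stats::median(err_edge), stats::median(err_central))
})

test_that("curve-family preconditions are enforced", {
  fx <- synthetic_curves()
  spec <- nacl_ideal_spec()
  expect_error(route_constant_mu(fx$curves[1:2], spec, 0.6), ">= 3")
  expect_error(route_constant_mu(fx$curves, spec, 1.0), "not in the curve family")
  spec_hot <- nacl_ideal_spec(temperature = 310)
  expect_error(route_constant_mu(fx$curves, spec_hot, 0.6), "temperature")
})

test_that("spreading-point estimate matches the hand-computed Lagrange derivative", {
  spec <- nacl_ideal_spec()
  sps <- list(spreading_point(0, 44.1), spreading_point(0.6, 46.5),
              spreading_point(2.0, 47.0))
  est <- spreading_point_adsorption(sps, spec, 0.6)
  # hand evaluation: dpi_sp/da|_{0.6} = -7/6*44.1 + 20/21*46.5 + 3/14*47.0
  slope <- -7 / 6 * 44.1 + 20 / 21 * 46.5 + 3 / 14 * 47.0          # mN/m per M
  expect_equal(est$dGamma_el,
               0.6 * slope * 1e-3 / (2 * fp_constants$R * 298.15) * 1e6,
               tolerance = 1e-10)
  expect_equal(est$dGamma_el, 0.351815, tolerance = 1e-5)
  expect_gt(est$dGamma_el, 0)          # electrolyte stabilizes the monolayer
  expect_equal(nrow(est), 1L)
  # reversing the concentration trend flips the sign
  rev_sps <- list(spreading_point(0, 47.0), spreading_point(0.6, 44.6),
                  spreading_point(2.0, 44.1))
  expect_lt(spreading_point_adsorption(rev_sps, spec, 0.6)$dGamma_el, 0)
  # constant pi_sp: zero
  flat <- lapply(c(0, 0.6, 2.0), spreading_point, pi_sp = 45)
  expect_equal(spreading_point_adsorption(flat, spec, 0.6)$dGamma_el, 0)
  expect_error(spreading_point_adsorption(sps[1:2], spec, 0.6), ">= 3")
  dup <- c(sps, list(spreading_point(0.6, 46.0)))
  expect_error(spreading_point_adsorption(dup, spec, 0.6), "duplicate")
})

test_that("higher salt lowers the chemical potential at fixed pi when pi_sp rises", {
  fx <- synthetic_curves()
  dmu_at_30 <- vapply(fx$curves, function(cv) fpmono:::curve_at_pi(cv, 30)$dmu,
                      numeric(1))
  pi_sp <- vapply(fx$sps, `[[`, numeric(1), "pi_sp")
  expect_true(all(diff(pi_sp) > 0))
  expect_true(all(diff(dmu_at_30) < 0))
})

test_that("consistency report measures relative deviation and flags failure", {
  fx <- synthetic_curves()
  spec <- nacl_ideal_spec()
  pm <- route_constant_mu(fx$curves, spec, 0.6)
  pp <- route_constant_pi(fx$curves, spec, 0.6)
  self <- consistency_report(pm, pm)
  expect_equal(self$max_rel_dev, 0)
  expect_true(self$pass)
  both <- consistency_report(pm, pp)
  expect_lt(both$max_rel_dev, 0.01)
  expect_true(both$pass)
  scaled <- pm
  scaled$dGamma_el <- 1.2 * scaled$dGamma_el
  rep12 <- consistency_report(pm, scaled)
  expect_equal(rep12$max_rel_dev, 0.2 / 1.1, tolerance = 1e-9)
  expect_false(rep12$pass)
  expect_error(consistency_report(pm, route_constant_mu(fx$curves, spec, 2.0)),
               "different target")
})
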