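test_that("forward model reproduces its own limits", {
  fm <- forward_model()
  RT <- fp_constants$R * fm$temperature
  # half-saturation: b e^{mu_s/RT} = 1  =>  Gamma_s = Gamma_inf / 2
  b <- fm$b0 * 0.6^fm$beta
  st <- forward_surface_state(fm, -RT * log(b) / 1e3, 0.6)
  expect_equal(st$Gamma_s, fm$Gamma_inf / 2, tolerance = 1e-10)
  # dilute limit: pi -> Gamma_s RT (2D ideal gas) at theta = 1e-3
  mu_dilute <- RT * (log(1e-3 / (1 - 1e-3)) - log(b)) / 1e3
  st2 <- forward_surface_state(fm, mu_dilute, 0.6)
  pi_ideal <- st2$Gamma_s * 1e-6 * RT * 1e3   # mN/m
  expect_equal(st2$pi / pi_ideal, 1, tolerance = 1e-3)
  # decoupled electrolyte: no induced adsorption anywhere
  fm0 <- forward_model(beta = 0)
  st0 <- forward_surface_state(fm0, seq(-5, 12, by = 1), 0.6)
  expect_true(all(st0$dGamma_el == 0))
})

test_that("generator proves its own Gibbs-Duhem consistency", {
  for (fm in list(forward_model(), forward_model(beta = 0.3, Gamma_inf = 2.5),
                  forward_model(beta = 0))) {
    for (state in list(c(5, 0.6), c(11.3, 2.0), c(-2, 0.05))) {
      errs <- gibbs_duhem_check(fm, state[1], state[2])
      expect_lt(errs[["gamma_s"]], 1e-6)
      expect_lt(errs[["electrolyte_coupling"]], 1e-6)
    }
  }
})

test_that("generated datasets cover the requested range with consistent bookkeeping", {
  fm <- forward_model()
  ds <- generate_dataset(fm, C_grid = c(0.05, 0.6, 2.0), n_points = 50)
  expect_equal(nrow(ds$oracle), 3 * 50)
  expect_equal(nrow(ds$spreading), 3)
  for (C in c(0.05, 0.6, 2.0)) {
    sub <- ds$isotherms[ds$isotherms$C_el_M == C, ]
    expect_equal(range(sub$pi_mN_m), c(1, 50), tolerance = 1e-9)
  }
  # coupled electrolyte: spreading pressure strictly increases with C
  expect_true(all(diff(ds$spreading$pi_sp_mN_m) > 0))
  # unreachable pressure range names the concentration
  expect_error(generate_dataset(fm, pi_range = c(1, 800)), "unreachable")
  expect_error(generate_dataset(fm, C_grid = c(0.6, 2.0)), "3")
})

test_that("a decoupled electrolyte produces a null dataset", {
  ds0 <- generate_dataset(forward_model(beta = 0))
  split0 <- split(ds0$isotherms[c("S_A2", "pi_mN_m")], ds0$isotherms$C_el_M)
  expect_identical(split0[[1]]$S_A2, split0[[2]]$S_A2)
  expect_identical(split0[[1]]$pi_mN_m, split0[[3]]$pi_mN_m)
  expect_equal(diff(range(ds0$spreading$pi_sp_mN_m)), 0)
  expect_true(all(ds0$oracle$dGamma_el_oracle_umol_m2 == 0))
})

test_that("noise injection is seeded, floored and at the right scale", {
  ds <- generate_dataset(forward_model())
  clean <- ds$isotherms
  expect_identical(add_noise(clean, 0, seed = 1), clean)
  n1 <- add_noise(clean, 0.3, seed = 42)
  n2 <- add_noise(clean, 0.3, seed = 42)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_noise(clean, 0.3, seed = 43)))
  expect_true(all(n1$pi_mN_m >= 0))
  # law of large numbers: sample sd of the perturbation ~ 0.3 over 1e4 rows
  big <- data.frame(pi_mN_m = rep(25, 1e4))
  noisy <- add_noise(big, 0.3, seed = 7)
  expect_equal(stats::sd(noisy$pi_mN_m - big$pi_mN_m), 0.3, tolerance = 0.05)
  # caller RNG state is not disturbed
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(add_noise(clean, 0.3, seed = 5)); after <- rnorm(1)
  expect_identical(before, after)
})
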