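test_that("activity interpolates the coefficient table and vanishes at C = 0", {
  spec <- electrolyte_spec("NaCl", 2,
    activity_table = data.frame(C = c(0, 0.5, 1.0), gamma = c(1, 0.68, 0.66)),
    sigma0_table = data.frame(C = c(0, 1), sigma0 = c(71.97, 73.6)))
  expect_equal(activity(spec, 0), 0)
  # hand linear interpolation: gamma(0.75) = 0.67, a = 0.75 * 0.67
  expect_equal(activity(spec, 0.75), 0.5025, tolerance = 1e-12)
  ideal <- nacl_ideal_spec()
  expect_equal(activity(ideal, 0.6), 0.6)
  expect_error(activity(spec, 2), "range")
})

test_that("chemical-potential differences are antisymmetric, additive and match RT ln", {
  spec <- nacl_ideal_spec()
  RT <- fp_constants$R * 298.15
  expect_equal(mu_el_difference(spec, 0.6, 0.6), 0)
  expect_equal(mu_el_difference(spec, 0.6, 2.0), RT * log(10 / 3), tolerance = 1e-12)
  expect_equal(mu_el_difference(spec, 0.6, 2.0), 2.98e3, tolerance = 3e-3)
  expect_equal(mu_el_difference(spec, 2.0, 0.6), -mu_el_difference(spec, 0.6, 2.0))
  # path additivity A -> B -> C == A -> C
  expect_equal(
    mu_el_difference(spec, 0.1, 0.7) + mu_el_difference(spec, 0.7, 2.5),
    mu_el_difference(spec, 0.1, 2.5), tolerance = 1e-12)
  expect_error(mu_el_difference(spec, 0, 1), "activity")
})

test_that("clean-surface tension interpolates its table with range errors", {
  spec <- electrolyte_spec("NaCl", 2,
    activity_table = data.frame(C = c(0, 3), gamma = c(1, 1)),
    sigma0_table = data.frame(C = c(0, 2.0), sigma0 = c(71.97, 75.2)))
  expect_equal(sigma0(spec, 0), 71.97)
  expect_equal(sigma0(spec, 1.0), 73.585, tolerance = 1e-12)
  expect_error(sigma0(spec, 3.0), "range")
})

test_that("table interpolants do not overshoot between nodes", {
  spec <- electrolyte_spec("NaCl", 2,
    activity_table = data.frame(C = c(0, 0.3, 0.9, 2.1), gamma = c(1, 0.71, 0.66, 0.67)),
    sigma0_table = data.frame(C = c(0, 0.5, 1.4, 2.1), sigma0 = c(71.97, 72.8, 74.1, 75.4)))
  set.seed(11)
  Cq <- runif(200, 0, 2.1)
  g <- activity(spec, Cq) / ifelse(Cq == 0, 1, Cq)
  expect_true(all(g[Cq > 0] <= max(spec$activity_table$gamma) + 1e-12))
  expect_true(all(g[Cq > 0] >= min(spec$activity_table$gamma) - 1e-12))
  s <- sigma0(spec, Cq)
  expect_true(all(s >= 71.97 - 1e-12 & s <= 75.4 + 1e-12))
  expect_true(all(diff(sigma0(spec, sort(Cq))) >= -1e-12))
})

test_that("baseline adsorption matches the closed-form Gibbs slope and scales as 1/nu", {
  # sigma0 linear in a with slope +1.6 mN/m per M, gamma = 1
  spec2 <- nacl_ideal_spec(nu = 2)
  expected <- -(1.0 / (2 * fp_constants$R * 298.15)) * 1.6e-3 * 1e6  # umol/m^2
  expect_equal(baseline_adsorption(spec2, 1.0), expected, tolerance = 1e-10)
  expect_lt(baseline_adsorption(spec2, 1.0), 0)   # salting-out: negative excess
  expect_equal(baseline_adsorption(spec2, 1.0), -0.32, tolerance = 0.01)
  spec4 <- nacl_ideal_spec(nu = 4)
  expect_equal(baseline_adsorption(spec4, 1.0),
               baseline_adsorption(spec2, 1.0) / 2, tolerance = 1e-12)
  # constant tension: no excess
  flat <- electrolyte_spec("X", 2,
    activity_table = data.frame(C = c(0, 3), gamma = c(1, 1)),
    sigma0_table = data.frame(C = c(0, 1, 3), sigma0 = c(72, 72, 72)))
  expect_equal(baseline_adsorption(flat, 1.0), 0)
  # sign equals -sign(dsigma0/dC)
  falling <- electrolyte_spec("Y", 2,
    activity_table = data.frame(C = c(0, 3), gamma = c(1, 1)),
    sigma0_table = data.frame(C = c(0, 1, 3), sigma0 = c(72, 71, 69)))
  expect_gt(baseline_adsorption(falling, 1.0), 0)
  few <- electrolyte_spec("Z", 2,
    activity_table = data.frame(C = c(0, 3), gamma = c(1, 1)),
    sigma0_table = data.frame(C = c(0, 2), sigma0 = c(72, 75)))
  expect_error(baseline_adsorption(few, 1.0), "3")
})

test_that("spec construction enforces table invariants", {
  expect_error(electrolyte_spec("NaCl", 0.5), "nu")
  expect_error(electrolyte_spec("NaCl", 2,
    activity_table = data.frame(C = c(0.5, 0.2), gamma = c(1, 1))), "increasing")
  expect_error(electrolyte_spec("NaCl", 2,
    activity_table = data.frame(C = c(0, 1), gamma = c(1, -0.5))), "> 0")
  expect_warning(electrolyte_spec("NaCl", 2), "ideal")
})
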