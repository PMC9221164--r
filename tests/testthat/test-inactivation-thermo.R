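test_that("noiseless exponential decay recovers kd exactly", {
  t <- c(5, 10, 15, 20)
  d <- tibble::tibble(time_min = t, residual_fraction = exp(-0.028 * t))
  fit <- fit_inactivation(d, temp_K = 333)
  expect_equal(fit$kd, 0.028, tolerance = 1e-12)
  expect_equal(fit$half_life, log(2) / 0.028, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
})

test_that("through-origin slope equals the analytic formula and a free intercept vanishes on anchored data", {
  set.seed(42)
  t <- c(5, 10, 20, 40, 80)
  f <- exp(-0.01 * t) * (1 + rnorm(5, 0, 0.02))
  d <- tibble::tibble(time_min = t, residual_fraction = f)

  fit <- fit_inactivation(d)
  expect_equal(fit$kd, -sum(t * log(f)) / sum(t^2), tolerance = 1e-12)

  # with the decay truly anchored at the origin, the free-intercept variant
  # estimates a near-zero intercept and a compatible slope
  fit_free <- fit_inactivation(d, intercept = TRUE)
  expect_lt(abs(fit_free$intercept), 0.05)
  expect_equal(fit_free$kd, fit$kd, tolerance = 0.01)
})

test_that("assay-floor samples are excluded and counted, not clamped into the fit", {
  d <- tibble::tibble(time_min = c(5, 10, 15, 30, 60),
                      residual_fraction = c(exp(-0.1 * c(5, 10, 15)), 0, 0))
  fit <- fit_inactivation(d)
  expect_equal(fit$n_points_used, 3L)
  expect_equal(fit$n_points_dropped, 2L)
  expect_equal(fit$kd, 0.1, tolerance = 1e-10)
})

test_that("unusable decay courses raise classed errors", {
  all_zero <- tibble::tibble(time_min = c(5, 10), residual_fraction = c(0, 0))
  expect_error(fit_inactivation(all_zero), class = "enzytherm_error_too_few_points")
  single <- tibble::tibble(time_min = c(5, 10), residual_fraction = c(0.5, 0))
  expect_error(fit_inactivation(single), class = "enzytherm_error_too_few_points")
  growing <- tibble::tibble(time_min = c(5, 10), residual_fraction = c(1.2, 1.5))
  expect_error(fit_inactivation(growing), class = "enzytherm_error_degenerate")
})

test_that("half-life and D-value identities hold universally", {
  expect_equal(half_life(2.0e-4), 3466, tolerance = 2e-4)
  expect_equal(half_life(2.2e-3), 315.1, tolerance = 1e-3)
  expect_equal(half_life(log(2)), 1)
  expect_equal(decimal_reduction(2.2e-3), 1046.6, tolerance = 1e-3)
  expect_equal(decimal_reduction(log(10)), 1)

  kds <- 10^runif(50, -5, 1)
  expect_equal(decimal_reduction(kds) / half_life(kds),
               rep(log(10) / log(2), 50), tolerance = 1e-13)
  expect_error(half_life(0), class = "enzytherm_error_bad_input")
  expect_error(decimal_reduction(-1), class = "enzytherm_error_bad_input")
})

test_that("stability decreases monotonically with temperature across panels", {
  tbl <- table5_kd()
  expect_true(all(diff(tbl$kd) > 0))
  expect_true(all(diff(half_life(tbl$kd)) < 0))
  expect_true(all(diff(decimal_reduction(tbl$kd)) < 0))

  panel <- fit_inactivation_panel(gen_decay_panel(ground_truth(noise_cv = 0)))
  expect_true(all(diff(panel$kd) > 0))
  expect_true(all(diff(panel$half_life) < 0))
})

test_that("deactivation energy regression matches closed forms", {
  R <- physical_constants()$R
  two <- tibble::tibble(temp_K = c(313, 353),
                        kd = exp(30 - 100000 / (R * c(313, 353))))
  expect_equal(deactivation_energy(two)$Ea, 100000, tolerance = 1e-6)

  flat <- tibble::tibble(temp_K = c(313, 333, 353), kd = rep(0.01, 3))
  expect_equal(deactivation_energy(flat)$Ea, 0, tolerance = 1e-9)

  oracle <- ols_oracle(1 / table5_kd()$temp_K, log(table5_kd()$kd))
  expect_equal(deactivation_energy(table5_kd())$Ea, -oracle$slope * R,
               tolerance = 1e-10)
})

test_that("deactivation thermodynamics reproduce the printed panel rows", {
  out <- deactivation_params(table5_kd(), Ea_d = ref_ead)

  r313 <- out[out$temp_K == 313, ]
  expect_equal(r313$dG_D / 1000, 109.6, tolerance = 1e-3)
  expect_equal(r313$dH_D / 1000, 192.8, tolerance = 1e-3)
  expect_equal(r313$dS_D, 265.8, tolerance = 1e-3)

  r333 <- out[out$temp_K == 333, ]
  expect_equal(r333$dG_D / 1000, 103.1, tolerance = 1e-3)

  # row identity dG_D = dH_D - T*dS_D within 30 J/mol
  expect_true(all(abs(out$dG_D - (out$dH_D - out$temp_K * out$dS_D)) < 30))

  # Ea_d = R*T zeroes the deactivation enthalpy
  R <- physical_constants()$R
  z <- deactivation_params(tibble::tibble(temp_K = 313, kd = 2e-4),
                           Ea_d = R * 313)
  expect_equal(z$dH_D, 0, tolerance = 1e-9)
})

test_that("non-covalent bond estimate scales the inactivation enthalpy", {
  expect_equal(bonds_broken(192800), 35.70, tolerance = 1e-3)
  expect_equal(bonds_broken(0), 0)
  expect_equal(bonds_broken(5400), 1)
  expect_error(bonds_broken(-1), class = "enzytherm_error_bad_input")
})
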