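test_that("two-point Arrhenius fit is exact and matches the OLS oracle", {
  R <- physical_constants()$R
  d <- tibble::tibble(temp_K = c(313, 333), rate = exp(20 - 40000 / (R * temp_K)))
  fit <- arrhenius_fit(d)
  expect_equal(fit$Ea, 40000, tolerance = 1e-9)
  expect_equal(fit$lnA, 20, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  # five-temperature inactivation panel against a first-principles OLS
  tbl <- table5_kd()
  oracle <- ols_oracle(1 / tbl$temp_K, log(tbl$kd))
  fit5 <- arrhenius_fit(tbl, rate = kd)
  expect_equal(fit5$Ea, -oracle$slope * R, tolerance = 1e-10)
  expect_equal(fit5$Ea / 1000, 195.0, tolerance = 0.005)
})

test_that("constant rates give zero activation energy", {
  d <- tibble::tibble(temp_K = c(303, 313, 323), rate = rep(5, 3))
  fit <- arrhenius_fit(d)
  expect_equal(fit$Ea, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
})

test_that("noiseless Arrhenius data of arbitrary Ea are recovered to 0.01%", {
  R <- physical_constants()$R
  set.seed(11)
  for (ea in c(5000, 39800, 120000, 195400)) {
    tk <- sort(sample(300:360, 5))
    d <- tibble::tibble(temp_K = tk, rate = exp(rnorm(1, 20, 2) - ea / (R * tk)))
    expect_lt(abs(arrhenius_fit(d)$Ea - ea) / ea, 1e-4)
  }
})

test_that("the ascending-limb window and input checks apply", {
  R <- physical_constants()$R
  tk <- c(313, 323, 333, 343)
  rate <- exp(20 - 39800 / (R * tk))
  rate[4] <- rate[4] * 0.2 # post-optimum collapse
  d <- tibble::tibble(temp_K = tk, rate = rate)
  expect_equal(arrhenius_fit(d, t_max = 333)$Ea, 39800, tolerance = 1e-6)
  expect_lt(arrhenius_fit(d)$r_squared, arrhenius_fit(d, t_max = 333)$r_squared)

  expect_error(arrhenius_fit(tibble::tibble(temp_K = 313, rate = 1)),
               class = "enzytherm_error_too_few_points")
  expect_error(arrhenius_fit(tibble::tibble(temp_K = c(313, 333), rate = c(1, 0))),
               class = "enzytherm_error_bad_input")
})

test_that("Q10 follows the temperature-squared Arrhenius form", {
  R <- physical_constants()$R
  expect_equal(q10(39800, 333), exp(10 * 39800 / (R * 333^2)), tolerance = 1e-12)
  expect_equal(round(q10(39800, 333), 1), 1.5)
  expect_equal(q10(0, 313), 1)
  expect_equal(q10(82000, 300), exp(820000 / (R * 90000)), tolerance = 1e-12)
  expect_equal(q10(82000, 300), 2.99, tolerance = 1e-3)
  expect_error(q10(Inf, 300), class = "enzytherm_error_bad_input")
})

test_that("Eyring free energy matches printed deactivation rows and inverts exactly", {
  cc <- physical_constants()
  # minutes -> seconds convention validated by the printed 333 K row
  expect_equal(gibbs_from_rate(2.8e-2, 333, rate_unit = "per_min") / 1000,
               103.1, tolerance = 1e-3)
  # rate equal to the frequency factor kB*T/h has zero barrier
  expect_equal(gibbs_from_rate(cc$kB * 333 / cc$h, 333), 0, tolerance = 1e-9)

  # round trip k -> dG -> k to 1e-10 relative
  for (k in c(1e-6, 4.667e-4, 49, 1e3)) {
    dg <- gibbs_from_rate(k, 333)
    back <- (cc$kB * 333 / cc$h) * exp(-dg / (cc$R * 333))
    expect_lt(abs(back - k) / k, 1e-10)
  }

  # strictly decreasing in the rate at fixed temperature
  ks <- 10^seq(-6, 3)
  expect_true(all(diff(gibbs_from_rate(ks, 333)) < 0))
  expect_error(gibbs_from_rate(0, 333), class = "enzytherm_error_bad_input")
})

test_that("activation parameters reproduce the printed enthalpy and entropy", {
  cc <- physical_constants()
  out <- activation_params(ref_ea, 49, 333, KM = ref_km)
  expect_equal(out$dH / 1000, 37.0, tolerance = 1e-3) # Ea - R*T
  expect_equal(out$Q10, 1.5, tolerance = 0.05)
  # assembled identity dG = dH - T*dS to 1 J/mol
  expect_equal(out$dG, out$dH - 333 * out$dS, tolerance = 1)
  # entropy from the printed enthalpy/free-energy pair
  expect_equal((37000 - 57600) / 333, -61.9, tolerance = 1e-3)
  # Ea = R*T zeroes the enthalpy
  expect_equal(activation_params(cc$R * 333, 49, 333)$dH, 0, tolerance = 1e-9)
})

test_that("binding and transition-state free energies follow their definitions", {
  R <- physical_constants()$R
  expect_equal(binding_free_energy(1, 333), 0)
  expect_equal(binding_free_energy(10, 300), R * 300 * log(10), tolerance = 1e-12)
  expect_equal(binding_free_energy(ref_km, 333) / 1000, 1.86, tolerance = 1e-2)

  expect_equal(transition_free_energy(7, 7, 333), 0)
  expect_equal(transition_free_energy(25, 50, 300), R * 300 * log(2), tolerance = 1e-12)
  expect_equal(transition_free_energy(49, ref_km, 333) / 1000, -8.9, tolerance = 1e-2)
  expect_error(transition_free_energy(-1, 2, 300), class = "enzytherm_error_bad_input")
})

test_that("celsius/kelvin conversion honours the table convention", {
  expect_equal(celsius_to_kelvin(40), 313)
  expect_equal(celsius_to_kelvin(40, offset = 273.15), 313.15)
  expect_equal(kelvin_to_celsius(333), 60)
  expect_error(celsius_to_kelvin(40, offset = 272))
})
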