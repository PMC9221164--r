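# shared fixtures, all built in code

# printed thermostability panel: integer-Kelvin temperatures with the
# per-temperature first-order inactivation rate constants (min^-1)
table5_kd <- function() {
  tibble::tibble(
    temp_K = c(313, 323, 333, 343, 353),
    kd = c(2.0e-4, 2.2e-3, 2.8e-2, 2.7e-1, 7.2e-1)
  )
}

# reference kinetic parameters of the xylanase / oat spelt xylan system
ref_km <- 1.96       # g/L
ref_vmax <- 58.6     # umol/min/mg
ref_mw <- 47890      # g/mol
ref_ea <- 39800      # J/mol
ref_ead <- 195400    # J/mol

mm_hyperbola <- function(s, km = ref_km, vmax = ref_vmax) vmax * s / (km + s)

noiseless_mm <- function(s = c(0.5, 1, 2, 5, 10, 20)) {
  tibble::tibble(substrate = s, rate = mm_hyperbola(s))
}

# independent closed-form OLS (slope/intercept from covariance formulas),
# kept free of lm() so regression code is checked against first principles
ols_oracle <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  list(slope = slope, intercept = (sy - slope * sx) / n)
}
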