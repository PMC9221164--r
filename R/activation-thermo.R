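#' Arrhenius regression of rates on temperature
#'
#' Ordinary least squares of `ln(rate)` on `1/T`. The activation energy is
#' `Ea = -slope * R`. Used both for catalysis (ln vmax vs 1/T, ascending
#' limb of the temperature-activity profile) and for thermal inactivation
#' (ln kd vs 1/T), where the slope is independent of the unit the rate is
#' expressed in.
#'
#' Rates measured above the temperature optimum reflect denaturation rather
#' than activation; restrict the fit to the ascending limb with `t_max`.
#'
#' @param data Data frame with one row per temperature.
#' @param temperature,rate Column names (unquoted) holding absolute
#'   temperature (K) and a positive rate. Defaults `temp_K`, `rate`.
#' @param t_max Optional upper temperature bound (K); points above it are
#'   dropped before fitting.
#' @return An object of class `arrhenius_fit` with elements `Ea` (J mol^-1),
#'   `lnA` (intercept), `r_squared`, `slope`, `n` and the points used.
#' @examples
#' d <- tibble::tibble(temp_K = c(303, 313, 323, 333),
#'                     rate = exp(25 - 39800 / (8.314 * temp_K)))
#' arrhenius_fit(d)$Ea # 39800
#' @export
arrhenius_fit <- function(data, temperature = temp_K, rate = rate, t_max = NULL) {
  tk <- dplyr::pull(data, {{ temperature }})
  k <- dplyr::pull(data, {{ rate }})
  if (!is.null(t_max)) {
    keep <- tk <= t_max
    tk <- tk[keep]
    k <- k[keep]
  }
  if (any(!is.finite(tk)) || any(tk <= 0)) {
    et_abort("temperatures must be positive and in Kelvin", "bad_input")
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    et_abort("rates must be positive to take logarithms", "bad_input")
  }
  if (length(unique(tk)) < 2) {
    et_abort("at least 2 distinct temperatures are required", "too_few_points")
  }

  inv_t <- 1 / tk
  fit <- lm(log(k) ~ inv_t)
  slope <- unname(coef(fit)[2])
  r2 <- r_squared_manual(fit, centered = TRUE)
  structure(
    list(
      Ea = -slope * physical_constants()$R,
      lnA = unname(coef(fit)[1]),
      r_squared = r2,
      slope = slope,
      n = length(tk),
      data = tibble(temp_K = tk, rate = k),
      fit = fit
    ),
    class = "arrhenius_fit"
  )
}

# R^2 without summary.lm (which warns on noiseless data); for a
# through-origin model the total sum of squares is uncentered
r_squared_manual <- function(fit, centered = TRUE) {
  y <- fit$model[[1]]
  ss_tot <- if (centered) sum((y - mean(y))^2) else sum(y^2)
  if (ss_tot == 0) return(1)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / ss_tot))
}

#' Temperature quotient Q10
#'
#' Factor by which a reaction rate increases for a 10 degC rise, computed
#' from the activation energy as `Q10 = exp(10 * Ea / (R * T^2))`. This is
#' the differential (Arrhenius-consistent) form: the rate ratio
#' k(T+10)/k(T) equals exp(10 Ea / (R T (T+10))), which the `T^2` form
#' approximates at the evaluation temperature; tables in this field are
#' computed with the `T^2` form and natural exponential.
#'
#' @param Ea Activation energy, J mol^-1.
#' @param temp_K Absolute temperature, K (> 0).
#' @return Dimensionless Q10; equals 1 iff `Ea` = 0.
#' @examples
#' q10(39800, 333) # ~1.5
#' @export
q10 <- function(Ea, temp_K) {
  if (any(!is.finite(Ea)) || any(!is.finite(temp_K)) || any(temp_K <= 0)) {
    et_abort("Ea must be finite and temp_K positive", "bad_input")
  }
  exp(10 * Ea / (physical_constants()$R * temp_K^2))
}

#' Gibbs free energy of activation from a rate constant
#'
#' Inverts the Eyring transition-state relation
#' \deqn{k = (k_B T / h) e^{-\Delta G^* / RT}}
#' to \eqn{\Delta G^* = -RT \ln(k h / (k_B T))}. The rate constant must be
#' a frequency in s^-1; rates tagged `per_min` are divided by 60 first
#' (assay rate constants such as thermal-inactivation kd are conventionally
#' reported in min^-1).
#'
#' @param k_rate First-order rate constant (> 0).
#' @param temp_K Absolute temperature, K.
#' @param rate_unit `"per_s"` (default) or `"per_min"`.
#' @return Free energy of activation, J mol^-1.
#' @examples
#' gibbs_from_rate(2e-4, 313, rate_unit = "per_min") / 1000 # ~109.6
#' @export
gibbs_from_rate <- function(k_rate, temp_K, rate_unit = c("per_s", "per_min")) {
  rate_unit <- match.arg(rate_unit)
  if (any(!is.finite(k_rate)) || any(k_rate <= 0)) {
    et_abort("rate constant must be positive", "bad_input")
  }
  if (any(!is.finite(temp_K)) || any(temp_K <= 0)) {
    et_abort("temp_K must be positive", "bad_input")
  }
  if (rate_unit == "per_min") k_rate <- k_rate / 60
  cc <- physical_constants()
  -cc$R * temp_K * log(k_rate * cc$h / (cc$kB * temp_K))
}

#' Transition-state thermodynamics of catalysis
#'
#' Assembles the activation parameters at a reference temperature from the
#' Arrhenius activation energy and the turnover number:
#' `dH = Ea - R*T`, `dG` from the Eyring relation ([gibbs_from_rate()]),
#' `dS = (dH - dG)/T`, plus the temperature quotient [q10()]. If the
#' Michaelis constant is supplied, the free energy of substrate binding
#' `dG_ES = R*T*ln(KM)` (from the association constant Ka = 1/KM) and of
#' transition-state formation `dG_ET = -R*T*ln(kcat/KM)` are added.
#'
#' @param Ea Activation energy, J mol^-1.
#' @param k_rate Rate constant entering the Eyring relation (kcat for
#'   catalysis), s^-1 unless `rate_unit = "per_min"`.
#' @param temp_K Reference absolute temperature, K.
#' @param KM Optional Michaelis constant (g L^-1).
#' @param rate_unit Unit of `k_rate`, passed to [gibbs_from_rate()].
#' @return One-row tibble with `temp_K`, `Ea`, `dH`, `dG`, `dS`, `Q10` and,
#'   when `KM` is given, `dG_ES` and `dG_ET` (energies in J mol^-1,
#'   entropy in J mol^-1 K^-1). The identity `dG = dH - T*dS` holds by
#'   construction.
#' @examples
#' activation_params(39800, 49, 333, KM = 1.96)
#' @export
activation_params <- function(Ea, k_rate, temp_K, KM = NULL,
                              rate_unit = c("per_s", "per_min")) {
  rate_unit <- match.arg(rate_unit)
  cc <- physical_constants()
  dH <- Ea - cc$R * temp_K
  dG <- gibbs_from_rate(k_rate, temp_K, rate_unit)
  out <- tibble(
    temp_K = temp_K, Ea = Ea, dH = dH, dG = dG, dS = (dH - dG) / temp_K,
    Q10 = q10(Ea, temp_K)
  )
  if (!is.null(KM)) {
    k_s <- if (rate_unit == "per_min") k_rate / 60 else k_rate
    out$dG_ES <- binding_free_energy(KM, temp_K)
    out$dG_ET <- transition_free_energy(k_s, KM, temp_K)
  }
  out
}

#' Free energy of substrate binding
#'
#' `dG_ES = -R*T*ln(Ka)` with the association constant taken as the
#' reciprocal Michaelis constant, `Ka = 1/KM`, i.e. `dG_ES = R*T*ln(KM)`.
#' With KM in g L^-1 (polymeric substrate) the value depends on that unit
#' convention; it is reported as conventionally tabulated.
#'
#' @param KM Michaelis constant (> 0).
#' @param temp_K Absolute temperature, K.
#' @return Free energy of substrate binding, J mol^-1.
#' @examples
#' binding_free_energy(1, 333) # 0
#' @export
binding_free_energy <- function(KM, temp_K) {
  if (any(!is.finite(KM)) || any(KM <= 0)) {
    et_abort("KM must be positive", "bad_input")
  }
  physical_constants()$R * temp_K * log(KM)
}

#' Free energy of transition-state formation
#'
#' `dG_ET = -R*T*ln(kcat/KM)`; negative values indicate spontaneous
#' product formation after substrate binding.
#'
#' @param kcat Turnover number, s^-1 (> 0).
#' @param KM Michaelis constant (> 0).
#' @param temp_K Absolute temperature, K.
#' @return Free energy of transition-state formation, J mol^-1.
#' @examples
#' transition_free_energy(25, 50, 300) # ~ +1730
#' @export
transition_free_energy <- function(kcat, KM, temp_K) {
  if (any(!is.finite(kcat)) || any(kcat <= 0) || any(!is.finite(KM)) || any(KM <= 0)) {
    et_abort("kcat and KM must be positive", "bad_input")
  }
  -physical_constants()$R * temp_K * log(kcat / KM)
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("Arrhenius fit (", x$n, " temperatures)\n", sep = "")
  cat(sprintf("  Ea  = %.4g kJ/mol\n  lnA = %.4g\n  R^2 = %.4f\n",
              x$Ea / 1000, x$lnA, x$r_squared))
  invisible(x)
}

#' @rdname arrhenius_fit
#' @param x An `arrhenius_fit` object.
#' @param ... Unused.
#' @method tidy arrhenius_fit
#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble(term = c("Ea", "lnA"), estimate = c(x$Ea, x$lnA),
         unit = c("J/mol", ""))
}

#' @rdname arrhenius_fit
#' @method glance arrhenius_fit
#' @export
glance.arrhenius_fit <- function(x, ...) {
  tibble(Ea = x$Ea, lnA = x$lnA, r_squared = x$r_squared, n = x$n)
}

#' @rdname arrhenius_fit
#' @param object An `arrhenius_fit` object.
#' @method autoplot arrhenius_fit
#' @export
autoplot.arrhenius_fit <- function(object, ...) {
  d <- dplyr::mutate(object$data, inv_T = 1 / .data$temp_K, ln_rate = log(.data$rate))
  ggplot2::ggplot(d, ggplot2::aes(.data$inv_T, .data$ln_rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$lnA, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "1/T (1/K)", y = "ln(rate)",
                  title = sprintf("Arrhenius plot: Ea = %.1f kJ/mol (R^2 = %.3f)",
                                  object$Ea / 1000, object$r_squared)) +
    ggplot2::theme_minimal()
}
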