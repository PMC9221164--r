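#' Fit a first-order thermal-inactivation time course
#'
#' Irreversible thermal inactivation is modelled as first-order decay of
#' residual activity, `ln(At/A0) = -kd * t`. Because the model has no
#' intercept (residual fraction is 1 at t = 0 by definition), the default
#' regression of `ln(residual)` on time is forced through the origin, for
#' which the least-squares slope has the closed form
#' `sum(t * ln f) / sum(t^2)`. Samples with residual fraction <= 0
#' (complete inactivation, below the assay floor) cannot enter a log fit
#' and are excluded, with the exclusion counted in the result.
#'
#' @param data Data frame with one row per sampling time.
#' @param time,residual Column names (unquoted) holding incubation time
#'   (min) and residual activity as a fraction of initial (At/A0).
#'   Defaults `time_min`, `residual_fraction`.
#' @param temp_K Optional absolute temperature of the course (K), carried
#'   into the result for panel assembly.
#' @param intercept If `TRUE`, fit a free-intercept regression instead;
#'   `kd` is still minus the slope.
#' @return An object of class `inactivation_fit` with elements `temp_K`,
#'   `kd` (min^-1), `half_life` (min), `D_value` (min), `r_squared`,
#'   `n_points_used`, `n_points_dropped`, `intercept` and the points used.
#' @examples
#' d <- tibble::tibble(time_min = c(5, 10, 15, 20),
#'                     residual_fraction = exp(-0.028 * time_min))
#' fit_inactivation(d)$kd # 0.028
#' @export
fit_inactivation <- function(data, time = time_min, residual = residual_fraction,
                             temp_K = NULL, intercept = FALSE) {
  t <- dplyr::pull(data, {{ time }})
  f <- dplyr::pull(data, {{ residual }})
  if (any(!is.finite(t)) || any(t < 0)) {
    et_abort("times must be finite and non-negative", "bad_input")
  }
  # only f <= 0 counts as an exclusion; the t = 0 anchor (fraction 1 by
  # definition) is uninformative for a through-origin slope and is not fitted
  n_dropped <- sum(!(is.finite(f) & f > 0))
  usable <- is.finite(f) & f > 0 & t > 0
  t_u <- t[usable]
  f_u <- f[usable]
  if (length(t_u) < 2) {
    et_abort("need at least 2 samples with positive time and residual activity",
             "too_few_points")
  }
  if (length(unique(t_u)) < 2) {
    et_abort("need at least 2 distinct sampling times", "too_few_points")
  }

  lf <- log(f_u)
  fit <- if (intercept) lm(lf ~ t_u) else lm(lf ~ 0 + t_u)
  slope <- unname(coef(fit)[["t_u"]])
  kd <- -slope
  if (kd <= 0) {
    et_abort("estimated kd is non-positive: activity does not decay over time",
             "degenerate")
  }
  r2 <- r_squared_manual(fit, centered = intercept)

  structure(
    list(
      temp_K = temp_K %||% NA_real_,
      kd = kd,
      half_life = half_life(kd),
      D_value = decimal_reduction(kd),
      r_squared = r2,
      n_points_used = length(t_u),
      n_points_dropped = n_dropped,
      intercept = if (intercept) unname(coef(fit)[1]) else 0,
      data = tibble(time_min = t_u, residual_fraction = f_u)
    ),
    class = "inactivation_fit"
  )
}

#' Half-life and decimal-reduction time of first-order inactivation
#'
#' `half_life()` is the time for residual activity to fall to 50 percent,
#' `ln(2)/kd`; `decimal_reduction()` (the D-value) is the time for a 90
#' percent reduction, `ln(10)/kd`. Their ratio is always
#' `ln(10)/ln(2) ~ 3.32`.
#'
#' @param kd First-order inactivation rate constant, min^-1 (> 0).
#' @return Time in the reciprocal unit of `kd` (min when kd is min^-1).
#' @examples
#' half_life(2.2e-3)         # ~315 min
#' decimal_reduction(2.2e-3) # ~1047 min
#' @export
half_life <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    et_abort("kd must be positive", "bad_input")
  }
  log(2) / kd
}

#' @rdname half_life
#' @export
decimal_reduction <- function(kd) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    et_abort("kd must be positive", "bad_input")
  }
  log(10) / kd
}

#' Fit an inactivation panel across temperatures
#'
#' Groups a long decay table by temperature and fits each time course with
#' [fit_inactivation()], returning one row per temperature.
#'
#' @param data Data frame with columns for temperature, time and residual
#'   fraction (long format, several temperatures stacked).
#' @param temperature,time,residual Column names (unquoted); defaults
#'   `temp_K`, `time_min`, `residual_fraction`.
#' @param intercept Passed to [fit_inactivation()].
#' @return A tibble of class `inactivation_panel` with columns `temp_K`,
#'   `kd`, `half_life`, `D_value`, `r_squared`, `n_points_used`,
#'   `n_points_dropped`, ordered by temperature.
#' @examples
#' panel <- gen_decay_panel(ground_truth(noise_cv = 0))
#' fit_inactivation_panel(panel)
#' @export
fit_inactivation_panel <- function(data, temperature = temp_K, time = time_min,
                                   residual = residual_fraction,
                                   intercept = FALSE) {
  grouped <- dplyr::group_split(dplyr::group_by(data, {{ temperature }}))
  rows <- purrr::map(grouped, function(g) {
    tk <- dplyr::pull(g, {{ temperature }})[1]
    fit <- fit_inactivation(g, time = {{ time }}, residual = {{ residual }},
                            temp_K = tk, intercept = intercept)
    glance(fit)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$temp_K)
  class(out) <- c("inactivation_panel", class(out))
  attr(out, "decay_data") <- as_tibble(data)
  out
}

#' Thermal deactivation energy from a temperature panel
#'
#' Arrhenius regression of the per-temperature inactivation rate constants:
#' OLS of `ln(kd)` on `1/T`, with `Ea_d = -slope * R`. The unit kd is
#' expressed in does not affect the slope.
#'
#' @param panel An `inactivation_panel` (or any data frame with `temp_K`
#'   and `kd` columns).
#' @return An [arrhenius_fit()] object whose `Ea` is the deactivation
#'   energy E(a)d in J mol^-1.
#' @examples
#' kd_tbl <- tibble::tibble(temp_K = c(313, 323, 333, 343, 353),
#'                          kd = c(2.0e-4, 2.2e-3, 2.8e-2, 2.7e-1, 7.2e-1))
#' deactivation_energy(kd_tbl)$Ea / 1000 # ~195.3 kJ/mol
#' @export
deactivation_energy <- function(panel) {
  arrhenius_fit(panel, temperature = temp_K, rate = kd)
}

#' Deactivation thermodynamics across a temperature panel
#'
#' For each temperature, computes the enthalpy, Gibbs free energy and
#' entropy of the inactivation transition state by the Eyring relations
#' with the inactivation rate constant in place of the catalytic one:
#' `dH_D = Ea_d - R*T`, `dG_D` from [gibbs_from_rate()] (kd converted from
#' min^-1 to s^-1 inside the Eyring expression), `dS_D = (dH_D - dG_D)/T`.
#' The global deactivation energy `Ea_d` is estimated from the panel by
#' [deactivation_energy()] unless supplied.
#'
#' @param panel An `inactivation_panel` or data frame with `temp_K` and
#'   `kd` (min^-1) columns; `half_life`/`D_value` columns are carried
#'   through (or derived from kd when absent).
#' @param Ea_d Optional deactivation energy in J mol^-1; default estimated
#'   from the panel.
#' @return A tibble with one row per temperature: `temp_K`, `kd`,
#'   `half_life`, `D_value`, `Ea_d`, `dG_D`, `dS_D`, `dH_D` (energies in
#'   J mol^-1, entropy in J mol^-1 K^-1) — the full thermostability table.
#' @examples
#' kd_tbl <- tibble::tibble(temp_K = c(313, 323, 333, 343, 353),
#'                          kd = c(2.0e-4, 2.2e-3, 2.8e-2, 2.7e-1, 7.2e-1))
#' deactivation_params(kd_tbl)
#' @export
deactivation_params <- function(panel, Ea_d = NULL) {
  if (is.null(Ea_d)) Ea_d <- deactivation_energy(panel)$Ea
  cc <- physical_constants()
  out <- as_tibble(panel)[, intersect(c("temp_K", "kd", "half_life", "D_value"),
                                      names(panel))]
  if (!"half_life" %in% names(out)) out$half_life <- half_life(out$kd)
  if (!"D_value" %in% names(out)) out$D_value <- decimal_reduction(out$kd)
  dplyr::mutate(
    out,
    Ea_d = Ea_d,
    dH_D = Ea_d - cc$R * .data$temp_K,
    dG_D = gibbs_from_rate(.data$kd, .data$temp_K, rate_unit = "per_min"),
    dS_D = (.data$dH_D - .data$dG_D) / .data$temp_K
  )
}

#' Non-covalent bonds disrupted on inactivation
#'
#' Average number of non-covalent (hydrophobic) contacts broken in forming
#' the inactivation transition state, estimated as the inactivation
#' enthalpy divided by the energy needed to remove one -CH2- moiety from a
#' hydrophobic bond (about 5.4 kJ mol^-1).
#'
#' @param dH_D Enthalpy of inactivation, J mol^-1 (>= 0).
#' @param bond_energy Energy per non-covalent bond, J mol^-1 (default 5400).
#' @return Dimensionless bond count.
#' @examples
#' bonds_broken(192800) # ~35.7
#' @export
bonds_broken <- function(dH_D, bond_energy = 5400) {
  if (any(!is.finite(dH_D)) || any(dH_D < 0)) {
    et_abort("dH_D must be non-negative", "bad_input")
  }
  dH_D / bond_energy
}

#' @export
print.inactivation_fit <- function(x, ...) {
  cat("First-order inactivation fit",
      if (!is.na(x$temp_K)) sprintf(" at %g K", x$temp_K), "\n", sep = "")
  cat(sprintf("  kd = %.3e 1/min, t1/2 = %.4g min, D = %.4g min (R^2 = %.4f)\n",
              x$kd, x$half_life, x$D_value, x$r_squared))
  if (x$n_points_dropped > 0) {
    cat(sprintf("  %d point(s) at/below the assay floor excluded\n", x$n_points_dropped))
  }
  invisible(x)
}

#' @rdname fit_inactivation
#' @param x An `inactivation_fit` object.
#' @param ... Unused.
#' @method tidy inactivation_fit
#' @export
tidy.inactivation_fit <- function(x, ...) {
  tibble(term = c("kd", "half_life", "D_value"),
         estimate = c(x$kd, x$half_life, x$D_value),
         unit = c("1/min", "min", "min"))
}

#' @rdname fit_inactivation
#' @method glance inactivation_fit
#' @export
glance.inactivation_fit <- function(x, ...) {
  tibble(temp_K = x$temp_K, kd = x$kd, half_life = x$half_life,
         D_value = x$D_value, r_squared = x$r_squared,
         n_points_used = x$n_points_used, n_points_dropped = x$n_points_dropped)
}

#' @rdname fit_inactivation_panel
#' @param object An `inactivation_panel` object.
#' @param ... Unused.
#' @method autoplot inactivation_panel
#' @export
autoplot.inactivation_panel <- function(object, ...) {
  raw <- attr(object, "decay_data")
  if (is.null(raw)) et_abort("panel carries no raw decay data to plot", "bad_input")
  d <- dplyr::filter(raw, .data$residual_fraction > 0)
  lines <- dplyr::mutate(as_tibble(object), slope = -.data$kd)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min, log(.data$residual_fraction),
                                  colour = factor(.data$temp_K))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = 0, slope = .data$slope,
                                      colour = factor(.data$temp_K))) +
    ggplot2::labs(x = "Time (min)", y = "ln(At/A0)", colour = "T (K)",
                  title = "First-order thermal inactivation") +
    ggplot2::theme_minimal()
}
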