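#' Fit initial-rate data to the Michaelis-Menten model
#'
#' Nonlinear least-squares fit of the rectangular hyperbola
#' \deqn{v = v_{max} S / (K_M + S)}
#' to substrate-concentration / initial-rate pairs. For a polymeric
#' substrate such as xylan, `KM` is expressed in g L^-1 and `vmax` as a
#' specific activity (umol min^-1 per mg protein).
#'
#' Fitting minimizes the sum of squared residuals
#' \eqn{\sum_i (v_i - v_{max} S_i/(K_M+S_i))^2} by Levenberg-Marquardt on
#' log-transformed parameters, which enforces positivity of both estimates.
#' Starting values are analytic: `vmax0 = 1.1 * max(v)` and `KM0` the
#' substrate concentration at half of `vmax0`, linearly interpolated from
#' the data. Replicate points at the same substrate level are kept as
#' separate residuals, not averaged.
#'
#' @param data Data frame with one row per assay point.
#' @param substrate,rate Column names (unquoted) holding substrate
#'   concentration (g L^-1) and initial rate. Defaults `substrate`, `rate`.
#' @param molecular_mass Optional enzyme molecular mass in g mol^-1. When
#'   supplied, the turnover number `kcat` (s^-1) and catalytic efficiency
#'   `kcat/KM` (L s^-1 g^-1) are derived from the fitted `vmax` via
#'   [turnover_number()]; otherwise both are left `NA`.
#' @param weight_inverse_rate If `TRUE`, residuals are weighted by `1/v`
#'   (useful when assay error is proportional to the signal). Default
#'   unweighted.
#'
#' @return An object of class `mm_fit`: a list with elements `KM`, `vmax`,
#'   `kcat`, `efficiency`, `sse`, `converged`, `n`, `molecular_mass`,
#'   `data` and the underlying `nls` object (`fit`). Use [tidy()] /
#'   [glance()] for tibble summaries and [autoplot()] for a diagnostic plot.
#'
#' @section Errors: at least 4 distinct substrate levels are required and
#'   the rates must not all be equal (a flat response leaves `KM`
#'   unidentifiable); violations raise a classed error. Non-convergence
#'   raises an error carrying the last iterate.
#'
#' @examples
#' d <- tibble::tibble(substrate = c(0.5, 1, 2, 5, 10, 20),
#'                     rate = 58.6 * substrate / (1.96 + substrate))
#' fit <- fit_michaelis_menten(d, molecular_mass = 47890)
#' glance(fit)
#' @export
fit_michaelis_menten <- function(data, substrate = substrate, rate = rate,
                                 molecular_mass = NULL,
                                 weight_inverse_rate = FALSE) {
  s <- dplyr::pull(data, {{ substrate }})
  v <- dplyr::pull(data, {{ rate }})
  if (any(!is.finite(s)) || any(!is.finite(v))) {
    et_abort("substrate and rate values must be finite numbers", "bad_input")
  }
  if (any(s < 0) || any(v < 0)) {
    et_abort("substrate concentrations and rates must be non-negative", "bad_input")
  }
  if (length(unique(s)) < 4) {
    et_abort("at least 4 distinct substrate concentrations are required", "too_few_points")
  }
  if (diff(range(v)) == 0) {
    et_abort("all rates are equal: KM is unidentifiable from a flat response", "degenerate")
  }

  vmax0 <- 1.1 * max(v)
  km0 <- km_start(s, v, vmax0)
  w <- if (weight_inverse_rate) 1 / pmax(v, .Machine$double.eps) else rep(1, length(v))

  df <- data.frame(s = s, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ exp(lvmax) * s / (exp(lkm) + s),
      data = df, weights = w,
      start = list(lvmax = log(vmax0), lkm = log(km0)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      et_abort(paste0("Michaelis-Menten fit failed to converge (last start: vmax = ",
                      signif(vmax0, 4), ", KM = ", signif(km0, 4), "): ",
                      conditionMessage(e)),
               "non_convergence")
    }
  )

  est <- exp(coef(fit))
  vmax <- unname(est["lvmax"])
  km <- unname(est["lkm"])
  kcat <- if (is.null(molecular_mass)) NA_real_ else turnover_number(vmax, molecular_mass)
  structure(
    list(
      KM = km, vmax = vmax, kcat = kcat,
      efficiency = if (is.na(kcat)) NA_real_ else kcat / km,
      sse = sum((v - vmax * s / (km + s))^2),
      converged = fit$convInfo$isConv %||% TRUE,
      n = length(s),
      molecular_mass = molecular_mass,
      data = tibble(substrate = s, rate = v),
      fit = fit
    ),
    class = "mm_fit"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# substrate level at half of vmax0, linearly interpolated; falls back to the
# median substrate when the half-maximal rate is outside the observed range
km_start <- function(s, v, vmax0) {
  o <- order(v)
  km0 <- suppressWarnings(approx(v[o], s[o], xout = vmax0 / 2, ties = mean)$y)
  if (!is.finite(km0) || km0 <= 0) km0 <- max(median(s), .Machine$double.eps)
  km0
}

#' Turnover number from specific activity and molecular mass
#'
#' Converts a maximal specific activity `vmax` in umol min^-1 (mg
#' protein)^-1 into a turnover number in s^-1:
#' `kcat = vmax * molecular_mass * 1e-3 / 60`. The factor follows from
#' units: 1 umol min^-1 mg^-1 equals 1 mmol min^-1 g^-1, so multiplying by
#' the molecular mass (g mol^-1) gives mmol min^-1 per mol of enzyme, i.e.
#' `1e-3` mol product per mol enzyme per minute, divided by 60 for s^-1.
#'
#' @param vmax Maximal specific activity, umol min^-1 mg^-1 (> 0).
#' @param molecular_mass Enzyme molecular mass, g mol^-1 (> 0).
#' @return Turnover number kcat in s^-1.
#' @examples
#' turnover_number(58.6, 47890) # ~46.8
#' @export
turnover_number <- function(vmax, molecular_mass) {
  if (!is.finite(vmax) || vmax <= 0) {
    et_abort("vmax must be a positive finite number", "bad_input")
  }
  if (!is.finite(molecular_mass) || molecular_mass <= 0) {
    et_abort("molecular_mass must be a positive finite number", "bad_input")
  }
  vmax * molecular_mass * 1e-3 / 60
}

#' Relative activity table
#'
#' Expresses activities as percentages of a reference condition, the way
#' substrate-specificity and modulator panels are reported (reference row
#' mapped to 100 percent).
#'
#' @param data Data frame with one row per condition.
#' @param reference Label (string) of the reference condition.
#' @param label,activity Column names (unquoted) holding the condition
#'   label and the measured activity. Defaults `label`, `activity`.
#' @return The input tibble with an added `relative_pct` column; the
#'   reference row is exactly 100.
#' @examples
#' d <- tibble::tibble(label = c("oat", "arabinoxylan", "CMC"),
#'                     activity = c(12.4, 27.6, 0))
#' relative_activity(d, reference = "oat")
#' @export
relative_activity <- function(data, reference, label = label, activity = activity) {
  labs <- dplyr::pull(data, {{ label }})
  act <- dplyr::pull(data, {{ activity }})
  if (!reference %in% labs) {
    et_abort(paste0("reference label '", reference, "' not found"), "missing_reference")
  }
  ref <- act[match(reference, labs)]
  if (!is.finite(ref) || ref <= 0) {
    et_abort("reference activity must be positive", "bad_reference")
  }
  dplyr::mutate(as_tibble(data), relative_pct = 100 * act / ref)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit (", x$n, " points)\n", sep = "")
  cat(sprintf("  KM   = %.4g g/L\n  vmax = %.4g umol/min/mg\n", x$KM, x$vmax))
  if (!is.na(x$kcat)) {
    cat(sprintf("  kcat = %.4g 1/s\n  kcat/KM = %.4g L/s/g\n", x$kcat, x$efficiency))
  }
  cat(sprintf("  SSE = %.4g, converged: %s\n", x$sse, x$converged))
  invisible(x)
}

#' @rdname fit_michaelis_menten
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("KM", "vmax", "kcat", "efficiency"),
    estimate = c(x$KM, x$vmax, x$kcat, x$efficiency),
    unit = c("g/L", "umol/min/mg", "1/s", "L/s/g")
  )
}

#' @rdname fit_michaelis_menten
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(KM = x$KM, vmax = x$vmax, kcat = x$kcat, efficiency = x$efficiency,
         sse = x$sse, n = x$n, converged = x$converged)
}

#' @rdname fit_michaelis_menten
#' @param object An `mm_fit` object.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble(substrate = seq(0, max(object$data$substrate), length.out = 200))
  grid$rate <- object$vmax * grid$substrate / (object$KM + grid$substrate)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$substrate, .data$rate)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Substrate (g/L)", y = "Rate (umol/min/mg)",
                  title = sprintf("Michaelis-Menten fit: KM = %.3g g/L, vmax = %.3g",
                                  object$KM, object$vmax)) +
    ggplot2::theme_minimal()
}
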