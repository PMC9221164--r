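#' Read assay CSV files
#'
#' Readers for the three flat CSV schemas used by the fitters, one file
#' per assay shape (RFC 4180, header row mandatory, decimal point `.`):
#'
#' * `read_mm_csv()`: columns `substrate_g_per_L`, `rate_umol_min_mg`,
#'   optional `temperature_C`, `pH` — one initial-rate point per row.
#' * `read_rate_temperature_csv()`: columns `temperature_C`, `rate`,
#'   `rate_unit` (`per_s`, `per_min` or `umol_min_mg`) — a maximal-rate
#'   vs temperature series for Arrhenius analysis.
#' * `read_decay_csv()`: columns `temperature_C`, `time_min`,
#'   `residual_activity_pct` (percent of initial activity); several
#'   temperatures may be stacked in one file. Values slightly above 100
#'   are accepted with a warning (assay noise); the fraction column is
#'   `residual_activity_pct / 100`.
#' * `read_xo_csv()`: columns `time_h`, `X1`..`X6` in g L^-1.
#'
#' Missing columns and non-numeric cells raise classed errors naming the
#' offending column (and row, for malformed cells).
#'
#' @param path Path to a CSV file.
#' @param kelvin_offset Celsius-to-Kelvin offset used to derive `temp_K`
#'   (see [celsius_to_kelvin()]).
#' @return A tibble in the column convention the fitters expect
#'   (`substrate`/`rate`, `temp_K`/`rate`/`rate_unit`,
#'   `temp_K`/`time_min`/`residual_fraction`, or `time_h`/`X1`..`X6`).
#' @name assay_readers
NULL

read_assay_csv <- function(path, required, optional = character()) {
  if (!file.exists(path)) {
    et_abort(paste0("file not found: ", path), "missing_file")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) et_abort(paste0("empty file: ", path), "empty_file")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    et_abort(paste0("missing column(s) in ", basename(path), ": ",
                    paste(missing, collapse = ", ")), "schema")
  }
  for (col in intersect(c(required, optional), names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]) & raw[[col]] != "NA")
    if (length(bad) > 0) {
      et_abort(paste0("non-numeric value in column '", col, "' at data row(s) ",
                      paste(bad, collapse = ", "), " of ", basename(path)),
               "malformed_cell")
    }
    raw[[col]] <- parsed
  }
  raw
}

#' @rdname assay_readers
#' @export
read_mm_csv <- function(path) {
  d <- read_assay_csv(path, c("substrate_g_per_L", "rate_umol_min_mg"),
                      optional = c("temperature_C", "pH"))
  out <- tibble(substrate = d$substrate_g_per_L, rate = d$rate_umol_min_mg)
  if ("temperature_C" %in% names(d)) out$temp_C <- d$temperature_C
  if ("pH" %in% names(d)) out$pH <- d$pH
  out
}

#' @rdname assay_readers
#' @export
read_rate_temperature_csv <- function(path, kelvin_offset = 273) {
  d <- read_assay_csv(path, c("temperature_C", "rate"))
  if (!"rate_unit" %in% names(d)) {
    et_abort("missing column(s): rate_unit", "schema")
  }
  allowed <- c("per_s", "per_min", "umol_min_mg")
  if (!all(d$rate_unit %in% allowed)) {
    et_abort(paste0("rate_unit must be one of ", paste(allowed, collapse = ", ")),
             "schema")
  }
  tibble(temp_C = d$temperature_C,
         temp_K = celsius_to_kelvin(d$temperature_C, kelvin_offset),
         rate = d$rate, rate_unit = d$rate_unit)
}

#' @rdname assay_readers
#' @export
read_decay_csv <- function(path, kelvin_offset = 273) {
  d <- read_assay_csv(path, c("temperature_C", "time_min", "residual_activity_pct"))
  over <- d$residual_activity_pct > 100
  if (any(over)) {
    warn(paste0(sum(over), " residual-activity value(s) above 100% retained",
                " (assay noise tolerance)"))
  }
  if (any(d$residual_activity_pct < 0)) {
    et_abort("residual_activity_pct must be non-negative", "bad_input")
  }
  tibble(temp_C = d$temperature_C,
         temp_K = celsius_to_kelvin(d$temperature_C, kelvin_offset),
         time_min = d$time_min,
         residual_fraction = d$residual_activity_pct / 100)
}

#' @rdname assay_readers
#' @export
read_xo_csv <- function(path) {
  d <- read_assay_csv(path, c("time_h", paste0("X", 1:6)))
  check_xo_course(d[, c("time_h", paste0("X", 1:6))])
}

#' Render a thermodynamic report
#'
#' Deterministic, locale-independent rendering of the two canonical result
#' tables:
#'
#' * `style = "stability"`: the output of [deactivation_params()] — one
#'   row per temperature with kd, half-life, D-value, E(a)d and the
#'   deactivation thermodynamics.
#' * `style = "activation"`: the one-row output of [activation_params()].
#'
#' Energies are reported in kJ mol^-1 at one decimal, entropies in
#' J mol^-1 K^-1 at one decimal, half-life and D-value as integer minutes
#' and kd in scientific notation — the precision conventions of published
#' thermostability tables. Internal computation stays in double-precision
#' J mol^-1; rounding happens only here.
#'
#' @param results A tibble from [deactivation_params()] or
#'   [activation_params()].
#' @param style `"stability"` or `"activation"`.
#' @param format `"text"` for a fixed-width table, `"json"` for a JSON
#'   string that round-trips losslessly through [parse_report()].
#' @return A single character string.
#' @examples
#' kd_tbl <- tibble::tibble(temp_K = c(313, 333), kd = c(2.0e-4, 2.8e-2))
#' cat(render_report(deactivation_params(kd_tbl, Ea_d = 195400)))
#' @export
render_report <- function(results, style = c("stability", "activation"),
                          format = c("text", "json")) {
  style <- match.arg(style)
  format <- match.arg(format)
  rounded <- round_report(results, style)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(list(style = style, rows = rounded),
                                         dataframe = "rows", auto_unbox = TRUE,
                                         digits = NA)))
  }
  render_text(rounded, style)
}

#' @rdname render_report
#' @param json A JSON string produced by `render_report(format = "json")`.
#' @export
parse_report <- function(json) {
  parsed <- jsonlite::fromJSON(json)
  rows <- as_tibble(parsed$rows)
  # reports carry energies in kJ/mol; restore the internal J/mol scale so a
  # parsed report can be re-rendered (or fed onward) like any result table
  for (col in intersect(c("Ea", "Ea_d", "dH", "dG", "dH_D", "dG_D",
                          "dG_ES", "dG_ET"), names(rows))) {
    rows[[col]] <- rows[[col]] * 1000
  }
  structure(rows, report_style = parsed$style)
}

round_report <- function(results, style) {
  cols <- if (style == "stability") {
    c("temp_K", "kd", "half_life", "D_value", "Ea_d", "dG_D", "dS_D", "dH_D")
  } else {
    intersect(c("temp_K", "Ea", "dH", "dG", "dS", "Q10", "dG_ES", "dG_ET"),
              names(results))
  }
  missing <- setdiff(cols, names(results))
  if (length(missing) > 0 || nrow(results) == 0) {
    et_abort(paste0("results are incomplete for style '", style, "'",
                    if (length(missing)) paste0(": missing ",
                                                paste(missing, collapse = ", "))),
             "incomplete_results")
  }
  out <- as_tibble(results)[, cols]
  for (col in intersect(c("Ea", "Ea_d", "dH", "dG", "dH_D", "dG_D",
                          "dG_ES", "dG_ET"), cols)) {
    out[[col]] <- round(out[[col]] / 1000, 1) # kJ/mol, one decimal
  }
  for (col in intersect(c("dS", "dS_D"), cols)) out[[col]] <- round(out[[col]], 1)
  for (col in intersect(c("half_life", "D_value"), cols)) {
    out[[col]] <- round(out[[col]])
  }
  if ("Q10" %in% cols) out$Q10 <- round(out$Q10, 1)
  if ("kd" %in% cols) out$kd <- signif(out$kd, 3)
  out
}

render_text <- function(rounded, style) {
  units <- c(temp_K = "K", kd = "1/min", half_life = "min", D_value = "min",
             Ea = "kJ/mol", Ea_d = "kJ/mol", dH = "kJ/mol", dG = "kJ/mol",
             dH_D = "kJ/mol", dG_D = "kJ/mol", dG_ES = "kJ/mol",
             dG_ET = "kJ/mol", dS = "J/mol/K", dS_D = "J/mol/K", Q10 = "")
  fmt_cell <- function(col, x) {
    if (col == "kd") sprintf("%.2e", x)
    else if (col %in% c("temp_K", "half_life", "D_value")) sprintf("%d", as.integer(round(x)))
    else sprintf("%.1f", x)
  }
  header <- vapply(names(rounded), function(cn) {
    if (nzchar(units[[cn]])) paste0(cn, " (", units[[cn]], ")") else cn
  }, character(1))
  body <- vapply(names(rounded), function(cn) {
    format(c(header[[cn]], fmt_cell(cn, rounded[[cn]])), justify = "right")
  }, character(nrow(rounded) + 1))
  title <- if (style == "stability") {
    "Thermal-inactivation kinetic and thermodynamic parameters"
  } else {
    "Activation thermodynamics of substrate hydrolysis"
  }
  lines <- apply(matrix(body, nrow = nrow(rounded) + 1), 1, paste, collapse = "  ")
  paste0(title, "\n", paste(lines, collapse = "\n"), "\n")
}
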