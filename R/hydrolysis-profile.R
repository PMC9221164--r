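#' Degree-of-polymerization distribution of a hydrolysate
#'
#' At a chosen sampling time, expresses each xylooligosaccharide species
#' (xylose X1 through xylohexaose X6) as a percentage of the total product
#' concentration. Percentages are defined on mass concentration (g L^-1),
#' matching chromatographic mass quantification; set `molar = TRUE` to
#' weight by molar concentration instead (molecular mass taken as
#' 132*DP + 18 g mol^-1 for a DP-mer plus one water).
#'
#' @param course Data frame with a `time_h` column and columns `X1`..`X6`
#'   holding concentrations in g L^-1 (see [read_xo_csv()] /
#'   [gen_xo_timecourse()]).
#' @param at_time Sampling time (h); must match a row of `course`.
#' @param molar Use molar rather than mass percentages. Default `FALSE`.
#' @return A tibble with columns `species`, `DP`, `conc` and `percent`;
#'   percentages sum to 100.
#' @examples
#' course <- tibble::tibble(time_h = 24, X1 = 5, X2 = 18, X3 = 32,
#'                          X4 = 29, X5 = 12, X6 = 3)
#' dp_distribution(course, at_time = 24)
#' @export
dp_distribution <- function(course, at_time, molar = FALSE) {
  check_xo_course(course)
  row <- dplyr::filter(course, .data$time_h == at_time)
  if (nrow(row) == 0) {
    et_abort(paste0("no sample at time ", at_time, " h in the course"),
             "time_not_found")
  }
  conc <- as.numeric(row[1, xo_species()])
  weight <- if (molar) conc / (132 * 1:6 + 18) else conc
  total <- sum(weight)
  if (total <= 0) {
    et_abort("total concentration at the requested time is zero", "zero_total")
  }
  tibble(species = xo_species(), DP = 1:6, conc = conc,
         percent = 100 * weight / total)
}

#' Reducing-end (xylose-equivalent) series of a hydrolysis time course
#'
#' Per sampling time, sums `conc(DP)/DP` over the six species: the mass
#' concentration of each oligomer divided by its chain length is the mass
#' carried by its reducing ends, so the sum tracks the number of chains in
#' solution. For a pure depolymerization without consumption of products
#' the series is monotone non-decreasing (every cleavage creates one new
#' reducing end) — a mass-balance audit for both real and generated data.
#' Optionally applies the anhydro correction 150/132 (free xylose vs the
#' anhydroxylose residue mass) to report in free-xylose mass units.
#'
#' @param course Data frame as in [dp_distribution()].
#' @param anhydro_correction Multiply by 150/132. Default `FALSE`.
#' @return A tibble with columns `time_h` and `equivalents` (g L^-1);
#'   zero-row input gives a zero-row series.
#' @examples
#' xylose_equivalents(tibble::tibble(time_h = 0, X1 = 0, X2 = 1, X3 = 0,
#'                                   X4 = 0, X5 = 0, X6 = 0))$equivalents # 0.5
#' @export
xylose_equivalents <- function(course, anhydro_correction = FALSE) {
  check_xo_course(course, allow_empty = TRUE)
  if (nrow(course) == 0) {
    return(tibble(time_h = numeric(), equivalents = numeric()))
  }
  m <- as.matrix(course[, xo_species()])
  eq <- as.numeric(m %*% (1 / (1:6)))
  if (anhydro_correction) eq <- eq * 150 / 132
  tibble(time_h = course$time_h, equivalents = eq)
}

xo_species <- function() paste0("X", 1:6)

check_xo_course <- function(course, allow_empty = FALSE) {
  missing <- setdiff(c("time_h", xo_species()), names(course))
  if (length(missing) > 0) {
    et_abort(paste0("course is missing column(s): ", paste(missing, collapse = ", ")),
             "schema")
  }
  if (!allow_empty && nrow(course) == 0) {
    et_abort("course has no rows", "bad_input")
  }
  conc <- as.matrix(course[, xo_species()])
  if (any(!is.finite(conc)) || any(conc < 0)) {
    et_abort("concentrations must be finite and non-negative", "bad_input")
  }
  invisible(course)
}

#' Plot a xylooligosaccharide time course
#'
#' Line plot of each species' concentration over time.
#'
#' @param course Data frame as in [dp_distribution()].
#' @return A ggplot object.
#' @export
plot_xo_timecourse <- function(course) {
  check_xo_course(course)
  long <- tidyr::pivot_longer(course, dplyr::all_of(xo_species()),
                              names_to = "species", values_to = "conc")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$conc,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Time (h)", y = "Concentration (g/L)", colour = NULL,
                  title = "Xylooligosaccharide release") +
    ggplot2::theme_minimal()
}
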