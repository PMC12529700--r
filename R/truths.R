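#' Ground-truth piecewise growth (or value) curve for one sex and breed
#'
#' Defines the generative model behind the synthetic slaughter, market and
#' movement datasets: a continuous piecewise-linear mean of liveweight (kg)
#' or monetary value (EUR) against age in days, plus additive calendar-month
#' and calendar-year offsets and Gaussian noise. Fitted models are judged by
#' how well they recover these parameters.
#'
#' @param sex `"female"` or `"male"`.
#' @param breed_category one of `"dairy"`, `"continental_beef"`,
#'   `"british_irish_beef"`.
#' @param intercept mean at age 0 (kg or EUR).
#' @param segment_slopes per-day slope within each segment, length
#'   `length(break_points) + 1`.
#' @param break_points strictly increasing ages (days) at which the slope
#'   changes.
#' @param month_effects numeric length-12 additive offset per calendar month.
#' @param year_effects named numeric additive offset per calendar year
#'   (names are years).
#' @param noise_sd residual standard deviation (>= 0).
#' @param units `"kg"` or `"eur"` (labelling only).
#' @return object of class `growth_truth`.
#' @export
growth_truth <- function(sex, breed_category, intercept, segment_slopes,
                         break_points, month_effects = rep(0, 12),
                         year_effects = c("2016" = 0), noise_sd = 0,
                         units = "kg") {
  sex <- match.arg(sex, c("female", "male"))
  breed_category <- match.arg(breed_category, breed_categories())
  break_points <- as.numeric(break_points)
  if (is.unsorted(break_points, strictly = TRUE))
    stop_config("break_points must be strictly increasing")
  if (length(segment_slopes) != length(break_points) + 1L)
    stop_config("need length(break_points) + 1 segment slopes")
  if (length(month_effects) != 12L)
    stop_config("month_effects must have length 12")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (is.null(names(year_effects)))
    stop_config("year_effects must be named by year")
  structure(list(sex = sex, breed_category = breed_category,
                 intercept = intercept,
                 segment_slopes = as.numeric(segment_slopes),
                 break_points = break_points,
                 month_effects = as.numeric(month_effects),
                 year_effects = year_effects,
                 noise_sd = noise_sd, units = units),
            class = "growth_truth")
}

#' @export
print.growth_truth <- function(x, ...) {
  cat(sprintf("<growth_truth> %s %s (%s): intercept %.1f, breaks [%s]\n",
              x$sex, x$breed_category, x$units, x$intercept,
              paste(x$break_points, collapse = ", ")))
  invisible(x)
}

#' Continuous piecewise-linear mean
#'
#' @param age_days numeric ages (days).
#' @param intercept value at age 0.
#' @param segment_slopes slopes per segment (length K + 1).
#' @param break_points K strictly increasing break ages.
#' @return numeric of `length(age_days)`.
#' @export
piecewise_mean <- function(age_days, intercept, segment_slopes, break_points) {
  y <- intercept + segment_slopes[1L] * age_days
  if (length(break_points)) {
    deltas <- diff(segment_slopes)
    for (k in seq_along(break_points))
      y <- y + deltas[k] * pmax(age_days - break_points[k], 0)
  }
  y
}

#' Evaluate a ground-truth mean, including calendar effects
#'
#' @param truth a [growth_truth()].
#' @param age_days ages in days.
#' @param month calendar month 1-12 (recycled).
#' @param year calendar year (recycled); years absent from the truth's
#'   `year_effects` contribute 0.
#' @return numeric mean response.
#' @export
truth_mean <- function(truth, age_days, month = NULL, year = NULL) {
  y <- piecewise_mean(age_days, truth$intercept, truth$segment_slopes,
                      truth$break_points)
  if (!is.null(month)) y <- y + truth$month_effects[month]
  if (!is.null(year)) {
    ye <- truth$year_effects[as.character(year)]
    ye[is.na(ye)] <- 0
    y <- y + as.numeric(ye)
  }
  y
}

breed_categories <- function() c("dairy", "continental_beef", "british_irish_beef")

# Breed-category mean offsets (kg or EUR) applied on top of the sex-level
# baseline curve, so that the fitted model's additive breed dummies have an
# exact generative counterpart. Dairy is the reference level.
default_breed_offsets <- function(units = c("kg", "eur")) {
  units <- match.arg(units)
  if (units == "kg")
    c(dairy = 0, continental_beef = 60, british_irish_beef = 25)
  else
    c(dairy = 0, continental_beef = 140, british_irish_beef = 60)
}

#' Default ground-truth curves for the synthetic cattle population
#'
#' One truth per sex and breed category. Within a sex all breed categories
#' share the break-point positions and slopes and differ by an additive
#' intercept offset, mirroring the additive structure of the fitted models.
#' The break positions are two per curve: 608/1878 days (female) and
#' 713/1884 days (male) for liveweight, 682/1254 days (female) and
#' 335/1041 days (male) for value. Slopes and intercepts are set to produce
#' realistic Irish cattle trajectories (about 40 kg at birth, roughly
#' 0.85-1.0 kg/day early growth, mature cows near 850 kg; values rising to
#' a plateau around first calving then slowly declining toward cull age).
#'
#' @param response `"liveweight"` or `"value"`.
#' @param noise_sd residual SD (kg or EUR); default 40 kg for liveweight and
#'   120 EUR for value.
#' @param years years for which linear year offsets are defined.
#' @return named list of [growth_truth()] objects, keyed `"sex.breed"`.
#' @export
default_truths <- function(response = c("liveweight", "value"),
                           noise_sd = NULL, years = 2011:2021) {
  response <- match.arg(response)
  pars <- if (response == "liveweight") list(
    female = list(intercept = 40, slopes = c(0.85, 0.22, 0.010),
                  breaks = c(608, 1878)),
    male = list(intercept = 45, slopes = c(1.00, 0.25, 0.015),
                breaks = c(713, 1884)),
    units = "kg", noise = 40,
    month_amp = 6, year_step = 2
  ) else list(
    female = list(intercept = 120, slopes = c(1.60, 0.35, -0.15),
                  breaks = c(682, 1254)),
    male = list(intercept = 150, slopes = c(2.20, 0.70, -0.05),
                breaks = c(335, 1041)),
    units = "eur", noise = 120,
    month_amp = 25, year_step = 15
  )
  if (is.null(noise_sd)) noise_sd <- pars$noise
  month_eff <- pars$month_amp * sin(2 * pi * (1:12 - 3) / 12)
  year_eff <- stats::setNames(pars$year_step * (years - years[1L]),
                              as.character(years))
  offs <- default_breed_offsets(pars$units)
  out <- list()
  for (sex in c("female", "male")) {
    p <- pars[[sex]]
    for (bc in breed_categories()) {
      out[[paste(sex, bc, sep = ".")]] <- growth_truth(
        sex = sex, breed_category = bc,
        intercept = p$intercept + offs[[bc]],
        segment_slopes = p$slopes, break_points = p$breaks,
        month_effects = month_eff, year_effects = year_eff,
        noise_sd = noise_sd, units = pars$units)
    }
  }
  out
}

truth_lookup <- function(truths, sex, breed_category) {
  key <- paste(sex, breed_category, sep = ".")
  tr <- truths[[key]]
  if (is.null(tr))
    stop_config("truth set is missing the %s combination", key)
  tr
}
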