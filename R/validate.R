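# Validation of the value model against category-labelled market data, and
# reference biomass denominators (LSU / TLU / PCU) for comparison with the
# model-based biomass.

#' Default market-category to age-range map
#'
#' Market records carry an animal category instead of a date of birth; the
#' value model is validated by predicting over each category's age range.
#' These ranges are plausible industry conventions shipped as replaceable
#' configuration (`inst/extdata/category_age_map.csv`), not an official
#' mapping.
#'
#' @return data.frame: `animal_category`, `sector` (dairy/beef), `sex`,
#'   `min_months`, `max_months`.
#' @export
default_category_age_map <- function() {
  path <- system.file("extdata", "category_age_map.csv",
                      package = "herdmass", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference-animal unit constants
#'
#' One livestock unit (LSU) corresponds to 650 kg liveweight, one tropical
#' livestock unit (TLU) to 250 kg, and the population correction unit
#' (PCU) assigns 450 kg to an adult cow.
#'
#' @return named list `lsu_kg`, `tlu_kg`, `pcu_adult_cow_kg`.
#' @export
unit_constants <- function() {
  list(lsu_kg = 650, tlu_kg = 250, pcu_adult_cow_kg = 450)
}

#' Mean model-predicted value over a market category's age range
#'
#' Predicts the value at each integer month of age in the category's range
#' (ages taken as `months * 30.4375` days), with month and year fixed at
#' the supplied medians, and averages the predictions unweighted.
#'
#' @param fit a value [segfit()] for the category's sex.
#' @param category animal category present in `map`.
#' @param map a [default_category_age_map()].
#' @param median_month,median_year covariate levels for the prediction.
#' @param breed_category breed category to predict for.
#' @return mean predicted value (EUR).
#' @export
predicted_category_mean <- function(fit, category, map = default_category_age_map(),
                                    median_month, median_year,
                                    breed_category) {
  row <- map[map$animal_category == category, , drop = FALSE]
  if (!nrow(row)) stop_config("category %s absent from age map", category)
  months <- seq(row$min_months[1L], row$max_months[1L])
  nd <- data.frame(age_days = months * 30.4375,
                   breed_category = breed_category,
                   month = median_month, year = median_year)
  mean(predict(fit, nd))
}

#' Validate the value model against market records
#'
#' For every sector/category cell in the market table: the market mean
#' price, the model's mean predicted value over the category's age range
#' (month and year fixed at the sale-date medians of the market table),
#' and their signed relative difference `predicted / market - 1`. The
#' within-10-percent screen is reported as `within_10pct`.
#'
#' @param fits list of value [segfit()]s named `female` and `male`.
#' @param market a market-record table (see [generate_market_records()]).
#' @param map a [default_category_age_map()]; market categories missing
#'   from it are listed in the `unmapped` attribute and excluded.
#' @param breed_for_sector breed category used to predict each sector;
#'   default dairy sector -> dairy, beef sector -> continental beef.
#' @return comparison data.frame: `sector`, `animal_category`,
#'   `market_mean`, `predicted`, `rel_diff`, `within_10pct`, `n`.
#' @export
validate_value_model <- function(fits, market,
                                 map = default_category_age_map(),
                                 breed_for_sector = c(
                                   dairy = "dairy",
                                   beef = "continental_beef")) {
  if (!nrow(market)) stop_config("market table is empty")
  med_month <- stats::median(date_month(market$sale_date))
  med_year <- stats::median(date_year(market$sale_date))
  unmapped <- setdiff(unique(market$animal_category), map$animal_category)
  mk <- market[market$animal_category %in% map$animal_category, ,
               drop = FALSE]
  cells <- unique(mk[, c("sector", "animal_category")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sec <- cells$sector[i]; cat <- cells$animal_category[i]
    sub <- mk[mk$sector == sec & mk$animal_category == cat, ]
    sex <- map$sex[map$animal_category == cat][1L]
    pred <- predicted_category_mean(fits[[sex]], cat, map, med_month,
                                    med_year, breed_for_sector[[sec]])
    data.frame(sector = sec, animal_category = cat,
               market_mean = mean(sub$price), predicted = pred,
               rel_diff = pred / mean(sub$price) - 1,
               n = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$within_10pct <- abs(out$rel_diff) <= 0.10
  out <- out[order(out$sector, out$animal_category), ]
  rownames(out) <- NULL
  attr(out, "median_month") <- med_month
  attr(out, "median_year") <- med_year
  attr(out, "unmapped") <- unmapped
  out
}

#' Reference biomass from head counts
#'
#' Converts head counts into kg using a coefficient-based denominator:
#' LSU mode multiplies per-category LSU coefficients by 650 kg, TLU mode
#' counts 250 kg per head, PCU mode multiplies per-category standard
#' weights (450 kg for an adult cow).
#'
#' @param head_counts named numeric: heads per animal category.
#' @param mode `"lsu"`, `"tlu"` or `"pcu"`.
#' @param coefficients per-category LSU coefficients (lsu mode) or kg
#'   weights (pcu mode); every counted category must be present.
#' @param constants see [unit_constants()].
#' @return total kg.
#' @export
reference_biomass <- function(head_counts,
                              mode = c("lsu", "tlu", "pcu"),
                              coefficients = NULL,
                              constants = unit_constants()) {
  mode <- match.arg(mode)
  if (any(head_counts < 0)) stop_config("head counts must be >= 0")
  if (mode == "tlu") return(sum(head_counts) * constants$tlu_kg)
  if (is.null(coefficients))
    coefficients <- if (mode == "lsu") default_lsu_coefficients()
                    else default_pcu_weights(constants)
  missing_cat <- setdiff(names(head_counts), names(coefficients))
  if (length(missing_cat))
    stop_config("no %s coefficient for category: %s", mode,
                paste(missing_cat, collapse = ", "))
  co <- coefficients[names(head_counts)]
  if (mode == "lsu") sum(head_counts * co) * constants$lsu_kg
  else sum(head_counts * co)
}

#' Default per-category coefficients for reference biomass
#'
#' EU farm-structure LSU coefficients for cattle (adult cow 1.0, other
#' bovines two years and over 1.0, one-to-two-year-olds 0.7, under one
#' year 0.4) and PCU-style standard weights in kg (adult cow 450). Both
#' are replaceable configuration.
#'
#' @return named numeric vector.
#' @export
default_lsu_coefficients <- function() {
  c(adult_cow = 1.0, bovine_over_2y = 1.0, bovine_1_2y = 0.7,
    bovine_under_1y = 0.4)
}

#' @rdname default_lsu_coefficients
#' @param constants see [unit_constants()].
#' @export
default_pcu_weights <- function(constants = unit_constants()) {
  c(adult_cow = constants$pcu_adult_cow_kg, bovine_over_2y = 420,
    bovine_1_2y = 200, bovine_under_1y = 80)
}
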