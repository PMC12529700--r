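# Synthetic slaughter-valuation, livestock-market and CPI generators.
# Every dataset is produced from explicit ground-truth parameters so that
# downstream estimates can be checked against a known generative model.

# Animal classes recorded at slaughter valuation, with the sex and the age
# window (days) each class is drawn from. "either" is resolved 50/50.
slaughter_class_table <- function() {
  data.frame(
    animal_class = c("calf", "heifer", "steer", "bull", "cow",
                     "pregnant_heifer"),
    sex = c("either", "female", "male", "male", "female", "female"),
    age_min = c(30, 365, 365, 730, 1095, 550),
    age_max = c(364, 800, 1100, 3200, 4200, 1050),
    stringsAsFactors = FALSE
  )
}

breed_codes_by_category <- function() {
  list(dairy = c("FR", "HO", "JE"),
       continental_beef = c("CH", "LM", "SI", "BB"),
       british_irish_beef = c("AA", "HE", "SH"))
}

#' Generate synthetic slaughter-valuation records
#'
#' Emulates a bTB-programme valuation dataset: one weighed and valued animal
#' per row, with liveweight and value drawn from piecewise-linear
#' ground-truth curves ([growth_truth()]) plus calendar effects and Gaussian
#' noise. Equal numbers are generated per animal class (calf, heifer, steer,
#' bull, cow, pregnant heifer).
#'
#' @param truth_w named list of liveweight truths covering both sexes and
#'   all three breed categories (see [default_truths()]).
#' @param truth_v named list of value truths, same coverage.
#' @param n_per_class records per animal class (>= 1).
#' @param seed integer seed; identical inputs give identical tables.
#' @param years calendar years slaughter dates are drawn from.
#' @param cross_frac fraction of records recorded under a cross code
#'   (sire code + "X"), resolved by the cleaning rules.
#' @param heteroscedastic if `TRUE`, the residual SD is
#'   `noise_sd / 100 * mean` instead of constant `noise_sd`.
#' @return data.frame with columns `animal_id`, `breed_code`,
#'   `sire_breed_code`, `animal_class`, `sex`, `date_of_birth`,
#'   `date_of_death`, `liveweight`, `value`.
#' @export
generate_slaughter_records <- function(truth_w, truth_v, n_per_class,
                                       seed = 1L, years = 2011:2021,
                                       cross_frac = 0.15,
                                       heteroscedastic = FALSE) {
  if (n_per_class < 1) stop_config("n_per_class must be >= 1")
  for (sex in c("female", "male"))
    for (bc in breed_categories()) {
      truth_lookup(truth_w, sex, bc)
      truth_lookup(truth_v, sex, bc)
    }
  classes <- slaughter_class_table()
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(classes)), function(i) {
      cl <- classes[i, ]
      sex <- if (cl$sex == "either")
        sample(c("female", "male"), n_per_class, replace = TRUE)
      else rep(cl$sex, n_per_class)
      data.frame(animal_class = cl$animal_class, sex = sex,
                 age_days = round(stats::runif(n_per_class, cl$age_min,
                                               cl$age_max)),
                 stringsAsFactors = FALSE)
    }))
    n <- nrow(rows)
    rows$animal_id <- sprintf("S%06d", seq_len(n))
    bc <- sample(breed_categories(), n, replace = TRUE)
    codes <- breed_codes_by_category()
    sire <- vapply(bc, function(b) sample(codes[[b]], 1L), "")
    is_cross <- stats::runif(n) < cross_frac
    rows$breed_code <- ifelse(is_cross, paste0(sire, "X"), sire)
    rows$sire_breed_code <- ifelse(is_cross, sire, NA_character_)
    date_lo <- as.Date(sprintf("%d-01-01", min(years)))
    date_hi <- as.Date(sprintf("%d-12-31", max(years)))
    rows$date_of_death <- date_lo +
      round(stats::runif(n, 0, as.numeric(date_hi - date_lo)))
    rows$date_of_birth <- rows$date_of_death - rows$age_days
    mth <- date_month(rows$date_of_death)
    yr <- date_year(rows$date_of_death)
    draw <- function(truths) {
      mu <- numeric(n)
      for (key in names(truths)) {
        tr <- truths[[key]]
        idx <- rows$sex == tr$sex & bc == tr$breed_category
        if (!any(idx)) next
        mu[idx] <- truth_mean(tr, rows$age_days[idx], mth[idx], yr[idx])
      }
      sd0 <- truths[[1L]]$noise_sd
      sds <- if (heteroscedastic) pmax(sd0 / 100 * mu, 0) else sd0
      mu + stats::rnorm(n, 0, sds)
    }
    rows$liveweight <- draw(truth_w)
    rows$value <- draw(truth_v)
    rows[, c("animal_id", "breed_code", "sire_breed_code", "animal_class",
             "sex", "date_of_birth", "date_of_death", "liveweight", "value")]
  })
}

#' Generate synthetic livestock-market price records
#'
#' Emulates weekly mart price returns: each record carries a sale date,
#' an animal category (never a date of birth), breed code, sex and price.
#' The latent age behind each record is allocated round-robin over the
#' integer months of the category's age range and is exposed in a
#' `latent_age_days` column for generator-level checks only; a real market
#' dataset would not contain it.
#'
#' @param truth_v named list of value truths (see [default_truths()]).
#' @param category_age_map data.frame from [default_category_age_map()]:
#'   columns `animal_category`, `sector`, `sex`, `min_months`, `max_months`.
#' @param n number of records (> 0), spread evenly over categories.
#' @param seed integer seed.
#' @param years calendar years sale dates are drawn from.
#' @param beef_breeds breed categories the beef-sector records draw from.
#' @return data.frame of market records.
#' @export
generate_market_records <- function(truth_v, category_age_map, n, seed = 1L,
                                    years = 2011:2021,
                                    beef_breeds = c("continental_beef",
                                                    "british_irish_beef")) {
  if (n <= 0) stop_config("n must be positive")
  m <- category_age_map
  if (any(m$max_months < m$min_months))
    stop_config("category_age_map has an empty age range")
  with_seed(seed, {
    cat_idx <- rep(seq_len(nrow(m)), length.out = n)
    codes <- breed_codes_by_category()
    rows <- lapply(seq_len(nrow(m)), function(i) {
      ni <- sum(cat_idx == i)
      if (!ni) return(NULL)
      months <- rep(seq(m$min_months[i], m$max_months[i]), length.out = ni)
      bc <- if (m$sector[i] == "dairy") rep("dairy", ni)
            else if (length(beef_breeds) == 1L) rep(beef_breeds, ni)
            else sample(beef_breeds, ni, replace = TRUE)
      data.frame(animal_category = m$animal_category[i], sector = m$sector[i],
                 sex = m$sex[i], breed_category = bc,
                 age_months = months, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    n <- nrow(rows)
    rows$breed_code <- vapply(rows$breed_category,
                              function(b) sample(codes[[b]], 1L), "")
    date_lo <- as.Date(sprintf("%d-01-01", min(years)))
    date_hi <- as.Date(sprintf("%d-12-31", max(years)))
    rows$sale_date <- date_lo +
      round(stats::runif(n, 0, as.numeric(date_hi - date_lo)))
    rows$latent_age_days <- rows$age_months * 30.4375
    mu <- numeric(n)
    for (key in names(truth_v)) {
      tr <- truth_v[[key]]
      idx <- rows$sex == tr$sex & rows$breed_category == tr$breed_category
      if (!any(idx)) next
      mu[idx] <- truth_mean(tr, rows$latent_age_days[idx],
                            date_month(rows$sale_date[idx]),
                            date_year(rows$sale_date[idx]))
    }
    rows$price <- mu + stats::rnorm(n, 0, truth_v[[1L]]$noise_sd)
    rows[, c("sale_date", "animal_category", "sector", "breed_code", "sex",
             "price", "latent_age_days")]
  })
}

#' Generate a synthetic consumer price index series
#'
#' Monthly index with geometric drift, normalised so the base period is
#' exactly 100. The annual view is the December (end-of-year) value: stock
#' value is a point-in-time quantity, so annual deflation uses the
#' end-of-year price level (a mean-of-months annual view is available via
#' `annual_method = "mean"`).
#'
#' @param start,end first/last month, `"YYYY-MM"`.
#' @param base_period month with index 100, `"YYYY-MM"`; must lie in range.
#' @param annual_drift fractional drift per year (0.02 = 2 %/yr).
#' @param monthly_noise_sd SD of multiplicative log-normal month noise.
#' @param seed integer seed (only matters when `monthly_noise_sd > 0`).
#' @param annual_method `"december"` or `"mean"`.
#' @return object of class `cpi_series`: list with `monthly` (year, month,
#'   index), `annual` (year, index) and `base_period`.
#' @export
generate_cpi_series <- function(start = "2011-01", end = "2021-12",
                                base_period = "2011-12", annual_drift = 0.02,
                                monthly_noise_sd = 0, seed = 1L,
                                annual_method = c("december", "mean")) {
  annual_method <- match.arg(annual_method)
  months <- month_starts(as.Date(paste0(start, "-01")),
                         as.Date(paste0(end, "-01")))
  base <- as.Date(paste0(base_period, "-01"))
  if (!base %in% months)
    stop_config("base_period %s outside series range", base_period)
  t_months <- 12 * (date_year(months) - date_year(base)) +
    (date_month(months) - date_month(base))
  idx <- 100 * (1 + annual_drift)^(t_months / 12)
  if (monthly_noise_sd > 0)
    idx <- with_seed(seed,
      idx * exp(stats::rnorm(length(idx), 0, monthly_noise_sd)))
  idx <- idx * 100 / idx[months == base]  # base exactly 100
  monthly <- data.frame(year = date_year(months), month = date_month(months),
                        index = idx)
  annual <- if (annual_method == "december")
    monthly[monthly$month == 12L, c("year", "index")]
  else
    stats::aggregate(index ~ year, monthly, mean)
  rownames(annual) <- NULL
  structure(list(monthly = monthly, annual = annual,
                 base_period = base_period, annual_method = annual_method),
            class = "cpi_series")
}

#' @export
print.cpi_series <- function(x, ...) {
  cat(sprintf("<cpi_series> %d months, base %s = 100 (annual = %s)\n",
              nrow(x$monthly), x$base_period, x$annual_method))
  invisible(x)
}

#' Look up a CPI index value
#'
#' @param cpi a [generate_cpi_series()] object.
#' @param year calendar year.
#' @param month calendar month; omit (`NULL`) for the annual index.
#' @return numeric index value(s).
#' @export
cpi_index <- function(cpi, year, month = NULL) {
  if (is.null(month)) {
    out <- cpi$annual$index[match(year, cpi$annual$year)]
  } else {
    key <- paste(year, month)
    out <- cpi$monthly$index[match(key, paste(cpi$monthly$year,
                                              cpi$monthly$month))]
  }
  if (anyNA(out)) stop_config("period outside the CPI series range")
  out
}
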