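# Apply the fitted liveweight and value models to every snapshot member,
# aggregate biomass (kg) and stock value (EUR) by herd, herd type and
# sector, and deflate nominal values to real prices with the CPI.

#' Predict liveweight and value for every snapshot member
#'
#' @param fits list with elements `liveweight` and `value`, each a list of
#'   [segfit()] objects named `female` and `male`.
#' @param snaps a [build_snapshots()] table.
#' @param breed_map a [breed_map()].
#' @param weight_floor minimum admissible prediction; lower (or negative)
#'   predictions are floored here with a warning.
#' @return data.frame of per-animal predictions: `animal_id`, `herd_id`,
#'   `snapshot_date`, `predicted_liveweight`, `predicted_value_nominal`;
#'   animals with unmappable breed codes are skipped and counted in the
#'   `n_skipped_breed` attribute.
#' @export
predict_population <- function(fits, snaps, breed_map = default_breed_map(),
                               weight_floor = 1) {
  stopifnot(all(c("liveweight", "value") %in% names(fits)))
  bc <- resolve_breed(snaps$breed_code, breed_map)
  keep <- !is.na(bc)
  n_skipped <- sum(!keep)
  s <- snaps[keep, , drop = FALSE]
  bc <- bc[keep]
  nd <- data.frame(age_days = s$age_days, breed_category = bc,
                   month = date_month(s$snapshot_date),
                   year = date_year(s$snapshot_date),
                   stringsAsFactors = FALSE)
  pred_one <- function(response) {
    out <- numeric(nrow(s))
    for (sex in c("female", "male")) {
      fit <- fits[[response]][[sex]]
      if (is.null(fit)) stop_config("missing %s fit for %s", response, sex)
      idx <- s$sex == sex
      if (any(idx)) out[idx] <- predict(fit, nd[idx, , drop = FALSE])
    }
    low <- out < weight_floor
    if (any(low)) {
      warning(sprintf("%d %s predictions floored at %g", sum(low),
                      response, weight_floor), call. = FALSE)
      out[low] <- weight_floor
    }
    out
  }
  res <- data.frame(animal_id = s$animal_id, herd_id = s$herd_id,
                    snapshot_date = s$snapshot_date,
                    predicted_liveweight = pred_one("liveweight"),
                    predicted_value_nominal = pred_one("value"),
                    stringsAsFactors = FALSE)
  attr(res, "n_skipped_breed") <- n_skipped
  res
}

#' Herd-by-month biomass and stock-value totals
#'
#' @param predictions a [predict_population()] table.
#' @param cpi optional [generate_cpi_series()]; when given, monthly real
#'   values are added using the monthly index.
#' @return data.frame, one row per herd and snapshot month: `herd_id`,
#'   `year`, `month`, `biomass_kg`, `value_nominal_eur`, `n_animals`, and
#'   `value_real_eur` when a CPI is supplied.
#' @export
herd_month_totals <- function(predictions, cpi = NULL) {
  key <- paste(predictions$herd_id, predictions$snapshot_date)
  agg <- stats::aggregate(
    cbind(biomass_kg = predicted_liveweight,
          value_nominal_eur = predicted_value_nominal) ~ herd_id +
      snapshot_date, data = predictions, FUN = sum)
  cnt <- stats::aggregate(list(n_animals = predictions$animal_id),
                          by = list(herd_id = predictions$herd_id,
                                    snapshot_date = predictions$snapshot_date),
                          FUN = length)
  out <- merge(agg, cnt, by = c("herd_id", "snapshot_date"))
  out$year <- date_year(out$snapshot_date)
  out$month <- date_month(out$snapshot_date)
  if (!is.null(cpi))
    out$value_real_eur <- deflate(out$value_nominal_eur, cpi,
                                  year = out$year, month = out$month)
  out <- out[order(out$herd_id, out$snapshot_date), ]
  rownames(out) <- NULL
  out
}

join_type <- function(totals, classifications) {
  m <- match(paste(totals$herd_id, totals$year),
             paste(classifications$herd_id, classifications$year))
  type <- classifications$herd_type[m]
  subtype <- classifications$subtype[m]
  type[is.na(type)] <- "unclassified"
  subtype[is.na(subtype)] <- "none"
  cbind(totals, herd_type = type, herd_subtype = subtype,
        stringsAsFactors = FALSE)
}

#' Within-year biomass/value profile by herd type
#'
#' For each herd type and calendar month, the mean herd-month total across
#' herds and study years — the seasonal profile of an average herd of that
#' type. Unclassified herds are reported under "unclassified".
#'
#' @param totals a [herd_month_totals()] table.
#' @param classifications a [classify_all()] table.
#' @param by `"herd_type"` or `"herd_subtype"`.
#' @return data.frame: grouping key, `month`, mean `biomass_kg`,
#'   mean `value_nominal_eur` (and mean `value_real_eur` if present),
#'   `n_herd_months`.
#' @export
within_year_profile <- function(totals, classifications, by = "herd_type") {
  t2 <- join_type(totals, classifications)
  vals <- intersect(c("biomass_kg", "value_nominal_eur", "value_real_eur"),
                    names(t2))
  g <- list(key = t2[[by]], month = t2$month)
  out <- stats::aggregate(t2[vals], by = g, FUN = mean)
  cnt <- stats::aggregate(list(n_herd_months = t2$herd_id), by = g,
                          FUN = length)
  out <- merge(out, cnt, by = c("key", "month"))
  names(out)[1L] <- by
  out[order(out[[1L]], out$month), ]
}

#' Annual herd, herd-type and sector aggregates
#'
#' A herd's annual figure is the mean of its monthly totals over all
#' snapshot months of that year, counting months in which the herd held no
#' animals as zero (an alternative mean over occupied months is available
#' via `empty_months_zero = FALSE`). Herd-type averages are means of herd
#' annual figures; the sector total is their sum across all herds
#' (equivalently the sum of type-level sums). A mean-of-monthly-national-
#' totals sector series is also returned for comparison.
#'
#' @param totals a [herd_month_totals()] table.
#' @param classifications a [classify_all()] table.
#' @param cpi optional CPI; annual real values use the annual index.
#' @param empty_months_zero count empty herd-months as zero.
#' @return list of data.frames: `herd` (annual average per herd),
#'   `herd_type` (average and total per type-year, with `n_herds`),
#'   `sector` (national totals per year, both definitions).
#' @export
annual_and_sector <- function(totals, classifications, cpi = NULL,
                              empty_months_zero = TRUE) {
  months_per_year <- stats::aggregate(
    list(n_months = totals$month),
    by = list(year = totals$year),
    FUN = function(m) length(unique(m)))
  t2 <- join_type(totals, classifications)
  vals <- c("biomass_kg", "value_nominal_eur")
  sums <- stats::aggregate(t2[vals],
                           by = list(herd_id = t2$herd_id, year = t2$year,
                                     herd_type = t2$herd_type),
                           FUN = sum)
  occ <- stats::aggregate(list(n_occupied = t2$month),
                          by = list(herd_id = t2$herd_id, year = t2$year),
                          FUN = length)
  herd <- merge(sums, occ, by = c("herd_id", "year"))
  herd <- merge(herd, months_per_year, by = "year")
  denom <- if (empty_months_zero) herd$n_months else herd$n_occupied
  for (v in vals) herd[[v]] <- herd[[v]] / denom
  if (!is.null(cpi))
    herd$value_real_eur <- deflate(herd$value_nominal_eur, cpi,
                                   year = herd$year)
  vals2 <- intersect(c(vals, "value_real_eur"), names(herd))
  htype <- stats::aggregate(herd[vals2],
                            by = list(herd_type = herd$herd_type,
                                      year = herd$year), FUN = mean)
  names(htype)[match(vals2, names(htype))] <- paste0("avg_", vals2)
  tsum <- stats::aggregate(herd[vals2],
                           by = list(herd_type = herd$herd_type,
                                     year = herd$year), FUN = sum)
  names(tsum)[match(vals2, names(tsum))] <- paste0("total_", vals2)
  nh <- stats::aggregate(list(n_herds = herd$herd_id),
                         by = list(herd_type = herd$herd_type,
                                   year = herd$year), FUN = length)
  htype <- Reduce(function(a, b) merge(a, b, by = c("herd_type", "year")),
                  list(htype, tsum, nh))
  sector <- stats::aggregate(herd[vals2], by = list(year = herd$year),
                             FUN = sum)
  names(sector)[match(vals2, names(sector))] <- paste0("total_", vals2)
  # alternative: annual mean of the monthly national sums
  nat <- stats::aggregate(t2[vals], by = list(year = t2$year,
                                              month = t2$month), FUN = sum)
  nat_mean <- stats::aggregate(nat[vals], by = list(year = nat$year),
                               FUN = mean)
  names(nat_mean)[match(vals, names(nat_mean))] <-
    paste0("monthly_mean_", vals)
  sector <- merge(sector, nat_mean, by = "year")
  list(herd = herd[order(herd$herd_id, herd$year), ],
       herd_type = htype[order(htype$herd_type, htype$year), ],
       sector = sector[order(sector$year), ])
}

#' Deflate nominal values with the CPI
#'
#' `real = nominal * 100 / index(period)`: monthly index when `month` is
#' given, annual index otherwise. At the base period (index 100) nominal
#' and real coincide.
#'
#' @param value_nominal numeric EUR.
#' @param cpi a [generate_cpi_series()] (or compatible `cpi_series`).
#' @param year,month the price period; errors outside the CPI range.
#' @return numeric real EUR.
#' @export
deflate <- function(value_nominal, cpi, year, month = NULL) {
  value_nominal * 100 / cpi_index(cpi, year, month)
}

#' Convert reporting units
#'
#' Biomass is carried in kg and value in EUR throughout; conversion to
#' thousand tonnes and EUR million happens only at the reporting boundary.
#'
#' @param kg,eur numeric.
#' @return numeric in '000 tonnes / EUR million.
#' @export
kg_to_kilotonnes <- function(kg) kg * 1e-6

#' @rdname kg_to_kilotonnes
#' @export
eur_to_millions <- function(eur) eur * 1e-6
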