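# Herd typology: each herd-year is assigned a functional type (beef,
# dairy, fattening, store/rearing, mixed, trading, unclassified) and
# subtype from its January, May and September snapshots plus that year's
# event flows, via an ordered decision tree with configurable thresholds.

#' Load the herd-classification rule thresholds
#'
#' @param path JSON file of named thresholds; default the packaged rule
#'   set (`inst/extdata/classifier_rules.json`).
#' @return named list of thresholds, class `classifier_rules`.
#' @export
default_classifier_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "classifier_rules.json",
                        package = "herdmass", mustWork = TRUE)
  rules <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules$comment <- NULL
  structure(rules, class = "classifier_rules")
}

#' Herd composition features for one herd-year
#'
#' Averages head counts over the January, May and September snapshots
#' (missing census months count as missing, not zero) and summarises the
#' year's event flows: births in the herd, move-in/out counts, inflow ages
#' and mean stay length of animals that both arrived and left within the
#' year, and on-site deaths.
#'
#' @param snaps a [build_snapshots()] table restricted to one herd.
#' @param events event table restricted to the same herd.
#' @param year calendar year.
#' @param breed_map a [breed_map()].
#' @param adult_age_days age separating youngstock from adults.
#' @return one-row data.frame of features.
#' @export
herd_features <- function(snaps, events, year, breed_map = default_breed_map(),
                          adult_age_days = 730) {
  census <- c(1L, 5L, 9L)
  snaps <- snaps[date_year(snaps$snapshot_date) == year &
                   date_month(snaps$snapshot_date) %in% census, , drop = FALSE]
  months_present <- unique(date_month(snaps$snapshot_date))
  n_census <- length(months_present)
  bc <- if (nrow(snaps)) resolve_breed(snaps$breed_code, breed_map)
        else character(0)
  dairy <- !is.na(bc) & bc == "dairy"
  adult <- snaps$age_days > adult_age_days
  fem <- snaps$sex == "female"
  avg <- function(x) if (n_census) sum(x) / n_census else 0
  ev <- events[date_year(events$event_date) == year, , drop = FALSE]
  ins <- ev[ev$event_kind == "move_in", ]
  outs <- ev[ev$event_kind == "move_out", ]
  thru <- intersect(ins$animal_id, outs$animal_id)
  stay <- if (length(thru)) {
    mean(vapply(thru, function(a)
      as.numeric(min(outs$event_date[outs$animal_id == a]) -
                   max(ins$event_date[ins$animal_id == a &
                                        ins$event_date <=
                                          min(outs$event_date[outs$animal_id == a])])),
      0), na.rm = TRUE)
  } else NA_real_
  data.frame(
    year = year, n_census_months = n_census,
    n_head = avg(rep(1, nrow(snaps))),
    n_adult_female = avg(adult & fem),
    n_adult_female_dairy = avg(adult & fem & dairy),
    n_adult_female_beef = avg(adult & fem & !dairy & !is.na(bc)),
    n_young = avg(!adult),
    n_young_female = avg(!adult & fem),
    n_young_dairy = avg(!adult & dairy),
    young_breed_purity = if (sum(!adult)) max(table(bc[!adult])) /
      sum(!adult) else NA_real_,
    breed_purity = if (nrow(snaps))
      max(table(snaps$breed_code)) / nrow(snaps) else NA_real_,
    frac_male = if (nrow(snaps)) mean(snaps$sex == "male") else NA_real_,
    births = sum(ev$event_kind == "birth"),
    n_in = nrow(ins), n_out = nrow(outs),
    deaths = sum(ev$event_kind == "death"),
    mean_stay_days = stay,
    mean_inflow_age = if (nrow(ins))
      mean(as.numeric(ins$event_date - ins$date_of_birth)) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Classify one herd-year from its features
#'
#' Ordered tree: herds with no data at any census month fall to the
#' throughput sub-rule (trading / fattening / unclassified); otherwise
#' calving herds split into mixed, dairy and beef on the breed make-up of
#' adult females, and non-calving herds into store/rearing (youngstock
#' dominated), trading (short-stay throughput) and fattening (inflow ending
#' in on-site slaughter). Subtypes follow the sex/breed mix and progeny
#' policy. Every path is recorded in `rule_trace`.
#'
#' @param features one-row data.frame from [herd_features()].
#' @param rules a [default_classifier_rules()] threshold set.
#' @return list with `herd_type`, `subtype`, `rule_trace`.
#' @export
classify_herd <- function(features, rules = default_classifier_rules()) {
  f <- features
  trace <- character(0)
  note <- function(id) trace <<- c(trace, id)
  result <- function(type, subtype = "none") {
    list(herd_type = type, subtype = subtype, rule_trace = trace)
  }
  if (f$n_census_months == 0L || f$n_head == 0) {
    note("no_census_data")
    moves <- f$n_in + f$n_out
    if (moves >= rules$trading_min_moves && !is.na(f$mean_stay_days) &&
        f$mean_stay_days <= rules$trading_max_stay_days) {
      note("fallback_trading"); return(result("trading"))
    }
    if (f$n_in >= rules$fattening_min_inflow && f$deaths > 0) {
      note("fallback_fattening"); return(result("fattening"))
    }
    note("fallback_unclassified"); return(result("unclassified"))
  }
  if (f$births >= rules$min_calvings && f$n_adult_female > 0) {
    note("calving_herd")
    dfrac <- f$n_adult_female_dairy / f$n_adult_female
    bfrac <- f$n_adult_female_beef / f$n_adult_female
    if (dfrac >= rules$mixed_min_frac && bfrac >= rules$mixed_min_frac) {
      note("mixed_cows"); return(result("mixed"))
    }
    if (dfrac >= rules$dairy_adult_female_frac) {
      note("dairy_cows")
      rearing <- f$n_young > 0
      if (!rearing) {
        sub <- if (f$n_in > 0) "DnR_C" else "DnR_nC"
        note("dairy_non_rearing"); return(result("dairy", sub))
      }
      male_young <- f$frac_male * f$n_head
      if (male_young / max(f$n_young, 1) >= rules$male_calf_rearing_frac &&
          f$frac_male > 0.1) {
        note("dairy_rearing_males"); return(result("dairy", "DRm"))
      }
      note("dairy_standard"); return(result("dairy", "D"))
    }
    note("beef_cows")
    if (!is.na(f$breed_purity) && f$breed_purity >= rules$beef_purity_bp) {
      note("beef_pedigree"); return(result("beef", "BP"))
    }
    sale_age <- sale_age_proxy(f)
    if (is.na(sale_age)) { note("beef_finishes_own"); return(result("beef", "BSB")) }
    if (sale_age <= rules$weanling_sale_age) {
      note("beef_sells_weanlings"); return(result("beef", "BSW"))
    }
    if (sale_age <= rules$youngstock_sale_age) {
      note("beef_sells_youngstock"); return(result("beef", "BSY"))
    }
    note("beef_finishes_own"); return(result("beef", "BSB"))
  }
  note("non_calving_herd")
  if (!is.na(f$mean_stay_days) &&
      f$mean_stay_days <= rules$trading_max_stay_days &&
      f$n_in + f$n_out >= rules$trading_min_moves) {
    note("short_stay_throughput"); return(result("trading"))
  }
  if (f$n_head > 0 && f$deaths == 0 &&
      f$n_young / f$n_head >= rules$store_young_frac) {
    note("store_rearing")
    dairy_frac <- f$n_young_dairy / max(f$n_young, 1)
    fem_frac <- f$n_young_female / max(f$n_young, 1)
    sub <- if (dairy_frac >= 0.5) {
      if (fem_frac >= 0.5) "Rdf" else "Sdm"
    } else if (fem_frac >= 0.7) "Sbf"
    else if (fem_frac <= 0.3) "Sbm"
    else "Sbmx"
    return(result("store_rearing", sub))
  }
  if (f$n_in >= rules$fattening_min_inflow && f$deaths > 0) {
    note("inflow_to_slaughter"); return(result("fattening"))
  }
  note("default_unclassified")
  result("unclassified")
}

# mean age at which home-born animals leave (move_out) — NA when the herd
# sells nothing
sale_age_proxy <- function(f) {
  if (!is.null(f$mean_sale_age)) f$mean_sale_age else NA_real_
}

#' Classify every herd for one or more years
#'
#' @param snaps full [build_snapshots()] table.
#' @param events full event table.
#' @param rules threshold set.
#' @param years years to classify; default every year in `snaps`.
#' @param breed_map a [breed_map()].
#' @return data.frame of class assignments: `herd_id`, `year`, `herd_type`,
#'   `subtype`, `rule_trace` (rule ids joined by ">").
#' @export
classify_all <- function(snaps, events, rules = default_classifier_rules(),
                         years = NULL, breed_map = default_breed_map()) {
  if (is.null(years))
    years <- sort(unique(date_year(snaps$snapshot_date)))
  herd_ids <- sort(unique(c(snaps$herd_id, events$herd_id)))
  ev_split <- split(seq_len(nrow(events)), events$herd_id)
  sn_split <- split(seq_len(nrow(snaps)), snaps$herd_id)
  out <- vector("list", length(herd_ids) * length(years))
  i <- 0L
  for (y in years) {
    for (h in herd_ids) {
      i <- i + 1L
      hs <- snaps[sn_split[[h]] %||% integer(0), , drop = FALSE]
      he <- events[ev_split[[h]] %||% integer(0), , drop = FALSE]
      f <- herd_features(hs, he, y, breed_map, rules$adult_age_days)
      f$mean_sale_age <- mean_sale_age(he, y)
      cl <- classify_herd(f, rules)
      out[[i]] <- data.frame(
        herd_id = h, year = y, herd_type = cl$herd_type,
        subtype = cl$subtype,
        rule_trace = paste(cl$rule_trace, collapse = ">"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(herd_id = character(0), year = integer(0),
                      herd_type = character(0), subtype = character(0),
                      rule_trace = character(0)))
  do.call(rbind, out)
}

# mean age (days) at move_out during the year for animals born in this herd
mean_sale_age <- function(herd_events, year) {
  born_here <- herd_events$animal_id[herd_events$event_kind == "birth"]
  outs <- herd_events[herd_events$event_kind == "move_out" &
                        date_year(herd_events$event_date) == year &
                        herd_events$animal_id %in% born_here, , drop = FALSE]
  if (!nrow(outs)) return(NA_real_)
  mean(as.numeric(outs$event_date - outs$date_of_birth))
}
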