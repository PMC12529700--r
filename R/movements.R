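# Synthetic registration/movement database: births, deaths and paired
# herd-to-herd moves for a population of herds built from archetypes.
# The event log is the single source of truth for population snapshots.

#' Herd archetype for the synthetic movement database
#'
#' Describes how a functional herd type behaves: how many breeding females
#' it holds, when they calve, which breeds it carries, and what happens to
#' progeny (retained, finished in-herd, or sold at a given age to rearing /
#' fattening herds). Store, fattening and trading herds are demand-driven:
#' they receive animals that breeding herds sell.
#'
#' @param herd_type one of beef, dairy, fattening, store_rearing, mixed,
#'   trading.
#' @param subtype subtype label (e.g. `"D"`, `"BSB"`, `"Rdf"`) or `"none"`.
#' @param count number of herds of this archetype.
#' @param size_median breeding females per herd (breeding types) — must be
#'   >= 1.
#' @param calving_month_distribution length-12 probabilities, summing to 1.
#' @param sale_age_window c(min, max) age in days at which sold progeny
#'   leave.
#' @param breed_mix named probabilities over breed categories, summing to 1.
#' @param sex_policy list of behavioural knobs: `retain_female_frac`,
#'   `male_stage` / `female_stage` (destination stage for sold calves:
#'   `"rearing_female"`, `"rearing_male"`, `"fattening"`, `"none"`),
#'   `finish_in_herd` (progeny slaughtered at home at `finish_age`),
#'   `cull_age`, `store_exit_age`, `hold_days`, `trade_stay_days`.
#' @return object of class `herd_archetype`.
#' @export
herd_archetype <- function(herd_type, subtype = "none", count = 1L,
                           size_median = 30,
                           calving_month_distribution = rep(1 / 12, 12),
                           sale_age_window = c(30, 60),
                           breed_mix = c(dairy = 1),
                           sex_policy = list()) {
  herd_type <- match.arg(herd_type, c("beef", "dairy", "fattening",
                                      "store_rearing", "mixed", "trading",
                                      "unclassified"))
  if (count < 1) stop_config("archetype count must be >= 1")
  if (size_median < 1) stop_config("size_median must be >= 1")
  if (abs(sum(calving_month_distribution) - 1) > 1e-9)
    stop_config("calving_month_distribution must sum to 1")
  if (abs(sum(breed_mix) - 1) > 1e-9)
    stop_config("breed_mix must sum to 1")
  if (!all(names(breed_mix) %in% breed_categories()))
    stop_config("breed_mix names must be breed categories")
  defaults <- list(retain_female_frac = 0, male_stage = "none",
                   female_stage = "none", finish_in_herd = FALSE,
                   finish_age = c(700, 800), cull_age = 3200,
                   store_exit_age = c(600, 680), hold_days = c(120, 180),
                   trade_stay_days = c(7, 21))
  sex_policy <- utils::modifyList(defaults, sex_policy)
  structure(list(herd_type = herd_type, subtype = subtype,
                 count = as.integer(count), size_median = size_median,
                 calving_month_distribution = calving_month_distribution,
                 sale_age_window = sale_age_window, breed_mix = breed_mix,
                 sex_policy = sex_policy),
            class = "herd_archetype")
}

#' Default archetype mix for the synthetic national population
#'
#' A small working model of the sector: spring-calving dairy herds selling
#' surplus calves to rearing herds, suckler beef herds finishing their own
#' stock, dairy-female rearing herds (with the characteristic October
#' biomass peak), fattening herds slaughtering bought-in stores, and
#' short-stay trading herds.
#'
#' @param scale multiplies every archetype's herd count.
#' @return list of [herd_archetype()] objects.
#' @export
default_archetypes <- function(scale = 1) {
  spring <- c(2, 5, 5, 3, 1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 1)
  spring <- spring / sum(spring)
  late_spring <- c(0.5, 1, 4, 5, 4, 2, 1, 0.5, 0.5, 0.5, 0.5, 0.5)
  late_spring <- late_spring / sum(late_spring)
  n <- function(k) max(1L, as.integer(round(k * scale)))
  list(
    herd_archetype("dairy", "D", count = n(12), size_median = 60,
                   calving_month_distribution = spring,
                   sale_age_window = c(25, 60),
                   breed_mix = c(dairy = 0.9, british_irish_beef = 0.1),
                   sex_policy = list(retain_female_frac = 0.25,
                                     male_stage = "rearing_male",
                                     female_stage = "rearing_female")),
    herd_archetype("beef", "BSB", count = n(25), size_median = 25,
                   calving_month_distribution = late_spring,
                   breed_mix = c(continental_beef = 0.6,
                                 british_irish_beef = 0.4),
                   sex_policy = list(retain_female_frac = 0.15,
                                     finish_in_herd = TRUE)),
    herd_archetype("store_rearing", "Rdf", count = n(6),
                   breed_mix = c(dairy = 1),
                   sex_policy = list(store_exit_age = c(600, 680))),
    herd_archetype("store_rearing", "Sdm", count = n(4),
                   breed_mix = c(dairy = 1),
                   sex_policy = list(store_exit_age = c(450, 550))),
    herd_archetype("fattening", "none", count = n(6),
                   sex_policy = list(hold_days = c(120, 180))),
    herd_archetype("trading", "none", count = n(2),
                   sex_policy = list(trade_stay_days = c(7, 21)))
  )
}

# month weights for routing a transfer through a trading herd: marts are
# busiest in spring and autumn.
trading_month_weights <- function() {
  c(0.05, 0.10, 0.45, 0.45, 0.10, 0.05, 0.05, 0.10, 0.45, 0.45, 0.10, 0.05)
}

#' Generate a synthetic registration and movement event database
#'
#' Simulates the life events of every animal in a population of herds built
#' from archetypes over a span of calendar years: exactly one birth per
#' animal, paired move-out/move-in events for every transfer (optionally
#' routed through a trading herd), and death events for culls and
#' slaughtered animals. The same seed and inputs always reproduce the same
#' table.
#'
#' @param archetypes list of [herd_archetype()] (see
#'   [default_archetypes()]).
#' @param years integer vector of consecutive calendar years simulated.
#' @param seed integer seed.
#' @return data.frame of animal events with columns `animal_id`,
#'   `event_kind` (birth / move_in / move_out / death), `herd_id`,
#'   `event_date`, `sex`, `breed_code`, `date_of_birth`, plus a `herds`
#'   attribute mapping herd ids to their archetype type/subtype (ground
#'   truth for classifier checks).
#' @export
generate_movement_db <- function(archetypes, years, seed = 1L) {
  if (!length(archetypes)) stop_config("need at least one archetype")
  if (!length(years)) stop_config("need at least one simulation year")
  years <- sort(unique(as.integer(years)))
  start <- as.Date(sprintf("%d-01-01", min(years)))
  end <- as.Date(sprintf("%d-12-31", max(years)))
  codes <- breed_codes_by_category()

  herds <- do.call(rbind, lapply(seq_along(archetypes), function(i) {
    a <- archetypes[[i]]
    data.frame(archetype = i, herd_type = a$herd_type, subtype = a$subtype,
               n = seq_len(a$count), stringsAsFactors = FALSE)
  }))
  herds$herd_id <- sprintf("H%04d", seq_len(nrow(herds)))

  with_seed(seed, {
    ev <- list(); ank <- 0L
    animals <- new.env(parent = emptyenv())  # id -> list(sex, breed, dob)
    intents <- list()  # transfer queue

    new_animal <- function(sex, breed_code, dob) {
      ank <<- ank + 1L
      id <- sprintf("A%07d", ank)
      assign(id, list(sex = sex, breed_code = breed_code, dob = dob),
             envir = animals)
      id
    }
    emit <- function(id, kind, herd, date) {
      ev[[length(ev) + 1L]] <<- list(id = id, kind = kind, herd = herd,
                                     date = as.numeric(date))
    }
    queue <- function(id, from, date, stage) {
      intents[[length(intents) + 1L]] <<- list(id = id, from = from,
                                               date = date, stage = stage)
    }
    pick_breed <- function(mix) {
      bc <- sample(names(mix), 1L, prob = mix)
      sample(codes[[bc]], 1L)
    }

    # breeding herds: cows and their annual calves
    for (h in seq_len(nrow(herds))) {
      a <- archetypes[[herds$archetype[h]]]
      if (!a$herd_type %in% c("dairy", "beef", "mixed")) next
      hid <- herds$herd_id[h]
      n_cows <- max(1L, stats::rpois(1L, a$size_median))
      cow_age0 <- round(stats::runif(n_cows, 750, 2800))
      for (ci in seq_len(n_cows)) {
        dob <- start - cow_age0[ci]
        id <- new_animal("female", pick_breed(a$breed_mix), dob)
        emit(id, "birth", hid, dob)
        cull <- dob + a$sex_policy$cull_age
        if (cull <= end) emit(id, "death", hid, cull)
        # one calf per year while the cow is alive
        for (y in years) {
          cm <- sample(1:12, 1L, prob = a$calving_month_distribution)
          cdate <- as.Date(sprintf("%d-%02d-%02d", y, cm,
                                   sample(1:28, 1L)))
          if (cdate <= dob + 730 || cdate >= cull) next
          sx <- sample(c("female", "male"), 1L)
          cid <- new_animal(sx, pick_breed(a$breed_mix), cdate)
          emit(cid, "birth", hid, cdate)
          pol <- a$sex_policy
          if (sx == "female" && stats::runif(1) < pol$retain_female_frac) {
            next  # replacement heifer stays for the simulated window
          }
          if (pol$finish_in_herd) {
            fin <- cdate + round(stats::runif(1, pol$finish_age[1],
                                              pol$finish_age[2]))
            if (fin <= end) emit(cid, "death", hid, fin)
            next
          }
          stage <- if (sx == "female") pol$female_stage else pol$male_stage
          if (stage == "none") next
          sale <- cdate + round(stats::runif(1, a$sale_age_window[1],
                                             a$sale_age_window[2]))
          if (sale <= end) queue(cid, hid, sale, stage)
        }
      }
    }

    stage_pool <- list(
      rearing_female = herds$herd_id[herds$subtype == "Rdf"],
      rearing_male = herds$herd_id[herds$subtype == "Sdm"],
      fattening = herds$herd_id[herds$herd_type == "fattening"])
    traders <- herds$herd_id[herds$herd_type == "trading"]
    tw <- trading_month_weights()

    # process the transfer queue; store arrivals enqueue their own later
    # move to fattening, so iterate until drained
    qi <- 1L
    while (qi <= length(intents)) {
      it <- intents[[qi]]; qi <- qi + 1L
      pool <- stage_pool[[it$stage]]
      if (it$stage %in% c("rearing_female", "rearing_male") && !length(pool))
        pool <- stage_pool$fattening
      if (!length(pool)) next  # no buyer anywhere: animal stays put
      dest <- if (length(pool) == 1L) pool else sample(pool, 1L)
      date <- it$date
      if (length(traders) &&
          stats::runif(1) < tw[date_month(date)]) {
        tr <- if (length(traders) == 1L) traders else sample(traders, 1L)
        stay <- round(stats::runif(1, 7, 21))
        emit(it$id, "move_out", it$from, date)
        emit(it$id, "move_in", tr, date)
        date2 <- min(date + stay, end)
        emit(it$id, "move_out", tr, date2)
        emit(it$id, "move_in", dest, date2)
        date <- date2
      } else {
        emit(it$id, "move_out", it$from, date)
        emit(it$id, "move_in", dest, date)
      }
      row <- herds[herds$herd_id == dest, ]
      pol <- archetypes[[row$archetype]]$sex_policy
      if (row$herd_type == "fattening") {
        kill <- date + round(stats::runif(1, pol$hold_days[1],
                                          pol$hold_days[2]))
        if (kill <= end) emit(it$id, "death", dest, kill)
      } else if (row$herd_type == "store_rearing") {
        dob <- get(it$id, envir = animals)$dob
        exit <- dob + round(stats::runif(1, pol$store_exit_age[1],
                                         pol$store_exit_age[2]))
        exit <- max(exit, date + 30)
        if (exit <= end) queue(it$id, dest, exit, "fattening")
      }
    }

    ids <- vapply(ev, `[[`, "", "id")
    info <- lapply(ids, get, envir = animals)
    events <- data.frame(
      animal_id = ids,
      event_kind = vapply(ev, `[[`, "", "kind"),
      herd_id = vapply(ev, `[[`, "", "herd"),
      event_date = as.Date(vapply(ev, `[[`, 0, "date"),
                           origin = "1970-01-01"),
      sex = vapply(info, `[[`, "", "sex"),
      breed_code = vapply(info, `[[`, "", "breed_code"),
      date_of_birth = as.Date(vapply(info, function(a) as.numeric(a$dob), 0),
                              origin = "1970-01-01"),
      stringsAsFactors = FALSE)
    kind_rank <- c(birth = 1L, move_out = 2L, move_in = 3L, death = 4L)
    events <- events[order(events$animal_id, events$event_date,
                           kind_rank[events$event_kind]), ]
    rownames(events) <- NULL
    attr(events, "herds") <- herds[, c("herd_id", "herd_type", "subtype")]
    events
  })
}
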