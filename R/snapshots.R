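# First-of-month population snapshots reconstructed from the movement
# event log: which animals stood in which herd on the 1st of every month.

#' Exact age in calendar days
#'
#' @param date_of_birth,at Dates.
#' @return integer day difference (`at - date_of_birth`).
#' @export
animal_age_days <- function(date_of_birth, at) {
  d <- as.integer(as.Date(at) - as.Date(date_of_birth))
  if (any(d < 0, na.rm = TRUE)) stop_config("age would be negative")
  d
}

# Per-animal herd-stay intervals [start, end) derived from the event
# sequence; death closes the final stay. Returns list(stays, quarantine).
build_stays <- function(events) {
  kind_rank <- c(birth = 1L, move_out = 2L, move_in = 3L, death = 4L)
  ev <- events[order(events$animal_id, events$event_date,
                     kind_rank[events$event_kind]), ]
  by_animal <- split(seq_len(nrow(ev)), ev$animal_id)
  stays <- vector("list", length(by_animal))
  bad <- character(0)
  for (i in seq_along(by_animal)) {
    rows <- by_animal[[i]]
    kinds <- ev$event_kind[rows]
    dates <- ev$event_date[rows]
    herd <- ev$herd_id[rows]
    id <- ev$animal_id[rows[1L]]
    ok <- kinds[1L] == "birth" && sum(kinds == "birth") == 1L &&
      !is.unsorted(as.numeric(dates))
    if (ok) {
      cur_herd <- herd[1L]
      cur_start <- dates[1L]
      segs <- list()
      dead <- FALSE
      for (j in seq_along(kinds)[-1L]) {
        k <- kinds[j]
        if (dead) { ok <- FALSE; break }
        if (k == "move_out") {
          if (is.na(cur_herd) || herd[j] != cur_herd) { ok <- FALSE; break }
          segs[[length(segs) + 1L]] <- c(cur_start, dates[j])
          names(segs)[length(segs)] <- cur_herd
          cur_herd <- NA_character_
        } else if (k == "move_in") {
          if (!is.na(cur_herd)) { ok <- FALSE; break }  # unmatched move_in
          cur_herd <- herd[j]
          cur_start <- dates[j]
        } else if (k == "death") {
          if (is.na(cur_herd) || herd[j] != cur_herd) { ok <- FALSE; break }
          segs[[length(segs) + 1L]] <- c(cur_start, dates[j])
          names(segs)[length(segs)] <- cur_herd
          cur_herd <- NA_character_
          dead <- TRUE
        } else { ok <- FALSE; break }  # second birth
      }
      if (ok && !is.na(cur_herd)) {  # open-ended final stay
        segs[[length(segs) + 1L]] <- c(cur_start, as.Date(NA))
        names(segs)[length(segs)] <- cur_herd
      }
    }
    if (!ok) { bad <- c(bad, id); next }
    stays[[i]] <- data.frame(
      animal_id = id, herd_id = names(segs),
      start = as.Date(vapply(segs, function(s) as.numeric(s[1]), 0),
                      origin = "1970-01-01"),
      end = as.Date(vapply(segs, function(s) as.numeric(s[2]), 0),
                    origin = "1970-01-01"),
      sex = ev$sex[rows[1L]], breed_code = ev$breed_code[rows[1L]],
      date_of_birth = ev$date_of_birth[rows[1L]],
      stringsAsFactors = FALSE)
  }
  list(stays = do.call(rbind, stays[!vapply(stays, is.null, TRUE)]),
       quarantine = bad)
}

#' Reconstruct first-of-month herd membership from the event log
#'
#' An animal belongs to herd h on snapshot date d when its event history
#' places it in h over an interval containing d: stays are half-open
#' `[start, end)`, so a move dated exactly on the 1st counts in the
#' destination herd and a death dated on the 1st removes the animal from
#' that snapshot. Animals with contradictory event sequences (no or
#' duplicated birth, unmatched moves, events after death) are quarantined
#' and skipped, not fatal.
#'
#' @param events animal-event data.frame (see [generate_movement_db()]).
#' @param from,to dates bounding the snapshot months (any day within the
#'   first and last month).
#' @return long data.frame of class `herd_snapshots` with one row per
#'   animal per snapshot: `herd_id`, `snapshot_date`, `animal_id`,
#'   `age_days`, `sex`, `breed_code`; quarantined animal ids in the
#'   `quarantine` attribute.
#' @export
build_snapshots <- function(events, from, to) {
  dates <- month_starts(from, to)
  bs <- build_stays(events)
  st <- bs$stays
  out <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    d <- dates[i]
    live <- st[st$start <= d & (is.na(st$end) | st$end > d), , drop = FALSE]
    if (!nrow(live)) next
    out[[i]] <- data.frame(
      herd_id = live$herd_id, snapshot_date = d,
      animal_id = live$animal_id,
      age_days = as.integer(d - live$date_of_birth),
      sex = live$sex, breed_code = live$breed_code,
      stringsAsFactors = FALSE)
  }
  snaps <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(snaps))
    snaps <- data.frame(herd_id = character(0),
                        snapshot_date = as.Date(character(0)),
                        animal_id = character(0), age_days = integer(0),
                        sex = character(0), breed_code = character(0))
  rownames(snaps) <- NULL
  attr(snaps, "quarantine") <- bs$quarantine
  class(snaps) <- c("herd_snapshots", "data.frame")
  snaps
}
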