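# Record-retention and breed-categorisation rules for slaughter-valuation
# tables: liveweight plausibility windows by animal class, completeness
# checks, and mapping of breed codes (resolving crosses to the sire breed)
# into dairy / continental beef / British-Irish beef categories.

#' Breed-code map
#'
#' @param codes named character vector: breed code -> breed category.
#' @param cross_suffixes suffix markers denoting a cross (stripped to the
#'   sire code before lookup, e.g. `"FRX"` -> `"FR"`).
#' @return object of class `breed_map`.
#' @export
breed_map <- function(codes, cross_suffixes = "X") {
  if (!length(codes) || is.null(names(codes)))
    stop_config("breed map needs named code -> category entries")
  if (!all(codes %in% breed_categories()))
    stop_config("breed map categories must be dairy, continental_beef or british_irish_beef")
  structure(list(codes = codes, cross_suffixes = cross_suffixes),
            class = "breed_map")
}

#' Default breed-code map
#'
#' Common Irish breed codes grouped by convention: Friesian/Holstein/Jersey
#' and other dairy breeds as dairy; Charolais, Limousin, Simmental, Belgian
#' Blue and other continental imports as continental beef; Angus, Hereford,
#' Shorthorn and native breeds as British-Irish beef. The map is a
#' replaceable configuration, not an official registry list; it ships as a
#' CSV under `inst/extdata/breed_map.csv`.
#'
#' @return a [breed_map()].
#' @export
default_breed_map <- function() {
  path <- system.file("extdata", "breed_map.csv", package = "herdmass",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  breed_map(stats::setNames(df$category, df$code))
}

#' Resolve a breed code to a breed category
#'
#' Cross codes are stripped of their cross suffix so that the lookup uses
#' the sire breed (e.g. a Friesian-cross "FRX" resolves as "FR", dairy).
#'
#' @param breed_code character vector of codes.
#' @param map a [breed_map()].
#' @return character vector of categories, `NA` where unmappable.
#' @export
resolve_breed <- function(breed_code, map = default_breed_map()) {
  code <- toupper(trimws(breed_code))
  hit <- map$codes[code]
  for (sfx in map$cross_suffixes) {
    is_cross <- is.na(hit) & endsWith(code, sfx) & nchar(code) > nchar(sfx)
    if (any(is_cross)) {
      sire <- substr(code[is_cross], 1L,
                     nchar(code[is_cross]) - nchar(sfx))
      hit[is_cross] <- map$codes[sire]
    }
  }
  unname(hit)
}

# liveweight plausibility windows (kg), closed at both ends
liveweight_windows <- function() {
  list(calf = c(30, 1400), heifer = c(30, 1400), steer = c(30, 1400),
       bull = c(200, 1400), cow = c(200, 1400),
       pregnant_heifer = c(200, 1400))
}

#' Liveweight plausibility rule
#'
#' Retains calves, heifers and steers weighing 30-1,400 kg and bulls, cows
#' and pregnant heifers weighing 200-1,400 kg (closed intervals); weights
#' outside these windows are treated as data-entry errors. Missing
#' liveweight fails the rule.
#'
#' @param liveweight numeric kg.
#' @param animal_class character class per record.
#' @return logical vector.
#' @export
retain_liveweight <- function(liveweight, animal_class) {
  w <- liveweight_windows()
  lo <- vapply(animal_class, function(cl) w[[cl]][1], 0)
  hi <- vapply(animal_class, function(cl) w[[cl]][2], 0)
  !is.na(liveweight) & liveweight >= lo & liveweight <= hi
}

#' Completeness rule
#'
#' A record is retained only when value (non-zero), liveweight, date of
#' birth, date of death, sex and breed are all present.
#'
#' @param records slaughter-record data.frame.
#' @return logical vector.
#' @export
retain_complete <- function(records) {
  ok <- !is.na(records$value) & records$value != 0 &
    !is.na(records$liveweight) &
    !is.na(records$date_of_birth) & !is.na(records$date_of_death) &
    !is.na(records$sex) & records$sex != "" &
    !is.na(records$breed_code) & records$breed_code != ""
  ok
}

#' Clean a slaughter-valuation table
#'
#' Applies, in order: completeness, liveweight window, breed resolution.
#' Each dropped record is attributed to the first rule it fails. The output
#' carries a `breed_category` column.
#'
#' @param records raw slaughter-record data.frame.
#' @param map a [breed_map()].
#' @return the retained records, with a `cleaning_report` attribute listing
#'   input/retained counts and drops per rule.
#' @export
clean_dataset <- function(records, map = default_breed_map()) {
  n_in <- nrow(records)
  if (!n_in) {
    out <- cbind(records, breed_category = character(0))
    attr(out, "cleaning_report") <- list(
      n_input = 0L, n_retained = 0L,
      dropped = c(incomplete = 0L, liveweight_window = 0L,
                  unmappable_breed = 0L))
    return(out)
  }
  complete <- retain_complete(records)
  in_window <- retain_liveweight(records$liveweight, records$animal_class)
  bc <- resolve_breed(records$breed_code, map)
  fail_complete <- !complete
  fail_window <- complete & !in_window
  fail_breed <- complete & in_window & is.na(bc)
  keep <- complete & in_window & !is.na(bc)
  out <- records[keep, , drop = FALSE]
  out$breed_category <- bc[keep]
  rownames(out) <- NULL
  attr(out, "cleaning_report") <- list(
    n_input = n_in, n_retained = sum(keep),
    dropped = c(incomplete = sum(fail_complete),
                liveweight_window = sum(fail_window),
                unmappable_breed = sum(fail_breed)))
  out
}
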