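# Reproducible end-to-end pipeline: simulate (or load) the four input
# tables, clean, sample, fit the four segmented models, snapshot, classify,
# predict, aggregate, deflate and validate, writing tidy CSV outputs and a
# JSON manifest with seeds, row counts and a config fingerprint.

table_schemas <- function() {
  list(
    events = c("animal_id", "event_kind", "herd_id", "event_date", "sex",
               "breed_code", "date_of_birth"),
    slaughter = c("animal_id", "breed_code", "animal_class", "sex",
                  "date_of_birth", "date_of_death", "liveweight", "value"),
    market = c("sale_date", "animal_category", "sector", "breed_code",
               "sex", "price"),
    cpi = c("year", "month", "index"))
}

#' Read a typed delimited table
#'
#' Comma-separated UTF-8 with ISO-8601 dates. Columns named `*date*` are
#' parsed as calendar dates. Missing schema columns raise an error naming
#' them; extra columns pass through.
#'
#' @param path CSV file.
#' @param schema required column names (character), or the name of a
#'   packaged schema (`"events"`, `"slaughter"`, `"market"`, `"cpi"`).
#' @return data.frame.
#' @export
read_table <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(schema) && length(schema) == 1L &&
      schema %in% names(table_schemas()))
    schema <- table_schemas()[[schema]]
  if (!is.null(schema)) {
    missing_cols <- setdiff(schema, names(df))
    if (length(missing_cols))
      stop_config("%s lacks required column(s): %s", path,
                  paste(missing_cols, collapse = ", "))
  }
  for (v in grep("date", names(df), value = TRUE))
    df[[v]] <- as.Date(df[[v]])
  df
}

#' Write a table as CSV
#'
#' @param df data.frame (dates serialised as ISO-8601).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All knobs of the end-to-end run in one list: simulation scale and years,
#' sampling sizes (600 liveweight / 1,000 value records per animal class),
#' fit settings, the break-point selection threshold, CPI drift and base
#' period, and output locations.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory.
#' @return named list, class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("herdmass_out_")) {
  structure(list(
    seed = as.integer(seed), out_dir = out_dir,
    years = 2016:2018, archetype_scale = 0.5,
    n_per_class_weight = 600L, n_per_class_value = 1000L,
    n_market = 2000L,
    noise_sd_weight = 40, noise_sd_value = 120,
    kmax = 2L, delta_r2_threshold = 0.01,
    cpi_base = NULL, cpi_drift = 0.015,
    empty_months_zero = TRUE), class = "pipeline_config")
}

#' Run the full estimation pipeline
#'
#' Simulates the four input datasets from ground truth, then executes
#' clean, stratified sample, four segmented fits (liveweight and value by
#' sex, break-point count selected by incremental R-squared), monthly
#' snapshots, herd classification, population prediction, aggregation and
#' CPI deflation, and market validation. All tables are written as CSV
#' under `config$out_dir` together with a JSON manifest.
#'
#' @param config a [pipeline_config()].
#' @return list with every intermediate product plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fingerprint <- fnv1a32(paste(deparse(unclass(cfg)), collapse = ""))
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest <- list(config_hash = fingerprint, seed = cfg$seed,
                       failed_stage = name, counts = counts)
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop_config("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e))
    })
  }

  truth_w <- default_truths("liveweight", noise_sd = cfg$noise_sd_weight,
                            years = cfg$years)
  truth_v <- default_truths("value", noise_sd = cfg$noise_sd_value,
                            years = cfg$years)
  map <- default_breed_map()

  # the slaughter pool must exceed the stratified sample even after
  # cleaning losses
  slaughter <- stage("simulate_slaughter", generate_slaughter_records(
    truth_w, truth_v,
    n_per_class = ceiling(1.3 * max(cfg$n_per_class_value,
                                    cfg$n_per_class_weight)),
    seed = cfg$seed + 1L, years = cfg$years))
  events <- stage("simulate_movements", generate_movement_db(
    default_archetypes(cfg$archetype_scale), cfg$years,
    seed = cfg$seed + 2L))
  cat_map <- default_category_age_map()
  market <- stage("simulate_market", generate_market_records(
    truth_v, cat_map, n = cfg$n_market, seed = cfg$seed + 3L,
    years = cfg$years))
  cpi <- stage("simulate_cpi", generate_cpi_series(
    start = sprintf("%d-01", min(cfg$years)),
    end = sprintf("%d-12", max(cfg$years)),
    base_period = cfg$cpi_base %||% sprintf("%d-12", min(cfg$years)),
    annual_drift = cfg$cpi_drift, seed = cfg$seed + 4L))
  counts$slaughter_raw <- nrow(slaughter)
  counts$events <- nrow(events)
  counts$market <- nrow(market)

  cleaned <- stage("clean", clean_dataset(slaughter, map))
  counts$slaughter_clean <- nrow(cleaned)

  sample_w <- stage("sample_weight", stratified_sample(
    cleaned, cfg$n_per_class_weight, seed = cfg$seed + 5L))
  sample_v <- stage("sample_value", stratified_sample(
    cleaned, cfg$n_per_class_value, seed = cfg$seed + 6L))
  prep <- function(s) {
    s$age_days <- animal_age_days(s$date_of_birth, s$date_of_death)
    s$month <- date_month(s$date_of_death)
    s$year <- date_year(s$date_of_death)
    s
  }
  sample_w <- prep(sample_w); sample_v <- prep(sample_v)

  fit_one <- function(dat, response) {
    f <- stats::as.formula(paste(
      response, "~ age_days + breed_category + month + year"))
    select_breakpoint_count(f, dat, kmax = cfg$kmax,
                            delta_r2_threshold = cfg$delta_r2_threshold)
  }
  fits <- stage("fit", list(
    liveweight = list(
      female = fit_one(sample_w[sample_w$sex == "female", ], "liveweight"),
      male = fit_one(sample_w[sample_w$sex == "male", ], "liveweight")),
    value = list(
      female = fit_one(sample_v[sample_v$sex == "female", ], "value"),
      male = fit_one(sample_v[sample_v$sex == "male", ], "value"))))

  snaps <- stage("snapshot", build_snapshots(
    events, sprintf("%d-01-01", min(cfg$years)),
    sprintf("%d-12-01", max(cfg$years))))
  counts$snapshot_rows <- nrow(snaps)

  classes <- stage("classify", classify_all(snaps, events,
                                            breed_map = map))
  pred <- stage("predict", suppressWarnings(
    predict_population(fits, snaps, map)))
  counts$predictions <- nrow(pred)
  totals <- stage("aggregate_monthly", herd_month_totals(pred, cpi))
  profile <- stage("aggregate_profile", within_year_profile(totals, classes))
  annual <- stage("aggregate_annual", annual_and_sector(
    totals, classes, cpi, empty_months_zero = cfg$empty_months_zero))
  validation <- stage("validate", validate_value_model(
    fits$value, market, cat_map))

  for (nm in c("slaughter", "market"))
    write_table(get(nm), file.path(cfg$out_dir, paste0(nm, ".csv")))
  write_table(events, file.path(cfg$out_dir, "events.csv"))
  write_table(cpi$monthly, file.path(cfg$out_dir, "cpi.csv"))
  write_table(totals, file.path(cfg$out_dir, "herd_month_totals.csv"))
  write_table(profile, file.path(cfg$out_dir, "within_year_profile.csv"))
  write_table(annual$herd_type, file.path(cfg$out_dir,
                                          "herd_type_annual.csv"))
  write_table(annual$sector, file.path(cfg$out_dir, "sector_annual.csv"))
  write_table(validation, file.path(cfg$out_dir, "validation.csv"))
  write_table(classes, file.path(cfg$out_dir, "classifications.csv"))

  manifest <- list(
    config_hash = fingerprint, seed = cfg$seed,
    years = cfg$years, counts = counts,
    breakpoints = lapply(fits, function(r) lapply(r, function(f) f$psi)),
    quarantined_animals = length(attr(snaps, "quarantine")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(config = cfg, truth_w = truth_w, truth_v = truth_v,
       slaughter = slaughter, events = events, market = market, cpi = cpi,
       cleaned = cleaned, fits = fits, snapshots = snaps,
       classifications = classes, predictions = pred, totals = totals,
       profile = profile, annual = annual, validation = validation,
       manifest = manifest)
}
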