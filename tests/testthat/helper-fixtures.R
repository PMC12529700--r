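# Shared fixtures, all built in code.

# noiseless truth set with flat calendar effects: every sex/breed shares
# one curve shape, breed offsets are zero, so model predictions can be
# compared to the curve exactly
flat_truths <- function(intercept, slopes, breaks, units = "kg",
                        noise_sd = 0) {
  out <- list()
  for (sex in c("female", "male"))
    for (bc in c("dairy", "continental_beef", "british_irish_beef"))
      out[[paste(sex, bc, sep = ".")]] <- growth_truth(
        sex, bc, intercept = intercept, segment_slopes = slopes,
        break_points = breaks, noise_sd = noise_sd, units = units)
  out
}

# stratified female-shaped regression sample: four female slaughter-class
# age windows, 2 true break-points at 608/1878 days
breakpoint_rep_data <- function(seed, noise_sd = 40) {
  herdmass:::with_seed(seed, {
    age <- c(round(stats::runif(150, 30, 364)),
             round(stats::runif(150, 365, 800)),
             round(stats::runif(150, 1095, 4200)),
             round(stats::runif(150, 550, 1050)))
    y <- piecewise_mean(age, 40, c(0.85, 0.22, 0.01), c(608, 1878)) +
      stats::rnorm(length(age), 0, noise_sd)
    data.frame(y = y, age = age)
  })
}

# replicate study shared by the break-point recovery tests: selection and
# parameter errors over seeded replicates (cached per session)
breakpoint_replicates <- local({
  cache <- NULL
  function(n_reps = 50L) {
    if (!is.null(cache) && nrow(cache) >= n_reps)
      return(cache[seq_len(n_reps), ])
    rows <- lapply(seq_len(n_reps), function(r) {
      d <- breakpoint_rep_data(1000L + r)
      sel <- select_breakpoint_count(y ~ age, d, kmax = 3)
      f2 <- sel$candidates[["2"]]
      sl <- slope_profile(f2)$slope
      data.frame(K = sel$K, psi1 = f2$psi[1], psi2 = f2$psi[2],
                 s1 = sl[1], s2 = sl[2], s3 = sl[3])
    })
    cache <<- do.call(rbind, rows)
    cache
  }
})

# minimal event table builder
event_row <- function(animal_id, kind, herd, date, sex = "female",
                      breed = "FR", dob = NULL) {
  data.frame(animal_id = animal_id, event_kind = kind, herd_id = herd,
             event_date = as.Date(date), sex = sex, breed_code = breed,
             date_of_birth = as.Date(dob %||% date),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small deterministic movement population used by several suites
demo_movements <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_movement_db(default_archetypes(0.5), 2016:2018,
                                     seed = 501)
    cache
  }
})

# four cached segmented fits (liveweight/value x sex) trained on a small
# synthetic slaughter sample; reused wherever population predictions are
# needed
pretrained_fits <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tw <- default_truths("liveweight")
    tv <- default_truths("value")
    s <- clean_dataset(generate_slaughter_records(tw, tv, 150, seed = 77,
                                                  years = 2016:2018))
    s$age_days <- animal_age_days(s$date_of_birth, s$date_of_death)
    s$month <- as.integer(format(s$date_of_death, "%m"))
    s$year <- as.integer(format(s$date_of_death, "%Y"))
    fit1 <- function(resp, sex) {
      f <- stats::as.formula(paste(resp,
                                   "~ age_days + breed_category + month + year"))
      segfit(f, s[s$sex == sex, ], K = 2)
    }
    cache <<- list(
      liveweight = list(female = fit1("liveweight", "female"),
                        male = fit1("liveweight", "male")),
      value = list(female = fit1("value", "female"),
                   male = fit1("value", "male")))
    cache
  }
})
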