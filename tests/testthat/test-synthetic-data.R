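test_that("piecewise mean is continuous across break-points", {
  tr <- growth_truth("female", "dairy", intercept = 40,
                     segment_slopes = c(0.9, 0.2, 0.01),
                     break_points = c(600, 1800))
  for (b in tr$break_points) {
    left <- truth_mean(tr, b - 1e-7)
    at <- truth_mean(tr, b)
    right <- truth_mean(tr, b + 1e-7)
    expect_equal(left, at, tolerance = 1e-6)
    expect_equal(right, at, tolerance = 1e-6)
  }
})

test_that("truth constructors validate their invariants", {
  expect_error(growth_truth("female", "dairy", 40, c(1, 0.2), c(500, 400)),
               "increasing")
  expect_error(growth_truth("female", "dairy", 40, c(1, 0.2, 0.1), 500),
               "slopes")
  expect_error(growth_truth("female", "dairy", 40, c(1, 0.2), 500,
                            noise_sd = -1), "noise_sd")
  tw <- default_truths("liveweight")
  expect_length(tw, 6L)
  for (tr in tw) expect_length(tr$break_points, 2L)
})

test_that("slaughter generator yields the stratified design size and is seeded", {
  tw <- default_truths("liveweight")
  tv <- default_truths("value")
  a <- generate_slaughter_records(tw, tv, n_per_class = 600, seed = 9)
  expect_equal(nrow(a), 3600L)
  expect_setequal(unique(a$animal_class),
                  c("calf", "heifer", "steer", "bull", "cow",
                    "pregnant_heifer"))
  expect_equal(as.vector(table(a$animal_class)), rep(600L, 6))
  b <- generate_slaughter_records(tw, tv, n_per_class = 600, seed = 9)
  expect_identical(a, b)
  expect_false(identical(
    a, generate_slaughter_records(tw, tv, n_per_class = 600, seed = 10)))
})

test_that("slaughter residuals about the generator truth match noise_sd", {
  tw <- default_truths("liveweight", noise_sd = 30)
  tv <- default_truths("value", noise_sd = 30)
  s <- generate_slaughter_records(tw, tv, n_per_class = 1500, seed = 21)
  bc <- resolve_breed(s$breed_code)
  age <- animal_age_days(s$date_of_birth, s$date_of_death)
  mu <- numeric(nrow(s))
  for (tr in tw) {
    idx <- s$sex == tr$sex & bc == tr$breed_category
    mu[idx] <- truth_mean(tr, age[idx],
                          as.integer(format(s$date_of_death[idx], "%m")),
                          as.integer(format(s$date_of_death[idx], "%Y")))
  }
  expect_lt(abs(stats::sd(s$liveweight - mu) - 30) / 30, 0.05)
})

test_that("slaughter generator rejects incomplete truth coverage", {
  tw <- default_truths("liveweight")
  tv <- default_truths("value")
  expect_error(generate_slaughter_records(tw[-1], tv, 10), "missing")
  expect_error(generate_slaughter_records(tw, tv, 0), "n_per_class")
})

test_that("market records stay inside their category age ranges", {
  tv <- flat_truths(120, c(1.5, 0.3, -0.1), c(680, 1250), units = "eur")
  map <- default_category_age_map()
  mk <- generate_market_records(tv, map, n = 400, seed = 3)
  expect_gt(nrow(mk), 0)
  for (i in seq_len(nrow(map))) {
    sub <- mk[mk$animal_category == map$animal_category[i], ]
    if (!nrow(sub)) next
    expect_true(all(sub$latent_age_days >= map$min_months[i] * 30.4375))
    expect_true(all(sub$latent_age_days <= map$max_months[i] * 30.4375))
  }
  # noiseless prices equal the truth mean at the latent age
  expect_equal(mk$price,
               piecewise_mean(mk$latent_age_days, 120,
                              c(1.5, 0.3, -0.1), c(680, 1250)),
               tolerance = 1e-9)
  expect_identical(mk, generate_market_records(tv, map, n = 400, seed = 3))
  expect_error(generate_market_records(tv, map, n = 0), "positive")
})

test_that("CPI series honours its base period and closed-form drift", {
  cpi <- generate_cpi_series("2011-01", "2021-12", "2011-12",
                             annual_drift = 0.02)
  expect_identical(cpi_index(cpi, 2011, 12), 100)
  flat <- generate_cpi_series("2011-01", "2021-12", "2011-12",
                              annual_drift = 0)
  expect_true(all(flat$monthly$index == 100))
  expect_equal(cpi_index(cpi, 2021), 100 * 1.02^10, tolerance = 1e-9)
  expect_error(generate_cpi_series("2012-01", "2014-12", "2011-12"),
               "outside")
  expect_error(cpi_index(cpi, 2031), "outside")
})

test_that("movement database is deterministic and structurally sound", {
  ev <- demo_movements()
  ev2 <- generate_movement_db(default_archetypes(0.5), 2016:2018,
                              seed = 501)
  expect_identical(ev, ev2)
  births <- ev[ev$event_kind == "birth", ]
  expect_equal(nrow(births), length(unique(ev$animal_id)))
  expect_false(any(duplicated(births$animal_id)))
  deaths <- ev[ev$event_kind == "death", ]
  expect_true(all(deaths$event_date > deaths$date_of_birth))
  # paired, chronologically consistent moves: the stay builder quarantines
  # nothing
  expect_length(attr(build_snapshots(ev, "2016-01-01", "2016-02-01"),
                     "quarantine"), 0L)
  expect_error(generate_movement_db(list(), 2016), "archetype")
})

test_that("trading herds peak in spring and autumn months", {
  arch <- list(
    herd_archetype("beef", "BSB", count = 10, size_median = 30,
                   calving_month_distribution = rep(1 / 12, 12),
                   sale_age_window = c(200, 260),
                   breed_mix = c(continental_beef = 1),
                   sex_policy = list(male_stage = "fattening",
                                     female_stage = "fattening")),
    herd_archetype("fattening", count = 3),
    herd_archetype("trading", count = 2))
  ev <- generate_movement_db(arch, 2016:2018, seed = 11)
  herds <- attr(ev, "herds")
  sn <- build_snapshots(ev, "2017-01-01", "2018-12-01")
  tr <- sn[sn$herd_id %in% herds$herd_id[herds$herd_type == "trading"], ]
  by_month <- tapply(tr$animal_id,
                     as.integer(format(tr$snapshot_date, "%m")), length)
  counts <- rep(0, 12)
  counts[as.integer(names(by_month))] <- by_month
  peak <- c(3, 4, 9, 10, 11)  # stays of 1-3 weeks spill into the next month
  expect_gt(mean(counts[peak]), 2 * mean(counts[-peak]))
})
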