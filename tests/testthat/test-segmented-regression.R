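test_that("noise-free one-break data is recovered exactly", {
  d <- herdmass:::with_seed(31, data.frame(age = round(runif(400, 0, 2000))))
  d$y <- piecewise_mean(d$age, 50, c(0.9, 0.2), 700)
  f <- segfit(y ~ age, d, K = 1)
  expect_true(f$converged)
  expect_lt(abs(f$psi - 700), 1)
  sl <- slope_profile(f)$slope
  expect_equal(sl, c(0.9, 0.2), tolerance = 1e-6)
  expect_equal(unname(coef(f)["(Intercept)"]), 50, tolerance = 1e-6)
})

test_that("noise-free fits with covariates reproduce the generator truth", {
  tw <- flat_truths(40, c(0.85, 0.22, 0.01), c(608, 1878))
  tv <- flat_truths(120, c(1.6, 0.35, -0.15), c(682, 1254), units = "eur")
  s <- clean_dataset(generate_slaughter_records(tw, tv, 150, seed = 8))
  s$age_days <- animal_age_days(s$date_of_birth, s$date_of_death)
  s$month <- as.integer(format(s$date_of_death, "%m"))
  s$year <- as.integer(format(s$date_of_death, "%Y"))
  sf <- s[s$sex == "female", ]
  f <- segfit(liveweight ~ age_days + breed_category + month + year, sf,
              K = 2)
  nd <- data.frame(age_days = c(100, 608, 1000, 1878, 3000),
                   breed_category = "dairy", month = sf$month[1],
                   year = sf$year[1])
  expect_equal(predict(f, nd),
               piecewise_mean(nd$age_days, 40, c(0.85, 0.22, 0.01),
                              c(608, 1878)),
               tolerance = 1e-6)
})

test_that("two break-points at 608/1878 days are recovered under noise", {
  d <- breakpoint_rep_data(77)
  f <- segfit(y ~ age, d, K = 2)
  expect_lt(abs(f$psi[1] - 608) / 608, 0.05)
  expect_lt(abs(f$psi[2] - 1878) / 1878, 0.05)
})

test_that("iterative fit matches the exhaustive grid-search oracle", {
  set.seed(19)
  for (K in 1:2) {
    age <- round(runif(300, 0, 500))
    breaks <- if (K == 1) 220 else c(150, 350)
    slopes <- if (K == 1) c(1.0, 0.3) else c(1.2, 0.4, -0.2)
    y <- piecewise_mean(age, 20, slopes, breaks) + rnorm(300, 0, 10)
    d <- data.frame(y = y, age = age)
    f <- segfit(y ~ age, d, K = K)
    g <- herdmass:::seg_grid_core(y, age, matrix(1, 300), K, step = 1)
    expect_lt(f$rss, g$rss * 1.001)
  }
})

test_that("purely linear data leaves no real break to find", {
  set.seed(4)
  age <- round(runif(250, 0, 1000))
  y <- 5 + 0.4 * age + rnorm(250, 0, 3)
  d <- data.frame(y = y, age = age)
  f <- segfit(y ~ age, d, K = 1)
  g <- herdmass:::seg_grid_core(y, age, matrix(1, 250), 1, step = 1)
  # the exhaustive search is a lower bound on any break placement
  expect_gte(f$rss, g$rss - 1e-6)
  # and the best break barely improves on the straight line: the slope
  # change is statistical noise
  lin_rss <- sum(stats::resid(stats::lm(y ~ age, d))^2)
  expect_lt((lin_rss - f$rss) / lin_rss, 0.02)
  expect_lt((lin_rss - g$rss) / lin_rss, 0.02)
  expect_lt(abs(coef(f)[["delta1"]]), abs(coef(f)[["age"]]) / 2)
})

test_that("R-squared never decreases with more break-points", {
  d <- breakpoint_rep_data(5)
  sel <- select_breakpoint_count(y ~ age, d, kmax = 3,
                                 delta_r2_threshold = 0.01)
  r2 <- sel$selection$r_squared
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("break-point count selection follows the incremental R2 rule", {
  d <- breakpoint_rep_data(12)
  sel <- select_breakpoint_count(y ~ age, d, kmax = 3)
  expect_equal(sel$K, 2L)
  # zero threshold: no improvement counts as minor, so kmax is kept
  sel0 <- select_breakpoint_count(y ~ age, d, kmax = 3,
                                  delta_r2_threshold = 0)
  expect_equal(sel0$K, 3L)
  # linear truth: the procedure bottoms out at K = 1 (it cannot return 0)
  set.seed(2)
  lin <- data.frame(age = round(runif(300, 0, 1000)))
  lin$y <- 3 + 0.5 * lin$age + rnorm(300, 0, 4)
  sel1 <- select_breakpoint_count(y ~ age, lin, kmax = 3)
  expect_equal(sel1$K, 1L)
})

test_that("predictions are continuous and handle covariate edge cases", {
  d <- breakpoint_rep_data(42)
  f <- segfit(y ~ age, d, K = 2)
  grid <- data.frame(age = seq(31, 4199))
  p <- predict(f, grid)
  max_slope <- max(abs(slope_profile(f)$slope))
  expect_lt(max(abs(diff(p))), max_slope + 1e-8)
  at <- data.frame(age = c(f$psi[1] - 1e-9, f$psi[1], f$psi[1] + 1e-9))
  expect_equal(diff(range(predict(f, at))), 0, tolerance = 1e-6)
  expect_error(predict(f, data.frame(age = -5)), "negative")

  # unseen factor levels fall back to the reference with a warning
  tw <- flat_truths(40, c(0.85, 0.22), 608)
  tv <- flat_truths(120, c(1.6, 0.35), 682, units = "eur")
  s <- clean_dataset(generate_slaughter_records(tw, tv, 60, seed = 6,
                                                years = 2016))
  s$age_days <- animal_age_days(s$date_of_birth, s$date_of_death)
  s$month <- as.integer(format(s$date_of_death, "%m"))
  s$year <- as.integer(format(s$date_of_death, "%Y"))
  fcov <- segfit(liveweight ~ age_days + breed_category + year,
                 s[s$sex == "female", ], K = 1)
  expect_warning(
    p2 <- predict(fcov, data.frame(age_days = 500,
                                   breed_category = "dairy", year = 2030)),
    "unseen")
  p_ref <- predict(fcov, data.frame(age_days = 500,
                                    breed_category = "dairy", year = 2016))
  expect_equal(p2, p_ref)
})

test_that("degenerate designs raise informative errors", {
  d <- breakpoint_rep_data(3)
  expect_error(segfit(y ~ age, d[1:10, ], K = 2), "observations")
  d$dup <- d$age
  expect_error(segfit(y ~ age + dup, d, K = 1))
})

test_that("stratified sampling hits the design sizes reproducibly", {
  tw <- default_truths("liveweight")
  tv <- default_truths("value")
  s <- clean_dataset(generate_slaughter_records(tw, tv, 1300, seed = 2))
  samp <- stratified_sample(s, 1000, seed = 10)
  expect_equal(nrow(samp), 6000L)
  expect_equal(as.vector(table(samp$animal_class)), rep(1000L, 6))
  expect_identical(samp, stratified_sample(s, 1000, seed = 10))
  expect_false(any(duplicated(samp$animal_id)))
  expect_error(stratified_sample(s, 10 + min(table(s$animal_class)),
                                 seed = 1),
               "insufficient")
  # sampling every record of every class returns a permutation
  small <- s[s$animal_class %in% c("cow", "bull"), ]
  k <- min(table(small$animal_class))
  small <- do.call(rbind, lapply(split(small, small$animal_class),
                                 function(g) g[seq_len(k), ]))
  perm <- stratified_sample(small, k, seed = 3)
  expect_setequal(perm$animal_id, small$animal_id)
})
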