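# deterministic prediction fixture: three herds, two months, hand-sized
toy_predictions <- function() {
  expand <- expand.grid(animal = 1:4, herd = c("H1", "H2", "H3"),
                        date = as.Date(c("2016-01-01", "2016-02-01")))
  data.frame(animal_id = paste0(expand$herd, "A", expand$animal),
             herd_id = as.character(expand$herd),
             snapshot_date = expand$date,
             predicted_liveweight = seq(100, by = 25,
                                        length.out = nrow(expand)),
             predicted_value_nominal = seq(200, by = 50,
                                           length.out = nrow(expand)),
             stringsAsFactors = FALSE)
}

toy_classes <- function() {
  data.frame(herd_id = c("H1", "H2", "H3"), year = 2016,
             herd_type = c("dairy", "dairy", "beef"),
             subtype = c("D", "D", "BSB"), rule_trace = "toy",
             stringsAsFactors = FALSE)
}

test_that("herd-month totals equal a brute-force group-by", {
  pred <- toy_predictions()
  tot <- herd_month_totals(pred)
  expect_equal(nrow(tot), 6L)
  oracle <- tapply(pred$predicted_liveweight,
                   paste(pred$herd_id, pred$snapshot_date), sum)
  for (i in seq_len(nrow(tot))) {
    key <- paste(tot$herd_id[i], tot$snapshot_date[i])
    expect_equal(tot$biomass_kg[i], unname(oracle[key]))
  }
  expect_equal(sum(tot$biomass_kg), sum(pred$predicted_liveweight))
  expect_equal(sum(tot$n_animals), nrow(pred))
})

test_that("additivity holds from animal to herd to type to sector", {
  pred <- toy_predictions()
  tot <- herd_month_totals(pred)
  agg <- annual_and_sector(tot, toy_classes())
  # herd annual mean: divides by the 2 snapshot months present
  h1 <- agg$herd[agg$herd$herd_id == "H1", ]
  expect_equal(h1$biomass_kg,
               sum(pred$predicted_liveweight[pred$herd_id == "H1"]) / 2)
  flat_sum <- sum(pred$predicted_liveweight) / 2
  expect_equal(agg$sector$total_biomass_kg, flat_sum,
               tolerance = 1e-6)
  type_totals <- tapply(agg$herd$biomass_kg, agg$herd$herd_type, sum)
  expect_equal(sum(type_totals), flat_sum, tolerance = 1e-6)
  expect_equal(sum(agg$herd_type$total_biomass_kg), flat_sum,
               tolerance = 1e-6)
  # both sector definitions coincide when every herd spans every month
  expect_equal(agg$sector$total_biomass_kg,
               agg$sector$monthly_mean_biomass_kg, tolerance = 1e-6)
})

test_that("type averages behave like means of herd annual figures", {
  pred <- toy_predictions()
  tot <- herd_month_totals(pred)
  agg <- annual_and_sector(tot, toy_classes())
  dairy <- agg$herd[agg$herd$herd_type == "dairy", ]
  row <- agg$herd_type[agg$herd_type$herd_type == "dairy", ]
  expect_equal(row$avg_biomass_kg, mean(dairy$biomass_kg))
  expect_equal(row$n_herds, 2L)
})

test_that("empty herd-months count as zero in the annual mean by default", {
  pred <- toy_predictions()
  pred <- pred[!(pred$herd_id == "H3" &
                   pred$snapshot_date == as.Date("2016-02-01")), ]
  tot <- herd_month_totals(pred)
  agg0 <- annual_and_sector(tot, toy_classes(), empty_months_zero = TRUE)
  agg1 <- annual_and_sector(tot, toy_classes(), empty_months_zero = FALSE)
  h3_sum <- sum(pred$predicted_liveweight[pred$herd_id == "H3"])
  expect_equal(agg0$herd$biomass_kg[agg0$herd$herd_id == "H3"], h3_sum / 2)
  expect_equal(agg1$herd$biomass_kg[agg1$herd$herd_id == "H3"], h3_sum / 1)
})

test_that("within-year profiles average herd-months by type and month", {
  pred <- toy_predictions()
  tot <- herd_month_totals(pred)
  prof <- within_year_profile(tot, toy_classes())
  jan_dairy <- prof[prof$herd_type == "dairy" & prof$month == 1, ]
  oracle <- mean(tot$biomass_kg[tot$herd_id %in% c("H1", "H2") &
                                  tot$month == 1])
  expect_equal(jan_dairy$biomass_kg, oracle)
  expect_equal(jan_dairy$n_herd_months, 2L)
  # a constant series gives a flat profile
  flat <- tot
  flat$biomass_kg <- 500
  p2 <- within_year_profile(flat, toy_classes())
  expect_true(all(p2$biomass_kg == 500))
})

test_that("deflation follows real = nominal * 100 / index", {
  cpi <- generate_cpi_series("2016-01", "2018-12", "2016-12",
                             annual_drift = 0.10)
  expect_equal(deflate(250, cpi, 2016), 250)  # base year identity
  idx <- cpi_index(cpi, 2018, 6)
  expect_equal(deflate(110, cpi, 2018, 6), 110 * 100 / idx)
  expect_true(deflate(110, cpi, 2018, 6) < 110)  # inflation shrinks value
  flat <- generate_cpi_series("2016-01", "2018-12", "2016-12",
                              annual_drift = 0)
  expect_equal(deflate(42, flat, 2017, 3), 42)
  expect_error(deflate(1, cpi, 2030), "outside")
})

test_that("reporting unit conversions are applied only at the boundary", {
  expect_equal(kg_to_kilotonnes(2924800 * 1e3), 2924.8)
  expect_equal(eur_to_millions(6323.7e6), 6323.7)
})

test_that("rearing-herd biomass peaks in the autumn", {
  arch <- list(
    herd_archetype("dairy", "D", count = 6, size_median = 50,
                   calving_month_distribution = (function(p) p / sum(p))(
                     c(3, 6, 6, 3, 1, rep(0.25, 7))),
                   sale_age_window = c(25, 60),
                   breed_mix = c(dairy = 1),
                   sex_policy = list(retain_female_frac = 0.2,
                                     male_stage = "fattening",
                                     female_stage = "rearing_female")),
    herd_archetype("store_rearing", "Rdf", breed_mix = c(dairy = 1),
                   count = 3,
                   sex_policy = list(store_exit_age = c(600, 680))),
    herd_archetype("fattening", count = 2))
  ev <- generate_movement_db(arch, 2016:2018, seed = 99)
  herds <- attr(ev, "herds")
  sn <- build_snapshots(ev, "2017-01-01", "2018-12-01")
  fits <- pretrained_fits()
  pred <- suppressWarnings(predict_population(fits, sn))
  tot <- herd_month_totals(pred)
  rdf <- tot[tot$herd_id %in% herds$herd_id[herds$subtype == "Rdf"], ]
  prof <- tapply(rdf$biomass_kg, rdf$month, mean)
  expect_true(which.max(prof) %in% 9:11)
  expect_gt(max(prof), 1.5 * min(prof))
})
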