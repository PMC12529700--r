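make_record <- function(animal_class = "heifer", sex = "female",
                        breed_code = "FR", liveweight = 400, value = 800,
                        dob = as.Date("2015-03-01"),
                        dod = as.Date("2016-09-01")) {
  data.frame(animal_id = "X1", breed_code = breed_code,
             sire_breed_code = NA_character_, animal_class = animal_class,
             sex = sex, date_of_birth = dob, date_of_death = dod,
             liveweight = liveweight, value = value,
             stringsAsFactors = FALSE)
}

test_that("cross codes resolve through the sire breed", {
  expect_equal(resolve_breed("FRX"), "dairy")
  expect_equal(resolve_breed("FR"), "dairy")
  expect_equal(resolve_breed("LM"), "continental_beef")
  expect_equal(resolve_breed("LMX"), "continental_beef")
  expect_equal(resolve_breed("AAX"), "british_irish_beef")
  # a code ending in X that is itself mapped is not treated as a cross
  expect_equal(resolve_breed("DX"), "british_irish_beef")
  expect_true(is.na(resolve_breed("ZZ")))
  expect_equal(resolve_breed(c("FRX", "CH", "ZZX")),
               c("dairy", "continental_beef", NA))
})

test_that("liveweight windows are closed intervals by animal class", {
  expect_false(retain_liveweight(29, "heifer"))
  expect_true(retain_liveweight(30, "heifer"))
  expect_true(retain_liveweight(30, "calf"))
  expect_true(retain_liveweight(1400, "steer"))
  expect_false(retain_liveweight(199, "bull"))
  expect_true(retain_liveweight(200, "bull"))
  expect_false(retain_liveweight(1401, "cow"))
  expect_false(retain_liveweight(199, "pregnant_heifer"))
  expect_false(retain_liveweight(NA_real_, "cow"))
})

test_that("completeness requires value, weight, dates, sex and breed", {
  expect_true(retain_complete(make_record()))
  expect_false(retain_complete(make_record(value = 0)))
  expect_false(retain_complete(make_record(value = NA)))
  expect_false(retain_complete(make_record(liveweight = NA)))
  expect_false(retain_complete(make_record(dob = as.Date(NA))))
  expect_false(retain_complete(make_record(dod = as.Date(NA))))
  expect_false(retain_complete(make_record(sex = NA)))
  expect_false(retain_complete(make_record(breed_code = "")))
})

test_that("clean_dataset composes the rules and reports attributed drops", {
  good <- do.call(rbind, lapply(1:7, function(i) make_record()))
  bad <- rbind(make_record(value = 0),            # incomplete
               make_record(liveweight = 20),      # below window
               make_record(breed_code = "ZZ"))    # unmappable
  x <- rbind(good, bad)[sample.int(10), ]
  out <- clean_dataset(x)
  rep <- attr(out, "cleaning_report")
  expect_equal(nrow(out), 7L)
  expect_equal(rep$n_input, 10L)
  expect_equal(unname(rep$dropped["incomplete"]), 1L)
  expect_equal(unname(rep$dropped["liveweight_window"]), 1L)
  expect_equal(unname(rep$dropped["unmappable_breed"]), 1L)
  expect_true(all(out$breed_category == "dairy"))

  # records failing several rules are attributed to the first rule only
  multi <- make_record(value = 0, liveweight = 10, breed_code = "ZZ")
  rep2 <- attr(clean_dataset(multi), "cleaning_report")
  expect_equal(sum(rep2$dropped), 1L)
  expect_equal(unname(rep2$dropped["incomplete"]), 1L)
})

test_that("cleaning is idempotent and passes clean tables through", {
  tw <- default_truths("liveweight")
  tv <- default_truths("value")
  s <- generate_slaughter_records(tw, tv, 80, seed = 14)
  once <- clean_dataset(s)
  twice <- clean_dataset(once)
  expect_equal(nrow(once), nrow(twice))
  expect_equal(once$animal_id, twice$animal_id)
  expect_equal(attr(twice, "cleaning_report")$n_input,
               attr(twice, "cleaning_report")$n_retained)

  empty <- clean_dataset(s[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "cleaning_report")$n_input, 0L)
})
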