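test_that("eligibility keeps >24h stays with orders and logs exclusions", {
  gl <- make_test_guidelines()
  pats <- make_test_patients(10)
  pats$exclusion_reason[c(2, 5, 8)] <- "congenital_anomaly"
  pats$exclusion_reason[1] <- "death"
  orders <- make_orders_at_recommendation(pats, gl)

  res <- apply_eligibility(pats, orders)
  expect_equal(nrow(res$included), 6)       # 10 - 3 anomalies - 1 death
  expect_equal(nrow(res$excluded), 4)
  expect_true(all(nzchar(res$excluded$exclusion_reason)))
  expect_true(any(grepl("death", res$log)))

  # a 1-day stay with one order and no exclusion reason is retained
  one_day <- pats[3, ]
  one_day$los_days <- 1L
  res2 <- apply_eligibility(one_day, orders[orders$patient_id ==
                                              one_day$patient_id, ][1, ])
  expect_equal(nrow(res2$included), 1)

  # short stays and order-less admissions get a derived reason
  pats$exclusion_reason <- NA_character_
  pats$los_days[4] <- 0L
  res3 <- apply_eligibility(pats, orders[orders$patient_id !=
                                           pats$patient_id[6], ])
  expect_setequal(res3$excluded$exclusion_reason,
                  c("stay_le_24h", "no_nutrition_orders"))
})

test_that("eligibility never mutates retained records and rejects duplicates", {
  gl <- make_test_guidelines()
  pats <- make_test_patients(8)
  orders <- make_orders_at_recommendation(pats, gl)
  res <- apply_eligibility(pats, orders)
  expect_identical(res$included, pats)

  dup <- rbind(pats, pats[1, ])
  expect_error(apply_eligibility(dup, orders), "duplicate patient_id.*T001")
})

test_that("gestation binning is half-open with the documented boundaries", {
  expect_equal(as.character(assign_gestation_category(32)), "G32_34")
  expect_equal(as.character(assign_gestation_category(30.1)), "G26_32")
  expect_equal(as.character(assign_gestation_category(38.5)), "G37_plus")
  expect_equal(as.character(assign_gestation_category(36.999)), "G34_37")
  expect_warning(cat22 <- assign_gestation_category(24), "folded")
  expect_equal(as.character(cat22), "G26_32")
  expect_error(assign_gestation_category(21.9), "outside")
  expect_error(assign_gestation_category(45.1), "outside")
})

test_that("stratification partitions any cohort", {
  set.seed(11)
  weeks <- runif(500, 26, 44)
  cats <- assign_gestation_category(weeks)
  expect_false(anyNA(cats))
  expect_equal(sum(table(cats)), 500)
  # each value lands in the interval of its label
  bins <- gestation_categories()
  idx <- match(as.character(cats), bins$label)
  expect_true(all(weeks >= bins$lo[idx] & weeks < bins$hi[idx]))
})

test_that("forward fill completes the day grid and is idempotent", {
  orders <- data.frame(day_of_life = c(1, 3), mode = "EN",
                       energy_kcal_per_kg = c(60, 90),
                       protein_g_per_kg = c(1.5, 2.5),
                       stringsAsFactors = FALSE)
  filled <- forward_fill_orders(orders, 4)
  expect_equal(filled$day_of_life, 1:4)
  expect_equal(filled$energy_kcal_per_kg, c(60, 60, 90, 90))
  expect_equal(filled$filled_forward, c(FALSE, TRUE, FALSE, TRUE))
  expect_false(any(filled$missing))

  # complete input comes back unchanged
  full <- data.frame(day_of_life = 1:3, mode = "PN",
                     energy_kcal_per_kg = c(40, 50, 60),
                     protein_g_per_kg = 2, stringsAsFactors = FALSE)
  out <- forward_fill_orders(full, 3)
  expect_equal(out$energy_kcal_per_kg, full$energy_kcal_per_kg)
  expect_false(any(out$filled_forward))

  # days before the first order stay missing and are flagged
  late <- data.frame(day_of_life = 2, mode = "EN",
                     energy_kcal_per_kg = 80, protein_g_per_kg = 2,
                     stringsAsFactors = FALSE)
  out2 <- forward_fill_orders(late, 3)
  expect_true(out2$missing[1])
  expect_true(is.na(out2$energy_kcal_per_kg[1]))
  expect_equal(out2$energy_kcal_per_kg[2:3], c(80, 80))

  # idempotence
  twice <- forward_fill_orders(forward_fill_orders(orders, 4), 4)
  expect_equal(twice, filled)
  expect_equal(forward_fill_orders(out2, 3), out2)

  expect_error(forward_fill_orders(orders[0, ], 3), "no nutrition orders")
})

test_that("mean imputation follows the 10% rule and preserves means", {
  pats <- make_test_patients(100)
  # 5% missing birth weight: imputed, mean preserved
  truth_mean <- mean(pats$birth_weight_g[6:100])
  pats$birth_weight_g[1:5] <- NA
  res <- impute_covariates(pats)
  expect_equal(res$dropped_fields, character(0))
  expect_false(anyNA(res$records$birth_weight_g))
  expect_equal(mean(res$records$birth_weight_g), truth_mean,
               tolerance = 1e-9)
  expect_equal(unname(res$imputed_counts["birth_weight_g"]), 5L)

  # 11% missing: field dropped, untouched
  pats2 <- make_test_patients(100)
  pats2$birth_weight_g[1:11] <- NA
  res2 <- impute_covariates(pats2)
  expect_equal(res2$dropped_fields, "birth_weight_g")
  expect_equal(sum(is.na(res2$records$birth_weight_g)), 11)

  # entirely missing: dropped, never imputed
  pats3 <- make_test_patients(20)
  pats3$gestation_weeks <- NA_real_
  res3 <- impute_covariates(pats3)
  expect_true("gestation_weeks" %in% res3$dropped_fields)

  # no missingness: identity
  pats4 <- make_test_patients(20)
  res4 <- impute_covariates(pats4)
  expect_identical(res4$records, pats4)

  # categorical missingness becomes an explicit unknown level
  pats5 <- make_test_patients(20)
  pats5$sex[3] <- NA
  res5 <- impute_covariates(pats5)
  expect_true("sex" %in% res5$flagged_categorical)
  expect_equal(res5$records$sex[3], "unknown")
})

test_that("cohort container validates order references and day ranges", {
  gl <- make_test_guidelines()
  pats <- make_test_patients(4)
  orders <- make_orders_at_recommendation(pats, gl)
  co <- nicu_cohort(pats, orders, orders[0, c("patient_id", "day_of_life")])
  expect_s3_class(co, "nicu_cohort")

  bad <- orders
  bad$patient_id[1] <- "GHOST"
  expect_error(nicu_cohort(pats, bad, orders[0, ]), "unknown patient_id")

  bad2 <- orders
  bad2$day_of_life[1] <- 99
  expect_error(nicu_cohort(pats, bad2, orders[0, ]), "outside")
})

test_that("cohort tables round-trip through delimited text", {
  co <- shared_small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$patients$patient_id, co$patients$patient_id)
  expect_equal(back$patients$los_days, co$patients$los_days)
  expect_equal(back$nutrition_orders$energy_kcal_per_kg,
               co$nutrition_orders$energy_kcal_per_kg)
  expect_equal(back$ground_truth$true_coefficients$energy_q4,
               co$ground_truth$true_coefficients[["energy_q4"]])
})
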