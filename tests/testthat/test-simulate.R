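test_that("identical seeds reproduce the cohort exactly", {
  cfg <- sim_config(n_patients = 120)
  a <- simulate_cohort(cfg, seed = 9)
  b <- simulate_cohort(cfg, seed = 9)
  expect_identical(a$patients, b$patients)
  expect_identical(a$nutrition_orders, b$nutrition_orders)
  expect_identical(a$medication_orders, b$medication_orders)
  expect_identical(a$ground_truth$patients, b$ground_truth$patients)
  c2 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(a$patients$los_days, c2$patients$los_days))
})

test_that("the noiseless zero-effect limit hits the stratum baselines", {
  cfg <- zero_gap_config(n_patients = 120)
  co <- simulate_cohort(cfg, seed = 3)
  cats <- as.character(assign_gestation_category(co$patients$gestation_weeks))
  expect_equal(co$patients$los_days,
               as.integer(ceiling(exp(cfg$baseline_log_los[cats]))))
})

test_that("stratum counts follow the configured mix within binomial error", {
  mix <- c(G26_32 = 0.10, G32_34 = 0.25, G34_37 = 0.32, G37_plus = 0.33)
  co <- simulate_cohort(sim_config(n_patients = 800, category_mix = mix),
                        seed = 21)
  counts <- table(assign_gestation_category(co$patients$gestation_weeks))
  for (cc in names(mix)) {
    expected <- 800 * mix[[cc]]
    band <- 3 * sqrt(800 * mix[[cc]] * (1 - mix[[cc]]))
    expect_lt(abs(counts[[cc]] - expected), band)
  }
})

test_that("constant-gap orders reproduce the latent deviation factor exactly", {
  co <- simulate_cohort(sim_config(n_patients = 150), seed = 31)
  gl <- default_guidelines()
  gaps <- daily_nutrition_deviations(
    nicu_cohort(within(co$patients, birth_weight_g[is.na(birth_weight_g)] <-
                         2000),
                co$nutrition_orders, co$medication_orders), gl)
  gt <- co$ground_truth$patients
  # restrict to patients with complete weight (missingness perturbs class)
  ok <- co$patients$patient_id[!is.na(co$patients$birth_weight_g)]
  ok <- intersect(ok, unique(gaps$patient_id))
  df <- vapply(split(gaps$energy_gap[gaps$patient_id %in% ok],
                     gaps$patient_id[gaps$patient_id %in% ok]),
               function(g) sqrt(sum(g^2)) / length(g), numeric(1))
  idx <- match(names(df), gt$patient_id)
  expect_equal(unname(df), gt$d_energy[idx], tolerance = 1e-6)
})

test_that("iid daily gaps have the chi-square second moment", {
  scale5 <- c(G26_32 = 5, G32_34 = 5, G34_37 = 5, G37_plus = 5)
  cfg <- sim_config(n_patients = 250,
                    deviation_profile = list(gap_model = "iid_daily",
                                             p_zero_gap = 0,
                                             energy_scale = scale5))
  co <- simulate_cohort(cfg, seed = 77)
  gl <- default_guidelines()
  pats <- co$patients
  pats$birth_weight_g[is.na(pats$birth_weight_g)] <- 2000
  gaps <- daily_nutrition_deviations(
    nicu_cohort(pats, co$nutrition_orders, co$medication_orders), gl)
  gt <- co$ground_truth$patients
  ss <- vapply(split(gaps$energy_gap, gaps$patient_id),
               function(g) sum(g^2), numeric(1))
  idx <- match(names(ss), gt$patient_id)
  n_days <- vapply(split(gaps$patient_id, gaps$patient_id), length,
                   integer(1))
  expected <- n_days * gt$d_energy[idx]^2  # E[sum gap^2] = n * sigma^2
  sel <- expected > 0
  expect_equal(sum(ss[sel]) / sum(expected[sel]), 1, tolerance = 0.15)
})

test_that("marginal prevalences are stable across seeds", {
  cfg <- sim_config(n_patients = 1000)
  a <- simulate_cohort(cfg, seed = 1)$patients
  b <- simulate_cohort(cfg, seed = 2)$patients
  for (f in c("sex", "delivery_mode", "rds")) {
    pa <- mean(a[[f]] == a[[f]][1])
    pb <- mean(b[[f]] == a[[f]][1])
    expect_lt(abs(pa - pb), 4 * sqrt(0.25 * 2 / 1000) + 0.02)
  }
})

test_that("per-record order simulation honours the profile switches", {
  gl <- default_guidelines()
  rec <- data.frame(patient_id = "X1", birth_weight_g = 1800,
                    gestation_weeks = 33, los_days = 6L,
                    stringsAsFactors = FALSE)
  # zero-gap profile: orders equal the recommendation, factor 0
  zero <- simulate_orders(rec, gl, profile = list(p_zero_gap = 1), seed = 5)
  gaps <- mapply(function(d, m, e) {
    recommend_nutrition(gl, 1800, d, m, "energy_kcal_per_kg") - e
  }, zero$nutrition$day_of_life, zero$nutrition$mode,
  zero$nutrition$energy_kcal_per_kg)
  expect_equal(deviation_factor(gaps, numeric(length(gaps))), 0)

  # a fixed 12%-high dose makes every medicated day a deviation day
  dev <- simulate_orders(rec, gl,
                         profile = list(medication_category = "no_deviation",
                                        fixed_dose_multiplier = 1.12),
                         seed = 6)
  s <- summarize_medication(dev$medication, gl, los_days = 6)
  core_days <- unique(dev$medication$day_of_life[
    !is_supplement(gl, dev$medication$drug)])
  expect_equal(s$medication_category, "deviation")
  expect_equal(s$deviation_days, length(core_days))

  # unknown drug in the panel errors
  expect_error(
    simulate_cohort(sim_config(n_patients = 50,
                               medication = list(panel = c("amikacin",
                                                           "unobtainium"))),
                    seed = 1),
    "unobtainium")
})

test_that("tiny cohorts are rejected and dates drive the split tag", {
  expect_error(simulate_cohort(sim_config(n_patients = 20)), "too small")
  co <- simulate_cohort(sim_config(n_patients = 300), seed = 12)
  cutoff <- seq(as.Date("2018-07-01"), by = "month", length.out = 13)[13]
  expect_equal(co$patients$split_tag == "validate",
               co$patients$admission_date >= cutoff)
  # both tags present, validate is the smaller fraction
  tab <- table(co$patients$split_tag)
  expect_true(all(c("train", "validate") %in% names(tab)))
  expect_lt(tab[["validate"]], tab[["train"]])
})
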