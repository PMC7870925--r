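# Shared fixtures, all built in code.

# A minimal guideline set with round numbers, independent of the shipped
# tables: one drug (rec 10 mg/kg, 2/day), one supplement, flat-ish
# nutrition bands.
make_test_guidelines <- function() {
  nutrition <- expand.grid(
    mode = c("EN", "PN"),
    nutrient = c("energy_kcal_per_kg", "protein_g_per_kg"),
    weight_class = c("le_2500g", "gt_2500g"),
    stringsAsFactors = FALSE
  )
  nutrition <- nutrition[rep(seq_len(nrow(nutrition)), each = 2), ]
  nutrition$day_lo <- rep(c(1, 4), 8)
  nutrition$day_hi <- rep(c(3, Inf), 8)
  base <- ifelse(nutrition$nutrient == "energy_kcal_per_kg", 100, 3)
  nutrition$recommended <- base *
    ifelse(nutrition$mode == "PN", 0.8, 1) *
    ifelse(nutrition$day_lo == 1, 0.5, 1)
  medication <- data.frame(
    drug = c("testdrug", "vitamin_d"),
    dose_per_kg = c(10, 1),
    frequency_per_day = c(2, 1),
    is_supplement = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  gl <- structure(
    list(nutrition = nutrition, medication = medication,
         supplements = "vitamin_d", version = "test-1"),
    class = "guideline_set"
  )
  validate_guidelines(gl)
  gl
}

# A small hand-built admission table covering all four strata.
make_test_patients <- function(n = 12) {
  weeks <- rep(c(30, 33, 35, 38), length.out = n)
  data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    site = "urban",
    gestation_weeks = weeks,
    birth_weight_g = rep(c(1400, 1900, 2300, 2800), length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    delivery_mode = rep(c("cesarean", "vaginal"), length.out = n),
    multiple_pregnancy = FALSE, inborn = TRUE,
    antenatal_steroids = "none", maternal_disease = FALSE,
    antenatal_infection = FALSE, antenatal_risk_factor = FALSE,
    need_ppv = FALSE, apgar5_lt5 = FALSE,
    admission_date = as.Date("2019-01-01") + seq_len(n),
    los_days = rep(c(5L, 3L, 4L, 6L), length.out = n),
    rds = FALSE, severe_rds = FALSE, ttnb = FALSE, mas = FALSE,
    pneumothorax = FALSE, pphn = FALSE, sepsis = FALSE, nnh = FALSE,
    asphyxia = FALSE,
    exclusion_reason = NA_character_,
    split_tag = "train",
    stringsAsFactors = FALSE
  )
}

# one EN nutrition order per day at the recommended value
make_orders_at_recommendation <- function(patients, guidelines) {
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    days <- seq_len(patients$los_days[i])
    data.frame(
      patient_id = patients$patient_id[i], day_of_life = days, mode = "EN",
      energy_kcal_per_kg = recommend_nutrition(
        guidelines, patients$birth_weight_g[i], days, "EN",
        "energy_kcal_per_kg"),
      protein_g_per_kg = recommend_nutrition(
        guidelines, patients$birth_weight_g[i], days, "EN",
        "protein_g_per_kg"),
      filled_forward = FALSE, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Memoised moderate-size simulated run shared across test files.
.test_cache <- new.env(parent = emptyenv())

shared_small_run <- function() {
  if (is.null(.test_cache$run)) {
    co <- simulate_cohort(sim_config(n_patients = 500), seed = 424242)
    .test_cache$run <- suppressWarnings(suppressMessages(
      run_pipeline(co, seed = 424242, n_iterations = 25)))
    .test_cache$cohort <- co
  }
  .test_cache$run
}

shared_small_cohort <- function() {
  shared_small_run()
  .test_cache$cohort
}

# Independent brute-force ordinary marginal means: explicit loops over the
# reference grid, weights taken straight from level frequencies in `data`.
brute_force_omm <- function(fit, data, factor_name) {
  cats <- names(fit$level_weights)
  levs <- lapply(cats, function(t) {
    lv <- names(fit$level_weights[[t]])
    if (identical(lv, c("FALSE", "TRUE"))) c(FALSE, TRUE) else lv
  })
  names(levs) <- cats
  grid <- expand.grid(levs, stringsAsFactors = FALSE)
  for (t in cats) {
    if (is.factor(data[[t]])) {
      grid[[t]] <- factor(grid[[t]], levels = levels(data[[t]]))
    }
  }
  for (t in names(fit$continuous_means)) {
    grid[[t]] <- fit$continuous_means[[t]]
  }
  target_levels <- names(fit$level_weights[[factor_name]])
  out <- numeric(0)
  for (L in target_levels) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(grid))) {
      if (as.character(grid[[factor_name]][i]) != L) next
      w <- 1
      for (t in setdiff(cats, factor_name)) {
        lev_i <- as.character(grid[[t]][i])
        w <- w * mean(as.character(data[[t]]) == lev_i)
      }
      num <- num + w * stats::predict(fit$model,
                                      newdata = grid[i, , drop = FALSE])
      den <- den + w
    }
    out[L] <- num / den
  }
  out
}
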