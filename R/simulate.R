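#' Simulation configuration for the synthetic NICU cohort
#'
#' Returns the default configuration of the synthetic two-site cohort
#' generator, optionally overriding any field. The defaults emulate the
#' covariate mix of a two-site level-III NICU population across the four
#' gestation strata (per-stratum prevalences of perinatal covariates and
#' diagnoses, gestational-age and birth-weight distributions, medication
#' use) and generate length of stay from a known multiplicative model:
#' `log(LOS) = baseline(category) + sum(beta * X) + Normal(0, noise_sd_log)`,
#' rounded up to at least one day. Effects on deviation quartiles are
#' injected by drawing each patient's continuous deviation first and adding
#' the LOS effect for patients whose deviation falls in the top quartile of
#' their stratum, using the analyzer's own quartile rule, so generator and
#' analyzer share the coding.
#'
#' A `response_family = "identity"` switch generates day-scale additive LOS
#' instead (`baseline_los_days`, `true_coefficients_days`,
#' `noise_sd_days`), giving model-family selection a case where the linear
#' family is the right answer.
#'
#' @param ... Named overrides of any default field.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(...) {
  cats <- c("G26_32", "G32_34", "G34_37", "G37_plus")
  pc <- function(...) stats::setNames(c(...), cats)
  cfg <- list(
    n_patients = 1047L,
    site_mix = 0.56,                    # proportion rural
    months_train = 12L,
    months_validate = 4L,
    start_date = as.Date("2018-07-01"),
    category_mix = pc(0.102, 0.252, 0.319, 0.327),
    response_family = "log",
    baseline_log_los = pc(2.60, 1.52, 0.95, 0.85),
    noise_sd_log = 0.3,
    # log-scale effects; zeros are designed null terms
    true_coefficients = c(
      gestation_centered = -0.08, sex_male = 0, multiple_pregnancy = 0,
      rds = 0, ttnb = 0, sepsis = 0.4, nnh = 0,
      med_no_deviation = 0, med_deviation = 0.5,
      energy_q4 = 0.808, protein_q4 = 0.1
    ),
    # identity-scale counterparts (used when response_family = "identity")
    baseline_los_days = pc(25, 6, 4, 4),
    noise_sd_days = 2.5,
    true_coefficients_days = c(
      gestation_centered = -2, sex_male = 1, multiple_pregnancy = 0,
      rds = 2, ttnb = 0, sepsis = 6, nnh = 0,
      med_no_deviation = 1, med_deviation = 5,
      energy_q4 = 5, protein_q4 = 1
    ),
    # nutrition deviation profile (per-patient latent deviation factors)
    deviation_profile = list(
      gap_model = "constant",           # or "iid_daily"
      p_zero_gap = 0.05,
      energy_scale = pc(15, 8, 7, 7),   # kcal/kg/day
      protein_scale = pc(0.5, 0.3, 0.25, 0.2),  # g/kg/day
      mode_probs = c(EN = 0.6, PN = 0.15, BOTH = 0.25)
    ),
    # medication behaviour
    medication = list(
      medicated_prob = pc(0.82, 0.32, 0.31, 0.40),
      deviation_prob_given_medicated = pc(0.40, 0.24, 0.23, 0.31),
      dose_deviation_magnitude = c(0.10, 0.35),  # relative, >= threshold
      clean_dose_jitter = 0.08,                  # relative, < threshold
      frequency_deviation_prob = 0.05,
      panel = c("amikacin", "gentamicin", "ampicillin", "cefotaxime",
                "caffeine_citrate", "phenobarbital"),
      supplements = c("vitamin_d", "iron"),
      sepsis_boost = 2                  # multiplier among dose-deviators
    ),
    diagnosis_prevalence = list(
      rds = pc(0.705, 0.445, 0.367, 0.293),
      severe_rds_given_rds = pc(0.27, 0.11, 0.30, 0.43),
      ttnb = pc(0.188, 0.104, 0.150, 0.102),
      mas = pc(0, 0, 0.007, 0.026),
      pneumothorax = pc(0.023, 0.013, 0.026, 0.022),
      pphn = pc(0, 0, 0, 0.006),
      sepsis = pc(0.388, 0.066, 0.109, 0.125),
      nnh = pc(0.600, 0.327, 0.330, 0.326),
      asphyxia = pc(0, 0, 0.007, 0.073)
    ),
    covariate_prevalence = list(
      male = pc(0.729, 0.602, 0.659, 0.725),
      cesarean = pc(0.823, 0.886, 0.794, 0.579),
      multiple_pregnancy = pc(0.529, 0.518, 0.221, 0.018),
      inborn = pc(0.788, 0.654, 0.640, 0.348),
      steroids_complete = pc(0.541, 0.548, 0.217, 0.018),
      steroids_incomplete = pc(0.10, 0.10, 0.05, 0.02),
      maternal_disease = pc(0.317, 0.370, 0.221, 0.062),
      antenatal_infection = pc(0.023, 0.005, 0.007, 0.009),
      antenatal_risk_factor = pc(0.329, 0.218, 0.104, 0.029),
      need_ppv = pc(0.070, 0.031, 0.019, 0.022),
      apgar5_lt5 = pc(0.011, 0.001, 0.003, 0.007)
    ),
    gestation_mean = pc(30.1, 33.1, 35.5, 38.5),
    gestation_sd = pc(1.5, 0.6, 0.8, 1.0),
    birth_weight_mean = pc(1425, 1876, 2236, 2737),
    birth_weight_sd = pc(312, 348, 508, 537),
    exclusion_rate = 0.04,
    no_orders_rate = 0.005,
    missingness_rates = c(birth_weight_g = 0.02, maternal_disease = 0.01),
    seed = 20260101L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Degenerate zero-deviation configuration
#'
#' All nutrition gaps zero, all medication doses at reference, no injected
#' effects, near-zero noise, no missingness: every deviation statistic
#' downstream must be exactly zero and predicted LOS must match the
#' stratum baselines within rounding. Used for end-to-end conservation
#' checks.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
zero_gap_config <- function(...) {
  zero_coefs <- sim_config()$true_coefficients * 0
  sim_config(
    deviation_profile = list(
      p_zero_gap = 1,
      energy_scale = c(G26_32 = 0, G32_34 = 0, G34_37 = 0, G37_plus = 0),
      protein_scale = c(G26_32 = 0, G32_34 = 0, G34_37 = 0, G37_plus = 0)
    ),
    medication = list(
      deviation_prob_given_medicated =
        c(G26_32 = 0, G32_34 = 0, G34_37 = 0, G37_plus = 0),
      clean_dose_jitter = 0, frequency_deviation_prob = 0
    ),
    true_coefficients = zero_coefs,
    noise_sd_log = 1e-9,
    missingness_rates = c(birth_weight_g = 0, maternal_disease = 0),
    exclusion_rate = 0,
    no_orders_rate = 0,
    ...
  )
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` or plain list with its fields.
#' @return Invisibly `TRUE`.
#' @export
validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$category_mix) - 1) > 1e-9) {
    stop("category_mix must sum to 1")
  }
  if (cfg$response_family == "log" && cfg$noise_sd_log <= 0) {
    stop("noise_sd_log must be > 0")
  }
  probs <- c(unlist(cfg$diagnosis_prevalence),
             unlist(cfg$covariate_prevalence),
             cfg$medication$medicated_prob,
             cfg$medication$deviation_prob_given_medicated,
             cfg$deviation_profile$p_zero_gap, cfg$site_mix)
  if (any(probs < 0 | probs > 1)) stop("prevalences must lie in [0, 1]")
  invisible(TRUE)
}

# Bernoulli draw per patient from a per-category prevalence vector
.draw_flag <- function(prev, category) {
  stats::runif(length(category)) < prev[as.character(category)]
}

.truncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x >= hi)
  for (i in bad) {
    for (try in 1:100) {
      x[i] <- stats::rnorm(1, mean[i], sd[i])
      if (x[i] >= lo[i] && x[i] < hi[i]) break
    }
    if (x[i] < lo[i] || x[i] >= hi[i]) {
      x[i] <- (lo[i] + min(hi[i], lo[i] + 4 * sd[i])) / 2
    }
  }
  x
}

# linear predictor from the generator's canonical effect names
.truth_lp <- function(df, coefs) {
  lp <- numeric(nrow(df))
  x <- list(
    gestation_centered = df$gestation_centered,
    sex_male = df$sex == "male",
    delivery_cesarean = df$delivery_mode == "cesarean",
    multiple_pregnancy = df$multiple_pregnancy,
    inborn = df$inborn,
    rds = df$rds, ttnb = df$ttnb, sepsis = df$sepsis, nnh = df$nnh,
    med_no_deviation = df$med_category == "no_deviation",
    med_deviation = df$med_category == "deviation",
    energy_q4 = df$energy_q4, protein_q4 = df$protein_q4
  )
  for (nm in names(coefs)) {
    if (!nm %in% names(x)) stop("unknown truth coefficient: ", nm)
    lp <- lp + coefs[[nm]] * as.numeric(x[[nm]])
  }
  lp
}

#' Simulate a synthetic NICU cohort with known ground truth
#'
#' Draws admission covariates, diagnoses, latent nutrition-deviation
#' factors and medication behaviour per gestation stratum, generates LOS
#' from the configured multiplicative (or additive) model, and emits the
#' daily nutrition and medication order streams whose downstream deviation
#' statistics reproduce the injected latent values exactly (constant-gap
#' profile). Identical seeds give identical cohorts.
#'
#' @param config A [sim_config()].
#' @param guidelines Guideline set used to anchor order values, default
#'   [default_guidelines()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A [nicu_cohort()] with a `ground_truth` element: the true
#'   coefficients, baselines, noise level, and a per-patient table of
#'   noiseless LOS, latent deviation factors, quartile flags and
#'   medication category.
#' @export
simulate_cohort <- function(config = sim_config(),
                            guidelines = default_guidelines(),
                            seed = NULL) {
  validate_sim_config(config)
  if (config$n_patients < 40) {
    stop("n_patients < 40 is too small for quartile coding")
  }
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  n <- as.integer(config$n_patients)
  cats <- names(config$category_mix)

  category <- factor(sample(cats, n, replace = TRUE,
                            prob = config$category_mix), levels = cats)
  cati <- as.character(category)
  edges_lo <- c(G26_32 = 26, G32_34 = 32, G34_37 = 34, G37_plus = 37)
  edges_hi <- c(G26_32 = 32, G32_34 = 34, G34_37 = 37, G37_plus = 42)
  gest <- .truncnorm(n, config$gestation_mean[cati],
                     config$gestation_sd[cati],
                     edges_lo[cati], edges_hi[cati])
  # keep the 1-decimal rounding inside the stratum's half-open interval
  gest <- pmax(edges_lo[cati], pmin(round(gest, 1), edges_hi[cati] - 0.1))
  bw <- .truncnorm(n, config$birth_weight_mean[cati],
                   config$birth_weight_sd[cati],
                   rep(500, n), rep(5500, n))

  cp <- config$covariate_prevalence
  dp <- config$diagnosis_prevalence
  steroid_draw <- stats::runif(n)
  p_comp <- cp$steroids_complete[cati]
  p_inc <- cp$steroids_incomplete[cati]
  df <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    site = ifelse(stats::runif(n) < config$site_mix, "rural", "urban"),
    gestation_weeks = gest,
    birth_weight_g = round(bw),
    sex = ifelse(.draw_flag(cp$male, category), "male", "female"),
    delivery_mode = ifelse(.draw_flag(cp$cesarean, category),
                           "cesarean", "vaginal"),
    multiple_pregnancy = .draw_flag(cp$multiple_pregnancy, category),
    inborn = .draw_flag(cp$inborn, category),
    antenatal_steroids = ifelse(steroid_draw < p_comp, "complete",
                                ifelse(steroid_draw < p_comp + p_inc,
                                       "incomplete", "none")),
    maternal_disease = .draw_flag(cp$maternal_disease, category),
    antenatal_infection = .draw_flag(cp$antenatal_infection, category),
    antenatal_risk_factor = .draw_flag(cp$antenatal_risk_factor, category),
    need_ppv = .draw_flag(cp$need_ppv, category),
    apgar5_lt5 = .draw_flag(cp$apgar5_lt5, category),
    stringsAsFactors = FALSE
  )
  df$gestation_centered <- df$gestation_weeks -
    gestation_reference_weeks()[cati]
  for (dx in c("rds", "ttnb", "mas", "pneumothorax", "pphn", "nnh",
               "asphyxia")) {
    df[[dx]] <- .draw_flag(dp[[dx]], category)
  }
  df$severe_rds <- df$rds & .draw_flag(dp$severe_rds_given_rds, category)

  # medication behaviour (latent truth)
  med <- config$medication
  medicated <- .draw_flag(med$medicated_prob, category)
  deviating <- medicated &
    .draw_flag(med$deviation_prob_given_medicated, category)
  df$med_category <- ifelse(!medicated, "not_required",
                            ifelse(deviating, "deviation", "no_deviation"))

  # sepsis: elevated among dose-deviators, never in the not-required group
  p_sepsis <- dp$sepsis[cati]
  p_sepsis[deviating] <- pmin(0.95, p_sepsis[deviating] * med$sepsis_boost)
  df$sepsis <- stats::runif(n) < p_sepsis & medicated

  # latent per-patient deviation factors, Q4-coded with the analyzer's rule
  prof <- config$deviation_profile
  zero_e <- stats::runif(n) < prof$p_zero_gap
  zero_p <- stats::runif(n) < prof$p_zero_gap
  df$d_energy <- ifelse(zero_e, 0,
                        abs(stats::rnorm(n, 0, prof$energy_scale[cati])))
  df$d_protein <- ifelse(zero_p, 0,
                         abs(stats::rnorm(n, 0, prof$protein_scale[cati])))
  df$energy_q4 <- FALSE
  df$protein_q4 <- FALSE
  for (cc in cats) {
    sel <- which(cati == cc)
    if (length(sel) >= 8) {
      df$energy_q4[sel] <- quartile_code(df$d_energy[sel])$code == "Q4"
      df$protein_q4[sel] <- quartile_code(df$d_protein[sel])$code == "Q4"
    }
  }

  # length of stay from the configured truth model
  if (config$response_family == "log") {
    lp <- config$baseline_log_los[cati] +
      .truth_lp(df, as.list(config$true_coefficients))
    z <- lp + stats::rnorm(n, 0, config$noise_sd_log)
    los <- pmax(1, ceiling(exp(z)))
    noiseless <- pmax(1, ceiling(exp(lp)))
  } else {
    lp <- config$baseline_los_days[cati] +
      .truth_lp(df, as.list(config$true_coefficients_days))
    z <- lp + stats::rnorm(n, 0, config$noise_sd_days)
    los <- pmax(1, ceiling(z))
    noiseless <- pmax(1, ceiling(lp))
  }
  df$los_days <- as.integer(los)

  # admission dates over the study window; split tag by date
  months_total <- config$months_train + config$months_validate
  month_seq <- seq(config$start_date, by = "month",
                   length.out = months_total + 1)
  total_days <- as.integer(month_seq[months_total + 1] - config$start_date)
  df$admission_date <- config$start_date +
    sample.int(total_days, n, replace = TRUE) - 1
  df$split_tag <- ifelse(
    df$admission_date < month_seq[config$months_train + 1],
    "train", "validate")

  # a-priori exclusions and order-less admissions
  reasons <- c("congenital_anomaly", "palliative", "discharge_on_request",
               "transfer", "death")
  df$exclusion_reason <- NA_character_
  excl <- stats::runif(n) < config$exclusion_rate
  df$exclusion_reason[excl] <- sample(reasons, sum(excl), replace = TRUE)
  no_orders <- !excl & stats::runif(n) < config$no_orders_rate

  eligible <- which(!excl & !no_orders)
  orders <- .simulate_cohort_orders(df[eligible, , drop = FALSE],
                                    guidelines, config)

  ground_truth <- list(
    response_family = config$response_family,
    baselines = as.list(if (config$response_family == "log")
      config$baseline_log_los else config$baseline_los_days),
    true_coefficients = as.list(if (config$response_family == "log")
      config$true_coefficients else config$true_coefficients_days),
    noise_sd = if (config$response_family == "log")
      config$noise_sd_log else config$noise_sd_days,
    patients = data.frame(
      patient_id = df$patient_id, gestation_category = cati,
      noiseless_lp = lp, noiseless_los_days = as.integer(noiseless),
      d_energy = df$d_energy, d_protein = df$d_protein,
      energy_q4 = df$energy_q4, protein_q4 = df$protein_q4,
      med_category = df$med_category, stringsAsFactors = FALSE
    )
  )

  patients <- df[, c(.patient_columns)]
  # inject missingness (ground truth keeps the complete values)
  mr <- config$missingness_rates
  for (f in names(mr)) {
    if (mr[[f]] <= 0 || !f %in% names(patients)) next
    patients[[f]][stats::runif(n) < mr[[f]]] <- NA
  }

  nicu_cohort(patients, orders$nutrition, orders$medication,
              ground_truth = ground_truth, config = config)
}

# order streams for eligible patients; latent columns must be present
.simulate_cohort_orders <- function(df, guidelines, config) {
  prof <- config$deviation_profile
  med_cfg <- config$medication
  panel <- med_cfg$panel
  unknown <- setdiff(c(panel, med_cfg$supplements),
                     guidelines$medication$drug)
  if (length(unknown)) {
    stop("drug panel not covered by guidelines: ",
         paste(unknown, collapse = ", "))
  }
  n <- nrow(df)
  los <- df$los_days

  # ---- nutrition: one order per day, mode drawn per day ----
  idx <- rep.int(seq_len(n), los)
  day <- sequence(los)
  mode <- sample(names(prof$mode_probs), length(day), replace = TRUE,
                 prob = prof$mode_probs)
  wc_weight <- df$birth_weight_g[idx]
  rec_e <- rep(NA_real_, length(day))
  rec_p <- rep(NA_real_, length(day))
  for (m in unique(mode)) {
    sel <- mode == m
    rec_e[sel] <- recommend_nutrition(guidelines, wc_weight[sel], day[sel],
                                      m, "energy_kcal_per_kg")
    rec_p[sel] <- recommend_nutrition(guidelines, wc_weight[sel], day[sel],
                                      m, "protein_g_per_kg")
  }

  gap_model <- prof$gap_model
  if (identical(gap_model, "constant")) {
    # constant daily gap g = d * sqrt(los): the downstream L2/n deviation
    # factor equals the latent d exactly; underfeeding flips to
    # overfeeding when it would drive an order negative
    g_e <- (df$d_energy * sqrt(los))[idx]
    g_p <- (df$d_protein * sqrt(los))[idx]
    s_e <- sample(c(-1, 1), n, replace = TRUE)[idx]
    s_p <- sample(c(-1, 1), n, replace = TRUE)[idx]
    min_rec_e <- tapply(rec_e, idx, min)[as.character(idx)]
    min_rec_p <- tapply(rec_p, idx, min)[as.character(idx)]
    s_e[s_e > 0 & g_e > min_rec_e] <- -1
    s_p[s_p > 0 & g_p > min_rec_p] <- -1
    ord_e <- rec_e - s_e * g_e
    ord_p <- rec_p - s_p * g_p
  } else if (identical(gap_model, "iid_daily")) {
    ord_e <- pmax(0, rec_e - stats::rnorm(length(day), 0,
                                          df$d_energy[idx]))
    ord_p <- pmax(0, rec_p - stats::rnorm(length(day), 0,
                                          df$d_protein[idx]))
  } else {
    stop("unknown gap_model: ", gap_model)
  }
  nutrition <- data.frame(
    patient_id = df$patient_id[idx], day_of_life = day, mode = mode,
    energy_kcal_per_kg = round(pmax(0, ord_e), 6),
    protein_g_per_kg = round(pmax(0, ord_p), 6),
    filled_forward = FALSE, stringsAsFactors = FALSE
  )

  # ---- medication ----
  med_rows <- vector("list", n)
  ref_dose <- stats::setNames(guidelines$medication$dose_per_kg,
                              guidelines$medication$drug)
  ref_freq <- stats::setNames(guidelines$medication$frequency_per_day,
                              guidelines$medication$drug)
  lo_mag <- med_cfg$dose_deviation_magnitude[1]
  hi_mag <- med_cfg$dose_deviation_magnitude[2]
  for (i in seq_len(n)) {
    rows <- data.frame(
      patient_id = df$patient_id[i],
      day_of_life = seq_len(min(los[i], length(med_cfg$supplements))),
      drug = med_cfg$supplements[seq_len(min(los[i],
                                             length(med_cfg$supplements)))],
      dose_per_kg = unname(ref_dose[med_cfg$supplements[
        seq_len(min(los[i], length(med_cfg$supplements)))]]),
      frequency_per_day = unname(ref_freq[med_cfg$supplements[
        seq_len(min(los[i], length(med_cfg$supplements)))]]),
      stringsAsFactors = FALSE
    )
    if (df$med_category[i] != "not_required") {
      drugs <- sample(panel, 1 + stats::rbinom(1, 1, 0.4))
      span <- max(1, min(los[i], sample(2:7, 1)))
      d_idx <- rep(seq_len(span), times = length(drugs))
      d_drug <- rep(drugs, each = span)
      mult <- 1 + stats::runif(length(d_idx), -1, 1) *
        med_cfg$clean_dose_jitter
      if (df$med_category[i] == "deviation") {
        p_day <- stats::runif(1, 0.2, 0.8)
        dev_day <- stats::runif(span) < p_day
        if (!any(dev_day)) dev_day[1] <- TRUE
        hit <- dev_day[d_idx]
        mult[hit] <- 1 + sample(c(-1, 1), sum(hit), replace = TRUE) *
          stats::runif(sum(hit), lo_mag, hi_mag)
      }
      freq <- unname(ref_freq[d_drug])
      fdev <- stats::runif(length(d_idx)) < med_cfg$frequency_deviation_prob
      freq[fdev] <- freq[fdev] + 1
      rows <- rbind(rows, data.frame(
        patient_id = df$patient_id[i], day_of_life = d_idx, drug = d_drug,
        dose_per_kg = round(unname(ref_dose[d_drug]) * mult, 6),
        frequency_per_day = freq, stringsAsFactors = FALSE
      ))
    }
    med_rows[[i]] <- rows
  }
  medication <- do.call(rbind, med_rows)
  rownames(medication) <- NULL
  list(nutrition = nutrition, medication = medication)
}

#' Simulate order streams for a single admission
#'
#' Stand-alone per-record version of the order generator: draws a latent
#' deviation factor from the profile and emits the daily nutrition orders
#' and the medication orders for one admission. Used for focused
#' order-level tests; [simulate_cohort()] generates whole cohorts with
#' injected LOS effects.
#'
#' @param record One-row data.frame with at least `patient_id`,
#'   `birth_weight_g`, `gestation_weeks`, `los_days`.
#' @param guidelines A `guideline_set`.
#' @param profile Deviation profile as in `sim_config()$deviation_profile`;
#'   may additionally carry `medication_category` (`"not_required"`,
#'   `"no_deviation"` or `"deviation"`, default `"no_deviation"`) and
#'   `fixed_dose_multiplier` (every non-supplement order's dose is the
#'   reference times this value).
#' @param seed Integer seed.
#' @return list with `nutrition` and `medication` data.frames.
#' @export
simulate_orders <- function(record, guidelines, profile, seed = 1L) {
  stopifnot(nrow(record) == 1)
  set.seed(seed)
  cfg <- sim_config()
  prof <- utils::modifyList(cfg$deviation_profile, profile)
  cati <- as.character(assign_gestation_category(record$gestation_weeks))
  df <- record
  df$d_energy <- abs(stats::rnorm(1, 0, prof$energy_scale[cati])) *
    (stats::runif(1) >= prof$p_zero_gap)
  df$d_protein <- abs(stats::rnorm(1, 0, prof$protein_scale[cati])) *
    (stats::runif(1) >= prof$p_zero_gap)
  df$med_category <- if (!is.null(profile$medication_category)) {
    profile$medication_category
  } else {
    "no_deviation"
  }
  config <- cfg
  config$deviation_profile <- prof
  out <- .simulate_cohort_orders(df, guidelines, config)
  if (!is.null(profile$fixed_dose_multiplier)) {
    core <- !is_supplement(guidelines, out$medication$drug)
    ref <- stats::setNames(guidelines$medication$dose_per_kg,
                           guidelines$medication$drug)
    out$medication$dose_per_kg[core] <-
      unname(ref[out$medication$drug[core]]) *
      profile$fixed_dose_multiplier
  }
  out
}
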