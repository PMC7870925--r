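#' @importFrom stats setNames quantile median sd rnorm runif rbinom complete.cases
#' @importFrom utils read.csv write.csv
NULL

# Column order used for all patient tables; keeps written tables stable.
.patient_columns <- c(
  "patient_id", "site", "gestation_weeks", "birth_weight_g", "sex",
  "delivery_mode", "multiple_pregnancy", "inborn", "antenatal_steroids",
  "maternal_disease", "antenatal_infection", "antenatal_risk_factor",
  "need_ppv", "apgar5_lt5", "admission_date", "los_days",
  "rds", "severe_rds", "ttnb", "mas", "pneumothorax", "pphn",
  "sepsis", "nnh", "asphyxia", "exclusion_reason", "split_tag"
)

.diagnosis_flags <- c(
  "rds", "severe_rds", "ttnb", "mas", "pneumothorax", "pphn",
  "sepsis", "nnh", "asphyxia"
)

.exclusion_reasons <- c(
  "congenital_anomaly", "palliative", "discharge_on_request",
  "transfer", "death", "stay_le_24h", "no_nutrition_orders"
)

#' Construct a NICU cohort object
#'
#' Bundles the three cohort tables (one admission per row, daily nutrition
#' orders, medication orders) into a validated container. Every order must
#' reference a known `patient_id` and its day of life must lie within
#' `[1, los_days]` for that patient (days of life are 1-based; day 1 is the
#' admission day).
#'
#' @param patients data.frame of admissions (see package README for the
#'   column contract).
#' @param nutrition_orders data.frame with columns `patient_id`,
#'   `day_of_life`, `mode` (`EN`, `PN` or `BOTH`), `energy_kcal_per_kg`,
#'   `protein_g_per_kg`, and optionally `filled_forward`.
#' @param medication_orders data.frame with columns `patient_id`,
#'   `day_of_life`, `drug`, `dose_per_kg`, `frequency_per_day`.
#' @param ground_truth Optional list attached by the simulator (true
#'   coefficients and noiseless LOS) -- `NULL` for real data.
#' @param config Optional simulation/run configuration to carry along.
#' @return An object of class `nicu_cohort`.
#' @export
nicu_cohort <- function(patients, nutrition_orders, medication_orders,
                        ground_truth = NULL, config = NULL) {
  stopifnot(is.data.frame(patients), is.data.frame(nutrition_orders),
            is.data.frame(medication_orders))
  if (anyDuplicated(patients$patient_id)) {
    dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
    stop("duplicate patient_id: ", paste(dup, collapse = ", "))
  }
  if (!"filled_forward" %in% names(nutrition_orders) &&
      nrow(nutrition_orders) > 0) {
    nutrition_orders$filled_forward <- FALSE
  }
  for (tab in list(nutrition_orders, medication_orders)) {
    if (nrow(tab) == 0) next
    unknown <- setdiff(unique(tab$patient_id), patients$patient_id)
    if (length(unknown)) {
      stop("orders reference unknown patient_id: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    los <- setNames(patients$los_days, patients$patient_id)
    over <- tab$day_of_life < 1 | tab$day_of_life > los[tab$patient_id]
    if (any(over, na.rm = TRUE)) {
      stop("order days outside [1, los_days] for patient(s): ",
           paste(unique(tab$patient_id[which(over)])[1:min(5, sum(over))],
                 collapse = ", "))
    }
  }
  structure(
    list(patients = patients, nutrition_orders = nutrition_orders,
         medication_orders = medication_orders,
         ground_truth = ground_truth, config = config),
    class = "nicu_cohort"
  )
}

#' @export
print.nicu_cohort <- function(x, ...) {
  cat("<nicu_cohort>", nrow(x$patients), "patients,",
      nrow(x$nutrition_orders), "nutrition orders,",
      nrow(x$medication_orders), "medication orders\n")
  if (!is.null(x$patients$gestation_weeks)) {
    print(table(assign_gestation_category(x$patients$gestation_weeks)))
  }
  invisible(x)
}

#' Apply study eligibility to raw admission records
#'
#' Retains admissions that stayed more than 24 hours (`los_days >= 1` on
#' the whole-day grid), have at least one nutrition order, and carry no
#' exclusion reason (congenital anomaly, palliative care, discharge on
#' request, transfer, death). Excluded records are returned alongside the
#' reason so that exclusions are auditable; retained records are returned
#' unmodified, field for field.
#'
#' @param raw_records data.frame of admission records, possibly including
#'   ineligible ones. An `exclusion_reason` column of `NA`/empty strings
#'   marks records with no a-priori exclusion.
#' @param nutrition_orders data.frame of daily nutrition orders used to
#'   check the "had nutrition orders" condition.
#' @return A list with elements `included` (eligible records),
#'   `excluded` (ineligible records with a filled `exclusion_reason`), and
#'   `log` (character vector, one message per exclusion).
#' @export
apply_eligibility <- function(raw_records, nutrition_orders) {
  stopifnot(is.data.frame(raw_records))
  if (anyDuplicated(raw_records$patient_id)) {
    dup <- unique(raw_records$patient_id[duplicated(raw_records$patient_id)])
    stop("duplicate patient_id: ", paste(dup, collapse = ", "))
  }
  reason <- raw_records$exclusion_reason
  if (is.null(reason)) reason <- rep(NA_character_, nrow(raw_records))
  reason[!is.na(reason) & reason == ""] <- NA_character_

  has_orders <- raw_records$patient_id %in% unique(nutrition_orders$patient_id)
  short_stay <- is.na(raw_records$los_days) | raw_records$los_days < 1

  derived <- ifelse(short_stay, "stay_le_24h",
                    ifelse(!has_orders, "no_nutrition_orders", NA_character_))
  reason <- ifelse(is.na(reason), derived, reason)

  keep <- is.na(reason)
  excluded <- raw_records[!keep, , drop = FALSE]
  excluded$exclusion_reason <- reason[!keep]
  log <- if (nrow(excluded)) {
    sprintf("excluded %s: %s", excluded$patient_id, excluded$exclusion_reason)
  } else {
    character(0)
  }
  list(
    included = raw_records[keep, , drop = FALSE],
    excluded = excluded,
    log = log
  )
}

#' Forward-fill a patient's daily nutrition orders
#'
#' Completes the day-of-life grid `1..los_days` for one patient: a day with
#' no order inherits the most recent prior day's order (marked
#' `filled_forward = TRUE`); days before the first observed order cannot be
#' filled and are emitted with `NA` intake values and `missing = TRUE`.
#' The operation is idempotent.
#'
#' @param orders data.frame of one patient's nutrition orders with columns
#'   `day_of_life`, `mode`, `energy_kcal_per_kg`, `protein_g_per_kg` and
#'   optionally `filled_forward`.
#' @param los_days Integer length of stay in days.
#' @return data.frame with one row per day `1..los_days`, columns as the
#'   input plus logical `filled_forward` and `missing`.
#' @export
#' @examples
#' orders <- data.frame(day_of_life = c(1, 3), mode = "EN",
#'                      energy_kcal_per_kg = c(60, 90),
#'                      protein_g_per_kg = c(1.5, 2.5))
#' forward_fill_orders(orders, los_days = 4)
forward_fill_orders <- function(orders, los_days) {
  stopifnot(is.data.frame(orders), los_days >= 1)
  # rows with no intake values are placeholders (e.g. an earlier fill's
  # leading-missing days), not orders
  orders <- orders[!(is.na(orders$energy_kcal_per_kg) &
                       is.na(orders$protein_g_per_kg)), , drop = FALSE]
  if (nrow(orders) == 0) {
    stop("no nutrition orders to fill; patient should have been excluded")
  }
  if (anyDuplicated(orders$day_of_life)) {
    # several orders in one day: keep the last entered for that day
    orders <- orders[!duplicated(orders$day_of_life, fromLast = TRUE), ,
                     drop = FALSE]
  }
  orders <- orders[order(orders$day_of_life), , drop = FALSE]
  if (!"filled_forward" %in% names(orders)) orders$filled_forward <- FALSE

  days <- seq_len(los_days)
  # index of the latest order on or before each day (0 = none yet)
  src <- findInterval(days, orders$day_of_life)
  missing <- src == 0
  out <- orders[pmax(src, 1), , drop = FALSE]
  out$day_of_life <- days
  out$filled_forward <- (!missing) & !(days %in% orders$day_of_life) |
    (out$filled_forward & days %in% orders$day_of_life)
  out$missing <- missing
  out$energy_kcal_per_kg[missing] <- NA_real_
  out$protein_g_per_kg[missing] <- NA_real_
  out$mode[missing] <- NA_character_
  rownames(out) <- NULL
  out
}

#' Forward-fill nutrition orders for every patient in a cohort
#'
#' @param cohort A [nicu_cohort()].
#' @return The cohort with a complete day-of-life grid of nutrition orders.
#' @export
forward_fill_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "nicu_cohort"))
  los <- setNames(cohort$patients$los_days, cohort$patients$patient_id)
  pieces <- lapply(split(cohort$nutrition_orders,
                         cohort$nutrition_orders$patient_id),
                   function(d) forward_fill_orders(d, los[[d$patient_id[1]]]))
  filled <- do.call(rbind, pieces)
  rownames(filled) <- NULL
  cohort$nutrition_orders <- filled
  cohort
}

#' Impute missing continuous covariates by the population mean
#'
#' Each continuous field's missing entries are replaced by the mean of its
#' non-missing entries. A field whose missing fraction exceeds `threshold`
#' (default 10%) is not imputed: it is listed in `dropped_fields` and must
#' be excluded from downstream modelling. Missing categorical entries are
#' never mean-imputed; character/factor fields gain an explicit `"unknown"`
#' level and logical fields are recoded to character with an `"unknown"`
#' level, and all such fields are reported in `flagged_categorical`.
#'
#' @param records data.frame of admission records.
#' @param fields Character vector of continuous fields eligible for
#'   imputation; defaults to `gestation_weeks` and `birth_weight_g`.
#' @param threshold Maximum tolerated imputed fraction per field.
#' @return list with `records` (imputed), `dropped_fields`,
#'   `imputed_counts` (named integer vector) and `flagged_categorical`.
#' @export
impute_covariates <- function(records,
                              fields = c("gestation_weeks", "birth_weight_g"),
                              threshold = 0.10) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  dropped <- character(0)
  counts <- integer(0)
  for (f in intersect(fields, names(records))) {
    x <- records[[f]]
    if (!is.numeric(x)) next
    n_miss <- sum(is.na(x))
    counts[f] <- n_miss
    if (n_miss == 0) next
    if (n_miss == length(x) || n_miss / length(x) > threshold) {
      dropped <- c(dropped, f)
      next
    }
    records[[f]][is.na(x)] <- mean(x, na.rm = TRUE)
  }
  flagged <- character(0)
  # exclusion_reason's NA means "not excluded", not missingness
  cat_fields <- setdiff(names(records),
                        c(fields, "patient_id", "exclusion_reason"))
  for (f in cat_fields) {
    x <- records[[f]]
    if (is.numeric(x) || !anyNA(x)) next
    flagged <- c(flagged, f)
    if (is.logical(x)) x <- as.character(x)
    if (is.factor(x)) x <- as.character(x)
    x[is.na(x)] <- "unknown"
    records[[f]] <- x
  }
  list(records = records, dropped_fields = dropped,
       imputed_counts = counts, flagged_categorical = flagged)
}

#' Write the cohort tables as delimited text
#'
#' Writes `patients.csv`, `nutrition_orders.csv`, `medication_orders.csv`
#' and, when present, `ground_truth.json` (true coefficients and per-patient
#' noiseless LOS) into `dir`.
#'
#' @param cohort A [nicu_cohort()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nicu_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "nutrition_orders.csv",
                            "medication_orders.csv"))
  write.csv(cohort$patients, paths[1], row.names = FALSE, quote = FALSE)
  write.csv(cohort$nutrition_orders, paths[2], row.names = FALSE, quote = FALSE)
  write.csv(cohort$medication_orders, paths[3], row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$ground_truth)) {
    gt_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(cohort$ground_truth, gt_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, gt_path)
  }
  invisible(paths)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir Directory containing `patients.csv`, `nutrition_orders.csv`
#'   and `medication_orders.csv` (and optionally `ground_truth.json`).
#' @return A [nicu_cohort()].
#' @export
read_cohort <- function(dir) {
  patients <- read.csv(file.path(dir, "patients.csv"),
                       stringsAsFactors = FALSE)
  for (f in intersect(c("multiple_pregnancy", "inborn", "maternal_disease",
                        "antenatal_infection", "antenatal_risk_factor",
                        "need_ppv", "apgar5_lt5", .diagnosis_flags),
                      names(patients))) {
    if (is.character(patients[[f]])) {
      patients[[f]] <- as.logical(patients[[f]])
    }
  }
  nut <- read.csv(file.path(dir, "nutrition_orders.csv"),
                  stringsAsFactors = FALSE)
  med <- read.csv(file.path(dir, "medication_orders.csv"),
                  stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path,
                                                      simplifyVector = TRUE)
  nicu_cohort(patients, nut, med, ground_truth = gt)
}
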