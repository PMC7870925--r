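#' Canonical modelling terms by risk-factor group
#'
#' The LOS models draw their regressors from four groups: antenatal and
#' perinatal covariates, nutrition-deviation quartile codes, the medication
#' category, and clinical diagnosis flags. The grouping also defines the
#' seven nested predictor sets used when comparing validation performance.
#'
#' @return Named list of character vectors of design-column names.
#' @export
term_groups <- function() {
  list(
    perinatal = c("gestation_centered", "sex", "delivery_mode",
                  "multiple_pregnancy", "inborn"),
    nutrition = c("energy_quartile", "protein_quartile"),
    medication = c("medication_category"),
    diagnoses = c("rds", "ttnb", "sepsis", "nnh")
  )
}

#' Default modelled term set
#'
#' The default full model offered to family comparison and significance
#' screening; a subset of [term_groups()] covering all four groups.
#'
#' @return Character vector of design-column names.
#' @export
default_terms <- function() {
  c("gestation_centered", "sex", "multiple_pregnancy", "rds", "ttnb",
    "sepsis", "nnh", "energy_quartile", "protein_quartile",
    "medication_category")
}

#' The seven risk-factor predictor sets used in validation comparisons
#'
#' Combinations of the antenatal/perinatal base set with nutrition,
#' medication and diagnosis groups, from base-only up to all four groups.
#'
#' @return Named list of character vectors of design-column names.
#' @export
risk_factor_sets <- function() {
  g <- term_groups()
  base <- g$perinatal
  list(
    "antenatal_perinatal" = base,
    "antenatal_perinatal_diagnoses" = c(base, g$diagnoses),
    "antenatal_perinatal_nutrition" = c(base, g$nutrition),
    "antenatal_perinatal_medication" = c(base, g$medication),
    "antenatal_perinatal_nutrition_diagnoses" =
      c(base, g$nutrition, g$diagnoses),
    "antenatal_perinatal_medication_diagnoses" =
      c(base, g$medication, g$diagnoses),
    "antenatal_perinatal_nutrition_medication_diagnoses" =
      c(base, g$nutrition, g$medication, g$diagnoses)
  )
}

#' Map between generator coefficient names and fitted coefficient names
#'
#' The synthetic-data generator expresses its ground-truth effects under
#' short names; fitted linear models name coefficients after the design
#' matrix columns. This map aligns the two for parameter-recovery studies.
#'
#' @return Named character vector: `names()` are generator truth names,
#'   values are `model.matrix` column names.
#' @export
truth_coefficient_map <- function() {
  c(sex_male = "sexmale",
    delivery_cesarean = "delivery_modecesarean",
    multiple_pregnancy = "multiple_pregnancyTRUE",
    inborn = "inbornTRUE",
    rds = "rdsTRUE",
    ttnb = "ttnbTRUE",
    sepsis = "sepsisTRUE",
    nnh = "nnhTRUE",
    med_no_deviation = "medication_categoryno_deviation",
    med_deviation = "medication_categorydeviation",
    energy_q4 = "energy_quartileQ4",
    protein_q4 = "protein_quartileQ4",
    gestation_centered = "gestation_centered")
}

#' Build the per-patient design table for LOS modelling
#'
#' Merges admission covariates with the patient's deviation summary and
#' encodes everything with fixed level orders: `sex` (`female` reference),
#' `delivery_mode` (`vaginal` reference), quartile codes (`remaining`
#' reference), `medication_category` (`not_required` reference). Continuous
#' gestational age is centred at the stratum reference week
#' ([gestation_reference_weeks()]).
#'
#' @param patients data.frame of eligible admissions.
#' @param deviations A `deviation_summary` from [compute_deviations()].
#' @return data.frame with one row per patient: `patient_id`, `los_days`,
#'   `split_tag` (if present), `gestation_category`, and the modelling
#'   columns of [term_groups()].
#' @export
build_design <- function(patients, deviations) {
  stopifnot(is.data.frame(patients))
  idx <- match(patients$patient_id, deviations$patient_id)
  if (anyNA(idx)) {
    stop("patients missing from deviation summary: ",
         paste(patients$patient_id[is.na(idx)][1:3], collapse = ", "))
  }
  cat <- assign_gestation_category(patients$gestation_weeks)
  ref <- gestation_reference_weeks()
  out <- data.frame(
    patient_id = patients$patient_id,
    los_days = patients$los_days,
    gestation_category = cat,
    gestation_centered = patients$gestation_weeks - ref[as.character(cat)],
    sex = factor(patients$sex, levels = c("female", "male")),
    delivery_mode = factor(patients$delivery_mode,
                           levels = c("vaginal", "cesarean")),
    multiple_pregnancy = as.logical(patients$multiple_pregnancy),
    inborn = as.logical(patients$inborn),
    rds = as.logical(patients$rds),
    ttnb = as.logical(patients$ttnb),
    sepsis = as.logical(patients$sepsis),
    nnh = as.logical(patients$nnh),
    energy_quartile = deviations$energy_quartile[idx],
    protein_quartile = deviations$protein_quartile[idx],
    medication_category = deviations$medication_category[idx],
    stringsAsFactors = FALSE
  )
  if ("split_tag" %in% names(patients)) out$split_tag <- patients$split_tag
  rownames(out) <- NULL
  out
}
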