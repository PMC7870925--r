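#' Per-patient deviation factor of daily guideline gaps
#'
#' Summarises a patient's daily deviations from the recommended intake over
#' the stay. With the default normalisation the statistic is the Euclidean
#' (L2) norm of the daily gaps divided by the number of days:
#' `sqrt(sum((recommended - ordered)^2)) / n`. Over- and under-feeding both
#' count, because gaps enter squared. Two alternative summaries are
#' available: the raw L2 norm (`l2_raw`) and the mean absolute gap
#' (`mean_abs`); all three are zero exactly when every daily gap is zero,
#' scale linearly in the gaps, and ignore the order of days.
#'
#' @param recommended Numeric vector of per-day recommended values.
#' @param ordered Numeric vector of per-day ordered values, same length.
#' @param normalization One of `"l2_over_n"` (default), `"l2_raw"`,
#'   `"mean_abs"`.
#' @return Non-negative scalar in the nutrient's per-kg daily units.
#' @export
#' @examples
#' deviation_factor(c(100, 110, 120), c(90, 100, 130))  # sqrt(300)/3
deviation_factor <- function(recommended, ordered,
                             normalization = c("l2_over_n", "l2_raw",
                                               "mean_abs")) {
  normalization <- match.arg(normalization)
  if (length(recommended) != length(ordered)) {
    stop("recommended and ordered must have the same length")
  }
  n <- length(recommended)
  if (n == 0) stop("need at least one day")
  gaps <- recommended - ordered
  if (any(!is.finite(gaps))) stop("non-finite daily values")
  switch(normalization,
         l2_over_n = sqrt(sum(gaps^2)) / n,
         l2_raw = sqrt(sum(gaps^2)),
         mean_abs = mean(abs(gaps)))
}

#' Daily nutrition gaps for a cohort's order stream
#'
#' Computes, for every patient-day and both nutrients, the signed gap
#' `recommended - ordered` (per kg per day). The recommendation honours the
#' order's feeding mode, including the highest-intake rule for days on both
#' EN and PN; days of withheld enteral feeds are entered with mode `"PN"`
#' and so are scored against the parenteral table. Birth weight is used as
#' the dosing weight throughout. Rows flagged `missing` (days before the
#' first order) are dropped from scoring.
#'
#' @param cohort A [nicu_cohort()] whose nutrition orders are complete
#'   (after [forward_fill_cohort()]).
#' @param guidelines A `guideline_set`.
#' @return data.frame with columns `patient_id`, `day_of_life`, `mode`,
#'   `energy_gap`, `protein_gap`.
#' @export
daily_nutrition_deviations <- function(cohort, guidelines) {
  stopifnot(inherits(cohort, "nicu_cohort"),
            inherits(guidelines, "guideline_set"))
  ord <- cohort$nutrition_orders
  if ("missing" %in% names(ord)) ord <- ord[!ord$missing, , drop = FALSE]
  wt <- stats::setNames(cohort$patients$birth_weight_g,
                        cohort$patients$patient_id)
  ord$weight_g <- wt[ord$patient_id]
  out <- data.frame(patient_id = ord$patient_id,
                    day_of_life = ord$day_of_life,
                    mode = ord$mode,
                    energy_gap = NA_real_, protein_gap = NA_real_,
                    stringsAsFactors = FALSE)
  for (m in unique(ord$mode)) {
    sel <- ord$mode == m
    out$energy_gap[sel] <- recommend_nutrition(
      guidelines, ord$weight_g[sel], ord$day_of_life[sel], m,
      "energy_kcal_per_kg") - ord$energy_kcal_per_kg[sel]
    out$protein_gap[sel] <- recommend_nutrition(
      guidelines, ord$weight_g[sel], ord$day_of_life[sel], m,
      "protein_g_per_kg") - ord$protein_g_per_kg[sel]
  }
  out
}

#' Top-quartile coding of deviation factors within one stratum
#'
#' Codes each patient as `Q4` (top-quartile, maximum deviation) or
#' `remaining` (the pooled lower three quartiles). The cutpoint is the
#' nearest-rank 75th percentile; only values strictly above it are `Q4`, so
#' ties at the cutpoint go to `remaining` and `Q4` holds strictly the
#' maximum-deviation group. Requires at least 8 patients; smaller strata
#' should be merged before coding.
#'
#' @param values Numeric vector of per-patient deviation factors within one
#'   gestation category.
#' @return list with `code` (factor, levels `remaining`, `Q4`, same order
#'   as `values`) and `cut` (the nearest-rank 75th-percentile cutpoint,
#'   reusable for coding new patients via [apply_quartile_cut()]).
#' @export
#' @examples
#' quartile_code(1:8)$code  # values 7 and 8 are Q4
quartile_code <- function(values) {
  if (length(values) < 8) {
    stop("need at least 8 patients to code quartiles; merge categories")
  }
  if (anyNA(values)) stop("missing deviation factors")
  cut <- sort(values)[ceiling(0.75 * length(values))]
  list(code = apply_quartile_cut(values, cut), cut = cut)
}

#' Code deviation factors against a frozen quartile cutpoint
#'
#' @param values Numeric vector of deviation factors.
#' @param cut Cutpoint from [quartile_code()] (e.g. estimated on training
#'   data and frozen for bedside use).
#' @return Factor with levels `remaining`, `Q4`.
#' @export
apply_quartile_cut <- function(values, cut) {
  factor(ifelse(values > cut, "Q4", "remaining"),
         levels = c("remaining", "Q4"))
}

#' Summarise one patient's medication orders
#'
#' A patient with no orders beyond supplements (vitamins, iron) is
#' `not_required`. Otherwise the patient's deviation days are the distinct
#' days of life with at least one dose-deviating order (the 10% rule on
#' dose; frequency deviations are tallied separately but do not count as
#' deviation days), and the category is `deviation` if there is at least
#' one such day, else `no_deviation`.
#'
#' @param orders data.frame of one patient's medication orders (may have
#'   zero rows) with columns `day_of_life`, `drug`, `dose_per_kg`,
#'   `frequency_per_day`.
#' @param guidelines A `guideline_set`.
#' @param los_days The patient's length of stay, for the day-range check.
#' @param unknown_drug Passed to [classify_medication_order()].
#' @return list with `medication_category` (one of `not_required`,
#'   `no_deviation`, `deviation`), `deviation_days` (integer),
#'   `frequency_deviation_days` (integer, reported but not modelled).
#' @export
summarize_medication <- function(orders, guidelines, los_days,
                                 unknown_drug = "error") {
  stopifnot(inherits(guidelines, "guideline_set"))
  if (nrow(orders) > 0 &&
      any(orders$day_of_life < 1 | orders$day_of_life > los_days)) {
    stop("medication order day outside [1, los_days]")
  }
  core <- orders[!is_supplement(guidelines, orders$drug), , drop = FALSE]
  if (nrow(core) == 0) {
    return(list(medication_category = "not_required",
                deviation_days = 0L, frequency_deviation_days = 0L))
  }
  cls <- classify_medication_order(guidelines, core$drug, core$dose_per_kg,
                                   core$frequency_per_day,
                                   unknown_drug = unknown_drug)
  dose_days <- unique(core$day_of_life[cls %in% c("dose_deviation",
                                                  "both_deviation")])
  freq_days <- unique(core$day_of_life[cls %in% c("frequency_deviation",
                                                  "both_deviation")])
  list(
    medication_category = if (length(dose_days)) "deviation" else
      "no_deviation",
    deviation_days = length(dose_days),
    frequency_deviation_days = length(freq_days)
  )
}

#' Per-patient deviation summary table for a cohort
#'
#' Runs the whole deviation pipeline: daily nutrition gaps against the
#' guidelines, the per-patient deviation factor for energy and protein,
#' top-quartile coding within gestation category, and the medication
#' summary. Quartile cutpoints are estimated within each gestation category
#' over the patients present in `cohort`; the per-category cutpoints are
#' returned so new patients can be coded against them.
#'
#' @param cohort A [nicu_cohort()] with forward-filled nutrition orders.
#' @param guidelines A `guideline_set`.
#' @param normalization Deviation-factor normalisation, see
#'   [deviation_factor()].
#' @param unknown_drug Passed to [classify_medication_order()].
#' @return An object of class `deviation_summary`: a data.frame with one
#'   row per patient (`patient_id`, `gestation_category`,
#'   `energy_dev_factor`, `protein_dev_factor`, `energy_quartile`,
#'   `protein_quartile`, `medication_category`, `medication_deviation_days`,
#'   `frequency_deviation_days`), with attributes `cutpoints` (per
#'   category) and `guideline_version`.
#' @export
compute_deviations <- function(cohort, guidelines = default_guidelines(),
                               normalization = "l2_over_n",
                               unknown_drug = "error") {
  stopifnot(inherits(cohort, "nicu_cohort"))
  pat <- cohort$patients
  gaps <- daily_nutrition_deviations(cohort, guidelines)

  dev_by_pat <- function(gap_col) {
    vapply(split(gaps[[gap_col]], gaps$patient_id), function(g) {
      deviation_factor(g, numeric(length(g)), normalization = normalization)
    }, numeric(1))
  }
  e_dev <- dev_by_pat("energy_gap")
  p_dev <- dev_by_pat("protein_gap")

  out <- data.frame(
    patient_id = pat$patient_id,
    gestation_category = assign_gestation_category(pat$gestation_weeks),
    energy_dev_factor = unname(e_dev[pat$patient_id]),
    protein_dev_factor = unname(p_dev[pat$patient_id]),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$energy_dev_factor)) {
    stop("patients without nutrition orders: ",
         paste(out$patient_id[is.na(out$energy_dev_factor)][1:3],
               collapse = ", "))
  }

  out$energy_quartile <- factor(NA, levels = c("remaining", "Q4"))
  out$protein_quartile <- factor(NA, levels = c("remaining", "Q4"))
  cuts <- list()
  for (cat in levels(out$gestation_category)) {
    sel <- out$gestation_category == cat
    if (!any(sel)) next
    qe <- quartile_code(out$energy_dev_factor[sel])
    qp <- quartile_code(out$protein_dev_factor[sel])
    out$energy_quartile[sel] <- qe$code
    out$protein_quartile[sel] <- qp$code
    cuts[[cat]] <- c(energy = qe$cut, protein = qp$cut)
  }

  med_split <- split(cohort$medication_orders,
                     factor(cohort$medication_orders$patient_id,
                            levels = pat$patient_id))
  los <- stats::setNames(pat$los_days, pat$patient_id)
  med <- lapply(pat$patient_id, function(id) {
    summarize_medication(med_split[[id]], guidelines, los[[id]],
                         unknown_drug = unknown_drug)
  })
  out$medication_category <- factor(
    vapply(med, `[[`, character(1), "medication_category"),
    levels = c("not_required", "no_deviation", "deviation")
  )
  out$medication_deviation_days <-
    vapply(med, `[[`, integer(1), "deviation_days")
  out$frequency_deviation_days <-
    vapply(med, `[[`, integer(1), "frequency_deviation_days")

  structure(out, cutpoints = cuts, guideline_version = guidelines$version,
            class = c("deviation_summary", "data.frame"))
}

#' Write a deviation summary as delimited text
#'
#' @param deviations A `deviation_summary` from [compute_deviations()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_deviations <- function(deviations, path) {
  df <- as.data.frame(deviations)
  df$guideline_version <- attr(deviations, "guideline_version")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
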