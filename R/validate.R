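#' Prediction metrics on the day scale
#'
#' @param observed Numeric vector of observed LOS in days.
#' @param predicted Numeric vector of predicted LOS in days.
#' @return list with `rmse`, `r_squared` (1 - SS_res/SS_tot of observed vs
#'   predicted, on the day scale), `mean_observed`, `sd_observed`,
#'   `mean_predicted`, `sd_predicted`, `n`. All metrics are `NA` when
#'   there are no observations (undefined, not zero).
#' @export
los_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n == 0) {
    return(list(rmse = NA_real_, r_squared = NA_real_,
                mean_observed = NA_real_, sd_observed = NA_real_,
                mean_predicted = NA_real_, sd_predicted = NA_real_, n = 0L))
  }
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  list(
    rmse = sqrt(ss_res / n),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else
      if (ss_res == 0) 1 else NA_real_,
    mean_observed = mean(observed), sd_observed = stats::sd(observed),
    mean_predicted = mean(predicted), sd_predicted = stats::sd(predicted),
    n = n
  )
}

#' Validate fitted stratum models on held-out patients
#'
#' Predicts the validation patients' LOS with their stratum's model and
#' reports per-stratum RMSE (days), day-scale R-squared of predicted vs
#' observed, and mean/SD of both. Strata absent from the validation data
#' yield `NA` metrics.
#'
#' @param fits Named list of `los_fit` objects, one per gestation category.
#' @param design_val Validation design table ([build_design()] rows).
#' @param unseen_level Passed to [predict_los()]; default `"reference"`
#'   because held-out data may lack levels seen in training.
#' @return data.frame with one row per category and the metric columns of
#'   [los_metrics()].
#' @export
validate_los <- function(fits, design_val, unseen_level = "reference") {
  cats <- levels(design_val$gestation_category)
  rows <- lapply(cats, function(cc) {
    d <- design_val[design_val$gestation_category == cc, , drop = FALSE]
    m <- if (nrow(d) && cc %in% names(fits)) {
      los_metrics(d$los_days,
                  predict_los(fits[[cc]], d, unseen_level = unseen_level))
    } else {
      los_metrics(numeric(0), numeric(0))
    }
    cbind(data.frame(gestation_category = cc, stringsAsFactors = FALSE),
          as.data.frame(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Observed-vs-predicted gaps for the seven risk-factor predictor sets
#'
#' For each of the seven nested predictor sets ([risk_factor_sets()]) and
#' each gestation category, fits the set's model on the training rows and
#' reports the absolute difference between the mean observed and mean
#' predicted LOS (days) on the validation rows.
#'
#' @param design_train Training design table.
#' @param design_val Validation design table.
#' @param family Response-transform family for all fits, default `"log"`.
#' @return data.frame: one row per risk-factor set, one column per
#'   gestation category, entries `|mean observed - mean predicted|` in
#'   days (`NA` where a stratum is empty).
#' @export
riskset_comparison <- function(design_train, design_val, family = "log") {
  sets <- risk_factor_sets()
  cats <- levels(design_train$gestation_category)
  out <- data.frame(risk_factor_set = names(sets),
                    stringsAsFactors = FALSE)
  for (cc in cats) {
    tr <- design_train[design_train$gestation_category == cc, , drop = FALSE]
    va <- design_val[design_val$gestation_category == cc, , drop = FALSE]
    vals <- vapply(sets, function(terms) {
      if (nrow(tr) < 20 || nrow(va) == 0) return(NA_real_)
      fit <- fit_los_model(tr, terms, family, category = cc)
      pred <- predict_los(fit, va, unseen_level = "reference")
      abs(mean(va$los_days) - mean(pred))
    }, numeric(1))
    out[[cc]] <- unname(vals)
  }
  out
}
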