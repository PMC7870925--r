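#' Read a run configuration file
#'
#' YAML run settings for the analysis pipeline: `missing_marker` (string
#' treated as missing on input), `imputation_threshold` (default 0.10),
#' `gestation_edges` (default 32, 34, 37), `normalization` (deviation
#' factor, default `l2_over_n`), `alpha` (significance screen, default
#' 0.05), `unknown_drug` (`error`/`skip`).
#'
#' @param path YAML file path.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  defaults <- list(missing_marker = "NA", imputation_threshold = 0.10,
                   gestation_edges = c(32, 34, 37),
                   normalization = "l2_over_n", alpha = 0.05,
                   unknown_drug = "error")
  cfg <- if (!is.null(path) && file.exists(path)) yaml::read_yaml(path)
  else list()
  utils::modifyList(defaults, cfg)
}

#' Run the full LOS analysis pipeline on a cohort
#'
#' Eligibility filtering, covariate imputation, forward filling, deviation
#' scoring and quartile coding, per-stratum family comparison, p < 0.05
#' screening and refit, day effects, validation metrics, the seven-set
#' risk-factor comparison, and bedside payloads for the validation
#' patients. Each stratum's response family is the winner of
#' [compare_families()] unless `family` is forced.
#'
#' @param cohort A [nicu_cohort()], e.g. from [simulate_cohort()] or
#'   [read_cohort()].
#' @param guidelines A `guideline_set`.
#' @param terms Candidate modelling terms, default [default_terms()].
#' @param family Optional family name to force (skips family comparison).
#' @param n_iterations Split iterations for family comparison; default one
#'   per patient in the stratum.
#' @param seed Integer seed controlling the family-comparison splits.
#' @param normalization Deviation-factor normalisation.
#' @param alpha Significance threshold for the variable screen.
#' @param timestamp Timestamp string stamped into payloads (pass a fixed
#'   value for reproducible output).
#' @param out_dir Optional directory: writes `deviations.csv`,
#'   `model_report.json`, `payloads.json` and `payloads.txt`.
#' @return list with `cohort` (post-eligibility), `deviations`, `design`,
#'   `rankings`, `models` (per category: `fit`, `effects`, `ranking`),
#'   `validation`, `riskset`, `payloads`, `dropped_fields`, `eligibility`.
#' @export
run_pipeline <- function(cohort, guidelines = default_guidelines(),
                         terms = default_terms(), family = NULL,
                         n_iterations = NULL, seed = 1L,
                         normalization = "l2_over_n", alpha = 0.05,
                         timestamp = "1970-01-01T00:00:00Z",
                         out_dir = NULL) {
  stopifnot(inherits(cohort, "nicu_cohort"))

  elig <- apply_eligibility(cohort$patients, cohort$nutrition_orders)
  imp <- impute_covariates(elig$included)
  keep_ids <- imp$records$patient_id
  nut <- cohort$nutrition_orders[
    cohort$nutrition_orders$patient_id %in% keep_ids, , drop = FALSE]
  med <- cohort$medication_orders[
    cohort$medication_orders$patient_id %in% keep_ids, , drop = FALSE]
  cohort2 <- nicu_cohort(imp$records, nut, med,
                         ground_truth = cohort$ground_truth)
  cohort2 <- forward_fill_cohort(cohort2)

  deviations <- compute_deviations(cohort2, guidelines,
                                   normalization = normalization)
  design <- build_design(cohort2$patients, deviations)
  has_split <- "split_tag" %in% names(design)
  train <- if (has_split) design[design$split_tag == "train", , drop = FALSE]
  else design
  val <- if (has_split) design[design$split_tag == "validate", , drop = FALSE]
  else design[0, , drop = FALSE]

  cats <- levels(design$gestation_category)
  models <- list()
  rankings <- list()
  for (k in seq_along(cats)) {
    cc <- cats[k]
    tr <- train[train$gestation_category == cc, , drop = FALSE]
    if (nrow(tr) < 20) next
    if (is.null(family)) {
      rk <- compare_families(tr, terms, n_iterations = n_iterations,
                             seed = seed + k)
      fam <- rk$family[1]
    } else {
      rk <- NULL
      fam <- family
    }
    fit <- select_significant(tr, terms, fam, alpha = alpha, category = cc)
    models[[cc]] <- list(fit = fit, effects = day_effects(fit), ranking = rk)
    rankings[[cc]] <- rk
  }

  fits <- lapply(models, `[[`, "fit")
  validation <- if (nrow(val)) validate_los(fits, val) else NULL
  riskset <- if (nrow(val)) {
    riskset_comparison(train, val, if (is.null(family)) "log" else family)
  }

  payload_rows <- if (nrow(val)) val else train
  payload_rows <- payload_rows[
    as.character(payload_rows$gestation_category) %in% names(models), ,
    drop = FALSE]
  payloads <- lapply(seq_len(nrow(payload_rows)), function(i) {
    build_payload(payload_rows[i, , drop = FALSE], models,
                  guideline_version = guidelines$version,
                  model_id = sprintf("neolos-seed%d", seed),
                  timestamp = timestamp)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_deviations(deviations, file.path(out_dir, "deviations.csv"))
    render_report(payloads, "json", file.path(out_dir, "payloads.json"))
    render_report(payloads, "text", file.path(out_dir, "payloads.txt"))
    report <- list(
      rankings = rankings,
      effects = lapply(models, function(m) as.data.frame(m$effects)),
      validation = validation, riskset = riskset,
      guideline_version = guidelines$version, seed = seed
    )
    jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         na = "null", null = "null")
  }

  list(cohort = cohort2, deviations = deviations, design = design,
       rankings = rankings, models = models, validation = validation,
       riskset = riskset, payloads = payloads,
       dropped_fields = imp$dropped_fields, eligibility = elig)
}
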