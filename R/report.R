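#' Build the bedside payload for one patient
#'
#' Assembles the per-patient bedside summary: the predicted LOS from the
#' patient's stratum model, and one row per (category, risk factor) with
#' the factor's day weight at the patient's current level. Factors of the
#' patient's own gestation category are `applicable`; factors modelled
#' only in other categories are carried for display but flagged
#' `applicable = FALSE`. When a previous payload is supplied, any
#' applicable factor whose level or day weight changed is `highlighted`
#' (the red-flag semantics of a daily update); the first payload carries
#' no highlights.
#'
#' @param patient One row of the design table ([build_design()]).
#' @param models Named list (by gestation category) of lists with elements
#'   `fit` (a `los_fit`) and `effects` (its [day_effects()] table).
#' @param previous_payload Optional payload from the previous day.
#' @param guideline_version Version tag carried through from the deviation
#'   stage.
#' @param model_id Identifier of the fitted model set.
#' @param timestamp Generation timestamp string; defaults to the current
#'   time (pass a fixed value for reproducible output).
#' @return An object of class `bedside_payload` (a named list).
#' @export
build_payload <- function(patient, models, previous_payload = NULL,
                          guideline_version = "unversioned",
                          model_id = "unnamed-model",
                          timestamp = format(Sys.time(), tz = "UTC")) {
  stopifnot(nrow(patient) == 1)
  cat_own <- as.character(patient$gestation_category)
  if (!cat_own %in% names(models)) {
    stop("no fitted model for category ", cat_own)
  }
  own <- models[[cat_own]]
  if (!identical(own$fit$category, cat_own)) {
    stop("category mismatch: patient is ", cat_own, ", model is fitted for ",
         own$fit$category)
  }
  predicted <- .round_half_away(predict_los(own$fit, patient,
                                            unseen_level = "reference"))

  risk_factors <- list()
  for (cc in names(models)) {
    eff <- models[[cc]]$effects
    for (f in unique(eff$factor)) {
      lvl <- as.character(patient[[f]])
      row <- eff[eff$factor == f & eff$level == lvl, , drop = FALSE]
      effect <- if (nrow(row)) row$effect_days[1] else NA_real_
      risk_factors[[length(risk_factors) + 1]] <- list(
        category = cc, name = f, level = lvl,
        effect_days = effect, applicable = cc == cat_own,
        highlighted = FALSE
      )
    }
  }

  if (!is.null(previous_payload)) {
    prev <- previous_payload$risk_factors
    key <- function(rf) paste(rf$category, rf$name)
    prev_by_key <- stats::setNames(prev, vapply(prev, key, character(1)))
    risk_factors <- lapply(risk_factors, function(rf) {
      if (rf$applicable) {
        p <- prev_by_key[[key(rf)]]
        if (!is.null(p) && (!identical(p$level, rf$level) ||
                            !identical(as.numeric(p$effect_days),
                                       as.numeric(rf$effect_days)))) {
          rf$highlighted <- TRUE
        }
      }
      rf
    })
  }

  structure(list(
    patient_id = patient$patient_id,
    gestation_category = cat_own,
    predicted_los_days = as.integer(predicted),
    risk_factors = risk_factors,
    median_los = as.numeric(attr(own$effects, "median_los")),
    iqr_los = as.numeric(attr(own$effects, "iqr_los")),
    guideline_version = guideline_version,
    model_id = model_id,
    generation_timestamp = timestamp
  ), class = "bedside_payload")
}

#' @export
print.bedside_payload <- function(x, ...) {
  cat("<bedside_payload>", x$patient_id, "(", x$gestation_category, ")",
      "predicted LOS:", x$predicted_los_days, "days\n")
  invisible(x)
}

.payload_to_list <- function(p) unclass(p)

#' Render bedside payloads to JSON or a text grid
#'
#' JSON output is stable: keys appear in construction order and numbers
#' are written with fixed precision, so identical payloads serialize to
#' byte-identical documents. The text rendering mirrors the bedside grid:
#' all four gestation categories are shown per patient, the patient's own
#' category is expanded with its applicable risk factors, and the other
#' categories' factors are annotated as not applicable.
#'
#' @param payloads A `bedside_payload` or list of them.
#' @param format `"json"` or `"text"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
render_report <- function(payloads, format = c("json", "text"), path) {
  format <- match.arg(format)
  if (inherits(payloads, "bedside_payload")) payloads <- list(payloads)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output dir: ", dir)
  }
  if (format == "json") {
    json <- jsonlite::toJSON(lapply(payloads, .payload_to_list),
                             auto_unbox = TRUE, digits = 10, pretty = TRUE,
                             null = "null", na = "null")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(json, con)
  } else {
    lines <- character(0)
    for (p in payloads) {
      lines <- c(lines, sprintf("== Patient %s ==", p$patient_id),
                 sprintf("predicted LOS: %d days (category %s, median %s, IQR %s)",
                         p$predicted_los_days, p$gestation_category,
                         format(p$median_los), format(p$iqr_los)))
      cats <- unique(vapply(p$risk_factors, `[[`, character(1), "category"))
      for (cc in cats) {
        zoom <- cc == p$gestation_category
        lines <- c(lines, sprintf("%s[%s]%s", if (zoom) "* " else "  ", cc,
                                  if (zoom) "" else " (not applicable)"))
        for (rf in p$risk_factors) {
          if (rf$category != cc) next
          lines <- c(lines, sprintf(
            "    %s = %s: %s day(s)%s%s", rf$name, rf$level,
            if (is.na(rf$effect_days)) "?" else
              sprintf("%+d", as.integer(rf$effect_days)),
            if (rf$applicable) "" else "  [grey]",
            if (isTRUE(rf$highlighted)) "  <<CHANGED>>" else ""))
        }
      }
      lines <- c(lines, "")
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Parse a payload JSON file back into payload objects
#'
#' Inverse of [render_report()] with `format = "json"`; round-tripping a
#' payload through JSON is lossless.
#'
#' @param path Path to a JSON file written by [render_report()].
#' @return List of `bedside_payload` objects.
#' @export
parse_payloads <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(p) {
    p$predicted_los_days <- as.integer(p$predicted_los_days)
    p$risk_factors <- lapply(p$risk_factors, function(rf) {
      rf$effect_days <- if (is.null(rf$effect_days)) NA_real_ else
        as.numeric(rf$effect_days)
      rf
    })
    structure(p, class = "bedside_payload")
  })
}
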