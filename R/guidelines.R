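#' Load a guideline set from delimited text tables
#'
#' The engine is fully table-driven: nutrition recommendations are indexed
#' by feeding mode (`EN`/`PN`), nutrient, birth-weight class (`le_2500g`
#' for weights of 2500 g and below, `gt_2500g` above) and an inclusive
#' day-of-life band; medication references carry a recommended per-kg dose
#' and daily frequency per drug, with supplements (vitamins, iron) marked
#' so they can be excluded from deviation accounting.
#'
#' The tables shipped with the package are editable placeholders with
#' plausible neonatal ranges, not a transcription of any published
#' guideline; replace them with your unit's reference tables for real use.
#'
#' @param nutrition_path CSV with columns `mode`, `nutrient`,
#'   `weight_class`, `day_lo`, `day_hi` (use `Inf` for an open band) and
#'   `recommended`.
#' @param medication_path CSV with columns `drug`, `dose_per_kg`,
#'   `frequency_per_day`, `is_supplement`.
#' @param version Version tag recorded in downstream outputs.
#' @return An object of class `guideline_set` with elements `nutrition`,
#'   `medication`, `supplements` and `version`.
#' @export
read_guidelines <- function(nutrition_path, medication_path,
                            version = "unversioned") {
  nut <- utils::read.csv(nutrition_path, stringsAsFactors = FALSE)
  med <- utils::read.csv(medication_path, stringsAsFactors = FALSE)
  needed_n <- c("mode", "nutrient", "weight_class", "day_lo", "day_hi",
                "recommended")
  needed_m <- c("drug", "dose_per_kg", "frequency_per_day", "is_supplement")
  if (!all(needed_n %in% names(nut))) {
    stop("nutrition table missing columns: ",
         paste(setdiff(needed_n, names(nut)), collapse = ", "))
  }
  if (!all(needed_m %in% names(med))) {
    stop("medication table missing columns: ",
         paste(setdiff(needed_m, names(med)), collapse = ", "))
  }
  nut$day_hi <- as.numeric(nut$day_hi)
  nut$day_lo <- as.numeric(nut$day_lo)
  if (is.character(med$is_supplement)) {
    med$is_supplement <- as.logical(med$is_supplement)
  }
  gl <- structure(
    list(nutrition = nut, medication = med,
         supplements = med$drug[med$is_supplement], version = version),
    class = "guideline_set"
  )
  validate_guidelines(gl)
  gl
}

#' Default placeholder guideline set shipped with the package
#'
#' @param version Version tag, defaults to `"neolos-default-1"`.
#' @return A `guideline_set`; see [read_guidelines()].
#' @export
default_guidelines <- function(version = "neolos-default-1") {
  read_guidelines(
    system.file("extdata", "nutrition_guidelines.csv", package = "neolos",
                mustWork = TRUE),
    system.file("extdata", "medication_references.csv", package = "neolos",
                mustWork = TRUE),
    version = version
  )
}

#' Validate a guideline set
#'
#' Checks that for every (mode, nutrient, weight class) the day bands tile
#' `1..Inf` without gap or overlap, that recommended values are positive,
#' and that each drug has exactly one reference row.
#'
#' @param guidelines A `guideline_set`.
#' @return Invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_guidelines <- function(guidelines) {
  stopifnot(inherits(guidelines, "guideline_set"))
  nut <- guidelines$nutrition
  if (any(nut$recommended <= 0)) stop("non-positive nutrition recommendation")
  cells <- split(nut, interaction(nut$mode, nut$nutrient, nut$weight_class,
                                  drop = TRUE))
  for (cell in cells) {
    cell <- cell[order(cell$day_lo), ]
    key <- paste(cell$mode[1], cell$nutrient[1], cell$weight_class[1])
    if (cell$day_lo[1] != 1) stop("day bands do not start at 1 for ", key)
    if (!is.infinite(cell$day_hi[nrow(cell)])) {
      stop("day bands do not extend to Inf for ", key)
    }
    if (nrow(cell) > 1 &&
        any(cell$day_lo[-1] != cell$day_hi[-nrow(cell)] + 1)) {
      stop("day bands have a gap or overlap for ", key)
    }
  }
  med <- guidelines$medication
  if (anyDuplicated(med$drug)) {
    stop("duplicate medication reference rows for: ",
         paste(unique(med$drug[duplicated(med$drug)]), collapse = ", "))
  }
  if (any(med$dose_per_kg <= 0) || any(med$frequency_per_day <= 0)) {
    stop("non-positive medication reference dose or frequency")
  }
  invisible(TRUE)
}

.weight_class <- function(weight_g) {
  ifelse(weight_g <= 2500, "le_2500g", "gt_2500g")
}

# Vectorised single-mode table lookup. Returns NA where uncovered.
.lookup_nutrition <- function(guidelines, mode, nutrient, weight_class, day) {
  n <- max(length(weight_class), length(day))
  weight_class <- rep_len(weight_class, n)
  day <- rep_len(day, n)
  out <- rep(NA_real_, n)
  tab <- guidelines$nutrition
  tab <- tab[tab$mode == mode & tab$nutrient == nutrient, , drop = FALSE]
  for (i in seq_len(nrow(tab))) {
    hit <- weight_class == tab$weight_class[i] &
      day >= tab$day_lo[i] & day <= tab$day_hi[i]
    out[hit] <- tab$recommended[i]
  }
  out
}

#' Recommended per-kg nutrition value for a patient-day
#'
#' Looks up the recommendation for the requested nutrient given
#' birth weight and day of life. For a day on both enteral and parenteral
#' nutrition (`mode = "BOTH"`), the recommendation is the highest of the
#' EN and PN values (the highest-intake rule). The 2500 g weight-class
#' boundary is inclusive on the low side: 2500 g uses the `le_2500g` rows.
#'
#' @param guidelines A `guideline_set`.
#' @param weight_g Birth weight in grams (scalar or vector).
#' @param day_of_life 1-based day of life (scalar or vector).
#' @param mode `"EN"`, `"PN"` or `"BOTH"` (scalar).
#' @param nutrient `"energy_kcal_per_kg"` or `"protein_g_per_kg"` (scalar).
#' @return Numeric vector of recommended per-kg daily values.
#' @export
#' @examples
#' gl <- default_guidelines()
#' recommend_nutrition(gl, 1400, 5, "BOTH", "energy_kcal_per_kg")
recommend_nutrition <- function(guidelines, weight_g, day_of_life, mode,
                                nutrient) {
  stopifnot(inherits(guidelines, "guideline_set"),
            mode %in% c("EN", "PN", "BOTH"),
            nutrient %in% c("energy_kcal_per_kg", "protein_g_per_kg"))
  if (any(day_of_life < 1)) stop("day_of_life must be >= 1")
  wc <- .weight_class(weight_g)
  out <- if (mode == "BOTH") {
    pmax(.lookup_nutrition(guidelines, "EN", nutrient, wc, day_of_life),
         .lookup_nutrition(guidelines, "PN", nutrient, wc, day_of_life))
  } else {
    .lookup_nutrition(guidelines, mode, nutrient, wc, day_of_life)
  }
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    stop(sprintf("no guideline row covers mode=%s nutrient=%s class=%s day=%d",
                 mode, nutrient, rep_len(wc, length(out))[i],
                 rep_len(day_of_life, length(out))[i]))
  }
  out
}

#' Classify a medication order against its reference
#'
#' An order deviates when its per-kg dose or its daily frequency differs
#' from the reference by 10% or more (relative error, inclusive threshold),
#' each assessed independently. Supplements (vitamins, iron) never count as
#' deviations and are excluded from medication-required accounting
#' upstream.
#'
#' @param guidelines A `guideline_set`.
#' @param drug Drug name (scalar or vector).
#' @param dose_per_kg Prescribed per-kg dose (same units as the reference).
#' @param frequency_per_day Prescribed administrations per day.
#' @param unknown_drug `"error"` (default) or `"skip"`; with `"skip"`,
#'   unknown drugs classify as `NA` with a warning rather than an error.
#' @return Character vector with values `no_deviation`, `dose_deviation`,
#'   `frequency_deviation` or `both_deviation` (and `NA` for skipped
#'   unknown drugs).
#' @export
#' @examples
#' gl <- default_guidelines()
#' classify_medication_order(gl, "amikacin", 16.5, 1)  # 10% high: deviation
classify_medication_order <- function(guidelines, drug, dose_per_kg,
                                      frequency_per_day,
                                      unknown_drug = c("error", "skip")) {
  stopifnot(inherits(guidelines, "guideline_set"))
  unknown_drug <- match.arg(unknown_drug)
  med <- guidelines$medication
  idx <- match(drug, med$drug)
  if (anyNA(idx)) {
    missing <- unique(drug[is.na(idx)])
    if (unknown_drug == "error") {
      stop("unknown drug(s): ", paste(missing, collapse = ", "))
    }
    warning("skipping unknown drug(s): ", paste(missing, collapse = ", "))
  }
  rec_dose <- med$dose_per_kg[idx]
  rec_freq <- med$frequency_per_day[idx]
  dose_dev <- abs(dose_per_kg - rec_dose) / rec_dose >= 0.10
  freq_dev <- abs(frequency_per_day - rec_freq) / rec_freq >= 0.10
  out <- ifelse(dose_dev & freq_dev, "both_deviation",
                ifelse(dose_dev, "dose_deviation",
                       ifelse(freq_dev, "frequency_deviation",
                              "no_deviation")))
  out[!is.na(idx) & med$is_supplement[idx]] <- "no_deviation"
  out
}

#' Is a drug an excluded supplement?
#'
#' @param guidelines A `guideline_set`.
#' @param drug Character vector of drug names.
#' @return Logical vector; `TRUE` for supplements (vitamins, iron) that are
#'   excluded from medication-required and deviation accounting.
#' @export
is_supplement <- function(guidelines, drug) {
  drug %in% guidelines$supplements
}
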