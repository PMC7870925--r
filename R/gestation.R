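#' Gestation category labels and intervals
#'
#' The pipeline stratifies every analysis into four gestational-age
#' categories. Intervals are left-closed, right-open, so a neonate born at
#' exactly 32.0 weeks belongs to the 32-34 week stratum; the last interval
#' is unbounded above.
#'
#' @param edges Numeric vector of three interior bin edges in completed
#'   weeks, defaults to `c(32, 34, 37)` with the first stratum starting at
#'   26 weeks.
#' @return A data.frame with columns `label`, `lo`, `hi` (in weeks; `hi` is
#'   `Inf` for the last stratum).
#' @export
#' @examples
#' gestation_categories()
gestation_categories <- function(edges = c(32, 34, 37)) {
  stopifnot(length(edges) == 3, !is.unsorted(edges))
  data.frame(
    label = c("G26_32", "G32_34", "G34_37", "G37_plus"),
    lo = c(26, edges),
    hi = c(edges, Inf),
    stringsAsFactors = FALSE
  )
}

#' Assign gestational-age categories
#'
#' Bins gestational age at birth into the four strata used throughout the
#' pipeline. Binning is left-closed/right-open. Extremely preterm values in
#' `[22, 26)` weeks are folded into the lowest stratum with a warning
#' (synthetic tails may fall below the lowest boundary even though the
#' modelled population starts at 26 weeks).
#'
#' @param gestation_weeks Numeric vector of gestational ages in weeks
#'   (completed weeks plus fraction). Values outside `[22, 45]` are an error.
#' @param edges Interior bin edges, see [gestation_categories()].
#' @return A factor with levels `G26_32`, `G32_34`, `G34_37`, `G37_plus`.
#' @export
#' @examples
#' assign_gestation_category(c(30.1, 32, 36.9, 38.5))
assign_gestation_category <- function(gestation_weeks, edges = c(32, 34, 37)) {
  if (!is.numeric(gestation_weeks)) {
    stop("`gestation_weeks` must be numeric")
  }
  bad <- !is.na(gestation_weeks) &
    (gestation_weeks < 22 | gestation_weeks > 45)
  if (any(bad)) {
    stop(
      "gestation_weeks outside [22, 45]: ",
      paste(format(gestation_weeks[bad]), collapse = ", ")
    )
  }
  if (any(!is.na(gestation_weeks) & gestation_weeks < 26)) {
    warning("gestation_weeks in [22, 26) folded into G26_32")
  }
  cats <- gestation_categories(edges)
  idx <- findInterval(gestation_weeks, c(-Inf, cats$lo[-1]))
  factor(cats$label[idx], levels = cats$label)
}

#' Category interval midpoints used to centre gestational age
#'
#' Continuous gestational age enters each stratum's model centred at a
#' fixed reference so that intercepts stay interpretable; the open-ended
#' last stratum uses 38.5 weeks (its approximate population mean).
#'
#' @param edges Interior bin edges, see [gestation_categories()].
#' @return Named numeric vector of reference weeks per category label.
#' @export
gestation_reference_weeks <- function(edges = c(32, 34, 37)) {
  cats <- gestation_categories(edges)
  mid <- (cats$lo + cats$hi) / 2
  mid[length(mid)] <- 38.5
  stats::setNames(mid, cats$label)
}
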