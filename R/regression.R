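#' @importFrom stats lm predict model.matrix as.formula coef vcov qt terms
NULL

# round to whole days, halves away from zero (so +6.5 -> +7, -6.5 -> -7)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# terms whose column is constant in `data` (inestimable within a stratum)
.constant_terms <- function(data, terms) {
  terms[vapply(terms, function(t) length(unique(data[[t]])) < 2, logical(1))]
}

.categorical_terms <- function(data, terms) {
  terms[vapply(terms, function(t) {
    is.factor(data[[t]]) || is.character(data[[t]]) || is.logical(data[[t]])
  }, logical(1))]
}

.term_levels <- function(x) {
  if (is.factor(x)) levels(x)
  else if (is.logical(x)) c(FALSE, TRUE)
  else sort(unique(x))
}

# observed-frequency weights of each level of a categorical column
.level_weights <- function(x) {
  lev <- .term_levels(x)
  w <- as.numeric(table(factor(x, levels = lev))) / length(x)
  stats::setNames(w, as.character(lev))
}

#' Fit a LOS model on a transformed response
#'
#' Ordinary least squares of the transformed length of stay on the
#' requested terms. Terms that are constant in `data` (inestimable, e.g. a
#' diagnosis absent from a stratum) are dropped before fitting and
#' reported. The fit stores the observed-frequency weights of every
#' categorical term's levels, which later drive the ordinary
#' (frequency-weighted) marginal means.
#'
#' @param data Design table, e.g. one gestation category's rows of
#'   [build_design()]; must contain `los_days`.
#' @param terms Character vector of modelled columns, default
#'   [default_terms()].
#' @param family A [los_family()] or family name; default `"log"`.
#' @param category Optional gestation-category label carried in the result.
#' @return An object of class `los_fit`: list with the `lm` fit (`model`),
#'   `family`, `terms`, `dropped_terms`, `level_weights`,
#'   `continuous_means`, `coefficients` table (estimate, se, p, 95% CI),
#'   day-scale `aic`/`bic` (Jacobian-corrected), transformed-scale
#'   `r_squared`, `category`, `n`, and the category's `median_los`/
#'   `iqr_los`.
#' @export
fit_los_model <- function(data, terms = default_terms(), family = "log",
                          category = NULL) {
  if (is.character(family)) family <- los_family(family)
  stopifnot(inherits(family, "los_family"), "los_days" %in% names(data))
  terms <- intersect(terms, names(data))
  dropped <- .constant_terms(data, terms)
  if (length(dropped)) {
    message("dropping constant term(s): ", paste(dropped, collapse = ", "))
  }
  terms <- setdiff(terms, dropped)

  data <- as.data.frame(data)
  data$.y <- family$transform(data$los_days)
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(".y ~", rhs))
  fit <- stats::lm(fml, data = data)

  X <- stats::model.matrix(fit)
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(stats::coef(fit))]
    stop("singular design; aliased terms: ", paste(aliased, collapse = ", "))
  }

  smry <- summary(fit)
  cf <- smry$coefficients
  dfres <- fit$df.residual
  tcrit <- stats::qt(0.975, dfres)
  coef_tab <- data.frame(
    coefficient = rownames(cf),
    estimate = cf[, 1], se = cf[, 2], p_value = cf[, 4],
    ci_lo = cf[, 1] - tcrit * cf[, 2],
    ci_hi = cf[, 1] + tcrit * cf[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )

  cat_terms <- .categorical_terms(data, terms)
  num_terms <- setdiff(terms, cat_terms)
  lw <- lapply(data[cat_terms], .level_weights)
  mu <- vapply(data[num_terms], mean, numeric(1))

  n <- nrow(data)
  rss <- sum(fit$residuals^2)
  k <- fit$rank + 1  # + residual variance
  jac <- sum(log(abs(family$dtransform(data$los_days))))
  ll_days <- -n / 2 * (log(2 * pi * rss / n) + 1) + jac

  structure(list(
    model = fit, family = family, terms = terms, dropped_terms = dropped,
    level_weights = lw, continuous_means = as.list(mu),
    coefficients = coef_tab,
    aic = -2 * ll_days + 2 * k, bic = -2 * ll_days + log(n) * k,
    r_squared = smry$r.squared, category = category, n = n,
    median_los = stats::median(data$los_days),
    iqr_los = unname(diff(stats::quantile(data$los_days, c(0.25, 0.75))))
  ), class = "los_fit")
}

#' @export
print.los_fit <- function(x, ...) {
  cat("<los_fit>", if (!is.null(x$category)) x$category else "",
      "family:", x$family$name, " n:", x$n, "\n")
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  cat(sprintf("  AIC %.1f  BIC %.1f  R2 %.3f\n", x$aic, x$bic, x$r_squared))
  invisible(x)
}

# Gaussian AIC/BIC on the day scale for an OLS fit on a transformed
# response (change-of-variables Jacobian), from raw pieces.
.ols_ic <- function(rss, n, rank, jac) {
  k <- rank + 1
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1) + jac
  c(aic = -2 * ll + 2 * k, bic = -2 * ll + log(n) * k)
}

#' Compare response-transform families by repeated 80/20 splits
#'
#' For each iteration a random 80% of the patients builds the model and
#' the held-out 20% tests it. Every family is fitted by ordinary least
#' squares on its transformed response; the construction AIC, BIC
#' (day-scale, Jacobian-corrected so transforms are comparable) and
#' transformed-scale R-squared are recorded together with the day-scale
#' test RMSE of back-transformed predictions. Families are ranked by mean
#' AIC with ties broken by mean test RMSE. The number of iterations
#' defaults to the number of patients in the table. Rows are put in a
#' canonical order (by `patient_id` when present) before splitting, so the
#' result does not depend on row order.
#'
#' @param data Design table for one stratum (or a pooled table).
#' @param terms Modelled columns, default [default_terms()].
#' @param families List of [los_family()] objects, default all four.
#' @param n_iterations Number of random splits; default `nrow(data)`.
#' @param seed Optional integer seed for the split randomisation.
#' @return data.frame ranking with one row per family: `family`,
#'   `mean_aic`, `mean_bic`, `mean_r2`, `mean_rmse_test`, `rank`, ordered
#'   by rank.
#' @export
compare_families <- function(data, terms = default_terms(),
                             families = los_families(),
                             n_iterations = NULL, seed = NULL) {
  data <- as.data.frame(data)
  if ("patient_id" %in% names(data)) {
    data <- data[order(data$patient_id), , drop = FALSE]
  }
  n <- nrow(data)
  if (n < 20) stop("need at least 20 patients to compare families")
  if (is.null(n_iterations)) n_iterations <- n
  stopifnot(n_iterations >= 1)
  terms <- setdiff(intersect(terms, names(data)),
                   .constant_terms(data, terms))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = data)
  if (qr(X)$rank < ncol(X)) {
    drop1 <- qr(X)
    aliased <- colnames(X)[drop1$pivot[-seq_len(drop1$rank)]]
    stop("singular design; aliased terms: ", paste(aliased, collapse = ", "))
  }
  y_days <- data$los_days
  ys <- lapply(families, function(f) f$transform(y_days))
  jacs <- lapply(families, function(f) log(abs(f$dtransform(y_days))))

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }

  n_test <- max(1, round(0.2 * n))
  m <- matrix(0, nrow = length(families), ncol = 4,
              dimnames = list(names(families),
                              c("aic", "bic", "r2", "rmse")))
  for (it in seq_len(n_iterations)) {
    test_idx <- sample.int(n, n_test)
    tr <- setdiff(seq_len(n), test_idx)
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[test_idx, , drop = FALSE]
    for (fi in seq_along(families)) {
      fam <- families[[fi]]
      ytr <- ys[[fi]][tr]
      fit <- stats::lm.fit(Xtr, ytr)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      rss <- sum(fit$residuals^2)
      ic <- .ols_ic(rss, length(tr), fit$rank, sum(jacs[[fi]][tr]))
      tss <- sum((ytr - mean(ytr))^2)
      pred_days <- .back_transform_days(fam, drop(Xte %*% beta))
      m[fi, ] <- m[fi, ] + c(ic["aic"], ic["bic"], 1 - rss / tss,
                             sqrt(mean((y_days[test_idx] - pred_days)^2)))
    }
  }
  m <- m / n_iterations
  out <- data.frame(family = rownames(m), mean_aic = m[, "aic"],
                    mean_bic = m[, "bic"], mean_r2 = m[, "r2"],
                    mean_rmse_test = m[, "rmse"], row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_aic, out$mean_rmse_test), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# map fitted coefficient rows to their term labels via the assign attribute
.coef_terms <- function(fit) {
  asgn <- attr(stats::model.matrix(fit), "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  c("(Intercept)", labels)[asgn + 1]
}

#' Screen terms at p < 0.05 and refit
#'
#' Fits the full model on all rows of `data`, retains every term with at
#' least one coefficient whose Wald p-value is below `alpha` (no
#' multiple-testing correction), and refits on the retained set. When
#' nothing is significant an intercept-only model is returned with a
#' warning.
#'
#' @param data Design table for one stratum.
#' @param terms Candidate terms, default [default_terms()].
#' @param family A [los_family()] or name, normally the winner of
#'   [compare_families()].
#' @param alpha Significance threshold, default 0.05.
#' @param category Optional category label carried in the result.
#' @return A `los_fit` on the retained terms, with attribute
#'   `screened_out` listing the removed terms.
#' @export
select_significant <- function(data, terms = default_terms(),
                               family = "log", alpha = 0.05,
                               category = NULL) {
  full <- fit_los_model(data, terms, family, category = category)
  cf <- full$coefficients
  term_of <- .coef_terms(full$model)
  keep <- unique(term_of[cf$p_value < alpha & term_of != "(Intercept)"])
  if (!length(keep)) {
    warning("no significant terms at p < ", alpha,
            "; returning intercept-only model")
  }
  refit <- fit_los_model(data, keep, full$family, category = category)
  attr(refit, "screened_out") <- setdiff(full$terms, keep)
  refit
}

# reference grid: all level combinations of the fit's categorical terms,
# continuous terms at their data means
.reference_grid <- function(fit, max_cells = 1e5) {
  lev <- lapply(names(fit$level_weights), function(t) {
    lv <- names(fit$level_weights[[t]])
    if (identical(lv, c("FALSE", "TRUE"))) c(FALSE, TRUE) else
      factor(lv, levels = lv)
  })
  names(lev) <- names(fit$level_weights)
  n_cells <- prod(vapply(lev, length, numeric(1)))
  if (length(lev) && n_cells > max_cells) {
    stop("reference grid has ", n_cells,
         " cells; reduce the number of modelled factors")
  }
  grid <- if (length(lev)) expand.grid(lev, KEEP.OUT.ATTRS = FALSE) else
    data.frame(row.names = 1)
  for (t in names(fit$continuous_means)) {
    grid[[t]] <- fit$continuous_means[[t]]
  }
  grid
}

# product of observed-frequency weights over the given terms, per grid row
.grid_weights <- function(fit, grid, over_terms) {
  w <- rep(1, nrow(grid))
  for (t in over_terms) {
    w <- w * fit$level_weights[[t]][as.character(grid[[t]])]
  }
  unname(w)
}

#' Ordinary (frequency-weighted) marginal means of a modelled factor
#'
#' Builds the reference grid -- every combination of the levels of the
#' modelled categorical factors, with continuous covariates fixed at their
#' data means -- and averages the model's transformed-scale predictions
#' over it. For each level of `factor`, predictions are averaged over the
#' grid rows at that level, weighting every *other* factor's levels by
#' their observed frequency in the fitting data. With balanced data the
#' weights are uniform and the result coincides with the equally-weighted
#' (estimated) marginal mean; with unbalanced data the occurrence weights
#' keep rare combinations from dominating.
#'
#' @param fit A `los_fit`.
#' @param factor Name of a modelled categorical term.
#' @param max_cells Guard on reference-grid size.
#' @return Named numeric vector: one transformed-scale mean per level.
#' @export
ordinary_marginal_means <- function(fit, factor, max_cells = 1e5) {
  stopifnot(inherits(fit, "los_fit"))
  if (!factor %in% names(fit$level_weights)) {
    stop("'", factor, "' is not a modelled categorical term")
  }
  grid <- .reference_grid(fit, max_cells)
  preds <- stats::predict(fit$model, newdata = grid)
  other <- setdiff(names(fit$level_weights), factor)
  w <- .grid_weights(fit, grid, other)
  lev <- names(fit$level_weights[[factor]])
  out <- vapply(lev, function(L) {
    sel <- as.character(grid[[factor]]) == L
    sum(w[sel] * preds[sel]) / sum(w[sel])
  }, numeric(1))
  stats::setNames(out, lev)
}

#' Per-level effects in days for every modelled factor
#'
#' Converts each factor's ordinary marginal means to the day scale and
#' anchors them at the frequency-weighted grand marginal mean: the effect
#' of a level is `back(OMM(level)) - back(grand OMM)`, rounded to whole
#' days (halves away from zero). Each level carries the screening p-value
#' of its term (the smallest coefficient p-value), and the table carries
#' the stratum's median LOS and IQR.
#'
#' @param fit A `los_fit`, normally the refit from [select_significant()].
#' @param max_cells Guard on reference-grid size.
#' @return data.frame of class `day_effect_table`: `factor`, `level`,
#'   `effect_days`, `p_value`; attributes `median_los`, `iqr_los`,
#'   `category`.
#' @export
day_effects <- function(fit, max_cells = 1e5) {
  stopifnot(inherits(fit, "los_fit"))
  cf <- fit$coefficients
  term_of <- .coef_terms(fit$model)
  rows <- list()
  for (t in names(fit$level_weights)) {
    omm <- ordinary_marginal_means(fit, t, max_cells)
    wts <- fit$level_weights[[t]]
    grand <- sum(wts * omm)
    eff <- .back_transform_days(fit$family, omm) -
      .back_transform_days(fit$family, grand)
    p <- min(cf$p_value[term_of == t])
    rows[[t]] <- data.frame(factor = t, level = names(omm),
                            effect_days = .round_half_away(unname(eff)),
                            raw_effect_days = unname(eff),
                            p_value = p, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(factor = character(0), level = character(0),
               effect_days = numeric(0), raw_effect_days = numeric(0),
               p_value = numeric(0))
  rownames(out) <- NULL
  structure(out, median_los = fit$median_los, iqr_los = fit$iqr_los,
            category = fit$category,
            class = c("day_effect_table", "data.frame"))
}

#' Predict length of stay in days
#'
#' Back-transformed linear prediction, clamped to at least one day. No
#' smearing correction is applied: effects are reported and predictions
#' made by plain inversion of the transform.
#'
#' @param fit A `los_fit`.
#' @param newdata data.frame with the model's term columns.
#' @param unseen_level `"error"` (default) names any factor level absent
#'   from the fit; `"reference"` falls back to the reference level with a
#'   warning.
#' @return Numeric vector of predicted days (>= 1).
#' @export
predict_los <- function(fit, newdata, unseen_level = c("error", "reference")) {
  stopifnot(inherits(fit, "los_fit"))
  unseen_level <- match.arg(unseen_level)
  newdata <- as.data.frame(newdata)
  for (t in names(fit$level_weights)) {
    known <- names(fit$level_weights[[t]])
    vals <- as.character(newdata[[t]])
    bad <- !vals %in% known
    if (any(bad)) {
      if (unseen_level == "error") {
        stop("unseen level(s) of ", t, ": ",
             paste(unique(vals[bad]), collapse = ", "))
      }
      warning("unseen level(s) of ", t, " mapped to reference '",
              known[1], "'")
      vals[bad] <- known[1]
    }
    newdata[[t]] <- if (identical(known, c("FALSE", "TRUE"))) {
      as.logical(vals)
    } else {
      factor(vals, levels = known)
    }
  }
  z <- stats::predict(fit$model, newdata = newdata)
  unname(.back_transform_days(fit$family, z))
}
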