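test_that("response transforms invert exactly", {
  y <- c(1, 2.5, 7, 30.2, 365)
  for (fam in los_families()) {
    expect_equal(fam$inverse(fam$transform(y)), y, tolerance = 1e-12)
  }
})

test_that("family comparison is deterministic and row-order invariant", {
  run <- shared_small_run()
  d <- run$design[run$design$gestation_category == "G34_37", ]
  a <- compare_families(d, n_iterations = 15, seed = 4)
  b <- compare_families(d, n_iterations = 15, seed = 4)
  expect_identical(a, b)
  perm <- d[sample(nrow(d)), ]
  c3 <- compare_families(perm, n_iterations = 15, seed = 4)
  expect_identical(a, c3)
  expect_equal(sort(a$rank), 1:4)
})

test_that("family comparison finds the generating transform", {
  # light version: 10 runs each way at n=300 (the acceptance suite runs 50)
  mix <- c(G26_32 = 1, G32_34 = 0, G34_37 = 0, G37_plus = 0)
  wins <- function(fam, R = 10) {
    first <- character(R)
    for (r in seq_len(R)) {
      co <- simulate_cohort(sim_config(n_patients = 300, category_mix = mix,
                                       response_family = fam),
                            seed = 600 + r)
      run <- suppressWarnings(suppressMessages(
        run_pipeline(co, family = "log", seed = r)))
      d <- run$design[run$design$gestation_category == "G26_32", ]
      first[r] <- compare_families(d, seed = r)$family[1]
    }
    first
  }
  expect_gte(mean(wins("log") == "log"), 0.9)
  expect_gt(mean(wins("identity") == "identity"), 0.5)
})

test_that("singular designs raise an error naming aliased terms", {
  run <- shared_small_run()
  d <- run$design[run$design$gestation_category == "G34_37", ]
  d$sex_copy <- d$sex
  expect_error(
    compare_families(d, terms = c("sex", "sex_copy"), n_iterations = 2,
                     seed = 1),
    "aliased")
  expect_error(fit_los_model(d, terms = c("sex", "sex_copy")), "aliased")
})

test_that("significance screening keeps strong terms and drops constants", {
  set.seed(5)
  n <- 200
  d <- data.frame(
    los_days = NA, x = factor(sample(c("a", "b"), n, TRUE)),
    noise1 = factor(sample(c("u", "v"), n, TRUE)),
    const = factor("k", levels = c("k", "l")),
    patient_id = sprintf("p%03d", 1:n)
  )
  d$los_days <- pmax(1, round(exp(1.5 + 0.5 * (d$x == "b") +
                                    rnorm(n, 0, 0.3))))
  expect_message(
    fit <- select_significant(d, terms = c("x", "noise1", "const"),
                              family = "log"),
    "constant")
  expect_true("x" %in% fit$terms)
  expect_false("const" %in% fit$terms)
  expect_s3_class(fit, "los_fit")

  # nothing significant: intercept-only with a warning
  d2 <- d
  d2$los_days <- pmax(1, round(exp(1.5 + rnorm(n, 0, 0.3))))
  expect_warning(
    fit2 <- select_significant(d2, terms = "noise1", family = "log"),
    "no significant")
  expect_length(fit2$terms, 0)
})

test_that("single-factor OMM equals the group means", {
  set.seed(8)
  n <- 60
  d <- data.frame(los_days = sample(2:30, n, TRUE),
                  g = factor(sample(c("lo", "hi"), n, TRUE)))
  fit <- fit_los_model(d, terms = "g", family = "log")
  omm <- ordinary_marginal_means(fit, "g")
  for (L in c("lo", "hi")) {
    expect_equal(omm[[L]], mean(log(d$los_days[d$g == L])),
                 tolerance = 1e-9)
  }
})

test_that("balanced designs reduce OMM to the equally-weighted EMM", {
  library(emmeans)
  set.seed(9)
  d <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"),
                   rep = 1:10, stringsAsFactors = TRUE)
  d$los_days <- pmax(1, round(exp(1 + 0.4 * (d$a == "a2") +
                                    0.2 * (d$b == "b2") +
                                    rnorm(nrow(d), 0, 0.2))))
  fit <- fit_los_model(d, terms = c("a", "b"), family = "log")
  omm <- ordinary_marginal_means(fit, "a")
  ref <- emmeans::emmeans(fit$model, "a")
  expect_equal(unname(omm), summary(ref)$emmean, tolerance = 1e-8)
})

test_that("two-factor OMM applies hand-computed occurrence weights", {
  set.seed(10)
  # nuisance factor with frequencies 0.75 / 0.25
  d <- data.frame(
    f = factor(rep(c("x", "y"), each = 16)),
    z = factor(rep(c(rep("a", 12), rep("b", 4)), 2))
  )
  d$los_days <- pmax(1, round(exp(1.2 + 0.5 * (d$f == "y") +
                                    0.3 * (d$z == "b") +
                                    rnorm(32, 0, 0.2))))
  fit <- fit_los_model(d, terms = c("f", "z"), family = "log")
  omm <- ordinary_marginal_means(fit, "f")
  for (L in c("x", "y")) {
    pred <- stats::predict(
      fit$model,
      newdata = data.frame(f = factor(L, levels = c("x", "y")),
                           z = factor(c("a", "b"))))
    expect_equal(omm[[L]], unname(0.75 * pred[1] + 0.25 * pred[2]),
                 tolerance = 1e-9)
  }
})

test_that("OMMs satisfy the weighted-average identity", {
  run <- shared_small_run()
  fit <- run$models[["G37_plus"]]$fit
  grid <- neolos:::.reference_grid(fit)
  preds <- stats::predict(fit$model, newdata = grid)
  w_all <- neolos:::.grid_weights(fit, grid, names(fit$level_weights))
  grand_pred <- sum(w_all * preds) / sum(w_all)
  for (t in names(fit$level_weights)) {
    omm <- ordinary_marginal_means(fit, t)
    wts <- fit$level_weights[[t]]
    expect_equal(sum(wts * omm), grand_pred, tolerance = 1e-9)
  }
})

test_that("day effects are whole days anchored at the grand mean", {
  set.seed(12)
  # symmetric groups with equal means: effects are zero
  d <- data.frame(g = factor(rep(c("a", "b"), each = 30)))
  d$los_days <- rep(c(4, 6), 30)
  fit <- fit_los_model(d, terms = "g", family = "log")
  eff <- day_effects(fit)
  expect_true(all(eff$effect_days == 0))
  expect_true(all(eff$effect_days == round(eff$effect_days)))
  expect_equal(attr(eff, "median_los"), 5)

  run <- shared_small_run()
  eff2 <- run$models[["G32_34"]]$effects
  # Q4 energy deviators sit above the remaining group
  if ("energy_quartile" %in% eff2$factor) {
    q4 <- eff2$effect_days[eff2$factor == "energy_quartile" &
                             eff2$level == "Q4"]
    rem <- eff2$effect_days[eff2$factor == "energy_quartile" &
                              eff2$level == "remaining"]
    expect_gt(q4, 0)
    expect_lt(rem, q4)
  }
})

test_that("LOS predictions back-transform, clamp and respect the model", {
  set.seed(13)
  d <- data.frame(los_days = sample(3:20, 50, TRUE),
                  g = factor(sample(c("a", "b"), 50, TRUE)))
  fit0 <- fit_los_model(d, terms = character(0), family = "log")
  expect_equal(predict_los(fit0, d[1:5, ]),
               rep(exp(coef(fit0$model)[[1]]), 5))

  fit <- fit_los_model(d, terms = "g", family = "log")
  # translation on the transformed scale
  p1 <- predict_los(fit, d)
  fit_shift <- fit
  fit_shift$model$coefficients[1] <- fit_shift$model$coefficients[1] + 0.3
  expect_equal(predict_los(fit_shift, d), pmin(p1 * exp(0.3), 365),
               tolerance = 1e-9)

  # monotone in a positive coefficient
  run <- shared_small_run()
  f32 <- run$models[["G32_34"]]$fit
  if ("energy_quartile" %in% f32$terms) {
    base <- run$design[run$design$gestation_category == "G32_34", ][1, ]
    lo <- hi <- base
    lo$energy_quartile <- factor("remaining", levels = c("remaining", "Q4"))
    hi$energy_quartile <- factor("Q4", levels = c("remaining", "Q4"))
    expect_gt(predict_los(f32, hi), predict_los(f32, lo))
  }

  # unseen levels error, or fall back with a warning
  d2 <- d[1, ]
  d2$g <- "zz"
  expect_error(predict_los(fit, d2), "zz")
  expect_warning(p <- predict_los(fit, d2, unseen_level = "reference"),
                 "reference")
  expect_true(p >= 1)
})

test_that("validation metrics behave at the edges", {
  m <- los_metrics(c(3, 5, 9), c(3, 5, 9))
  expect_equal(m$rmse, 0)
  expect_equal(m$r_squared, 1)
  obs <- c(2, 4, 6, 8)
  m2 <- los_metrics(obs, rep(mean(obs), 4))
  expect_equal(m2$r_squared, 0)
  m3 <- los_metrics(numeric(0), numeric(0))
  expect_true(is.na(m3$rmse))

  run <- shared_small_run()
  expect_true(all(is.finite(run$validation$rmse)))
  expect_equal(nrow(run$riskset), 7)
  expect_true(all(levels(run$design$gestation_category) %in%
                    names(run$riskset)))
})
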