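test_that("AIC and deviance identities hold for every fit", {
  d <- make_toy_dataset()
  fit <- fit_mle(d, "PExpoN", n_starts = 2, seed = 1)
  expect_equal(fit$deviance, -2 * fit$log_likelihood)
  expect_equal(fit$aic, fit$deviance + 2 * fit$n_params)
  expect_equal(fit$n_params, length(param_names("PExpoN")))
  m <- fit_metrics(fit, d)
  expect_equal(m$aic, fit$aic)
  expect_identical(fit$n_obs, nrow(d))
})

test_that("R-squared is 1 for perfect prediction and NA without variance", {
  d <- make_toy_dataset()
  fit <- fit_mle(d, "ZExpoB", n_starts = 2, seed = 2)
  gs <- grid_summary(d)
  # a pseudo-dataset whose observed grid CP rates equal the model prediction
  pred <- predict_cp(fit$spec, fit$estimates, gs$distance, gs$fb_width,
                     clip = FALSE)
  counts <- round(pred / 100 * 5 * k_grains(d))   # 5 cobs worth of grains
  perfect <- fb_dataset(data.frame(
    experiment_id = gs$experiment_id, grid_id = gs$grid_id,
    distance = gs$distance, fb_width = gs$fb_width, cp_grains = counts
  ), k_grains = 5 * k_grains(d))
  # rebuild predictions on the rounded rates: R2 must be ~1
  expect_gt(fit_metrics(fit, perfect)$r_squared, 0.999)
  flat <- fb_dataset(data.frame(
    experiment_id = "A", grid_id = c("g1", "g2"), distance = c(1, 2),
    fb_width = 0, cp_grains = c(5L, 5L)
  ), 400)
  expect_true(is.na(fit_metrics(fit, flat)$r_squared))
})

test_that("a constant-rate Poisson fit recovers the sample mean", {
  lay <- experiment_layout("one", fb_width = 0, n_recipient_rows = 1)
  cfg <- sim_config(lay, "PExpoN",
                    c(Ke = 0.3, a1 = 0.4, a2 = 0.05, D = 3),
                    cobs_per_grid = 200, seed = 8)
  d <- simulate_experiment(cfg)
  fit <- fit_mle(d, "PExpoN", seed = 3)
  lam_hat <- expected_cp_grains(
    kernel_expo(effective_distance(0.75, 0, "PExpoN"), 0,
                c(fit$estimates, k = 0), fb_effect = FALSE),
    k_grains(d))
  expect_equal(lam_hat, mean(d$cp_grains), tolerance = 1e-5)
})

test_that("refitting from the optimum is a fixed point", {
  d <- make_toy_dataset()
  fit <- fit_mle(d, "PCauchyB", seed = 4)
  refit <- fit_mle(d, "PCauchyB", init = fit$estimates, n_starts = 1)
  expect_lt(abs(refit$log_likelihood - fit$log_likelihood), 1e-4)
})

test_that("predictive r needs 3 grids and is high for well-specified models", {
  d <- make_toy_dataset()
  fit <- fit_mle(d, "ZExpoB", n_starts = 2, seed = 5)
  tiny <- fb_dataset(as.data.frame(d)[1:2, ], k_grains(d))
  expect_error(predictive_r(fit, tiny), "3 validation grids")
  # train/validate split of a synthetic suite: r should be high
  suite <- paper_scale_suite(seed = 21)
  all_d <- combine_datasets(suite)
  fold <- pollenFB:::crossval_partition(all_d, seed = 21)
  train <- fb_dataset(as.data.frame(all_d)[fold != 1, ], k_grains(all_d))
  valid <- fb_dataset(as.data.frame(all_d)[fold == 1, ], k_grains(all_d))
  fit2 <- fit_mle(train, "ZExpoB", seed = 6)
  expect_gte(predictive_r(fit2, valid), 0.8)
})

test_that("the grouped threefold partition is balanced, exhaustive and seeded", {
  d <- fb_dataset(data.frame(
    experiment_id = rep(c("A", "A", "B"), each = 3),
    grid_id = rep(c("g1", "g2", "g3"), each = 3),
    distance = rep(c(1, 2, 1), each = 3),
    fb_width = 0,
    cp_grains = 0:8
  ), 400)
  fold <- pollenFB:::crossval_partition(d, seed = 5)
  # 9 observations in 3 groups of 3: each fold holds one observation per group
  expect_equal(sort(unique(fold)), 1:3)
  key <- paste(d$experiment_id, d$distance)
  for (g in unique(key)) {
    expect_equal(sort(fold[key == g]), 1:3)
  }
  # union of folds is the dataset, folds are disjoint by construction
  expect_equal(sort(unlist(lapply(1:3, function(f) which(fold == f)))),
               seq_len(nrow(d)))
  expect_identical(fold, pollenFB:::crossval_partition(d, seed = 5))
  expect_false(identical(fold, pollenFB:::crossval_partition(d, seed = 6)))
  # a too-small group is reported
  small <- fb_dataset(as.data.frame(d)[-1, ], 400)
  expect_error(pollenFB:::crossval_partition(small, seed = 1), "fewer than 3")
})

test_that("cross-validation reports per-fold fits and mean/SD summaries", {
  lay <- small_layout(rows = 8)
  d <- simulate_experiment(sim_config(lay, cobs_per_grid = 6, seed = 13))
  cv <- crossval_threefold(d, "PExpoN", seed = 2, n_starts = 2)
  expect_length(cv$per_fold, 3L)
  expect_setequal(cv$summary$metric, c("aic", "deviance", "r_squared", "r"))
  expect_true(all(is.finite(cv$summary$mean)))
  expect_true(all(cv$summary$sd >= 0))
  # fold assignment covers the dataset
  expect_equal(length(cv$fold), nrow(d))
})
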