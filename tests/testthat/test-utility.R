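test_that("overlay places both datasets in the original-fitted space", {
  ds <- generate_mixed(n = 150, seed = 81)
  ov <- overlay_coordinates(ds, ds)
  expect_equal(ov$original, ov$synthetic)
  expect_equal(ncol(ov$original_2d), 2L)

  av <- generate_avatars(ds, avatar_config(k = 20, seed = 4))
  ov2 <- overlay_coordinates(ds, av$data)
  # avatars are convex mixes of originals, so per-component means agree
  se <- apply(ov2$original, 2L, sd) / sqrt(nrow(ov2$original))
  expect_true(all(abs(colMeans(ov2$synthetic) - colMeans(ov2$original)) <= 3 * se + 1e-8))

  shifted <- ds$data
  shifted$x1 <- shifted$x1 + 5
  ov3 <- overlay_coordinates(ds, tabular_dataset(shifted, schema = ds$schema))
  expect_gt(max(abs(colMeans(ov3$synthetic) - colMeans(ov3$original))), 0.5)
})

test_that("survival comparison recovers a known hazard ratio", {
  ds <- generate_survival(n = 2000, hr = 0.5, seed = 91)
  fit <- survival_comparison(ds, "time", "event", "arm")
  expect_true(fit$ci[1] <= 0.5 && 0.5 <= fit$ci[2])
  expect_lt(fit$wald_p, 0.001)
  expect_lt(fit$logrank_p, 0.001)
  expect_s3_class(fit$km, "survfit")
})

test_that("identical arms give a hazard-ratio CI covering 1", {
  set.seed(92)
  df <- data.frame(time = rexp(600, 0.1), event = TRUE,
                   arm = as.character(rbinom(600, 1, 0.5)),
                   stringsAsFactors = FALSE)
  ds <- tabular_dataset(df, schema = list(
    variable_spec("time", "continuous"), variable_spec("event", "boolean"),
    variable_spec("arm", "categorical", categories = c("0", "1"))))
  fit <- survival_comparison(ds, "time", "event", "arm")
  expect_true(fit$ci[1] <= 1 && 1 <= fit$ci[2])
})

test_that("survival comparison rejects degenerate arms", {
  df <- data.frame(time = rexp(100, 0.1) + 0.01,
                   event = rep(c(TRUE, FALSE), 50),
                   arm = rep(c("0", "1"), each = 50),
                   stringsAsFactors = FALSE)
  df$event[df$arm == "1"] <- FALSE   # no events in arm 1
  ds <- tabular_dataset(df, schema = list(
    variable_spec("time", "continuous"), variable_spec("event", "boolean"),
    variable_spec("arm", "categorical", categories = c("0", "1"))))
  expect_error(survival_comparison(ds, "time", "event", "arm"),
               class = "avt_utility_error")
})

test_that("log-HR is approximately unbiased on data from its own model", {
  lhr <- vapply(1:25, function(s) {
    ds <- generate_survival(n = 2000, hr = 0.5, seed = 1000 + s)
    survival_comparison(ds, "time", "event", "arm")$log_hr
  }, 0)
  expect_lt(abs(mean(lhr) - log(0.5)), 0.05)
})

test_that("F-scores behave analytically and ignore row order", {
  X <- cbind(flat = rep(3, 40), split = c(rep(1, 20), rep(9, 20)))
  y <- c(rep(FALSE, 20), rep(TRUE, 20))
  fs <- f_scores(X, y)
  expect_identical(unname(fs["flat"]), 0)  # identical in both classes
  expect_identical(unname(fs["split"]), Inf)  # zero within-class variance
  set.seed(66)
  X2 <- cbind(noise = rnorm(40), graded = ifelse(y, 7, 3) + rnorm(40))
  fs2 <- f_scores(X2, y)
  expect_gt(fs2["graded"], 10 * fs2["noise"])
  perm <- sample(40)
  expect_equal(f_scores(X2[perm, ], y[perm]), fs2)
  expect_error(f_scores(X2, rep(TRUE, 40)), class = "avt_utility_error")
})

test_that("a perfectly separating feature ranks first and drives AUC to 100", {
  ds <- generate_classification(n = 300, separable = TRUE, seed = 15)
  cc <- classification_comparison(ds, "outcome", n_repeats = 10, seed = 8)
  expect_equal(names(which.max(cc$f_score_mean)), "sep")
  expect_equal(cc$selection_freq[["sep"]], 1)
  expect_gt(cc$auc_mean, 99.9)
})

test_that("null features give chance-level AUC", {
  ds <- generate_classification(n = 400, effect_sizes = rep(0, 5), seed = 16)
  cc <- classification_comparison(ds, "outcome", n_repeats = 10, seed = 9)
  expect_gt(cc$auc_mean, 35)
  expect_lt(cc$auc_mean, 65)
})

test_that("AUC is invariant to feature rescaling", {
  ds <- generate_classification(n = 300, seed = 17)
  cc1 <- classification_comparison(ds, "outcome", n_repeats = 5, seed = 10)
  scaled <- ds$data
  scaled$v1 <- scaled$v1 * 100
  scaled$v2 <- scaled$v2 / 50
  ds2 <- tabular_dataset(scaled, schema = ds$schema)
  cc2 <- classification_comparison(ds2, "outcome", n_repeats = 5, seed = 10)
  expect_equal(cc1$auc_values, cc2$auc_values, tolerance = 1e-8)
})
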