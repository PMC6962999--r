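test_that("design matrix standardizes, one-hot encodes and stores constants", {
  set.seed(3)
  n <- 200
  obs <- tibble::tibble(
    y = rnorm(n),
    ppfd = runif(n, 0, 1500), temperature = runif(n, 5, 30),
    flat = 1,
    species = sample(c("a", "b", "c"), n, replace = TRUE),
    genotype = sample(paste0("g", 1:6), n, replace = TRUE))
  cov <- list(continuous = c("ppfd", "temperature", "flat"),
              categorical = c("species", "genotype"))
  expect_warning(des <- build_design_matrix(obs, "y", cov), "zero-variance")
  # 2 continuous + (3-1) + (6-1) one-hot columns
  expect_equal(ncol(des$Z), 2 + 2 + 5)
  expect_lt(abs(mean(des$Z[, "ppfd"])), 1e-10)
  expect_lt(abs(sd(des$Z[, "ppfd"]) - 1), 1e-10)
  # projection of new data reuses the training constants
  td <- design_transform(des, obs[1:10, ])
  expect_equal(td$Z, des$Z[1:10, ])
  expect_error(design_transform(des, obs[, -2]), "schema")
})

test_that("full shrinkage gives the intercept-only model", {
  d <- sim_driver_data(n = 300, seed = 4)
  des <- build_design_matrix(d, "y", driver_covariates)
  fit <- fit_lasso_cv(des, folds = 5, seed = 4)
  # at the top of the path (lambda_max) every coefficient is zero and the
  # intercept is the response mean
  top <- as.numeric(stats::coef(fit$glmnet_fit$glmnet.fit,
                                s = max(fit$cv_curve$lambda)))
  expect_equal(top[-1], rep(0, ncol(des$Z)))
  expect_equal(top[1], mean(des$y), tolerance = 1e-8)
  # nonzero count is non-increasing along increasing lambda
  curve <- fit$cv_curve[order(fit$cv_curve$lambda), ]
  expect_true(all(diff(curve$nonzero) <= 0))
})

test_that("CV-chosen lasso recovers a known driver among pure noise", {
  d <- sim_driver_data(n = 2000, seed = 1)
  des <- build_design_matrix(d, "y", driver_covariates)
  fit <- fit_lasso_cv(des, seed = 1)
  b_temp <- fit$u["temperature"]
  b_noise <- fit$u[setdiff(names(fit$u), "temperature")]
  expect_gt(abs(b_temp), 0)
  expect_gte(abs(b_temp), 4 * max(abs(b_noise)))
  expect_gte(sum(b_noise == 0), 8)
  # same seed reproduces lambda and coefficients exactly
  fit2 <- fit_lasso_cv(des, seed = 1)
  expect_identical(fit$lambda, fit2$lambda)
  expect_identical(fit$u, fit2$u)
})

test_that("prediction is mu + Z u with the training standardization", {
  d <- sim_driver_data(n = 500, seed = 6)
  des <- build_design_matrix(d, "y", driver_covariates)
  fit <- fit_lasso_cv(des, folds = 5, seed = 6)
  # training predictions from the definition
  expect_equal(predict(fit), drop(des$Z %*% fit$u) + fit$mu)
  # held-out rows give finite predictions and reproducible residuals
  newd <- sim_driver_data(n = 100, seed = 7)
  pr <- predict(fit, newd)
  expect_true(all(is.finite(pr$predicted)))
  expect_equal(length(pr$predicted), 100)
  # an all-zero coefficient vector predicts the constant intercept
  fit0 <- fit; fit0$u[] <- 0
  expect_equal(unique(predict(fit0)), fit0$mu)
})

test_that("accuracy is Pearson r on (genotype, day, hour) cell means", {
  set.seed(8)
  n <- 120
  g <- rep(c("A", "B"), each = n / 2)
  date <- rep(as.Date("2017-04-01") + 0:4, length.out = n)
  hour <- rep(8:11, length.out = n)
  obsv <- rnorm(n)
  acc <- validate_accuracy(obsv, obsv, g, date, hour)
  expect_equal(acc$r, c(1, 1))
  acc_neg <- validate_accuracy(-obsv + 2, obsv, g, date, hour)
  expect_equal(acc_neg$r, c(-1, -1))
  # constant observations leave r undefined and flagged
  accc <- validate_accuracy(obsv, rep(1, n), g, date, hour)
  expect_true(all(is.na(accc$r)))
  expect_true(all(accc$flag == "undefined"))
  # averaging happens before correlating: perfect cell means, noisy rows
  cellmean <- ave(obsv, paste(g, date, hour))
  acc2 <- validate_accuracy(cellmean, obsv, g, date, hour)
  expect_equal(acc2$r, c(1, 1))
})

test_that("half-days split alternates calendar days deterministically", {
  obs <- tibble::tibble(date = rep(as.Date("2017-04-01") + 0:9, each = 3))
  parts <- split_train_validation(obs, "half-days")
  expect_equal(length(unique(parts$train$date)), 5)
  expect_equal(length(unique(parts$validation$date)), 5)
  expect_length(intersect(parts$train$date, parts$validation$date), 0)
  expect_equal(nrow(parts$train) + nrow(parts$validation), nrow(obs))
  # 95 days split 48 / 47, training takes the extra day
  obs95 <- tibble::tibble(date = as.Date("2016-05-01") + 0:94)
  p95 <- split_train_validation(obs95, "half-days")
  expect_equal(nrow(p95$train), 48)
  expect_equal(nrow(p95$validation), 47)
  expect_error(split_train_validation(obs95[1, ], "half-days"), ">= 2")
  expect_error(split_train_validation(obs95, "by-season"), "season")
})

test_that("Type-I partition conserves SS and credits a perfect predictor", {
  set.seed(10)
  n <- 240
  obs <- tibble::tibble(
    temperature = runif(n, 4, 30),
    month = sample(4:6, n, replace = TRUE),
    genotype = sample(c("g1", "g2"), n, replace = TRUE),
    hour_of_day = sample(0:23, n, replace = TRUE))
  obs$fr2_ratio <- 0.3 + 0.012 * obs$temperature  # no noise
  vp <- partition_variance(obs, "fr2",
                           factors = c("temperature", "month", "genotype",
                                       "hour"))
  expect_equal(vp$pct_explained[vp$factor == "temperature"], 100,
               tolerance = 1e-6)
  expect_true(all(vp$pct_explained[vp$factor != "temperature"] < 1e-6))
  expect_equal(sum(vp$sum_sq), attr(vp, "total_ss"), tolerance = 1e-8)
  expect_equal(sum(vp$pct_explained), 100, tolerance = 0.1)

  # orthogonal balanced factors keep their SS under permutation
  grid <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"), rep = 1:20)
  set.seed(11)
  grid$fr2_ratio <- 0.5 + 0.1 * (grid$a == "x") + 0.05 * (grid$b == "u") +
    rnorm(nrow(grid), 0, 0.01)
  v1 <- partition_variance(grid, "fr2", factors = c("factor(a)", "factor(b)"))
  v2 <- partition_variance(grid, "fr2", factors = c("factor(b)", "factor(a)"))
  expect_equal(v1$sum_sq[v1$factor == "factor(a)"],
               v2$sum_sq[v2$factor == "factor(a)"], tolerance = 1e-10)
  expect_equal(v1$sum_sq[v1$factor == "factor(b)"],
               v2$sum_sq[v2$factor == "factor(b)"], tolerance = 1e-10)
})

test_that("response curves recover exact coefficients and map groups", {
  T <- seq(4, 30, length.out = 60)
  obs <- tibble::tibble(temperature = T,
                        fr2_ratio = 0.1 + 0.02 * sqrt(T))
  fit <- fit_response_curve(obs, "fr2", "temperature", terms = "sqrt")
  expect_equal(fit$intercept, 0.1, tolerance = 1e-8)
  expect_equal(fit$b_sqrt, 0.02, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)

  # five groups give five fits
  obs5 <- tibble::tibble(
    ppfd = rep(seq(50, 1500, length.out = 30), 5),
    pri_level = rep(paste0("L", 1:5), each = 30))
  obs5$fvfm <- 0.8 - 0.008 * sqrt(obs5$ppfd) +
    0.01 * as.integer(factor(obs5$pri_level))
  fits <- fit_response_curve(obs5, "fvfm", "ppfd", terms = "sqrt",
                             group = "pri_level")
  expect_equal(nrow(fits), 5)
  expect_true(all(fits$r_squared > 0.99))
  # groups under the row minimum are skipped with a message
  expect_message(
    fit_response_curve(obs5[c(1:30, 31:35), ], "fvfm", "ppfd",
                       terms = "sqrt", group = "pri_level"),
    "skipped")
})
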