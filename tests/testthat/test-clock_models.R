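# Reduced hyperparameter settings keep the model tests fast; the full grid
# runs in the acceptance suite.
fast_rf_params <- function(seed = 1L) {
  rf_clock_params(seed = seed, n_trees_grid = 200L, max_depth_grid = c(Inf, 5),
                  min_leaf_grid = c(1L, 3L), cv_folds = 3L,
                  stability_reps = 2L, stability_folds = 5L)
}

# Feature matrix (features x samples) with one oracle feature ~ age and noise.
oracle_matrix <- function(n = 40L, n_noise = 8L, seed = 2L, noise_sd = 0.5) {
  set.seed(seed)
  ages <- runif(n, 20, 60)
  mat <- rbind(oracle = ages + rnorm(n, sd = noise_sd),
               matrix(runif(n_noise * n), n_noise, n,
                      dimnames = list(paste0("noise", seq_len(n_noise)), NULL)))
  colnames(mat) <- sprintf("s%02d", seq_len(n))
  list(mat = mat, ages = ages)
}

test_that("train/test split is disjoint, exhaustive and reproducible", {
  ids <- sprintf("s%02d", 1:10)
  sp <- split_train_test(ids, 0.8, seed = 4L)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_train_test(ids, 0.8, seed = 4L))
  sp100 <- split_train_test(sprintf("x%03d", 1:100), 0.8, seed = 1L)
  expect_length(sp100$train, 80L)
  expect_error(split_train_test(ids, 1.2), "fraction")
  expect_error(split_train_test(ids[1:3], 0.8), "at least 5")
})

test_that("evaluate_clock computes MAE and the coefficient of determination", {
  ev <- evaluate_clock(c(20, 30, 40), c(20, 30, 40))
  expect_equal(ev$mae, 0); expect_equal(ev$r2, 1)
  ev2 <- evaluate_clock(c(20, 30, 40), rep(30, 3))
  expect_equal(ev2$r2, 0)
  ev3 <- evaluate_clock(c(20, 30, 40), c(22, 28, 44))
  expect_equal(ev3$mae, 8 / 3)
  expect_error(evaluate_clock(c(30, 30), c(28, 29)), "zero variance")
})

test_that("oracle features yield a near-perfect RF clock", {
  set.seed(21)
  ages <- runif(50, 20, 60)
  mat <- rbind(oracle1 = ages, oracle2 = ages)   # every split sees the truth
  colnames(mat) <- sprintf("s%02d", seq_along(ages))
  fit <- fit_wsh_rf_clock(mat, ages, rownames(mat), fast_rf_params())
  expect_lt(fit$test$mae, 1.5)
  expect_gt(fit$test$r2, 0.95)

  om <- oracle_matrix(noise_sd = 0.1)
  params <- fast_rf_params()
  params$mtry <- 9L   # all features per split, sklearn-style
  fit <- fit_wsh_rf_clock(om$mat, om$ages, rownames(om$mat), params)
  expect_lt(fit$test$mae, 2)
  expect_gt(fit$test$r2, 0.9)
  # regression-forest range property
  preds <- predict(fit$model, t(om$mat))
  tr_ages <- om$ages[match(fit$split$train, colnames(om$mat))]
  expect_true(all(preds >= min(tr_ages) & preds <= max(tr_ages)))
  expect_error(fit_wsh_rf_clock(om$mat, om$ages, "oracle", fast_rf_params()),
               "fewer than 2")
})

test_that("RF imputation medians come from the training split only", {
  om <- oracle_matrix()
  mat <- om$mat
  sp <- split_train_test(colnames(mat), 0.8, seed = 1L)
  # poison the test columns of one feature; the train median must be unaffected
  mat["noise1", sp$test] <- NA
  fit <- fit_wsh_rf_clock(mat, om$ages, rownames(mat), fast_rf_params())
  train_vals <- mat["noise1", fit$split$train]
  expect_equal(unname(fit$imputation_medians["noise1"]),
               median(train_vals, na.rm = TRUE))
})

test_that("RF clock is reproducible for a fixed seed", {
  om <- oracle_matrix(n = 30L, n_noise = 4L)
  f1 <- fit_wsh_rf_clock(om$mat, om$ages, rownames(om$mat), fast_rf_params(7L))
  f2 <- fit_wsh_rf_clock(om$mat, om$ages, rownames(om$mat), fast_rf_params(7L))
  expect_identical(f1$test, f2$test)
  expect_identical(f1$best, f2$best)
})

lasso_matrix <- function(n = 60L, n_inf = 5L, n_noise = 15L, seed = 6L) {
  set.seed(seed)
  ages <- runif(n, 20, 60)
  a <- (ages - 20) / 40
  inf <- t(sapply(seq_len(n_inf), function(i) {
    plogis(-1 + (1 + 0.2 * i) * a) + rnorm(n, sd = 0.02)
  }))
  noise <- matrix(runif(n_noise * n, 0.2, 0.8), n_noise, n)
  mat <- rbind(inf, noise)
  rownames(mat) <- c(sprintf("c1:%d-%d", seq_len(n_inf) * 1000,
                             seq_len(n_inf) * 1000 + 250),
                     sprintf("c2:%d-%d", seq_len(n_noise) * 1000,
                             seq_len(n_noise) * 1000 + 250))
  colnames(mat) <- sprintf("s%02d", seq_len(n))
  list(mat = mat, ages = ages)
}

test_that("LASSO clock fits, reports sparsity within bounds, and predicts", {
  lm_ <- lasso_matrix()
  fit <- fit_region_lasso_clock(lm_$mat, lm_$ages)
  expect_gte(fit$n_nonzero, 1L)
  expect_lte(fit$n_nonzero, nrow(lm_$mat))
  expect_lt(fit$test$mae, 6)
  expect_equal(sort(names(fit$coefficients)), sort(rownames(lm_$mat)))
})

test_that("duplicate feature rows do not change LASSO predictions", {
  lm_ <- lasso_matrix(n = 40L, n_inf = 3L, n_noise = 5L)
  dup <- rbind(lm_$mat, lm_$mat[1, , drop = FALSE])
  rownames(dup)[nrow(dup)] <- "c9:1-251"
  f1 <- fit_region_lasso_clock(lm_$mat, lm_$ages)
  # at a fixed penalty the fitted values are identical with or without the
  # duplicated column (coefficient mass may split, predictions cannot)
  y <- lm_$ages[match(f1$split$train, colnames(lm_$mat))]
  g1 <- glmnet::glmnet(t(lm_$mat[, f1$split$train]), y, alpha = 1,
                       lambda = f1$lambda, thresh = 1e-12)
  g2 <- glmnet::glmnet(t(dup[, f1$split$train]), y, alpha = 1,
                       lambda = f1$lambda, thresh = 1e-12)
  p1 <- predict(g1, t(lm_$mat[, f1$split$test]))
  p2 <- predict(g2, t(dup[, f1$split$test]))
  expect_equal(as.numeric(p2), as.numeric(p1), tolerance = 1e-4)
})

test_that("the lasso path never gains coefficients as the penalty grows", {
  lm_ <- lasso_matrix()
  X <- t(lm_$mat)
  fit <- glmnet::glmnet(X, lm_$ages, alpha = 1)
  nz <- fit$df  # non-zero counts along the decreasing-lambda path
  expect_true(all(diff(rev(nz)) <= 0))
})

test_that("RFE keeps the oracle feature and collapses to a singleton", {
  om <- oracle_matrix(n = 50L, n_noise = 10L, noise_sd = 0.1)
  sp <- split_train_test(colnames(om$mat), 0.8, seed = 2L)
  rfe <- rfe_curve(om$mat, om$ages, rownames(om$mat), sp, family = "lasso",
                   seed = 3L)
  expect_equal(rfe$curve$k, seq(nrow(om$mat), 1L))
  expect_equal(rfe$minimal_k, 1L)
  expect_equal(rfe$minimal_features, "oracle")
  # single-feature start: curve of length 1
  rfe1 <- rfe_curve(om$mat, om$ages, "oracle", sp, family = "lasso", seed = 3L)
  expect_equal(nrow(rfe1$curve), 1L)
})

test_that("RFE works on the random-forest route", {
  om <- oracle_matrix(n = 40L, n_noise = 4L, noise_sd = 0.1)
  sp <- split_train_test(colnames(om$mat), 0.8, seed = 2L)
  rfe <- rfe_curve(om$mat, om$ages, rownames(om$mat), sp, family = "rf",
                   seed = 3L, rf_args = list(n_trees = 100L))
  expect_equal(rfe$curve$k, seq(5L, 1L))
  expect_true("oracle" %in% rfe$minimal_features)
})

test_that("clock JSON serialization is self-describing", {
  lm_ <- lasso_matrix(n = 40L, n_inf = 3L, n_noise = 5L)
  fit <- fit_region_lasso_clock(lm_$mat, lm_$ages)
  f <- withr::local_tempfile(fileext = ".json")
  write_clock_json(fit, f)
  obj <- jsonlite::read_json(f)
  expect_equal(obj$family, "LASSO")
  expect_equal(obj$n_nonzero, fit$n_nonzero)
  om <- oracle_matrix(n = 30L, n_noise = 3L)
  rfit <- fit_wsh_rf_clock(om$mat, om$ages, rownames(om$mat), fast_rf_params())
  write_clock_json(rfit, f)
  obj2 <- jsonlite::read_json(f)
  expect_equal(obj2$family, "RF")
  expect_length(obj2$features, 4L)
})
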