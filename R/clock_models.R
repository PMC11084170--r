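# Age-prediction clock models: random-forest clocks on high-correlation
# heterogeneity loci, LASSO clocks on window methylation, evaluation, and
# recursive feature elimination. Feature matrices follow the package
# convention: features (loci/windows) as rows, samples as columns.

#' Split sample ids into train and test sets
#'
#' @param sample_ids Character vector of sample ids.
#' @param fraction Training fraction in (0,1); default 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_train_test <- function(sample_ids, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  n <- length(sample_ids)
  if (n < 5L) stop("need at least 5 samples to split")
  n_train <- round(fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = sample_ids[sort(idx)], test = sample_ids[sort(setdiff(seq_len(n), idx))])
}

# Run expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

make_folds <- function(n, k, seed) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Evaluate predicted against true ages
#'
#' @param true_ages,predicted_ages Equal-length numeric vectors (>= 2).
#' @return List with `mae` (mean absolute error, years), `r2` (coefficient
#'   of determination, 1 - SS_res/SS_tot), `r2_cor` (squared Pearson
#'   correlation; reported alongside because conventions differ), `n`, and
#'   the per-sample `predictions` table.
#' @export
evaluate_clock <- function(true_ages, predicted_ages) {
  stopifnot(length(true_ages) == length(predicted_ages), length(true_ages) >= 2L)
  if (stats::sd(true_ages) == 0) stop("R^2 undefined: true ages have zero variance")
  ss_res <- sum((true_ages - predicted_ages)^2)
  ss_tot <- sum((true_ages - mean(true_ages))^2)
  r2c <- if (stats::sd(predicted_ages) > 0) stats::cor(true_ages, predicted_ages)^2 else NA_real_
  list(mae = mean(abs(true_ages - predicted_ages)),
       r2 = 1 - ss_res / ss_tot,
       r2_cor = r2c,
       n = length(true_ages),
       predictions = data.table::data.table(true_age = true_ages,
                                            predicted_age = predicted_ages))
}

#' Parameters for the random-forest clock
#'
#' @param split_fraction Training fraction (default 0.8).
#' @param seed Seed driving the split, folds and forests.
#' @param n_trees_grid,max_depth_grid,min_leaf_grid Hyperparameter grid
#'   searched by cross-validated MAE.
#' @param cv_folds Folds for hyperparameter selection (default 5).
#' @param stability_reps,stability_folds Repeats x folds of the stability
#'   cross-validation run with the chosen hyperparameters (default 5 x 10).
#' @param mtry Features tried per split (default `NULL`: sqrt of the
#'   feature count).
#' @export
rf_clock_params <- function(split_fraction = 0.8, seed = 1L,
                            n_trees_grid = c(200L, 500L),
                            max_depth_grid = c(Inf, 5, 10),
                            min_leaf_grid = c(1L, 3L, 5L),
                            cv_folds = 5L, stability_reps = 5L,
                            stability_folds = 10L, mtry = NULL) {
  as.list(environment())
}

impute_median_train <- function(X_train, X_other) {
  med <- apply(X_train, 2L, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  fill <- function(X) {
    for (j in seq_len(ncol(X))) {
      na <- is.na(X[, j])
      if (any(na)) X[na, j] <- med[j]
    }
    X
  }
  list(train = fill(X_train), other = fill(X_other), medians = med)
}

#' Fit a WSH random-forest age clock
#'
#' Features are the highly age-correlated loci of one heterogeneity metric.
#' The samples are split 80/20; hyperparameters are chosen by k-fold
#' cross-validated MAE on the training split (the tree-count axis reuses
#' prefixes of the largest forest); stability is estimated by repeated
#' k-fold cross-validation with the chosen hyperparameters; the final model
#' is fit on the full training split and evaluated on the untouched test
#' split. Missing scores are imputed with per-feature training medians.
#'
#' @param mat Locus-by-sample score matrix.
#' @param ages Ages aligned with the matrix columns.
#' @param features Character vector of locus keys to use (the `high`
#'   subset); must contain at least 2 loci present in the matrix.
#' @param params [rf_clock_params()].
#' @return List with `model` (the final `wsh_rf`), `best` hyperparameters,
#'   `cv` (stability evaluation: mean/sd of MAE and R^2 across repeats),
#'   `test` ([evaluate_clock()] on the test split), `split`, `features`.
#' @export
fit_wsh_rf_clock <- function(mat, ages, features, params = rf_clock_params()) {
  features <- intersect(features, rownames(mat))
  if (length(features) < 2L) {
    stop("fewer than 2 features available; relax the correlation threshold")
  }
  stopifnot(ncol(mat) == length(ages))
  sp <- split_train_test(colnames(mat), params$split_fraction, params$seed)
  X <- t(mat[features, , drop = FALSE])
  y <- stats::setNames(ages, colnames(mat))
  im <- impute_median_train(X[sp$train, , drop = FALSE], X[sp$test, , drop = FALSE])
  Xtr <- im$train; Xte <- im$other
  ytr <- y[sp$train]; yte <- y[sp$test]

  grid <- expand.grid(max_depth = params$max_depth_grid,
                      min_leaf = params$min_leaf_grid)
  nt_max <- max(params$n_trees_grid)
  folds <- make_folds(nrow(Xtr), params$cv_folds, params$seed + 1L)
  cv_mae <- array(0, dim = c(nrow(grid), length(params$n_trees_grid)))
  for (g in seq_len(nrow(grid))) {
    abs_err <- matrix(0, nrow(Xtr), length(params$n_trees_grid))
    for (f in seq_len(params$cv_folds)) {
      tr <- folds != f
      fit <- rf_fit(Xtr[tr, , drop = FALSE], ytr[tr], n_trees = nt_max,
                    mtry = params$mtry,
                    max_depth = grid$max_depth[g], min_leaf = grid$min_leaf[g],
                    seed = params$seed + 100L * g + f)
      for (ti in seq_along(params$n_trees_grid)) {
        pred <- predict(fit, Xtr[!tr, , drop = FALSE],
                        n_trees = params$n_trees_grid[ti])
        abs_err[!tr, ti] <- abs(pred - ytr[!tr])
      }
    }
    cv_mae[g, ] <- colMeans(abs_err)
  }
  best_idx <- which(cv_mae == min(cv_mae), arr.ind = TRUE)[1L, ]
  best <- list(n_trees = params$n_trees_grid[best_idx[2L]],
               max_depth = grid$max_depth[best_idx[1L]],
               min_leaf = grid$min_leaf[best_idx[1L]],
               cv_mae = min(cv_mae))

  # stability: repeated k-fold CV with the selected hyperparameters
  rep_mae <- numeric(params$stability_reps)
  rep_r2 <- numeric(params$stability_reps)
  for (r in seq_len(params$stability_reps)) {
    sf <- make_folds(nrow(Xtr), params$stability_folds, params$seed + 1000L + r)
    pred <- numeric(nrow(Xtr))
    for (f in seq_len(params$stability_folds)) {
      tr <- sf != f
      if (sum(!tr) == 0L) next
      fit <- rf_fit(Xtr[tr, , drop = FALSE], ytr[tr], n_trees = best$n_trees,
                    mtry = params$mtry,
                    max_depth = best$max_depth, min_leaf = best$min_leaf,
                    seed = params$seed + 2000L * r + f)
      pred[!tr] <- predict(fit, Xtr[!tr, , drop = FALSE])
    }
    ev <- evaluate_clock(ytr, pred)
    rep_mae[r] <- ev$mae; rep_r2[r] <- ev$r2
  }

  model <- rf_fit(Xtr, ytr, n_trees = best$n_trees, mtry = params$mtry,
                  max_depth = best$max_depth,
                  min_leaf = best$min_leaf, seed = params$seed)
  test_ev <- evaluate_clock(yte, predict(model, Xte))
  list(model = model, best = best,
       cv = list(mae = mean(rep_mae), mae_sd = stats::sd(rep_mae),
                 r2 = mean(rep_r2), r2_sd = stats::sd(rep_r2),
                 rep_mae = rep_mae, rep_r2 = rep_r2),
       test = test_ev, split = sp, features = features,
       imputation_medians = im$medians)
}

#' Parameters for the region LASSO clock
#'
#' @param split_fraction Training fraction (default 0.8).
#' @param seed Seed for the split and fold assignment.
#' @param cv_folds Folds for the penalty search (default 10).
#' @param nlambda Length of the log-spaced penalty grid (default 100).
#' @export
lasso_clock_params <- function(split_fraction = 0.8, seed = 1L,
                               cv_folds = 10L, nlambda = 100L) {
  as.list(environment())
}

#' Fit a region-based LASSO age clock
#'
#' Features are genomic windows passing the Pearson age-correlation filter.
#' The L1 penalty is chosen on a log-spaced grid by k-fold cross-validated
#' MAE on the training split; the final model is refit on the full training
#' split at the chosen penalty and evaluated on the untouched test split.
#' Both the cross-validated performance (out-of-fold predictions) and the
#' train-refit performance are reported, since conventions differ.
#'
#' @param mat Window-by-sample methylation matrix (no NA cells).
#' @param ages Ages aligned with the matrix columns.
#' @param features Optional subset of window keys (default: all rows).
#' @param params [lasso_clock_params()].
#' @return List with `model` (glmnet fit), `lambda`, `n_nonzero` (windows
#'   with non-zero coefficient), `nonzero_features`, `cv`, `train`, `test`
#'   evaluations and `split`.
#' @export
fit_region_lasso_clock <- function(mat, ages, features = NULL,
                                   params = lasso_clock_params()) {
  if (is.null(features)) features <- rownames(mat)
  features <- intersect(features, rownames(mat))
  if (length(features) < 2L) stop("fewer than 2 window features available")
  stopifnot(ncol(mat) == length(ages))
  sp <- split_train_test(colnames(mat), params$split_fraction, params$seed)
  X <- t(mat[features, , drop = FALSE])
  y <- stats::setNames(ages, colnames(mat))
  Xtr <- X[sp$train, , drop = FALSE]; Xte <- X[sp$test, , drop = FALSE]
  ytr <- y[sp$train]; yte <- y[sp$test]
  foldid <- make_folds(nrow(Xtr), params$cv_folds, params$seed + 1L)
  cvfit <- glmnet::cv.glmnet(Xtr, ytr, alpha = 1, foldid = foldid,
                             type.measure = "mae", nlambda = params$nlambda,
                             keep = TRUE)
  if (max(cvfit$nzero) == 0L) {
    stop("all coefficients zero along the penalty path; extend the lambda grid")
  }
  ilam <- which(cvfit$lambda == cvfit$lambda.min)[1L]
  cv_pred <- cvfit$fit.preval[, ilam]
  cv_ev <- evaluate_clock(ytr, cv_pred)
  model <- glmnet::glmnet(Xtr, ytr, alpha = 1, lambda = cvfit$lambda.min)
  beta <- as.numeric(stats::coef(model))[-1L]
  nz <- which(beta != 0)
  train_ev <- evaluate_clock(ytr, as.numeric(stats::predict(model, Xtr)))
  test_ev <- evaluate_clock(yte, as.numeric(stats::predict(model, Xte)))
  list(model = model, lambda = cvfit$lambda.min,
       n_nonzero = length(nz), nonzero_features = features[nz],
       coefficients = stats::setNames(beta, features),
       intercept = as.numeric(stats::coef(model))[1L],
       cv = cv_ev, train = train_ev, test = test_ev, split = sp,
       features = features)
}

#' Recursive feature elimination curve
#'
#' Starting from a feature list (typically the LASSO non-zero windows), the
#' least important feature is removed one at a time; the model is retrained
#' on the training split and evaluated on the fixed test split at every
#' size k down to 1. Importance is the standardised coefficient magnitude
#' (LASSO route, refit at a fixed penalty chosen once by cross-validation)
#' or the impurity importance (random-forest route). The minimal set is the
#' smallest k whose test MAE is within `(1 + tol)` of the full model's.
#'
#' @param mat Feature-by-sample matrix.
#' @param ages Ages aligned with columns.
#' @param features Starting feature keys.
#' @param split A `list(train, test)` of sample ids (fixed across the
#'   whole curve so the test set never informs elimination).
#' @param family `"lasso"` or `"rf"`.
#' @param tol Relative MAE tolerance for the minimal set (default 0.05).
#' @param seed Seed for fold assignment / forests.
#' @param rf_args Extra arguments for [rf_fit()] on the rf route.
#' @return List with `curve` (`data.table` of k, test MAE/R^2, feature
#'   removed after evaluation), `minimal_k`, `minimal_features`,
#'   `full_mae`.
#' @export
rfe_curve <- function(mat, ages, features, split, family = c("lasso", "rf"),
                      tol = 0.05, seed = 1L, rf_args = list()) {
  family <- match.arg(family)
  features <- intersect(features, rownames(mat))
  stopifnot(length(features) >= 1L, ncol(mat) == length(ages))
  X <- t(mat[features, , drop = FALSE])
  y <- stats::setNames(ages, colnames(mat))
  Xtr <- X[split$train, , drop = FALSE]; Xte <- X[split$test, , drop = FALSE]
  ytr <- y[split$train]; yte <- y[split$test]

  lambda_fix <- NULL
  if (family == "lasso" && length(features) >= 2L) {
    foldid <- make_folds(nrow(Xtr), min(10L, nrow(Xtr)), seed)
    cvf <- glmnet::cv.glmnet(Xtr, ytr, alpha = 1, foldid = foldid,
                             type.measure = "mae")
    lambda_fix <- cvf$lambda.min
  }

  fit_and_rank <- function(feats) {
    Xk <- Xtr[, feats, drop = FALSE]
    if (family == "rf") {
      args <- c(list(X = Xk, y = ytr, seed = seed), rf_args)
      fit <- do.call(rf_fit, args)
      imp <- fit$importance
      pred <- predict(fit, Xte[, feats, drop = FALSE])
    } else if (length(feats) >= 2L) {
      fit <- glmnet::glmnet(Xk, ytr, alpha = 1, lambda = lambda_fix)
      beta <- as.numeric(stats::coef(fit))[-1L]
      imp <- abs(beta) * apply(Xk, 2L, stats::sd)
      names(imp) <- feats
      pred <- as.numeric(stats::predict(fit, Xte[, feats, drop = FALSE]))
    } else {
      df <- data.frame(y = ytr, x = Xk[, 1L])
      fit <- stats::lm(y ~ x, data = df)
      imp <- stats::setNames(abs(stats::coef(fit)[2L]), feats)
      pred <- stats::predict(fit, data.frame(x = Xte[, 1L]))
    }
    list(imp = imp, pred = as.numeric(pred))
  }

  feats <- features
  ks <- integer(); maes <- numeric(); r2s <- numeric(); removed <- character()
  sets <- list()
  while (length(feats) >= 1L) {
    fr <- fit_and_rank(feats)
    ev <- evaluate_clock(yte, fr$pred)
    ks <- c(ks, length(feats)); maes <- c(maes, ev$mae); r2s <- c(r2s, ev$r2)
    sets[[length(sets) + 1L]] <- feats
    if (length(feats) == 1L) { removed <- c(removed, NA_character_); break }
    worst <- names(fr$imp)[order(fr$imp, seq_along(fr$imp))][1L]
    removed <- c(removed, worst)
    feats <- setdiff(feats, worst)
  }
  curve <- data.table::data.table(k = ks, test_mae = maes, test_r2 = r2s,
                                  removed_after = removed)
  full_mae <- maes[1L]
  # reduce while accuracy is uncompromised: the minimal set is the smallest
  # k reached before test MAE first exceeds (1 + tol) x the full model's
  ok <- maes <= (1 + tol) * full_mae
  minimal_idx <- if (all(ok)) length(ks) else max(which(cumsum(!ok) == 0L))
  list(curve = curve, full_mae = full_mae,
       minimal_k = ks[minimal_idx],
       minimal_features = sets[[minimal_idx]])
}

#' Serialize a fitted clock to self-describing JSON
#'
#' @param fit Result of [fit_wsh_rf_clock()] or [fit_region_lasso_clock()].
#' @param path Output path.
#' @export
write_clock_json <- function(fit, path) {
  obj <- if (inherits(fit$model, "wsh_rf")) {
    list(family = "RF", features = fit$features,
         importance = as.list(fit$model$importance),
         hyperparameters = fit$best[c("n_trees", "max_depth", "min_leaf")],
         seed = fit$model$seed, train_samples = fit$split$train,
         cv = fit$cv[c("mae", "r2")], test = fit$test[c("mae", "r2")])
  } else {
    list(family = "LASSO", features = fit$features,
         coefficients = as.list(fit$coefficients[fit$coefficients != 0]),
         intercept = fit$intercept, lambda = fit$lambda,
         n_nonzero = fit$n_nonzero, train_samples = fit$split$train,
         cv = fit$cv[c("mae", "r2")], test = fit$test[c("mae", "r2")])
  }
  obj$hyperparameters <- lapply(obj$hyperparameters, function(v) {
    if (is.numeric(v) && any(is.infinite(v))) "unbounded" else v
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
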