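# pIC50 regression suite: model specifications, train/test splitting,
# grid search inside 5-fold cross-validation, regression and discretized
# classification metrics, perturbation robustness, Taylor statistics.
#
# Engines: ridge -> glmnet; linear_svr -> e1071; extra_trees /
# random_forest -> ranger; xgboost and the leaf-wise (lossguide) gradient
# booster standing behind the "lightgbm" spec -> xgboost. cnn/gnn are
# flag-gated and reported as explicit skips unless enabled.

MODEL_NAMES <- c("ridge", "linear_svr", "extra_trees", "lightgbm",
                 "xgboost", "random_forest", "cnn", "gnn")

DEFAULT_HYPERPARAMS <- list(
  ridge = list(alpha = 1.0, fit_intercept = TRUE, max_iter = 1000),
  linear_svr = list(C = 0.1, epsilon = 0.01, fit_intercept = TRUE,
                    max_iter = 1000),
  extra_trees = list(n_estimators = 200, max_depth = NULL,
                     min_samples_split = 2, min_samples_leaf = 1,
                     max_features = "sqrt"),
  lightgbm = list(learning_rate = 0.05, n_estimators = 300, max_depth = 7,
                  num_leaves = 31, min_child_samples = 20, reg_lambda = 0),
  xgboost = list(learning_rate = 0.1, n_estimators = 200, max_depth = 6,
                 lambda = 1.0, alpha = 0.0, subsample = 0.8),
  random_forest = list(n_estimators = 150, max_depth = NULL,
                       min_samples_split = 2, min_samples_leaf = 1,
                       max_features = "sqrt"),
  cnn = list(num_conv_layers = 2, filters = c(64, 128), kernel_size = 3,
             pooling = "max", learning_rate = 0.001, dropout = 0.3,
             batch_size = 32),
  gnn = list(num_layers = 3, hidden_dim = 128, aggregation = "mean",
             learning_rate = 0.001, dropout = 0.2, batch_size = 64)
)

#' Model specification
#'
#' A named model family with hyperparameters and an optional grid of
#' candidates for grid search. Defaults are the final tuned configurations
#' of the suite (e.g. ridge alpha 1.0, extra_trees 200 trees, xgboost
#' eta 0.1 / 200 rounds / depth 6 / subsample 0.8).
#'
#' @param name One of `"ridge"`, `"linear_svr"`, `"extra_trees"`,
#'   `"lightgbm"`, `"xgboost"`, `"random_forest"`, `"cnn"`, `"gnn"`.
#' @param hyperparams Named list overriding defaults.
#' @param grid Named list of candidate vectors for grid search; by default
#'   each hyperparameter's grid is the single default value.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, hyperparams = list(), grid = list()) {
  name <- match.arg(name, MODEL_NAMES)
  hp <- utils::modifyList(DEFAULT_HYPERPARAMS[[name]], hyperparams)
  structure(list(name = name, hyperparams = hp, grid = grid),
            class = "model_spec")
}

#' Default model suite
#'
#' @param include_neural Also include the optional `cnn`/`gnn` entries
#'   (reported as skipped unless an engine for them is registered).
#' @return Named list of `model_spec`s.
#' @export
default_model_specs <- function(include_neural = FALSE) {
  nm <- c("ridge", "linear_svr", "extra_trees", "lightgbm", "xgboost",
          "random_forest")
  if (include_neural) nm <- c(nm, "cnn", "gnn")
  stats::setNames(lapply(nm, model_spec), nm)
}

#' Reproducible train/test split
#'
#' @param n Number of rows (>= 5).
#' @param test_fraction Fraction held out (0 < f < 1; default 0.2).
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test`, a disjoint
#'   exhaustive partition of `1:n`.
#' @export
split_train_test <- function(n, test_fraction = 0.2, seed = 1L) {
  if (n < 5L) stop("need at least 5 rows to split")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  n_test <- max(1L, round(n * test_fraction))
  if (n_test >= n) stop("degenerate split: empty training set")
  rng <- local_rng(seed)
  test <- sort(rng(sample.int(n, n_test)))
  list(train = setdiff(seq_len(n), test), test = test)
}

# run `expr` under a private RNG state
local_rng <- function(seed) {
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
  }
}

k_folds <- function(n, k = 5L, seed = 1L) {
  rng <- local_rng(seed)
  ix <- rng(sample.int(n))
  fold <- rep(seq_len(k), length.out = n)
  stats::setNames(fold[order(ix)], NULL)
}

record_event <- function(recorder, event, model, rows) {
  if (is.null(recorder)) return(invisible(NULL))
  recorder$log[[length(recorder$log) + 1L]] <-
    list(event = event, model = model, rows = sort(as.integer(rows)))
  invisible(NULL)
}

#' Create a fit/score recorder
#'
#' An instrumentation hook: every engine fit and score call logs the row
#' indices it touched, so tests can assert that grid search never sees the
#' held-out test split.
#'
#' @return An environment with a `log` list.
#' @export
new_recorder <- function() {
  e <- new.env(parent = emptyenv())
  e$log <- list()
  e
}

# --- engines ---------------------------------------------------------------

fit_engine <- function(spec, X, y, seed, rows = seq_len(nrow(X)),
                       recorder = NULL) {
  record_event(recorder, "fit", spec$name, rows)
  hp <- spec$hyperparams
  rng <- local_rng(seed)
  obj <- switch(
    spec$name,
    ridge = {
      lam <- hp$alpha / length(y)
      fit <- rng(glmnet::glmnet(X, y, alpha = 0, lambda = lam,
                                standardize = FALSE,
                                intercept = isTRUE(hp$fit_intercept),
                                maxit = hp$max_iter * 100))
      list(kind = "glmnet", fit = fit, lambda = lam)
    },
    linear_svr = {
      fit <- rng(e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                            cost = hp$C, epsilon = hp$epsilon, scale = FALSE))
      list(kind = "svm", fit = fit)
    },
    extra_trees = {
      fit <- ranger::ranger(
        x = X, y = y, num.trees = hp$n_estimators,
        mtry = max(1L, floor(sqrt(ncol(X)))),
        splitrule = "extratrees", num.random.splits = 1L,
        replace = FALSE, sample.fraction = 1,
        min.node.size = hp$min_samples_split,
        max.depth = if (is.null(hp$max_depth)) 0 else hp$max_depth,
        num.threads = 1L, seed = seed)
      list(kind = "ranger", fit = fit)
    },
    random_forest = {
      fit <- ranger::ranger(
        x = X, y = y, num.trees = hp$n_estimators,
        mtry = max(1L, floor(sqrt(ncol(X)))),
        splitrule = "variance", replace = TRUE,
        min.node.size = hp$min_samples_split,
        max.depth = if (is.null(hp$max_depth)) 0 else hp$max_depth,
        num.threads = 1L, seed = seed)
      list(kind = "ranger", fit = fit)
    },
    lightgbm = {
      # leaf-wise (lossguide) histogram gradient boosting
      params <- list(objective = "reg:squarederror", eta = hp$learning_rate,
                     max_depth = hp$max_depth, max_leaves = hp$num_leaves,
                     grow_policy = "lossguide", tree_method = "hist",
                     lambda = hp$reg_lambda, nthread = 1, seed = seed)
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      fit <- rng(xgboost::xgb.train(params, dtrain, nrounds = hp$n_estimators,
                                    verbose = 0))
      list(kind = "xgb", fit = fit)
    },
    xgboost = {
      params <- list(objective = "reg:squarederror", eta = hp$learning_rate,
                     max_depth = hp$max_depth, subsample = hp$subsample,
                     lambda = hp$lambda, alpha = hp$alpha, nthread = 1,
                     seed = seed)
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      fit <- rng(xgboost::xgb.train(params, dtrain, nrounds = hp$n_estimators,
                                    verbose = 0))
      list(kind = "xgb", fit = fit)
    },
    stop("no engine available for model family '", spec$name, "'")
  )
  structure(c(obj, list(name = spec$name, hyperparams = hp)),
            class = "ligscreen_fit")
}

#' Predict from a fitted suite model
#'
#' @param object A `ligscreen_fit`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.ligscreen_fit <- function(object, newdata, ...) {
  switch(object$kind,
         glmnet = as.numeric(glmnet::predict.glmnet(object$fit, newdata,
                                                    s = object$lambda)),
         svm = as.numeric(stats::predict(object$fit, newdata)),
         ranger = as.numeric(stats::predict(object$fit, data = newdata,
                                            num.threads = 1L)$predictions),
         xgb = as.numeric(stats::predict(object$fit,
                                         xgboost::xgb.DMatrix(newdata))),
         stop("unknown fit kind"))
}

score_engine <- function(fit, X, y, rows, recorder = NULL) {
  record_event(recorder, "score", fit$name, rows)
  p <- predict(fit, X)
  list(pred = p, mae = mean(abs(p - y)), rmse = sqrt(mean((p - y)^2)),
       r2 = r_squared(y, p))
}

r_squared <- function(y, p) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - p)^2) / ss_tot
}

#' Classification metrics on discretized activity
#'
#' Discretizes true and predicted pIC50 at `threshold` (high = pIC50 >
#' threshold) and reports accuracy, precision, recall and F1, with
#' precision/recall taken on the high class. Degenerate cases (no
#' predicted positives, no true positives) are flagged `undefined` rather
#' than propagating NaN.
#'
#' @param y_true,y_pred Equal-length numeric vectors of pIC50 values.
#' @param threshold Discretization threshold (default 7).
#' @return List with `accuracy`, `precision`, `recall`, `f1`,
#'   `precision_defined`, `recall_defined`.
#' @export
classification_metrics <- function(y_true, y_pred, threshold = 7) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0L) {
    stop("y_true and y_pred must be equal-length, non-empty")
  }
  t_hi <- y_true > threshold
  p_hi <- y_pred > threshold
  tp <- sum(t_hi & p_hi); fp <- sum(!t_hi & p_hi)
  fn <- sum(t_hi & !p_hi); tn <- sum(!t_hi & !p_hi)
  acc <- (tp + tn) / length(y_true)
  prec_def <- (tp + fp) > 0
  rec_def <- (tp + fn) > 0
  prec <- if (prec_def) tp / (tp + fp) else NA_real_
  rec <- if (rec_def) tp / (tp + fn) else NA_real_
  f1 <- if (prec_def && rec_def && (prec + rec) > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       precision_defined = prec_def, recall_defined = rec_def)
}

expand_grid_list <- function(defaults, grid) {
  if (!length(grid)) return(list(defaults))
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    utils::modifyList(defaults, as.list(combos[i, , drop = FALSE]))
  })
}

#' Train and evaluate the regression suite
#'
#' Splits the data 80/20 (configurable), fits column standardization on the
#' training split only, runs grid search for each model inside 5-fold
#' cross-validation on the training split, refits the selected
#' configuration on the full training split and scores the held-out test
#' split once. CV classification metrics are computed per fold on that
#' fold's predictions and averaged. Model families without an engine
#' produce explicit `skipped` entries.
#'
#' @param X Feature matrix (unstandardized; standardization is fitted on
#'   the training split).
#' @param y pIC50 vector, `length(y) == nrow(X)`.
#' @param specs List of `model_spec`s (default [default_model_specs()]).
#' @param seed Top-level seed; fanned out deterministically to the
#'   splitter, fold assignment and engines.
#' @param test_fraction Held-out fraction.
#' @param n_folds CV folds (default 5).
#' @param threshold Activity threshold for the binary metrics.
#' @param recorder Optional [new_recorder()] instrumentation hook.
#' @return An `eval_report`.
#' @export
train_and_evaluate <- function(X, y, specs = default_model_specs(), seed = 1L,
                               test_fraction = 0.2, n_folds = 5L,
                               threshold = 7, recorder = NULL) {
  stopifnot(nrow(X) == length(y))
  split <- split_train_test(nrow(X), test_fraction, seed = seed)
  st <- standardize_fit(X[split$train, , drop = FALSE])
  Xtr <- standardize_apply(X[split$train, , drop = FALSE], st)
  Xte <- standardize_apply(X[split$test, , drop = FALSE], st)
  ytr <- y[split$train]; yte <- y[split$test]
  folds <- k_folds(length(ytr), n_folds, seed = seed + 1000L)

  models <- list()
  for (spec in specs) {
    nm <- spec$name
    if (nm %in% c("cnn", "gnn")) {
      models[[nm]] <- list(status = "skipped",
                           reason = "neural engine not enabled")
      next
    }
    combos <- expand_grid_list(spec$hyperparams, spec$grid)
    cv_results <- lapply(combos, function(hp) {
      sp <- structure(list(name = nm, hyperparams = hp, grid = list()),
                      class = "model_spec")
      fold_mae <- fold_r2 <- numeric(n_folds)
      fold_cls <- vector("list", n_folds)
      for (f in seq_len(n_folds)) {
        tr <- which(folds != f); va <- which(folds == f)
        fit <- fit_engine(sp, Xtr[tr, , drop = FALSE], ytr[tr],
                          seed = seed + 10L * f, rows = split$train[tr],
                          recorder = recorder)
        sc <- score_engine(fit, Xtr[va, , drop = FALSE], ytr[va],
                           rows = split$train[va], recorder = recorder)
        fold_mae[f] <- sc$mae; fold_r2[f] <- sc$r2
        fold_cls[[f]] <- classification_metrics(ytr[va], sc$pred, threshold)
      }
      list(hp = hp, cv_mae = mean(fold_mae), cv_r2 = mean(fold_r2),
           cv_cls = average_cls(fold_cls))
    })
    best <- which.min(vapply(cv_results, `[[`, numeric(1), "cv_mae"))
    hp_best <- cv_results[[best]]$hp
    sp_best <- structure(list(name = nm, hyperparams = hp_best, grid = list()),
                         class = "model_spec")
    fit <- fit_engine(sp_best, Xtr, ytr, seed = seed, rows = split$train,
                      recorder = recorder)
    tr_sc <- score_engine(fit, Xtr, ytr, rows = split$train,
                          recorder = recorder)
    te_sc <- score_engine(fit, Xte, yte, rows = split$test,
                          recorder = recorder)
    models[[nm]] <- list(
      status = "ok", hyperparams = hp_best,
      grid_results = lapply(cv_results, function(r) r[c("hp", "cv_mae", "cv_r2")]),
      cv = c(list(mae = cv_results[[best]]$cv_mae,
                  r2 = cv_results[[best]]$cv_r2), cv_results[[best]]$cv_cls),
      train = c(tr_sc[c("mae", "rmse", "r2")],
                classification_metrics(ytr, tr_sc$pred, threshold)),
      test = c(te_sc[c("mae", "rmse", "r2")],
               classification_metrics(yte, te_sc$pred, threshold)),
      predictions = list(train = tr_sc$pred, test = te_sc$pred),
      fit = fit
    )
  }
  structure(
    list(models = models, split = split, folds = folds, seed = seed,
         standardization = st, y = y, threshold = threshold,
         meta = list(
           n = nrow(X), n_folds = n_folds, test_fraction = test_fraction,
           cv_classification = "discretized per fold on fold predictions, then averaged"
         )),
    class = "eval_report")
}

average_cls <- function(cls_list) {
  agg <- function(field) {
    v <- vapply(cls_list, function(x) {
      z <- x[[field]]
      if (is.null(z) || !is.finite(z)) NA_real_ else z
    }, numeric(1))
    mean(v, na.rm = TRUE)
  }
  list(accuracy = agg("accuracy"), precision = agg("precision"),
       recall = agg("recall"), f1 = agg("f1"))
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$meta$n, " (", x$meta$n_folds, "-fold CV, ",
      round(100 * x$meta$test_fraction), "% test)\n", sep = "")
  tab <- metrics_table(x)
  print(tab, digits = 4)
  invisible(x)
}

#' Metrics table for an evaluation report
#'
#' One row per model with train/test MAE and R-squared plus the CV and test
#' classification metrics of the binary high/low task.
#'
#' @param report An `eval_report`.
#' @return A data.frame.
#' @export
metrics_table <- function(report) {
  rows <- lapply(names(report$models), function(nm) {
    m <- report$models[[nm]]
    if (!identical(m$status, "ok")) {
      return(data.frame(model = nm, status = m$status, train_mae = NA,
                        test_mae = NA, train_r2 = NA, test_r2 = NA,
                        cv_accuracy = NA, cv_f1 = NA, test_accuracy = NA,
                        test_f1 = NA))
    }
    data.frame(model = nm, status = "ok",
               train_mae = m$train$mae, test_mae = m$test$mae,
               train_r2 = m$train$r2, test_r2 = m$test$r2,
               cv_accuracy = m$cv$accuracy, cv_f1 = m$cv$f1,
               test_accuracy = m$test$accuracy, test_f1 = m$test$f1)
  })
  do.call(rbind, rows)
}

#' Perturbation robustness analysis
#'
#' Adds zero-mean Gaussian noise with standard deviation `intensity x
#' column-sd` to the evaluation features and tracks MAE and R-squared as
#' the intensity grows. At intensity 0 the curve equals the baseline
#' metrics exactly; every other point averages `repeats` independent noise
#' draws.
#'
#' @param fit A fitted `ligscreen_fit`.
#' @param X Evaluation feature matrix (standardized scale recommended).
#' @param y True pIC50 values.
#' @param intensities Increasing numeric vector starting at 0.
#' @param repeats Noise draws per intensity (default 20).
#' @param seed Seed for the noise draws.
#' @return data.frame with columns `intensity`, `mae`, `r2`.
#' @export
perturbation_analysis <- function(fit, X, y, intensities = c(0, 0.1, 0.25, 0.5, 1),
                                  repeats = 20L, seed = 1L) {
  if (!length(intensities)) stop("empty intensity list")
  if (intensities[1] != 0) stop("intensities must start at 0 (baseline)")
  if (is.unsorted(intensities)) stop("intensities must be increasing")
  col_sd <- apply(X, 2, stats::sd)
  col_sd[!is.finite(col_sd) | col_sd == 0] <- 0
  base <- score_engine(fit, X, y, rows = integer(0))
  rows <- lapply(seq_along(intensities), function(k) {
    s <- intensities[k]
    if (s == 0) {
      return(data.frame(intensity = 0, mae = base$mae, r2 = base$r2))
    }
    maes <- r2s <- numeric(repeats)
    for (r in seq_len(repeats)) {
      rng <- local_rng(seed + 1000L * k + r)
      noise <- rng(matrix(stats::rnorm(length(X), 0, 1), nrow(X), ncol(X)))
      Xp <- X + sweep(noise, 2, s * col_sd, "*")
      sc <- score_engine(fit, Xp, y, rows = integer(0))
      maes[r] <- sc$mae; r2s[r] <- sc$r2
    }
    data.frame(intensity = s, mae = mean(maes), r2 = mean(r2s))
  })
  do.call(rbind, rows)
}

#' Taylor-diagram statistics
#'
#' For each prediction vector: the (population) standard deviation of
#' predictions, the Pearson correlation with the observations, and the
#' centered RMSE. The identity `cRMSE^2 = sd_p^2 + sd_o^2 - 2 sd_p sd_o r`
#' holds exactly.
#'
#' @param y_true Observations (length >= 2, non-constant).
#' @param preds A numeric vector or named list of prediction vectors.
#' @return data.frame with `model`, `sd_pred`, `sd_obs`, `correlation`,
#'   `centered_rmse`.
#' @export
taylor_stats <- function(y_true, preds) {
  if (!is.list(preds)) preds <- list(model = preds)
  n <- length(y_true)
  if (n < 2L) stop("need at least 2 observations")
  sd_p0 <- function(v) sqrt(mean((v - mean(v))^2))
  sd_o <- sd_p0(y_true)
  if (sd_o == 0) stop("zero-variance observations")
  rows <- lapply(names(preds), function(nm) {
    p <- preds[[nm]]
    stopifnot(length(p) == n)
    sd_p <- sd_p0(p)
    r <- if (sd_p == 0) NA_real_ else
      mean((p - mean(p)) * (y_true - mean(y_true))) / (sd_p * sd_o)
    crmse <- sqrt(mean(((p - mean(p)) - (y_true - mean(y_true)))^2))
    data.frame(model = nm, sd_pred = sd_p, sd_obs = sd_o, correlation = r,
               centered_rmse = crmse)
  })
  do.call(rbind, rows)
}
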