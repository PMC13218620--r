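test_that("model specs default to the tuned hyperparameter configurations", {
  specs <- default_model_specs()
  expect_named(specs, c("ridge", "linear_svr", "extra_trees", "lightgbm",
                        "xgboost", "random_forest"))
  expect_equal(specs$ridge$hyperparams$alpha, 1.0)
  expect_equal(specs$linear_svr$hyperparams[c("C", "epsilon")],
               list(C = 0.1, epsilon = 0.01))
  expect_equal(specs$extra_trees$hyperparams$n_estimators, 200)
  expect_equal(specs$lightgbm$hyperparams[c("learning_rate", "n_estimators",
                                            "max_depth", "num_leaves")],
               list(learning_rate = 0.05, n_estimators = 300, max_depth = 7,
                    num_leaves = 31))
  expect_equal(specs$xgboost$hyperparams[c("learning_rate", "n_estimators",
                                           "max_depth", "subsample")],
               list(learning_rate = 0.1, n_estimators = 200, max_depth = 6,
                    subsample = 0.8))
  expect_equal(specs$random_forest$hyperparams$n_estimators, 150)
})

test_that("train/test splitting is a reproducible disjoint partition", {
  s1 <- split_train_test(10, 0.2, seed = 5)
  expect_length(s1$test, 2L)
  expect_length(s1$train, 8L)
  expect_equal(sort(c(s1$train, s1$test)), 1:10)
  expect_identical(s1, split_train_test(10, 0.2, seed = 5))
  expect_false(identical(s1$test, split_train_test(10, 0.2, seed = 6)$test))
  expect_error(split_train_test(3, 0.2), "at least 5")
  expect_error(split_train_test(10, 1.2), "test_fraction")
})

test_that("classification metrics match a hand-computed confusion matrix", {
  # perfect predictions
  y <- c(8, 7.5, 6, 5)
  m <- classification_metrics(y, y)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # true classes 1,1,0,0; predicted 1,0,0,0 -> acc .75, prec 1, rec .5
  y_true <- c(8, 8, 6, 6)
  y_pred <- c(8, 6, 6, 6)
  m2 <- classification_metrics(y_true, y_pred)
  expect_equal(m2$accuracy, 0.75)
  expect_equal(m2$precision, 1)
  expect_equal(m2$recall, 0.5)
  expect_equal(m2$f1, 2 / 3)
  # all-negative degenerate case: flagged, not NaN
  m3 <- classification_metrics(c(5, 6), c(5.5, 6.2))
  expect_equal(m3$accuracy, 1)
  expect_false(m3$precision_defined)
  expect_false(m3$recall_defined)
  expect_true(is.na(m3$precision))
})

test_that("ridge recovers an exactly linear signal", {
  set.seed(11)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- 2 * X[, 3] + 5
  rep_ <- train_and_evaluate(X, y, list(model_spec("ridge")), seed = 1)
  expect_gt(rep_$models$ridge$test$r2, 0.99)
})

test_that("destroying the signal drives extra_trees test R2 toward zero", {
  s <- small_set()
  r2s <- vapply(1:20, function(i) {
    rng <- ligscreen:::local_rng(100 + i)
    y_perm <- rng(sample(s$lig$table$pic50))
    rep_ <- train_and_evaluate(
      s$X, y_perm,
      list(model_spec("extra_trees", list(n_estimators = 100))), seed = i)
    rep_$models$extra_trees$test$r2
  }, numeric(1))
  expect_lt(mean(r2s), 0.2)
  expect_lt(stats::quantile(r2s, 0.9), 0.35)
})

test_that("grid search stays inside the training split (instrumented)", {
  s <- small_set()
  rec <- new_recorder()
  spec <- model_spec("ridge", grid = list(alpha = c(0.1, 1, 10)))
  rep_ <- train_and_evaluate(s$X, s$lig$table$pic50, list(spec), seed = 3,
                             recorder = rec)
  test_rows <- rep_$split$test
  fits <- Filter(function(e) e$event == "fit", rec$log)
  scores <- Filter(function(e) e$event == "score", rec$log)
  # every fit touches training rows only
  for (e in fits) expect_length(intersect(e$rows, test_rows), 0L)
  # the test split is scored exactly once, and only scored
  test_scores <- Filter(function(e) setequal(e$rows, test_rows), scores)
  expect_length(test_scores, 1L)
  for (e in scores) {
    if (!setequal(e$rows, test_rows)) {
      expect_length(intersect(e$rows, test_rows), 0L)
    }
  }
  # grid search evaluated all three candidates and kept the CV-best
  expect_length(rep_$models$ridge$grid_results, 3L)
  cv_maes <- vapply(rep_$models$ridge$grid_results, `[[`, numeric(1), "cv_mae")
  expect_equal(rep_$models$ridge$cv$mae, min(cv_maes))
})

test_that("fold assignment partitions the training set into 5 near-equal folds", {
  s <- small_set()
  rep_ <- train_and_evaluate(s$X, s$lig$table$pic50,
                             list(model_spec("ridge")), seed = 2)
  folds <- rep_$folds
  expect_length(folds, length(rep_$split$train))
  expect_equal(sort(unique(folds)), 1:5)
  expect_lte(diff(range(table(folds))), 1)
})

test_that("cnn/gnn produce explicit skip entries, not silent omission", {
  s <- small_set()
  rep_ <- train_and_evaluate(
    s$X[1:40, ], s$lig$table$pic50[1:40],
    list(model_spec("ridge"), model_spec("cnn"), model_spec("gnn")), seed = 1)
  expect_equal(rep_$models$cnn$status, "skipped")
  expect_equal(rep_$models$gnn$status, "skipped")
  expect_match(rep_$models$cnn$reason, "engine")
  expect_true("cnn" %in% metrics_table(rep_)$model)
})

test_that("perturbation curves equal the baseline at intensity zero and
           degrade with noise", {
  s <- small_set()
  rep_ <- train_and_evaluate(s$X, s$lig$table$pic50,
                             list(model_spec("extra_trees",
                                             list(n_estimators = 100))),
                             seed = 1)
  fit <- rep_$models$extra_trees$fit
  st <- rep_$standardization
  Xte <- standardize_apply(s$X[rep_$split$test, ], st)
  yte <- s$lig$table$pic50[rep_$split$test]
  pa <- perturbation_analysis(fit, Xte, yte, intensities = c(0, 0.25, 1, 10),
                              repeats = 20, seed = 4)
  expect_equal(pa$mae[1], rep_$models$extra_trees$test$mae)
  expect_equal(pa$r2[1], rep_$models$extra_trees$test$r2)
  # MAE non-decreasing in expectation over the 20-repeat means
  expect_true(all(diff(pa$mae) > -0.02))
  # overwhelming noise destroys the signal
  expect_lt(pa$r2[nrow(pa)], pa$r2[1])
  expect_error(perturbation_analysis(fit, Xte, yte, intensities = c(0.5)),
               "start at 0")
  expect_error(perturbation_analysis(fit, Xte, yte, numeric(0)), "empty")
})

test_that("Taylor statistics satisfy the centered-RMSE identity and match
           a direct formula oracle", {
  set.seed(9)
  y <- rnorm(50)
  p <- 0.7 * y + rnorm(50, 0, 0.4)
  ts <- taylor_stats(y, list(m = p))
  # brute-force population formulas
  sdp <- sqrt(mean((p - mean(p))^2)); sdo <- sqrt(mean((y - mean(y))^2))
  r <- mean((p - mean(p)) * (y - mean(y))) / (sdp * sdo)
  expect_equal(ts$sd_pred, sdp, tolerance = 1e-10)
  expect_equal(ts$correlation, r, tolerance = 1e-10)
  expect_equal(ts$centered_rmse^2,
               ts$sd_pred^2 + ts$sd_obs^2 -
                 2 * ts$sd_pred * ts$sd_obs * ts$correlation,
               tolerance = 1e-8)
  # degenerate cases
  tid <- taylor_stats(y, list(m = y))
  expect_equal(tid$correlation, 1)
  expect_equal(tid$centered_rmse, 0)
  tc <- taylor_stats(y, list(m = rep(mean(y), 50)))
  expect_equal(tc$sd_pred, 0)
  expect_error(taylor_stats(rep(1, 10), list(m = rnorm(10))), "zero-variance")
})

test_that("the whole suite runs and respects metric ranges", {
  s <- small_set()
  rep_ <- train_and_evaluate(s$X, s$lig$table$pic50, default_model_specs(),
                             seed = 7)
  tab <- metrics_table(rep_)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$test_r2 <= 1))
  expect_true(all(tab$test_mae >= 0))
  cls <- unlist(tab[, c("cv_accuracy", "cv_f1", "test_accuracy", "test_f1")])
  expect_true(all(cls >= 0 & cls <= 1, na.rm = TRUE))
})
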