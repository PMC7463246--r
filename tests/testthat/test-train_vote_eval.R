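test_that("training fits a separable patch set without touching the backbone", {
  ps <- make_separable_patches(60, seed = 2)
  val <- make_separable_patches(20, seed = 3)
  for (mode in c("fusion1", "fusion2")) {
    model <- tiny_model(mode, seed = 1)
    frozen_before <- serialize(model$backbone, NULL)
    fit <- train(model, ps, val,
                 train_config(epochs = 4, batch_size = 32, seed = 1,
                              early_stopping_patience = 10))
    # frozen-weight conservation, bit exact
    expect_identical(serialize(fit$model$backbone, NULL), frozen_before,
                     info = mode)
    # separable signal: training loss strictly decreases over first epochs
    h <- fit$history
    expect_true(all(diff(h$train_loss[1:3]) < 0), info = mode)
    expect_gt(h$train_acc[nrow(h)], 0.9)
    expect_equal(nrow(h), 4)
  }
})

test_that("training is bit-reproducible under a fixed config seed", {
  ps <- make_separable_patches(30, seed = 5)
  run <- function() {
    model <- tiny_model("fusion2", seed = 7)
    train(model, ps, NULL, train_config(epochs = 2, batch_size = 16,
                                        seed = 9))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
})

test_that("training rejects empty input and mislabeled patches", {
  model <- tiny_model()
  empty <- patch_set(array(0, c(72, 72, 0)), character(), character(),
                     integer(), integer())
  expect_error(train(model, empty), "empty")
})

test_that("majority vote returns the mode with a prefer-tumor tie rule", {
  expect_equal(majority_vote(rep(c("Tumor", "Normal"), c(13, 12))), "Tumor")
  expect_equal(majority_vote(rep("Normal", 25)), "Normal")
  expect_equal(majority_vote(c("Tumor", "Tumor", "Normal", "Normal")),
               "Tumor")
  expect_equal(majority_vote(c("Normal", "Normal", "Tumor", "Tumor"),
                             tie_rule = "first"), "Normal")
  expect_error(majority_vote(character()), "empty")
})

test_that("ROI voting aggregates patch predictions as configured", {
  roi <- make_test_roi("Tumor", 4)
  model <- tiny_model(seed = 2)
  # force an always-Tumor classifier through the output bias
  model$params[["head.out.W"]][] <- 0
  model$params[["head.out.b"]] <- c(-50, 50)
  v <- classify_roi(model, roi, seed = 1)
  expect_s3_class(v, "voting_result")
  expect_equal(v$n, 25L)
  expect_equal(v$vote_fraction_tumor, 1)
  expect_equal(v$predicted_label, "Tumor")
  expect_gt(v$mean_tumor_prob, 0.999)
  # n = 1 equals the single patch's prediction; same seed, same result
  v1 <- classify_roi(model, roi, n = 1, seed = 3)
  expect_equal(v1$vote_fraction_tumor, 1)
  expect_identical(classify_roi(model, roi, seed = 5),
                   classify_roi(model, roi, seed = 5))
})

test_that("ROI tumor score is the mean patch probability", {
  roi <- make_test_roi("Normal", 6)
  model <- tiny_model(seed = 3)
  s <- roi_tumor_score(model, roi, n = 10, seed = 2)
  ps <- sample_patches(roi, 10, size = 72, centralize = TRUE, seed = 2)
  probs <- predict_patch_probs(model, ps)[, "Tumor"]
  expect_equal(s, mean(probs))
  expect_gte(s, min(probs))
  expect_lte(s, max(probs))
})

test_that("metrics follow the confusion-matrix definitions", {
  truth <- rep(c("Normal", "Tumor"), c(5, 5))
  rep_all <- compute_metrics(truth, truth)
  expect_equal(rep_all$accuracy, 1)
  expect_true(all(rep_all$per_class[, c("recall", "precision", "f1")] == 1))
  # hand-checked small case: 4/5 normals, 3/5 tumors correct
  pred <- c("Normal", "Normal", "Normal", "Normal", "Tumor",
            "Tumor", "Tumor", "Tumor", "Normal", "Normal")
  r <- compute_metrics(truth, pred)
  expect_equal(unname(r$confusion), c(4, 1, 2, 3))  # TN FP FN TP
  expect_equal(r$per_class$recall, c(4 / 5, 3 / 5))
  expect_equal(r$per_class$precision, c(4 / 6, 3 / 4))
  expect_equal(r$accuracy, 0.7)
  # never-predicted class has precision and F1 zero, not NaN
  r0 <- compute_metrics(truth, rep("Tumor", 10))
  expect_equal(r0$per_class$precision[1], 0)
  expect_equal(r0$per_class$f1[1], 0)
  expect_error(compute_metrics(truth, pred[-1]), "equal")
})

test_that("ROC/PR sweeps behave at the extremes and on random scores", {
  truth <- rep(c("Normal", "Tumor"), each = 10)
  perfect <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  cv <- roc_pr_curves(truth, perfect)
  expect_equal(cv$auc_roc, 1)
  expect_equal(cv$auc_pr, 1, tolerance = 1e-9)
  flat <- roc_pr_curves(truth, rep(0.5, 20))
  expect_equal(flat$auc_roc, 0.5)
  # chance level on uniform random scores
  set.seed(123)
  n <- 2000
  t2 <- sample(rep(c("Normal", "Tumor"), each = n / 2))
  r2 <- roc_pr_curves(t2, runif(n))
  expect_lt(abs(r2$auc_roc - 0.5), 0.05)
  expect_true(r2$auc_pr >= 0 && r2$auc_pr <= 1)
  # thresholds monotone decreasing along the sweep
  expect_true(all(diff(r2$roc$threshold) <= 0))
  expect_true(all(diff(r2$roc$fpr) >= 0))
  expect_error(roc_pr_curves(rep("Tumor", 5), runif(5)), "single-class")
})

test_that("evaluate_rois produces a coherent report", {
  rois <- make_roi_set(2)
  model <- tiny_model(seed = 2)
  model$params[["head.out.W"]][] <- 0
  model$params[["head.out.b"]] <- c(-50, 50)
  ev <- evaluate_rois(model, rois, n = 5, seed = 1)
  expect_equal(nrow(ev$votes), 4L)
  expect_equal(sum(ev$report$confusion), 4)
  expect_equal(ev$report$per_class$recall[2], 1)  # always-Tumor
  expect_equal(ev$report$accuracy, 0.5)
  expect_identical(evaluate_rois(model, rois, n = 5, seed = 1)$votes,
                   ev$votes)
})
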