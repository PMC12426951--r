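make_toy_manifest <- function(n_per_class = 10) {
  cls <- rep(leaf_classes(), each = n_per_class)
  tibble::tibble(path = sprintf("img_%03d.png", seq_along(cls)),
                 label = factor(cls, levels = leaf_classes()))
}

test_that("stratified folds partition the data with a 10% validation slice", {
  m <- make_toy_manifest(10)  # 30 images, 10 per class
  folds <- make_folds(m, k = 5, seed = 1)
  expect_length(folds, 5)
  tests <- lapply(folds, function(f) f$test$path)
  expect_setequal(unlist(tests), m$path)              # union is everything
  expect_equal(sum(lengths(tests)), 30)               # pairwise disjoint
  for (f in folds) {
    expect_equal(nrow(f$test), 6)
    expect_equal(as.vector(table(f$test$label)), c(2, 2, 2))
    # within one fold: train/val/test partition the manifest
    expect_setequal(c(f$train$path, f$val$path, f$test$path), m$path)
    expect_length(intersect(f$train$path, f$val$path), 0)
    # ~10% of the training portion per class, at least 1: round(0.1 * 8) = 1
    expect_equal(as.vector(table(f$val$label)), c(1, 1, 1))
    expect_equal(nrow(f$train), 21)
  }
  expect_identical(make_folds(m, k = 5, seed = 1), folds)
  expect_false(identical(make_folds(m, k = 5, seed = 2), folds))
  expect_error(make_folds(make_toy_manifest(3), k = 5), "at least k")
})

test_that("metrics: identity, constant-classifier and toy-matrix cases", {
  cls <- leaf_classes()
  truth <- rep(cls, each = 4)
  perfect <- compute_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$confusion, diag(4L, 3),
               ignore_attr = TRUE)

  allone <- compute_metrics(truth, rep(cls[1], 12))
  expect_equal(allone$accuracy, 1 / 3)
  expect_equal(allone$recall, 1 / 3)

  # realise the confusion matrix [[4,1,0],[0,5,0],[0,0,5]]
  truth2 <- rep(cls, each = 5)
  pred2 <- c(rep(cls[1], 4), cls[2], rep(cls[2], 5), rep(cls[3], 5))
  mm <- compute_metrics(truth2, pred2)
  expect_equal(mm$accuracy, 14 / 15)
  expect_equal(mm$confusion["Healthy", "Angular Leaf Spot"], 1)
  expect_equal(sum(mm$confusion), 15)
  expect_error(compute_metrics(truth2, c(pred2[-1], "Mildew")), "outside")
})

test_that("metrics agree with brute-force evaluation on random labels", {
  cls <- leaf_classes()
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- sample(10:100, 1)
      truth <- sample(cls, n, replace = TRUE)
      pred <- sample(cls, n, replace = TRUE)
      if (length(unique(truth)) < 3) next
      m <- compute_metrics(truth, pred)
      expect_equal(m$accuracy, mean(truth == pred))
      prec <- rec <- numeric(3)
      for (i in 1:3) {
        tp <- sum(truth == cls[i] & pred == cls[i])
        prec[i] <- if (sum(pred == cls[i]) > 0) tp / sum(pred == cls[i]) else 0
        rec[i] <- if (sum(truth == cls[i]) > 0) tp / sum(truth == cls[i]) else 0
      }
      expect_equal(m$precision, mean(prec))
      expect_equal(m$recall, mean(rec))
      f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
      expect_equal(m$f1, mean(f1))
      expect_equal(rowSums(m$confusion), table(factor(truth, levels = cls)),
                   ignore_attr = TRUE)
    }
  })
})

test_that("run comparison reproduces the closed-form Welch t-test", {
  a <- c(0.9, 0.91, 0.92)
  b <- c(0.5, 0.51, 0.52)
  res <- compare_runs(a, b)
  # independent closed-form evaluation
  se2 <- stats::var(a) / 3 + stats::var(b) / 3
  t_ref <- (mean(a) - mean(b)) / sqrt(se2)
  df_ref <- se2^2 / ((stats::var(a) / 3)^2 / 2 + (stats::var(b) / 3)^2 / 2)
  p_ref <- 2 * stats::pt(-abs(t_ref), df_ref)
  expect_equal(res$statistic, t_ref, tolerance = 1e-8)
  expect_equal(res$df, df_ref, tolerance = 1e-8)
  expect_equal(res$p_value, p_ref, tolerance = 1e-8)
  expect_lt(res$p_value, 0.001)

  swapped <- compare_runs(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)

  same <- compare_runs(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  degen <- compare_runs(c(1, 1, 1), c(1, 1, 1))
  expect_true(degen$degenerate)
  expect_equal(degen$statistic, 0)
  expect_true(is.na(degen$p_value))
  expect_error(compare_runs(1, c(1, 2)), "at least 2")
})

test_that("cross-validation summarises per-fold metrics coherently", {
  m <- small_dataset()
  cv <- run_cross_validation(m, small_train_config(seed = 6), k = 4)
  expect_length(cv$per_fold, 4)
  expect_equal(cv$mean_accuracy, mean(cv$accuracies))
  expect_true(all(cv$summary$accuracy >= 0 & cv$summary$accuracy <= 1))
  for (f in cv$per_fold) expect_equal(sum(f$confusion), f$n)
})

test_that("block-size ablation deduplicates sizes and stays in range", {
  m <- small_dataset()
  cfg <- train_config(learning_rate = 0.05, epochs = 3, input_side = 64,
                      seed = 7)
  tab <- ablate_block_size(m, c(16, 8, 16), cfg)
  expect_equal(tab$block_size, c(16, 8))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_identical(ablate_block_size(m, c(16, 8), cfg), tab)
  expect_error(ablate_block_size(m, integer(0), cfg), "non-empty")
})
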