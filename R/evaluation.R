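# Stratified k-fold cross-validation, classification metrics, the
# cross-method significance test, and the block-size ablation sweep.

#' Stratified k-fold splits with a held-out validation slice
#'
#' Partitions the manifest into `k` stratified test folds; within each
#' fold's training portion a further stratified `val_fraction` (10% by
#' default) is held out for validation, never augmented and never trained
#' on. Deterministic under `seed`.
#'
#' @param manifest Manifest tibble (`path`, `label`).
#' @param k Number of folds (default 5).
#' @param val_fraction Fraction of each fold's training portion used for
#'   validation (default 0.1; at least one image per class).
#' @param seed Integer seed.
#' @return A list of `k` `fold_split` objects, each with elements `fold`,
#'   `train`, `val`, `test`.
#' @export
make_folds <- function(manifest, k = 5L, val_fraction = 0.1, seed = 1L) {
  if (is.null(manifest) || nrow(manifest) < k) stop("manifest too small for ", k, " folds")
  if (val_fraction <= 0 || val_fraction >= 1) stop("`val_fraction` must be in (0, 1)")
  labs <- as.character(manifest$label)
  counts <- table(labs)
  if (any(counts < k)) {
    stop("every class needs at least k = ", k, " samples; got: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  fold_of <- integer(nrow(manifest))
  withr::with_seed(as.integer(seed), {
    for (cl in names(counts)) {
      idx <- sample(which(labs == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    lapply(seq_len(k), function(f) {
      test_idx <- which(fold_of == f)
      pool_idx <- which(fold_of != f)
      val_idx <- integer(0)
      for (cl in names(counts)) {
        cl_pool <- sample(pool_idx[labs[pool_idx] == cl])
        n_val <- max(1L, round(val_fraction * length(cl_pool)))
        val_idx <- c(val_idx, cl_pool[seq_len(n_val)])
      }
      train_idx <- setdiff(pool_idx, val_idx)
      structure(list(fold = f,
                     train = manifest[sort(train_idx), ],
                     val = manifest[sort(val_idx), ],
                     test = manifest[sort(test_idx), ]),
                class = "fold_split")
    })
  })
}

#' Confusion matrix and macro-averaged classification metrics
#'
#' Rows of the confusion matrix are true classes, columns predictions.
#' Accuracy is the diagonal total over the sample count; precision, recall
#' and F1 are computed per class and macro-averaged (equal class weight —
#' the task's classes are nearly balanced, so macro and weighted averages
#' almost coincide). A class absent from both truth and prediction
#' contributes 0 to the macro averages.
#'
#' @param truth,predicted Equal-length vectors of class labels drawn from
#'   `classes`.
#' @param classes Class vocabulary; defaults to [leaf_classes()].
#' @return An object of class `metrics_report`: list with
#'   `confusion` (matrix), `accuracy`, `precision`, `recall`, `f1`,
#'   `per_class` (tibble), `n`.
#' @export
compute_metrics <- function(truth, predicted, classes = leaf_classes()) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("label vectors differ in length")
  if (length(truth) == 0L) stop("empty label vectors")
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0L) {
    stop("labels outside the class set: ", paste(bad, collapse = ", "))
  }
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  cm <- table(truth = tf, predicted = pf)
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    confusion = cm,
    accuracy = sum(tp) / length(truth),
    precision = mean(prec),
    recall = mean(rec),
    f1 = mean(f1),
    per_class = tibble::tibble(class = classes, precision = unname(prec),
                               recall = unname(rec), f1 = unname(f1),
                               support = unname(rowSums(cm))),
    n = length(truth)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  accuracy=%.4f  precision=%.4f  recall=%.4f  F1=%.4f\n",
              x$n, x$accuracy, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Compare two runs' per-fold accuracies with a Welch two-sample t-test
#'
#' The unequal-variance (Welch) form is used; under equal variances it
#' reaches the same conclusion as the pooled test. When both groups have
#' zero internal variance the statistic is degenerate: the result is
#' flagged and no p-value is reported.
#'
#' @param accuracies_a,accuracies_b Numeric vectors (>= 2 values each),
#'   e.g. per-fold accuracies of two pipelines.
#' @return A list with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   and `degenerate` (logical).
#' @export
compare_runs <- function(accuracies_a, accuracies_b) {
  a <- as.numeric(accuracies_a); b <- as.numeric(accuracies_b)
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per group")
  if (stats::var(a) + stats::var(b) == 0) {
    return(list(statistic = if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf,
                df = NA_real_, p_value = NA_real_,
                mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       degenerate = FALSE)
}

# Train on one fold and score its test set.
run_fold <- function(fold, cfg, enhancement = NULL, augmentation = NULL,
                     backbone = "tiny-test") {
  model <- build_model(3L, backbone)
  model <- fine_tune(model, fold$train, fold$val, cfg,
                     enhancement = enhancement, augmentation = augmentation)
  pred <- predict(model, fold$test)
  list(model = model,
       metrics = compute_metrics(fold$test$label, pred$labels))
}

#' Run k-fold cross-validation of the classification pipeline
#'
#' Trains one model per fold (optionally with block-wise enhancement and/or
#' training-time augmentation) and scores each fold's held-out test set.
#'
#' @param manifest Manifest tibble.
#' @param cfg A [train_config()]; its `seed` also drives the fold split.
#' @param enhancement Optional [enhancement_config()].
#' @param augmentation Optional [augmentation_policy()].
#' @param k Number of folds (default 5).
#' @param backbone Passed to [build_model()].
#' @return List with `per_fold` (list of [compute_metrics()] reports),
#'   `accuracies` (per-fold numeric), `mean_accuracy`, and `summary`
#'   (tibble of per-fold metrics).
#' @export
run_cross_validation <- function(manifest, cfg = train_config(),
                                 enhancement = NULL, augmentation = NULL,
                                 k = 5L, backbone = "tiny-test") {
  folds <- make_folds(manifest, k = k, seed = cfg$seed)
  per_fold <- lapply(folds, function(f) {
    run_fold(f, cfg, enhancement, augmentation, backbone)$metrics
  })
  acc <- vapply(per_fold, function(m) m$accuracy, 0)
  list(per_fold = per_fold,
       accuracies = acc,
       mean_accuracy = mean(acc),
       summary = tibble::tibble(
         fold = seq_len(k),
         accuracy = acc,
         precision = vapply(per_fold, function(m) m$precision, 0),
         recall = vapply(per_fold, function(m) m$recall, 0),
         f1 = vapply(per_fold, function(m) m$f1, 0)))
}

#' Block-size ablation on a single fold
#'
#' Holds the data split, backbone and optimiser fixed (fold 1 of the
#' stratified 5-fold split) and varies only the enhancement block size,
#' reporting test accuracy per size. Non-divisible sizes (e.g. 15 on
#' 224x224) are handled by the enhancer's padding. Duplicate sizes are
#' evaluated once.
#'
#' @param manifest Manifest tibble.
#' @param sizes Integer vector of block sizes to sweep.
#' @param cfg A [train_config()].
#' @param backbone Passed to [build_model()].
#' @return A tibble with columns `block_size` and `accuracy`, one row per
#'   distinct size, in the order first given.
#' @export
ablate_block_size <- function(manifest, sizes, cfg = train_config(),
                              backbone = "tiny-test") {
  if (length(sizes) == 0L) stop("`sizes` must be non-empty")
  sizes <- unique(as.integer(sizes))
  fold <- make_folds(manifest, k = 5L, seed = cfg$seed)[[1L]]
  acc <- vapply(sizes, function(b) {
    run_fold(fold, cfg, enhancement_config(block_size = b),
             backbone = backbone)$metrics$accuracy
  }, 0)
  tibble::tibble(block_size = sizes, accuracy = acc)
}
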