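align_metadata <- function(table, metadata) {
  if (!is.null(metadata$sample_id)) rownames(metadata) <- metadata$sample_id
  missing <- setdiff(rownames(table), rownames(metadata))
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
  metadata[rownames(table), , drop = FALSE]
}

source_factor <- function(x) factor(x, levels = c("farmed", "wild"))

fit_rf <- function(x, y, n_trees, importance = FALSE) {
  randomForest::randomForest(x = x, y = y, ntree = n_trees,
                             importance = importance)
}

rf_wild_prob <- function(model, x) {
  stats::predict(model, x, type = "prob")[, "wild"]
}

#' Stratified train/test splits
#'
#' Within every stratum (batch by default, so each batch appears in both
#' partitions at the requested ratio), `round(train_fraction * n)` samples
#' go to training and the remainder to testing, clamped so both partitions
#' are non-empty per stratum. Splits are seed-reproducible.
#'
#' @param metadata data.frame with `sample_id` plus the stratifying column.
#' @param train_fraction fraction in (0, 1).
#' @param stratify_by metadata column (`"batch"` or `"source"`).
#' @param n_iterations number of independent splits.
#' @param seed integer seed.
#' @return list of length `n_iterations`; each element has `train` and
#'   `test` character vectors of sample ids.
#' @export
split_train_test <- function(metadata, train_fraction = 0.5,
                             stratify_by = "batch", n_iterations = 10L,
                             seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly in (0, 1)")
  if (!is.null(metadata$sample_id)) rownames(metadata) <- metadata$sample_id
  strata <- split(rownames(metadata), metadata[[stratify_by]])
  sizes <- lengths(strata)
  if (any(sizes < 2L))
    stop("stratum with a single sample: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  set.seed(seed)
  lapply(seq_len(n_iterations), function(it) {
    parts <- lapply(strata, function(ids) {
      n_train <- min(max(round(train_fraction * length(ids)), 1L),
                     length(ids) - 1L)
      tr <- sample(ids, n_train)
      list(train = tr, test = setdiff(ids, tr))
    })
    list(train = unlist(lapply(parts, `[[`, "train"), use.names = FALSE),
         test = unlist(lapply(parts, `[[`, "test"), use.names = FALSE))
  })
}

#' ROC curve and AUC from wild-probability scores
#'
#' AUC by the rank (Mann-Whitney) statistic, equivalent to trapezoidal
#' integration of the ROC curve with tied scores handled at rank midpoints.
#'
#' @param scores numeric vector: predicted probability of the positive
#'   class (`wild`).
#' @param labels true labels, two classes.
#' @param positive label treated as positive (default `"wild"`).
#' @return list with `auc` and `curve` (data.frame of fpr, tpr).
#' @export
roc_auc <- function(scores, labels, positive = "wild") {
  labels <- as.character(labels)
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- t(vapply(thresholds, function(t) {
    called <- scores >= t
    c(fpr = sum(called & !pos) / n0, tpr = sum(called & pos) / n1)
  }, numeric(2L)))
  list(auc = auc, curve = as.data.frame(curve))
}

#' Train and evaluate the wild/farmed random-forest classifier
#'
#' Repeated stratified splits; per iteration a random forest (default 5001
#' trees, default mtry) is fit on the training partition and evaluated on
#' the test partition: ROC/AUC from the predicted wild-probability and
#' per-class accuracy at the 0.5 threshold. Importances are out-of-bag
#' permutation importances (mean decrease in accuracy), averaged across
#' iterations. The input table should already be prevalence-filtered
#' (rare OTUs below 20% frequency removed).
#'
#' @param table OTU count matrix (samples x OTUs), prevalence-filtered.
#' @param metadata data.frame with `sample_id`, `source`, `batch`.
#' @param train_fraction fraction of each stratum used for training.
#' @param n_iterations number of split/fit repetitions.
#' @param n_trees trees per forest (default 5001).
#' @param stratify_by stratum column for the split.
#' @param seed integer seed.
#' @return object of class `classifier_report`.
#' @export
train_and_evaluate <- function(table, metadata, train_fraction = 0.5,
                               n_iterations = 10L, n_trees = 5001L,
                               stratify_by = "batch", seed = 1L) {
  validate_otu_table(table)
  md <- align_metadata(table, metadata)
  y_all <- source_factor(md$source)
  splits <- split_train_test(md, train_fraction, stratify_by,
                             n_iterations, seed)
  x_all <- table / rowSums(table)

  auc <- numeric(n_iterations)
  acc <- matrix(NA_real_, n_iterations, 2L,
                dimnames = list(NULL, c("farmed", "wild")))
  imp <- matrix(0, ncol(table), n_iterations,
                dimnames = list(colnames(table), NULL))
  prob_sum <- stats::setNames(numeric(nrow(table)), rownames(table))
  prob_n <- stats::setNames(integer(nrow(table)), rownames(table))

  for (it in seq_len(n_iterations)) {
    tr <- splits[[it]]$train; te <- splits[[it]]$test
    y_tr <- droplevels(y_all[match(tr, rownames(table))])
    if (nlevels(y_tr) < 2L)
      stop("training partition of iteration ", it, " has a single class")
    set.seed(seed + it)
    model <- fit_rf(x_all[tr, , drop = FALSE],
                    source_factor(md[tr, "source"]), n_trees,
                    importance = TRUE)
    p_wild <- rf_wild_prob(model, x_all[te, , drop = FALSE])
    truth <- as.character(md[te, "source"])
    auc[it] <- roc_auc(p_wild, truth)$auc
    pred <- ifelse(p_wild >= 0.5, "wild", "farmed")
    for (cls in c("farmed", "wild"))
      acc[it, cls] <- mean(pred[truth == cls] == cls)
    imp[, it] <- randomForest::importance(model,
                                          type = 1L, scale = FALSE)[, 1L]
    p_true <- ifelse(truth == "wild", p_wild, 1 - p_wild)
    prob_sum[te] <- prob_sum[te] + p_true
    prob_n[te] <- prob_n[te] + 1L
  }

  structure(list(
    scheme = list(train_fraction = train_fraction,
                  stratify_by = stratify_by,
                  n_iterations = n_iterations, seed = seed),
    n_trees = n_trees,
    auc = auc, mean_auc = mean(auc),
    per_class_accuracy = acc,
    mean_per_class_accuracy = colMeans(acc, na.rm = TRUE),
    per_sample_probability = ifelse(prob_n > 0, prob_sum / prob_n, NA_real_),
    importances = rowMeans(imp),
    importance_mode = "oob_permutation"
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "Random-forest source classifier (%d trees, train fraction %.2f, %d iterations)\n",
    x$n_trees, x$scheme$train_fraction, x$scheme$n_iterations))
  cat(sprintf("  mean AUC = %.3f; accuracy farmed = %.3f, wild = %.3f\n",
              x$mean_auc, x$mean_per_class_accuracy["farmed"],
              x$mean_per_class_accuracy["wild"]))
  invisible(x)
}

#' Top discriminative OTUs by mean decrease in accuracy
#'
#' @param report a `classifier_report`.
#' @param k number of OTUs to keep (default 15). Ties are broken by
#'   lexicographic OTU id.
#' @return character vector of OTU ids, best first.
#' @export
select_top_features <- function(report, k = 15L) {
  stopifnot(inherits(report, "classifier_report"))
  imp <- report$importances
  if (k > length(imp))
    stop("k = ", k, " exceeds the ", length(imp), " available OTUs")
  if (k == 0L) return(character())
  ord <- order(-imp, names(imp))
  names(imp)[ord][seq_len(k)]
}

#' Cross-validated error rate versus feature-set size
#'
#' k-fold cross-validation (folds stratified by source): within each
#' training fold, OTUs are ranked by mean decrease in accuracy, and for
#' each candidate size the forest is refit on the top-ranked OTUs and
#' scored on the held-out fold — the ranking is recomputed per fold so no
#' selection information leaks into the validation samples.
#'
#' @param table OTU count matrix.
#' @param metadata data.frame with `source`.
#' @param k_folds number of folds (default 10).
#' @param feature_grid ascending candidate feature-set sizes.
#' @param n_trees trees per forest.
#' @param seed integer seed.
#' @return list with `curve` (data.frame n_features, error_rate) and
#'   `best_n_features` (argmin; smallest size on ties).
#' @export
kfold_feature_curve <- function(table, metadata, k_folds = 10L,
                                feature_grid = c(5L, 10L, 15L, 20L, 30L),
                                n_trees = 501L, seed = 1L) {
  validate_otu_table(table)
  md <- align_metadata(table, metadata)
  n <- nrow(table)
  if (k_folds > n) stop("k_folds exceeds the number of samples")
  if (is.unsorted(feature_grid)) stop("feature_grid must be ascending")
  feature_grid <- pmin(as.integer(feature_grid), ncol(table))
  x_all <- table / rowSums(table)
  y_all <- source_factor(md$source)

  set.seed(seed)
  fold <- stats::setNames(integer(n), rownames(table))
  for (cls in levels(y_all)) {
    idx <- which(y_all == cls)
    fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }

  err <- matrix(NA_real_, k_folds, length(feature_grid))
  for (kf in seq_len(k_folds)) {
    tr <- fold != kf; te <- !tr
    if (nlevels(droplevels(y_all[tr])) < 2L) next
    set.seed(seed + kf)
    ranker <- fit_rf(x_all[tr, , drop = FALSE], y_all[tr], n_trees,
                     importance = TRUE)
    imp <- randomForest::importance(ranker, type = 1L, scale = FALSE)[, 1L]
    ranked <- names(imp)[order(-imp, names(imp))]
    for (gi in seq_along(feature_grid)) {
      feats <- ranked[seq_len(feature_grid[gi])]
      set.seed(seed + 1000L * kf + gi)
      model <- fit_rf(x_all[tr, feats, drop = FALSE], y_all[tr], n_trees)
      pred <- stats::predict(model, x_all[te, feats, drop = FALSE])
      err[kf, gi] <- mean(pred != y_all[te])
    }
  }
  curve <- data.frame(n_features = feature_grid,
                      error_rate = colMeans(err, na.rm = TRUE))
  list(curve = curve,
       best_n_features = curve$n_features[which.min(curve$error_rate)])
}

#' Leave-one-batch-out validation
#'
#' For every batch, forests are repeatedly trained on the remaining
#' batches (using an internal stratified split at `train_fraction`,
#' default 8:2) and scored on the entire held-out batch; the held-out
#' accuracy is averaged over `n_boot` repeats. A batch whose removal
#' leaves a single source in the training data is an error.
#'
#' @param table OTU count matrix.
#' @param metadata data.frame with `source` and `batch`.
#' @param train_fraction internal split fraction (default 0.8).
#' @param n_boot repeats per batch (default 20).
#' @param n_trees trees per forest.
#' @param seed integer seed.
#' @return named numeric vector: mean held-out accuracy per batch.
#' @export
loo_batch_validation <- function(table, metadata, train_fraction = 0.8,
                                 n_boot = 20L, n_trees = 501L, seed = 1L) {
  validate_otu_table(table)
  md <- align_metadata(table, metadata)
  x_all <- table / rowSums(table)
  batches <- sort(unique(md$batch))
  out <- stats::setNames(numeric(length(batches)), batches)
  for (bi in seq_along(batches)) {
    held <- rownames(md)[md$batch == batches[bi]]
    rest <- setdiff(rownames(md), held)
    if (length(unique(md[rest, "source"])) < 2L)
      stop("source entirely contained in held-out batch ", batches[bi])
    accs <- numeric(n_boot)
    splits <- split_train_test(md[rest, , drop = FALSE], train_fraction,
                               "batch", n_boot, seed + bi)
    for (b in seq_len(n_boot)) {
      tr <- splits[[b]]$train
      set.seed(seed + 1000L * bi + b)
      model <- fit_rf(x_all[tr, , drop = FALSE],
                      source_factor(md[tr, "source"]), n_trees)
      pred <- stats::predict(model, x_all[held, , drop = FALSE])
      accs[b] <- mean(as.character(pred) == md[held, "source"])
    }
    out[bi] <- mean(accs)
  }
  out
}

#' Bootstrapped per-sample assignment probability
#'
#' Repeats a per-batch stratified split (default 5:5) `n_boot` times
#' (default 100); in every iteration where a sample lands in the test
#' partition, the model's predicted probability of the sample's true class
#' is recorded. The per-sample mean of those probabilities is returned;
#' samples with mean probability < 0.5 are flagged poorly assigned.
#'
#' @param table OTU count matrix.
#' @param metadata data.frame with `source` and `batch`.
#' @param n_boot bootstrap iterations (default 100).
#' @param train_fraction split fraction per batch (default 0.5).
#' @param n_trees trees per forest.
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `mean_correct_probability`,
#'   `n_test`, `poorly_assigned`.
#' @export
bootstrap_assignment_probability <- function(table, metadata, n_boot = 100L,
                                             train_fraction = 0.5,
                                             n_trees = 501L, seed = 1L) {
  validate_otu_table(table)
  md <- align_metadata(table, metadata)
  x_all <- table / rowSums(table)
  prob_sum <- stats::setNames(numeric(nrow(table)), rownames(table))
  prob_n <- stats::setNames(integer(nrow(table)), rownames(table))
  splits <- split_train_test(md, train_fraction, "batch", n_boot, seed)
  for (b in seq_len(n_boot)) {
    tr <- splits[[b]]$train; te <- splits[[b]]$test
    set.seed(seed + b)
    model <- fit_rf(x_all[tr, , drop = FALSE],
                    source_factor(md[tr, "source"]), n_trees)
    p_wild <- rf_wild_prob(model, x_all[te, , drop = FALSE])
    truth <- md[te, "source"]
    p_true <- ifelse(truth == "wild", p_wild, 1 - p_wild)
    prob_sum[te] <- prob_sum[te] + p_true
    prob_n[te] <- prob_n[te] + 1L
  }
  never <- prob_n == 0L
  if (any(never))
    warning(sum(never), " sample(s) never landed in a test partition")
  mp <- ifelse(never, NaN, prob_sum / pmax(prob_n, 1L))
  data.frame(sample_id = rownames(table),
             mean_correct_probability = mp,
             n_test = as.integer(prob_n),
             poorly_assigned = !is.nan(mp) & mp < 0.5,
             row.names = NULL, stringsAsFactors = FALSE)
}
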