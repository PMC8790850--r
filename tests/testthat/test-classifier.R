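# small separable dataset used across classifier tests
classifier_sim <- function(seed = 1, ...) {
  sim <- simulate_dataset(sim_config(
    n_otus = 80, n_samples_per_batch = 10,
    batches = data.frame(name = c("C", "F", "T", "H"),
                         source = rep(c("wild", "farmed"), each = 2)),
    seed = seed, ...))
  sim$filtered <- prevalence_abundance_filter(sim$table, 0, 0.20)
  sim
}

test_that("stratified splits respect ratios, coverage and determinism", {
  md <- toy_metadata(paste0("s", 1:30),
                     rep(c("wild", "farmed", "farmed"), each = 10),
                     rep(c("C", "T", "H"), each = 10))
  sp <- split_train_test(md, 0.5, "batch", n_iterations = 3, seed = 1)
  for (it in sp) {
    expect_length(intersect(it$train, it$test), 0)
    expect_setequal(c(it$train, it$test), md$sample_id)
    for (b in c("C", "T", "H")) {
      ids <- md$sample_id[md$batch == b]
      expect_equal(sum(it$train %in% ids), 5)
    }
  }
  sp9 <- split_train_test(md, 0.9, "batch", n_iterations = 1, seed = 2)
  expect_equal(sum(sp9[[1]]$train %in% md$sample_id[md$batch == "C"]), 9)
  expect_identical(split_train_test(md, 0.5, "batch", 2, seed = 9),
                   split_train_test(md, 0.5, "batch", 2, seed = 9))
  md1 <- rbind(md, data.frame(sample_id = "x", source = "wild",
                              batch = "Z"))
  expect_error(split_train_test(md1, 0.5), "single sample")
  expect_error(split_train_test(md, 0), "strictly")
})

test_that("AUC equals the pair-counting oracle, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c("wild", "wild", "farmed", "farmed"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6),
                       rep(c("wild", "farmed"), 3))$auc, 0.5)
  # 3-sample case: pairs (0.9 vs 0.8) and (0.3 vs 0.8) -> (1 + 0)/2
  expect_equal(roc_auc(c(0.9, 0.8, 0.3),
                       c("wild", "farmed", "wild"))$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.9), c("wild", "wild")), "both classes")

  # exhaustive equivalence on random inputs with <= 12 samples
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    labels <- sample(c("wild", "farmed"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("wild", "farmed")
    scores <- round(runif(n), 2) # rounding provokes ties
    expect_equal(roc_auc(scores, labels)$auc, bf_auc(scores, labels))
  }
  # ROC curve starts at (0,0), ends at (1,1), is monotone
  rc <- roc_auc(round(runif(10), 1),
                sample(rep(c("wild", "farmed"), 5)))$curve
  expect_equal(unlist(rc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rc[nrow(rc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("the classifier separates strongly selected sources", {
  aucs <- vapply(1:2, function(s) {
    sim <- classifier_sim(s)
    rep <- train_and_evaluate(sim$filtered, sim$metadata,
                              train_fraction = 0.5, n_iterations = 2,
                              n_trees = 201, seed = s)
    rep$mean_auc
  }, numeric(1))
  expect_true(all(aucs >= 0.95))
})

test_that("label permutation collapses AUC to chance", {
  sim <- classifier_sim(4)
  aucs <- vapply(1:10, function(s) {
    md <- sim$metadata
    set.seed(1000 + s)
    md$source <- sample(md$source) # break the batch->source nesting too
    md$batch <- sample(rep(c("C", "F", "T", "H"),
                           length.out = nrow(md)))
    train_and_evaluate(sim$filtered, md, train_fraction = 0.5,
                       n_iterations = 1, n_trees = 201,
                       seed = s)$mean_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("reports carry importances, probabilities and class accuracies", {
  sim <- classifier_sim(2)
  rep <- train_and_evaluate(sim$filtered, sim$metadata, 0.5,
                            n_iterations = 2, n_trees = 201, seed = 2)
  expect_length(rep$importances, ncol(sim$filtered))
  expect_true(all(rep$per_sample_probability >= 0 &
                    rep$per_sample_probability <= 1, na.rm = TRUE))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  expect_named(rep$mean_per_class_accuracy, c("farmed", "wild"))
  expect_identical(rep$importance_mode, "oob_permutation")
})

test_that("top-feature selection orders by importance with lexicographic ties", {
  rep <- structure(list(importances = c(b = 3, a = 3, d = 5, c = 1)),
                   class = "classifier_report")
  expect_identical(select_top_features(rep, 4), c("d", "a", "b", "c"))
  expect_identical(select_top_features(rep, 0), character())
  expect_error(select_top_features(rep, 5), "exceeds")
})

test_that("planted discriminative OTUs rank inside the top importances", {
  # mild batch noise: recovery is a property of the source signal, not of
  # batch-amplified bystanders
  sim <- classifier_sim(6, batch_effect_sd = 0.3)
  rep <- train_and_evaluate(sim$filtered, sim$metadata, 0.5,
                            n_iterations = 5, n_trees = 301, seed = 6)
  planted <- names(sim$truth$role)[sim$truth$role != "neutral"]
  top <- select_top_features(rep, 15)
  expect_true(all(intersect(planted, colnames(sim$filtered)) %in% top))
})

test_that("the cross-validated feature curve is well-formed", {
  sim <- classifier_sim(3)
  res <- kfold_feature_curve(sim$filtered, sim$metadata, k_folds = 4,
                             feature_grid = c(5, 10, 20),
                             n_trees = 151, seed = 3)
  expect_equal(res$curve$n_features, c(5, 10, 20))
  expect_true(all(res$curve$error_rate >= 0 & res$curve$error_rate <= 1))
  expect_true(res$best_n_features %in% res$curve$n_features)
  # with 10 planted informative OTUs the optimum needs few features
  expect_lte(res$best_n_features, 20)
  expect_error(kfold_feature_curve(sim$filtered, sim$metadata,
                                   k_folds = 1000), "exceeds")
})

test_that("leave-one-batch-out flags shifted batches", {
  sim <- classifier_sim(5)
  acc <- loo_batch_validation(sim$filtered, sim$metadata, n_boot = 2,
                              n_trees = 201, seed = 5)
  expect_named(acc, c("C", "F", "H", "T"))
  expect_gte(mean(acc), 0.9) # in-distribution batches are predictable
  # scramble one batch's OTU identities: batch effect >> source effect
  tab2 <- sim$filtered
  w_rows <- sim$metadata$sample_id[sim$metadata$batch == "H"]
  set.seed(1)
  tab2[w_rows, ] <- tab2[w_rows, sample(ncol(tab2))]
  acc2 <- loo_batch_validation(tab2, sim$metadata, n_boot = 2,
                               n_trees = 201, seed = 5)
  expect_lt(acc2["H"], mean(acc2[c("C", "F", "T")]))
  # deterministic under a fixed seed
  expect_identical(acc, loo_batch_validation(sim$filtered, sim$metadata,
                                             n_boot = 2, n_trees = 201,
                                             seed = 5))
})

test_that("bootstrapped assignment probabilities find the odd one out", {
  sim <- classifier_sim(7)
  tab <- sim$filtered
  md <- sim$metadata
  # give one wild sample the exact profile of a farmed sample
  w <- md$sample_id[md$source == "wild"][1]
  f <- md$sample_id[md$source == "farmed"][1]
  tab[w, ] <- tab[f, ]
  res <- bootstrap_assignment_probability(tab, md, n_boot = 20,
                                          n_trees = 201, seed = 7)
  pw <- res$mean_correct_probability[res$sample_id == w]
  expect_lt(pw, 0.5)
  expect_true(res$poorly_assigned[res$sample_id == w])
  others <- res$mean_correct_probability[res$sample_id != w]
  expect_gt(mean(others > 0.5), 0.9)
  # reproducible under the same seed
  res2 <- bootstrap_assignment_probability(tab, md, n_boot = 20,
                                           n_trees = 201, seed = 7)
  expect_identical(res, res2)
})
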