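#!/usr/bin/env Rscript
# Random-forest host-source tracking on the moderate-regime dataset, where
# classification is informative rather than saturated: train-fraction
# sweep, top-15 discriminative OTUs, 10-fold feature curve, and
# leave-one-batch-out validation.

suppressMessages(library(microsource))
dir.create("results", showWarnings = FALSE)

tab <- read_otu_table("results/data/moderate/otu_table.tsv")
md <- read_metadata("results/data/moderate/metadata.tsv")
rare <- rarefy(tab, 10000, seed = 1)
filt <- prevalence_abundance_filter(rare, 0, 0.20)
cat("after rare-OTU filter (<20% prevalence):", ncol(filt), "OTUs\n")

fractions <- c(0.5, 0.6, 0.7, 0.8, 0.9)
sweep <- t(vapply(fractions, function(fr) {
  rep <- train_and_evaluate(filt, md, fr, n_iterations = 10,
                            n_trees = 501, seed = 1)
  c(auc = rep$mean_auc, rep$mean_per_class_accuracy)
}, numeric(3)))
sweep <- data.frame(train_fraction = fractions, sweep)
cat("train-fraction sweep (10 iterations each):\n")
print(sweep, digits = 3)
write.table(sweep, "results/classifier_sweep.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rep5 <- train_and_evaluate(filt, md, 0.5, n_iterations = 10,
                           n_trees = 501, seed = 1)
top <- select_top_features(rep5, 15)
cat("top 15 OTUs by mean decrease in accuracy:\n")
print(top)
write.table(data.frame(otu_id = names(sort(rep5$importances,
                                           decreasing = TRUE)),
                       mean_decrease_accuracy =
                         sort(rep5$importances, decreasing = TRUE)),
            "results/importances.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

curve <- kfold_feature_curve(filt, md, k_folds = 10,
                             feature_grid = c(5, 10, 15, 20, 30, 50),
                             n_trees = 301, seed = 1)
cat("10-fold CV error by feature count (argmin =",
    curve$best_n_features, "):\n")
print(curve$curve, digits = 3)
write.table(curve$curve, "results/feature_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

loo <- loo_batch_validation(filt, md, train_fraction = 0.8, n_boot = 20,
                            n_trees = 301, seed = 1)
cat("leave-one-batch-out accuracy:\n")
print(round(loo, 3))
write.table(data.frame(batch = names(loo), accuracy = loo),
            "results/loo_batch.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
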