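#!/usr/bin/env Rscript
# Phylogenetic null models on the dominance dataset: per-sample NTI and
# per-source betaNTI against taxa-label randomizations, with the
# -2/+2 assembly-process summary. A thinned sample set keeps the pairwise
# betaNTI null affordable at desk scale.

suppressMessages(library(microsource))
dir.create("results", showWarnings = FALSE)

tab <- read_otu_table("results/data/dominance/otu_table.tsv")
md <- read_metadata("results/data/dominance/metadata.tsv")
tree <- read_newick("results/data/dominance/tree.nwk")
rare <- rarefy(tab, 10000, seed = 1)
md <- md[rownames(rare), ]

r_nti <- nti(rare, tree, n_null = 999, seed = 1, threshold = 1e-4)
cat(sprintf("NTI over %d samples: mean = %.2f (positive = clustering)\n",
            length(r_nti$z), mean(r_nti$z, na.rm = TRUE)))
write.table(data.frame(sample_id = names(r_nti$z), nti = r_nti$z),
            "results/nti_per_sample.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

summaries <- list()
for (src in c("wild", "farmed")) {
  sub <- rare[md$source == src, , drop = FALSE][seq(1, 100, by = 4), ]
  bn <- beta_nti(sub, tree, n_null = 499, seed = 1, threshold = 1e-4)
  s <- assembly_summary(bn)
  summaries[[src]] <- s
  cat(sprintf("%s betaNTI (%d pairs): %.1f%% < -2 (homogeneous selection), %.1f%% within, %.1f%% > 2\n",
              src, s$n_scores, 100 * s$frac_below, 100 * s$frac_within,
              100 * s$frac_above))
}
write_report(summaries, "results/betanti_summary.json")
cat("note: with realistic marker-set sizes the within-source betaNTI signal\n",
    "is conservative (see the methods vignette); the strong homogeneous-\n",
    "selection signature needs many turnover-prone taxa in the conserved\n",
    "clade, demonstrated by the constructed contrast in the test suite.\n",
    sep = "")
cat("wrote results/nti_per_sample.tsv, betanti_summary.json\n")
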