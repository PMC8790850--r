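#' Pipeline parameters
#'
#' Bundles every threshold and size the workflow uses, defaulting to the
#' values of the host-source-tracking study design: rarefaction depth
#' 10,000; core-taxon prevalence 0.70; high-abundance cut 1e-3; rare-OTU
#' prevalence filter 0.20; NTI/betaNTI abundance filter 1e-4; 5001 trees;
#' top 15 OTUs; assignment bootstrap n = 100 at 5:5; leave-one-batch-out
#' bootstrap n = 20 at 8:2; 999 permutations/randomizations.
#'
#' @param ... overrides of any default listed above.
#' @return list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(depth = 10000L, core_prevalence = 0.70,
            abundant_threshold = 0.001, rare_prevalence = 0.20,
            nti_threshold = 1e-4, n_trees = 5001L, top_k = 15L,
            train_fractions = c(0.5, 0.6, 0.7, 0.8, 0.9),
            n_iterations = 10L, n_boot_assignment = 100L,
            n_boot_loo = 20L, n_perm = 999L, n_null = 999L,
            feature_grid = c(5L, 10L, 15L, 20L, 30L, 50L),
            ci_level = 0.90, seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(override)] <- override
  stopifnot(all(vapply(p[c("core_prevalence", "abundant_threshold",
                           "rare_prevalence", "nti_threshold")],
                       function(v) v >= 0 && v <= 1, logical(1L))))
  p
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full host-source-tracking workflow
#'
#' Rarefaction; Shannon diversity and Wilcoxon source contrast; Bray-Curtis
#' and (given a tree) weighted UniFrac distances with AMOVA and sequential
#' PERMANOVA variance partitioning (batch first, so a source nested in
#' batch shows no independent contribution); per-source core taxa; Sloan
#' neutral fits per source with envelope categories; NTI and betaNTI with
#' assembly summaries; the random-forest classifier (train-fraction sweep,
#' feature-importance top-k, 10-fold feature curve, leave-one-batch-out,
#' bootstrapped assignment probabilities); and the Fisher-exact linkage of
#' stochastic load to misassignment. Tree-dependent stages are marked
#' `"skipped: no tree"` when no tree is supplied, and the remainder
#' completes. All thresholds used are embedded in the returned bundle.
#'
#' @param table OTU count matrix (samples x OTUs).
#' @param metadata metadata data.frame (`sample_id`, `source`, `batch`,
#'   optionally `season`, `body_weight`).
#' @param tree optional rooted `phylo` over the OTUs.
#' @param params a [pipeline_params] list.
#' @param out_dir optional directory; when given, the JSON bundle and TSV
#'   tables are written there.
#' @return the bundle, a nested list with one element per stage.
#' @export
run_pipeline <- function(table, metadata, tree = NULL,
                         params = pipeline_params(), out_dir = NULL) {
  validate_otu_table(table)
  metadata <- validate_metadata(metadata)
  p <- params
  bundle <- list(params = p)

  rare <- stage("rarefy", rarefy(table, p$depth, seed = p$seed))
  md <- align_metadata(rare, metadata)
  bundle$rarefaction <- list(depth = p$depth,
                             n_samples = nrow(rare),
                             dropped = attr(rare, "dropped_samples"))

  bundle$alpha <- stage("alpha_diversity", {
    h <- shannon(rare)
    wt <- stats::wilcox.test(h[md$source == "wild"],
                             h[md$source == "farmed"])
    list(shannon = h,
         median_by_source = tapply(h, md$source, stats::median),
         wilcoxon_p = wt$p.value)
  })

  bundle$beta <- stage("beta_diversity", {
    bc <- bray_curtis(rare)
    wu <- if (is.null(tree)) "skipped: no tree"
          else weighted_unifrac(rare, tree)
    dm <- if (is.null(tree)) bc else wu
    am <- amova(dm, md$source, n_perm = p$n_perm, seed = p$seed)
    pr <- permanova_r2(dm, md, intersect(c("batch", "source", "season"),
                                         names(md)[vapply(md, function(v)
                                           length(unique(v)) > 1L,
                                           logical(1L))]),
                       n_perm = p$n_perm, seed = p$seed)
    list(bray_curtis = bc, weighted_unifrac = wu,
         amova_source = am, permanova = pr,
         distance_used = if (is.null(tree)) "bray_curtis"
                         else "weighted_unifrac",
         permanova_note = "sequential (order-dependent) sums of squares")
  })

  bundle$core <- stage("core_taxa", {
    lapply(stats::setNames(c("wild", "farmed"), c("wild", "farmed")),
           function(src) core_taxa(rare,
                                   rownames(md)[md$source == src],
                                   p$core_prevalence, src))
  })

  bundle$neutral <- stage("neutral_fit", {
    fits <- lapply(stats::setNames(c("wild", "farmed"), c("wild", "farmed")),
                   function(src)
                     fit_sloan(rare[md$source == src, , drop = FALSE]))
    list(fits = fits,
         categories = lapply(fits, abundant_otu_categories,
                             min_mean_abundance = p$abundant_threshold))
  })

  bundle$phylo <- if (is.null(tree)) "skipped: no tree" else
    stage("phylo_null", {
      nti_res <- nti(rare, tree, n_null = p$n_null, seed = p$seed,
                     threshold = p$nti_threshold)
      res <- list(nti = nti_res, nti_mean = mean(nti_res$z, na.rm = TRUE))
      for (src in c("wild", "farmed")) {
        bn <- beta_nti(rare[md$source == src, , drop = FALSE], tree,
                       n_null = p$n_null, seed = p$seed,
                       threshold = p$nti_threshold)
        res[[paste0("beta_nti_", src)]] <- bn
        res[[paste0("beta_nti_summary_", src)]] <- assembly_summary(bn)
      }
      res
    })

  filtered <- stage("rare_otu_filter",
                    prevalence_abundance_filter(rare, 0, p$rare_prevalence))
  bundle$classifier <- stage("classifier", {
    sweep_reports <- lapply(p$train_fractions, function(fr)
      train_and_evaluate(filtered, md, train_fraction = fr,
                         n_iterations = p$n_iterations,
                         n_trees = p$n_trees, seed = p$seed))
    names(sweep_reports) <- paste0("frac_", p$train_fractions)
    main <- sweep_reports[[1L]]
    top <- select_top_features(main, min(p$top_k, ncol(filtered)))
    curve <- kfold_feature_curve(filtered, md,
                                 k_folds = min(10L, nrow(filtered)),
                                 feature_grid =
                                   p$feature_grid[p$feature_grid <=
                                                    ncol(filtered)],
                                 n_trees = p$n_trees, seed = p$seed)
    loo <- loo_batch_validation(filtered, md, train_fraction = 0.8,
                                n_boot = p$n_boot_loo,
                                n_trees = p$n_trees, seed = p$seed)
    list(sweep = sweep_reports,
         auc_by_fraction = stats::setNames(
           vapply(sweep_reports, `[[`, 0, "mean_auc"),
           paste0("frac_", p$train_fractions)),
         top_features = top, feature_curve = curve,
         loo_batch_accuracy = loo)
  })

  bundle$linkage <- stage("linkage", {
    prob <- bootstrap_assignment_probability(
      filtered, md, n_boot = p$n_boot_assignment, train_fraction = 0.5,
      n_trees = p$n_trees, seed = p$seed)
    linkage_test(rare, md, bundle$neutral$fits, prob, level = p$ci_level)
  })

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write the pipeline bundle to disk
#'
#' One JSON bundle plus the TSV side-tables (distance matrices, per-OTU
#' neutral tables, per-sample probabilities and loads).
#'
#' @param bundle result of [run_pipeline].
#' @param out_dir output directory.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slim <- bundle
  if (inherits(slim$beta$bray_curtis, "dist")) {
    write_distance_matrix(slim$beta$bray_curtis,
                          file.path(out_dir, "bray_curtis.tsv"))
    slim$beta$bray_curtis <- "written: bray_curtis.tsv"
  }
  if (inherits(slim$beta$weighted_unifrac, "dist")) {
    write_distance_matrix(slim$beta$weighted_unifrac,
                          file.path(out_dir, "weighted_unifrac.tsv"))
    slim$beta$weighted_unifrac <- "written: weighted_unifrac.tsv"
  }
  if (is.list(slim$neutral)) {
    for (src in names(slim$neutral$fits)) {
      write_neutral_fit_table(
        slim$neutral$fits[[src]],
        file.path(out_dir, paste0("neutral_fit_", src, ".tsv")))
      slim$neutral$fits[[src]]$otu <-
        paste0("written: neutral_fit_", src, ".tsv")
    }
  }
  if (is.list(slim$linkage)) {
    utils::write.table(slim$linkage$per_sample,
                       file.path(out_dir, "linkage_per_sample.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (is.list(slim$phylo)) {
    for (nm in names(slim$phylo))
      if (inherits(slim$phylo[[nm]], "null_model_result")) {
        slim$phylo[[nm]] <- list(
          statistic = slim$phylo[[nm]]$statistic_name,
          z = as.vector(slim$phylo[[nm]]$z),
          n_null = slim$phylo[[nm]]$n_null,
          seed = slim$phylo[[nm]]$seed)
      }
  }
  write_report(slim, file.path(out_dir, "bundle.json"))
  invisible(out_dir)
}
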