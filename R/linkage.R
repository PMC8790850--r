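#' Per-sample load of a neutral-fit OTU category
#'
#' Sum of a sample's relative abundance over the OTUs a neutral fit placed
#' in the given category (within / below / above the prediction envelope).
#' OTUs present in the table but absent from the fit (zero mean abundance
#' in the fit's group) contribute zero and are counted in a warning.
#'
#' @param table OTU count matrix.
#' @param fit a `neutral_fit` computed on the relevant sample group.
#' @param category `"within"`, `"below"` or `"above"`.
#' @return named numeric vector of per-sample load fractions.
#' @export
sample_category_load <- function(table, fit,
                                 category = c("within", "below", "above")) {
  category <- match.arg(category)
  stopifnot(inherits(fit, "neutral_fit"))
  validate_otu_table(table)
  missing <- setdiff(colnames(table), fit$otu$otu_id)
  if (length(missing))
    warning(length(missing),
            " OTU(s) absent from the neutral fit contribute zero load")
  cat_otus <- fit$otu$otu_id[fit$otu$category == category]
  rel <- table / rowSums(table)
  keep <- intersect(colnames(table), cat_otus)
  if (!length(keep))
    return(stats::setNames(numeric(nrow(table)), rownames(table)))
  rowSums(rel[, keep, drop = FALSE])
}

#' Upper boundary of the load confidence interval
#'
#' Normal-approximation upper bound of the two-sided interval at the given
#' level: mean + z_\{(1 + level)/2\} * sd. The empirical quantile at the
#' same upper tail is reported alongside as an alternative, so the choice
#' of construction is auditable.
#'
#' @param loads numeric vector of per-sample loads.
#' @param level two-sided interval level (default 0.90).
#' @return list with `boundary` (normal), `empirical` (quantile), `level`.
#' @export
ci_upper_boundary <- function(loads, level = 0.90) {
  loads <- loads[!is.na(loads)]
  if (length(loads) < 3L) stop("need at least 3 loads")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  s <- stats::sd(loads)
  upper_tail <- (1 + level) / 2
  if (s == 0) {
    warning("zero variance in loads; boundary equals the mean")
    b <- mean(loads)
  } else {
    b <- mean(loads) + stats::qnorm(upper_tail) * s
  }
  list(boundary = b,
       empirical = unname(stats::quantile(loads, upper_tail, type = 7L)),
       level = level)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability method (summing the
#' hypergeometric probabilities of all tables, conditional on the margins,
#' that are no more probable than the observed one), with the conditional
#' maximum-likelihood odds ratio — the construction of
#' [stats::fisher.test], to which this delegates.
#'
#' @param table2x2 2x2 matrix of non-negative integers.
#' @return list with `p_two_sided` and `odds_ratio` (may be 0 or Inf).
#' @export
fisher_exact <- function(table2x2) {
  m <- as.matrix(table2x2)
  if (!all(dim(m) == 2L)) stop("need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("cells must be non-negative integers")
  if (sum(m) == 0) stop("all-zero table")
  ft <- stats::fisher.test(m)
  list(p_two_sided = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Link stochastic OTU load to classifier misassignment
#'
#' For every sample, the accumulated relative abundance of neutral
#' ("within") and below-prediction OTUs is computed against the neutral fit
#' of the sample's own source group; samples above the upper boundary of
#' the 90% confidence interval of that load are cross-tabulated against
#' poorly assigned samples (bootstrapped mean correct-class probability
#' < 0.5) and tested with Fisher's exact test. Because published practice
#' is ambiguous about whether the neutral and below-prediction loads are
#' pooled or tested separately, the combined load (default) and both
#' single-category tests are all reported.
#'
#' @param table OTU count matrix.
#' @param metadata data.frame with `source`.
#' @param fit_by_source named list `list(wild = , farmed = )` of
#'   `neutral_fit` objects.
#' @param probabilities data.frame from
#'   [bootstrap_assignment_probability].
#' @param level confidence level for the load boundary (default 0.90).
#' @return object of class `linkage_result`: per-sample table, the 2x2
#'   contingency table, `fisher_p`, `odds_ratio`, the boundary used, and
#'   the per-category auxiliary tests.
#' @export
linkage_test <- function(table, metadata, fit_by_source, probabilities,
                         level = 0.90) {
  validate_otu_table(table)
  md <- align_metadata(table, metadata)
  stopifnot(all(c("wild", "farmed") %in% names(fit_by_source)))
  ids <- rownames(table)

  load_cat <- function(category) {
    out <- stats::setNames(numeric(length(ids)), ids)
    for (src in c("wild", "farmed")) {
      sel <- ids[md$source == src]
      if (!length(sel)) next
      out[sel] <- suppressWarnings(
        sample_category_load(table[sel, , drop = FALSE],
                             fit_by_source[[src]], category))
    }
    out
  }
  neutral_load <- load_cat("within")
  below_load <- load_cat("below")
  combined <- neutral_load + below_load

  prob <- probabilities$mean_correct_probability[
    match(ids, probabilities$sample_id)]
  if (anyNA(prob)) {
    warning(sum(is.na(prob)), " sample(s) without an assignment ",
            "probability excluded from the linkage test")
    keep <- !is.na(prob)
    ids <- ids[keep]
    md <- md[keep, , drop = FALSE]
    table <- table[keep, , drop = FALSE]
    prob <- prob[keep]
    neutral_load <- neutral_load[keep]
    below_load <- below_load[keep]
    combined <- combined[keep]
  }
  poorly <- prob < 0.5

  one_test <- function(loads) {
    ci <- ci_upper_boundary(loads, level)
    above <- loads > ci$boundary
    tab <- table(factor(above, c(TRUE, FALSE)),
                 factor(poorly, c(TRUE, FALSE)))
    dimnames(tab) <- list(load = c("above_boundary", "within_boundary"),
                          assignment = c("poor", "good"))
    empty_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    ft <- if (empty_margin) list(p_two_sided = 1, odds_ratio = NA_real_)
          else fisher_exact(tab)
    list(boundary = ci$boundary, empirical_boundary = ci$empirical,
         above = above, contingency = unclass(tab),
         fisher_p = ft$p_two_sided, odds_ratio = ft$odds_ratio,
         empty_margin = empty_margin)
  }

  main <- one_test(combined)
  structure(list(
    per_sample = data.frame(
      sample_id = ids, source = md$source,
      neutral_load = unname(neutral_load),
      below_load = unname(below_load),
      combined_load = unname(combined),
      mean_correct_probability = prob,
      poorly_assigned = poorly,
      above_ci_boundary = unname(main$above),
      row.names = NULL, stringsAsFactors = FALSE),
    ci_boundary = main$boundary,
    ci_boundary_empirical = main$empirical_boundary,
    ci_level = level,
    contingency = main$contingency,
    fisher_p = main$fisher_p,
    odds_ratio = main$odds_ratio,
    empty_margin = main$empty_margin,
    by_category = list(neutral = one_test(neutral_load)[
                         c("boundary", "contingency", "fisher_p",
                           "odds_ratio", "empty_margin")],
                       below = one_test(below_load)[
                         c("boundary", "contingency", "fisher_p",
                           "odds_ratio", "empty_margin")])
  ), class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("Stochastic-load vs misassignment linkage\n")
  cat(sprintf("  combined load boundary = %.4f (%.0f%% CI, normal approx)\n",
              x$ci_boundary, 100 * x$ci_level))
  print(x$contingency)
  cat(sprintf("  Fisher two-sided p = %.4g, odds ratio = %.3g\n",
              x$fisher_p, x$odds_ratio))
  invisible(x)
}
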