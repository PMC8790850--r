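#' Rarefy an OTU table to a common depth
#'
#' Subsamples each sample's reads without replacement (one multivariate
#' hypergeometric draw per sample) so that every retained sample has exactly
#' `depth` reads. Samples with fewer reads than `depth` are dropped with a
#' warning listing them, matching the normalization used in mothur-style
#' 16S workflows.
#'
#' @param table OTU count matrix (samples x OTUs).
#' @param depth target reads per sample.
#' @param seed integer seed controlling the subsampling.
#' @return rarefied OTU matrix; dropped samples are recorded in
#'   `attr(, "dropped_samples")`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  validate_otu_table(table)
  if (length(depth) != 1L || !is.finite(depth) || depth < 1)
    stop("depth must be a positive integer")
  depth <- as.integer(depth)
  totals <- rowSums(table)
  drop <- totals < depth
  if (all(drop)) stop("no sample reaches depth ", depth)
  if (any(drop))
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(rownames(table)[drop], collapse = ", "))
  kept <- table[!drop, , drop = FALSE]
  set.seed(seed)
  out <- t(apply(kept, 1L, function(v) {
    n <- sum(v)
    if (n == depth) return(v)
    reads <- sample.int(n, depth)
    # map sampled read indices back to OTUs through cumulative counts
    tabulate(findInterval(reads, cumsum(v) - v + 1L), nbins = length(v))
  }))
  dimnames(out) <- dimnames(kept)
  storage.mode(out) <- "integer"
  attr(out, "dropped_samples") <- rownames(table)[drop]
  out
}

#' Shannon diversity per sample
#'
#' H = -sum p_i log p_i over nonzero proportions, natural log.
#'
#' @param table OTU count matrix (samples x OTUs).
#' @return named numeric vector, one entry per sample.
#' @export
shannon <- function(table) {
  validate_otu_table(table)
  apply(table, 1L, function(v) {
    p <- v[v > 0] / sum(v)
    -sum(p * log(p))
  })
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param table OTU count matrix.
#' @param use_relative convert rows to relative abundances first (default
#'   TRUE), giving values in \[0, 1\].
#' @return a `dist` object.
#' @export
bray_curtis <- function(table, use_relative = TRUE) {
  validate_otu_table(table)
  if (nrow(table) < 2L) stop("need at least 2 samples")
  x <- if (use_relative) table / rowSums(table) else table
  vegan::vegdist(x, method = "bray")
}

#' Weighted UniFrac distance matrix
#'
#' For every branch of the rooted tree, the absolute difference between the
#' fractions of the two samples' reads descending from that branch is
#' accumulated, weighted by branch length. The normalized variant (default)
#' divides by the same sum taken over the branch-wise totals, bounding the
#' distance in \[0, 1\].
#'
#' OTUs in the table that are not tips of the tree are dropped with a
#' warning; a sample left without reads after pruning is an error.
#'
#' @param table OTU count matrix (samples x OTUs).
#' @param tree rooted `phylo` with branch lengths over the OTU tips.
#' @param normalized divide by the branch-length-weighted total mass.
#' @return a `dist` object over samples.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  validate_otu_table(table)
  missing_otus <- setdiff(colnames(table), tree$tip.label)
  if (length(missing_otus)) {
    warning(length(missing_otus),
            " OTU(s) absent from tree dropped: ",
            paste(utils::head(missing_otus, 5L), collapse = ", "),
            if (length(missing_otus) > 5L) ", ...")
    table <- table[, setdiff(colnames(table), missing_otus), drop = FALSE]
    empty <- rowSums(table) == 0
    if (any(empty))
      stop("sample(s) left empty after pruning to tree tips: ",
           paste(rownames(table)[empty], collapse = ", "))
  }
  keep <- intersect(tree$tip.label, colnames(table))
  if (length(setdiff(tree$tip.label, keep)))
    tree <- ape::keep.tip(tree, keep)
  p <- table[, tree$tip.label, drop = FALSE] / rowSums(table)

  # postorder accumulation: W[node, sample] = fraction of reads below node
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  W <- matrix(0, n_node, nrow(table))
  W[seq_len(n_tip), ] <- t(p)
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (i in seq_len(nrow(edge)))
    W[edge[i, 1L], ] <- W[edge[i, 1L], ] + W[edge[i, 2L], ]
  A <- W[tree$edge[, 2L], , drop = FALSE] # per-branch descendant mass
  len <- tree$edge.length

  n <- nrow(table)
  d <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    num <- sum(len * abs(A[, i] - A[, j]))
    d[i, j] <- d[j, i] <- if (normalized) {
      den <- sum(len * (A[, i] + A[, j]))
      if (den == 0) 0 else num / den
    } else num
  }
  stats::as.dist(d)
}

#' AMOVA on a distance matrix
#'
#' Excoffier-style analysis of molecular variance: the total sum of squared
#' pairwise distances is partitioned into among- and within-group
#' components, and the F-like ratio is tested by permuting group labels.
#' The p-value uses the (count + 1)/(n_perm + 1) estimator.
#'
#' @param dm `dist` or square symmetric matrix.
#' @param grouping factor-like vector of group labels, one per sample, in
#'   the order of the distance matrix.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list with `Fs`, `p`, `ss_among`, `ss_within`, `df`.
#' @export
amova <- function(dm, grouping, n_perm = 999L, seed = 1L) {
  d2 <- as.matrix(dm)^2
  n <- nrow(d2)
  grouping <- as.character(grouping)
  if (length(grouping) != n)
    stop("grouping length does not match distance matrix")
  sizes <- table(grouping)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))

  amova_stat <- function(g) {
    ssw <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    sst <- sum(d2) / (2 * n)
    a <- length(unique(g))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }

  f_obs <- amova_stat(grouping)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm))
    if (amova_stat(sample(grouping)) >= f_obs) count <- count + 1L

  a <- length(sizes)
  ssw <- 0
  for (lev in names(sizes)) {
    idx <- which(grouping == lev)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  sst <- sum(d2) / (2 * n)
  list(Fs = f_obs, p = (count + 1L) / (n_perm + 1L),
       ss_among = sst - ssw, ss_within = ssw,
       df = c(among = a - 1L, within = n - a))
}

#' Sequential PERMANOVA variance partitioning
#'
#' Partitions the total sum of squares of a distance matrix among an ordered
#' list of metadata factors (sequential sums of squares, so term order
#' matters: a factor nested inside an earlier term explains nothing further).
#' Delegates to [vegan::adonis2]. Terms with zero degrees of freedom after
#' earlier terms are reported as non-estimable rather than raising.
#'
#' @param dm `dist` over samples.
#' @param metadata data.frame with one row per sample (rownames = sample
#'   ids, or a `sample_id` column), in any order.
#' @param terms character vector of metadata column names, in fitting order.
#' @param n_perm permutations for per-term p-values.
#' @param seed integer seed.
#' @return data.frame with one row per term plus `Residual`, columns `term`,
#'   `df`, `R2`, `p`, `estimable`.
#' @export
permanova_r2 <- function(dm, metadata, terms, n_perm = 999L, seed = 1L) {
  ids <- attr(dm, "Labels")
  if (is.null(ids)) ids <- rownames(as.matrix(dm))
  if (!is.null(metadata$sample_id)) rownames(metadata) <- metadata$sample_id
  if (!all(ids %in% rownames(metadata)))
    stop("metadata missing sample(s): ",
         paste(setdiff(ids, rownames(metadata)), collapse = ", "))
  md <- metadata[ids, , drop = FALSE]
  for (tm in terms) {
    md[[tm]] <- factor(md[[tm]])
    if (nlevels(md[[tm]]) < 2L)
      stop("term '", tm, "' has fewer than 2 levels among analyzed samples")
  }
  fml <- stats::as.formula(paste("dm ~", paste(terms, collapse = " + ")))
  set.seed(seed)
  fit <- vegan::adonis2(fml, data = md, permutations = n_perm, by = "terms")
  res <- data.frame(term = rownames(fit), df = fit$Df, R2 = fit$R2,
                    p = fit[["Pr(>F)"]], row.names = NULL,
                    stringsAsFactors = FALSE)
  res <- res[res$term != "Total", , drop = FALSE]
  res$estimable <- res$df > 0L
  res$R2[!res$estimable] <- 0
  # terms fully aliased by earlier ones are dropped by adonis2; report them
  # as non-estimable (zero independent contribution) instead
  gone <- setdiff(terms, res$term)
  if (length(gone)) {
    res <- rbind(res[res$term != "Residual", , drop = FALSE],
                 data.frame(term = gone, df = 0L, R2 = 0, p = NA_real_,
                            estimable = FALSE, stringsAsFactors = FALSE),
                 res[res$term == "Residual", , drop = FALSE])
    rownames(res) <- NULL
  }
  res
}

#' Core taxa of a sample group
#'
#' An OTU is core when its detection frequency (fraction of the group's
#' samples with a nonzero count) strictly exceeds the prevalence threshold
#' (default 0.70). The result carries each core OTU's detection frequency
#' and median relative abundance within the group.
#'
#' @param table OTU count matrix.
#' @param group character vector of sample ids defining the group (default:
#'   all samples).
#' @param prevalence_threshold strict lower bound on detection frequency.
#' @param group_label label stored in the result.
#' @return list with `group_label`, `prevalence_threshold`, `core_otu_ids`,
#'   `detection_frequency`, `median_rel_abundance` (the latter two named
#'   over all OTUs).
#' @export
core_taxa <- function(table, group = rownames(table),
                      prevalence_threshold = 0.70, group_label = "group") {
  validate_otu_table(table)
  if (!length(group)) stop("group is empty")
  if (!all(group %in% rownames(table)))
    stop("unknown sample(s) in group: ",
         paste(setdiff(group, rownames(table)), collapse = ", "))
  sub <- table[group, , drop = FALSE]
  freq <- colMeans(sub > 0)
  rel <- sub / rowSums(sub)
  med <- apply(rel, 2L, stats::median)
  core <- colnames(sub)[freq > prevalence_threshold]
  list(group_label = group_label,
       prevalence_threshold = prevalence_threshold,
       core_otu_ids = core,
       detection_frequency = freq,
       median_rel_abundance = med)
}

#' Filter OTUs on mean relative abundance and prevalence
#'
#' Retains OTUs whose mean relative abundance strictly exceeds
#' `min_mean_abundance` and whose prevalence (fraction of samples with a
#' nonzero count) strictly exceeds `min_prevalence`. Either threshold may be
#' 0 to disable it.
#'
#' @param table OTU count matrix.
#' @param min_mean_abundance fraction in \[0, 1\].
#' @param min_prevalence fraction in \[0, 1\].
#' @return filtered OTU matrix.
#' @export
prevalence_abundance_filter <- function(table, min_mean_abundance = 0,
                                        min_prevalence = 0) {
  validate_otu_table(table)
  if (min_mean_abundance < 0 || min_mean_abundance > 1 ||
      min_prevalence < 0 || min_prevalence > 1)
    stop("thresholds must lie in [0, 1]")
  rel <- table / rowSums(table)
  keep <- (min_mean_abundance == 0 | colMeans(rel) > min_mean_abundance) &
          (min_prevalence == 0 | colMeans(table > 0) > min_prevalence)
  if (!any(keep))
    stop("all OTUs removed by the filter; relax the thresholds")
  table[, keep, drop = FALSE]
}

#' 16S rRNA gene copies per ng of genomic DNA
#'
#' Analytic expectation for a bacterium of the given genome size carrying
#' the given number of 16S operons, assuming 650 g/mol per base pair of
#' double-stranded DNA. For a 4 Mbp genome with four copies this is about
#' 9.2e5 copies per ng, the yardstick against which measured gut bacterial
#' loads are judged low.
#'
#' @param genome_size_bp genome size in base pairs.
#' @param copies_per_genome 16S copies per genome.
#' @return copies of the 16S gene per ng of DNA.
#' @export
gene_copies_per_ng <- function(genome_size_bp, copies_per_genome) {
  if (genome_size_bp < 1 || copies_per_genome < 1)
    stop("both arguments must be >= 1")
  avogadro <- 6.02214076e23
  genome_mass_ng <- genome_size_bp * 650 / avogadro * 1e9
  copies_per_genome / genome_mass_ng
}

#' Wilcoxon rank-sum group contrasts with BH correction
#'
#' Thin utility for per-OTU two-group comparisons of relative abundance
#' (Wilcoxon rank-sum, Benjamini-Hochberg FDR), the standard annotation for
#' differential-taxon panels.
#'
#' @param table OTU count matrix.
#' @param grouping two-level vector over samples (order of `table` rows).
#' @return data.frame with `otu_id`, `p`, `p_adj`, `median_a`, `median_b`.
#' @export
group_contrasts <- function(table, grouping) {
  validate_otu_table(table)
  g <- factor(grouping)
  if (nlevels(g) != 2L) stop("grouping must have exactly 2 levels")
  rel <- table / rowSums(table)
  p <- apply(rel, 2L, function(v)
    suppressWarnings(stats::wilcox.test(v[g == levels(g)[1L]],
                                        v[g == levels(g)[2L]]))$p.value)
  data.frame(otu_id = colnames(table), p = p,
             p_adj = stats::p.adjust(p, "BH"),
             median_a = apply(rel[g == levels(g)[1L], , drop = FALSE], 2L,
                              stats::median),
             median_b = apply(rel[g == levels(g)[2L], , drop = FALSE], 2L,
                              stats::median),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Principal coordinates of a distance matrix
#'
#' Classical MDS (PCoA) ordination surface for distance matrices, with the
#' fraction of (positive) eigenvariance per axis.
#'
#' @param dm `dist` object.
#' @param k number of axes.
#' @return list with `points` (samples x k) and `eig_fraction`.
#' @export
pcoa_ordination <- function(dm, k = 2L) {
  fit <- stats::cmdscale(dm, k = k, eig = TRUE)
  pos <- fit$eig[fit$eig > 0]
  list(points = fit$points, eig_fraction = fit$eig[seq_len(k)] / sum(pos))
}
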