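#' Mean nearest taxon distance of one community
#'
#' For every taxon present in the sample, the patristic distance to its
#' nearest phylogenetic neighbour also present in the sample; the MNTD is
#' the (optionally abundance-weighted) mean of those nearest distances.
#'
#' @param abundance named abundance vector over taxa (names = tip labels).
#' @param tree rooted `phylo`, or a precomputed patristic distance matrix.
#' @param weighted weight each taxon's nearest distance by its relative
#'   abundance (default TRUE, the convention used throughout).
#' @return MNTD, a single number.
#' @export
mntd <- function(abundance, tree, weighted = TRUE) {
  D <- if (is.matrix(tree)) tree else patristic_distances(tree)
  present <- names(abundance)[abundance > 0]
  if (length(present) < 2L)
    stop("MNTD requires at least 2 taxa present in the sample")
  if (!all(present %in% rownames(D)))
    stop("taxa absent from tree: ",
         paste(setdiff(present, rownames(D)), collapse = ", "))
  sub <- D[present, present, drop = FALSE]
  diag(sub) <- Inf
  nn <- apply(sub, 1L, min)
  if (weighted) {
    w <- abundance[present]
    sum(nn * w) / sum(w)
  } else mean(nn)
}

#' Between-sample mean nearest taxon distance
#'
#' Average of the two directed nearest-taxon distances: each taxon of one
#' sample is matched to its nearest neighbour in the other sample, weighted
#' by relative abundance.
#'
#' @inheritParams mntd
#' @param abundance_a,abundance_b named abundance vectors over taxa.
#' @return betaMNTD, a single number.
#' @export
beta_mntd <- function(abundance_a, abundance_b, tree, weighted = TRUE) {
  D <- if (is.matrix(tree)) tree else patristic_distances(tree)
  pa <- names(abundance_a)[abundance_a > 0]
  pb <- names(abundance_b)[abundance_b > 0]
  if (!length(pa) || !length(pb)) stop("both samples must contain taxa")
  sub <- D[pa, pb, drop = FALSE]
  nn_a <- apply(sub, 1L, min)
  nn_b <- apply(sub, 2L, min)
  if (weighted) {
    wa <- abundance_a[pa] / sum(abundance_a[pa])
    wb <- abundance_b[pb] / sum(abundance_b[pb])
    (sum(nn_a * wa) + sum(nn_b * wb)) / 2
  } else (mean(nn_a) + mean(nn_b)) / 2
}

#' Patristic (tip-to-tip) distance matrix of a tree
#'
#' Computed once per tree; quadratic in the number of tips, fine at desk
#' scale.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @return symmetric matrix over tip labels.
#' @export
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}

# row minima of a (strictly positive-diagonal-masked) matrix via max.col,
# which is C-optimized; used in the null loops where apply(x, 1, min) is
# too slow
row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

prepare_null_input <- function(table, tree, threshold) {
  validate_otu_table(table)
  rel <- table / rowSums(table)
  keep <- colnames(table)[colMeans(rel) > threshold]
  dropped_tree <- setdiff(keep, tree$tip.label)
  if (length(dropped_tree)) {
    warning(length(dropped_tree), " filtered OTU(s) absent from tree dropped")
    keep <- setdiff(keep, dropped_tree)
  }
  if (length(keep) < 3L)
    stop("fewer than 3 OTUs pass the abundance threshold ", threshold)
  keep <- sort(keep) # canonical taxon order: nulls invariant to column order
  D <- patristic_distances(ape::keep.tip(tree, keep))[keep, keep]
  list(rel = rel[, keep, drop = FALSE], D = D, taxa = keep)
}

#' Nearest taxon index against taxa-label nulls
#'
#' Per-sample z-score of the abundance-weighted MNTD against a null in
#' which taxa labels are shuffled across the patristic distance matrix
#' (`taxa.labels` null, one shuffle per null iteration shared by all
#' samples). Sign convention: NTI = -z(MNTD), so phylogenetic clustering
#' (co-occurring taxa more related than chance) gives positive NTI.
#' OTUs are first filtered to mean relative abundance > `threshold`
#' (default 1e-4, i.e. 0.01%).
#'
#' @param table OTU count matrix.
#' @param tree rooted `phylo` over the OTUs.
#' @param n_null number of label randomizations (default 999).
#' @param seed integer seed.
#' @param threshold strict mean-relative-abundance filter.
#' @param weighted abundance-weighted MNTD (default TRUE).
#' @return object of class `null_model_result` with per-sample `z`
#'   (= NTI), `observed`, `null_mean`, `null_sd`.
#' @export
nti <- function(table, tree, n_null = 999L, seed = 1L, threshold = 1e-4,
                weighted = TRUE) {
  if (n_null < 30L)
    warning("n_null = ", n_null, " gives a noisy null; 999 is the default")
  inp <- prepare_null_input(table, tree, threshold)
  S <- length(inp$taxa)
  samples <- rownames(inp$rel)

  # precompute per-sample presence indices and weights once; nulls then
  # only re-index the distance matrix (taxa-label shuffle)
  present <- lapply(samples, function(s) which(inp$rel[s, ] > 0))
  wts <- lapply(seq_along(samples), function(i) {
    w <- inp$rel[i, present[[i]]]
    w / sum(w)
  })
  big <- max(inp$D) * 2 + 1
  sample_mntd <- function(perm) {
    vapply(seq_along(samples), function(i) {
      idx <- perm[present[[i]]]
      if (length(idx) < 2L) return(NA_real_)
      sub <- inp$D[idx, idx, drop = FALSE]
      diag(sub) <- big
      nn <- row_mins(sub)
      if (weighted) sum(nn * wts[[i]]) else mean(nn)
    }, numeric(1L))
  }
  obs <- stats::setNames(sample_mntd(seq_len(S)), samples)
  if (anyNA(obs))
    warning(sum(is.na(obs)), " sample(s) with < 2 filtered taxa: NTI is NA")

  set.seed(seed)
  null_mat <- matrix(NA_real_, n_null, length(samples),
                     dimnames = list(NULL, samples))
  for (b in seq_len(n_null))
    null_mat[b, ] <- sample_mntd(sample.int(S))
  null_mean <- colMeans(null_mat)
  null_sd <- apply(null_mat, 2L, stats::sd)
  degenerate <- !is.na(null_sd) & null_sd < 1e-12
  if (any(degenerate))
    warning("null standard deviation ~0 for ", sum(degenerate),
            " sample(s); z reported as 0 (no deviation) or NaN")
  z <- -(obs - null_mean) / ifelse(degenerate, NaN, null_sd)
  # observed identical to a constant null: no deviation, not undefined
  z[degenerate & !is.na(obs) & abs(obs - null_mean) < 1e-12] <- 0

  structure(list(statistic_name = "NTI", observed = obs,
                 null_mean = null_mean, null_sd = null_sd, z = z,
                 n_null = n_null, seed = seed, abundance_weighted = weighted,
                 otu_abundance_threshold = threshold, n_taxa = S),
            class = "null_model_result")
}

#' Beta nearest taxon index against taxa-label nulls
#'
#' Per-pair z-score of the abundance-weighted betaMNTD under the same
#' taxa-label null as [nti]. betaNTI = +z, so betaNTI < -2 indicates
#' homogeneous selection, betaNTI > 2 variable selection, and |betaNTI| <= 2
#' a stochastic pattern (closed interval: ties at the thresholds count as
#' stochastic).
#'
#' Because betaNTI is pairwise while published summaries are often
#' per-sample, the result also carries two per-sample reductions: the
#' fraction of a sample's pairs in each class, and the sample's majority
#' class.
#'
#' @inheritParams nti
#' @return object of class `null_model_result` with `z` a `dist` over
#'   samples, plus `pair_fractions` and per-sample summaries.
#' @export
beta_nti <- function(table, tree, n_null = 999L, seed = 1L, threshold = 1e-4,
                     weighted = TRUE) {
  if (nrow(table) < 2L) stop("betaNTI needs at least 2 samples")
  if (n_null < 30L)
    warning("n_null = ", n_null, " gives a noisy null; 999 is the default")
  inp <- prepare_null_input(table, tree, threshold)
  S <- length(inp$taxa)
  samples <- rownames(inp$rel)
  n <- length(samples)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)

  present <- lapply(seq_len(n), function(i) which(inp$rel[i, ] > 0))
  wts <- lapply(seq_len(n), function(i) {
    w <- inp$rel[i, present[[i]]]
    w / sum(w)
  })
  pair_bmntd <- function(perm) {
    vapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      sub <- inp$D[perm[present[[i]]], perm[present[[j]]], drop = FALSE]
      nn_i <- row_mins(sub)
      nn_j <- row_mins(t(sub))
      if (weighted) (sum(nn_i * wts[[i]]) + sum(nn_j * wts[[j]])) / 2
      else (mean(nn_i) + mean(nn_j)) / 2
    }, numeric(1L))
  }
  obs <- pair_bmntd(seq_len(S))

  set.seed(seed)
  null_mat <- matrix(NA_real_, n_null, nrow(pairs))
  for (b in seq_len(n_null))
    null_mat[b, ] <- pair_bmntd(sample.int(S))
  null_mean <- colMeans(null_mat)
  null_sd <- apply(null_mat, 2L, stats::sd)
  degenerate <- null_sd < 1e-12
  if (any(degenerate))
    warning("null standard deviation ~0 for ", sum(degenerate), " pair(s)")
  z <- (obs - null_mean) / ifelse(degenerate, NaN, null_sd)
  z[degenerate & abs(obs - null_mean) < 1e-12] <- 0

  zm <- matrix(0, n, n, dimnames = list(samples, samples))
  zm[cbind(pairs[, 1L], pairs[, 2L])] <- z
  zm <- zm + t(zm)
  per_sample <- t(vapply(samples, function(s) {
    zi <- zm[s, setdiff(samples, s)]
    zi <- zi[!is.nan(zi)]
    c(frac_below = mean(zi < -2), frac_within = mean(abs(zi) <= 2),
      frac_above = mean(zi > 2))
  }, numeric(3L)))
  majority <- colnames(per_sample)[max.col(per_sample, ties.method = "first")]

  structure(list(statistic_name = "betaNTI", observed = obs,
                 null_mean = null_mean, null_sd = null_sd,
                 z = stats::as.dist(zm), z_matrix = zm,
                 per_sample_fractions = per_sample,
                 per_sample_majority = stats::setNames(majority, samples),
                 n_null = n_null, seed = seed, abundance_weighted = weighted,
                 otu_abundance_threshold = threshold, n_taxa = S),
            class = "null_model_result")
}

#' Assembly-process summary of a null-model result
#'
#' Fractions of z-scores below -2 (homogeneous selection), within \[-2, 2\]
#' (stochastic), and above +2 (variable selection). Thresholds are closed
#' on the stochastic side; NaN z-scores are excluded and counted.
#'
#' @param result a `null_model_result`.
#' @return list with the three fractions (summing to 1), `n_scores`,
#'   `n_nan`.
#' @export
assembly_summary <- function(result) {
  stopifnot(inherits(result, "null_model_result"))
  z <- as.vector(result$z)
  nan <- sum(is.na(z) | is.nan(z))
  z <- z[!(is.na(z) | is.nan(z))]
  if (!length(z)) stop("all z-scores are NaN")
  list(frac_below = mean(z < -2),
       frac_within = mean(abs(z) <= 2),
       frac_above = mean(z > 2),
       n_scores = length(z), n_nan = nan)
}

#' @export
print.null_model_result <- function(x, ...) {
  z <- as.vector(x$z)
  cat(sprintf("%s over %d taxa, %d nulls (seed %d)\n", x$statistic_name,
              x$n_taxa, x$n_null, x$seed))
  cat(sprintf("  mean z = %.3f, sd = %.3f, n = %d\n",
              mean(z, na.rm = TRUE), stats::sd(z, na.rm = TRUE),
              sum(!is.na(z))))
  invisible(x)
}
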