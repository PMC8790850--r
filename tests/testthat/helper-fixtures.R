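# Fixtures and independent oracles shared across the suite.

# small OTU matrix with names
otu_mat <- function(x, samples = paste0("s", seq_len(nrow(x))),
                    otus = paste0("OTU", seq_len(ncol(x)))) {
  m <- as.matrix(x)
  dimnames(m) <- list(samples, otus)
  storage.mode(m) <- "integer"
  m
}

# two-clade tree with uniform (star) clades: clade A tight, clade B deep.
# A uniform background keeps the taxa-label null tight, so phylogenetic
# clustering inside A is unambiguous.
star_two_clade_tree <- function(n_a, n_b, a_len = 0.01, b_len = 1) {
  labs <- sprintf("OTU_%04d", seq_len(n_a + n_b))
  a <- labs[seq_len(n_a)]
  b <- labs[n_a + seq_len(n_b)]
  nw_a <- paste0("(", paste0(a, ":", a_len, collapse = ","), "):1")
  nw_b <- paste0("(", paste0(b, ":", b_len, collapse = ","), "):1")
  tree <- ape::read.tree(text = paste0("(", nw_a, ",", nw_b, ");"))
  list(tree = tree, clade_a = a, clade_b = b)
}

# communities confined to the tight clade (with a reference sample covering
# the background so the taxa pool spans both clades)
clade_confined_fixture <- function(seed, n_a = 10, n_b = 90, n_samples = 6,
                                   n_present = 8) {
  set.seed(seed)
  fx <- star_two_clade_tree(n_a, n_b)
  tab <- matrix(0L, n_samples, n_a + n_b,
                dimnames = list(paste0("s", seq_len(n_samples)),
                                fx$tree$tip.label))
  for (i in seq_len(n_samples)) {
    present <- sample(fx$clade_a, n_present)
    tab[i, present] <- stats::rpois(n_present, 50) + 1L
  }
  tab <- rbind(tab, ref = 0L)
  tab["ref", fx$clade_b] <- 5L
  storage.mode(tab) <- "integer"
  c(fx, list(table = tab, focal = paste0("s", seq_len(n_samples))))
}

# strongly selected, phylogenetically conserved communities: samples draw
# many (turnover-prone) taxa of the tight clade; neutral samples draw from
# the whole pool
selected_vs_neutral_fixture <- function(seed, n_a = 40, n_b = 160,
                                        n_samples = 10, n_present_a = 25) {
  set.seed(seed)
  fx <- star_two_clade_tree(n_a, n_b)
  labs <- fx$tree$tip.label
  one <- function(pool, n_present, lambda) {
    v <- stats::setNames(integer(length(labs)), labs)
    present <- sample(pool, n_present)
    v[present] <- stats::rpois(n_present, lambda) + 1L
    v
  }
  sel <- t(vapply(seq_len(n_samples), function(i)
    one(fx$clade_a, n_present_a, 50) + one(fx$clade_b, 5, 3),
    integer(length(labs))))
  neu <- t(vapply(seq_len(n_samples), function(i) one(labs, 30, 20),
                  integer(length(labs))))
  rownames(sel) <- paste0("sel", seq_len(n_samples))
  rownames(neu) <- paste0("neu", seq_len(n_samples))
  storage.mode(sel) <- "integer"
  storage.mode(neu) <- "integer"
  c(fx, list(selected = sel, neutral = neu))
}

## -------- independent oracles --------

# weighted UniFrac by naive recursive branch enumeration
bf_weighted_unifrac <- function(tab, tree, normalized = TRUE) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  desc <- function(node) {
    if (node <= n_tip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  p <- tab / rowSums(tab)
  n <- nrow(tab)
  d <- matrix(0, n, n, dimnames = list(rownames(tab), rownames(tab)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    num <- 0; den <- 0
    for (e in seq_len(nrow(tree$edge))) {
      dd <- tips[desc(tree$edge[e, 2])]
      a <- sum(p[i, dd]); b <- sum(p[j, dd])
      num <- num + tree$edge.length[e] * abs(a - b)
      den <- den + tree$edge.length[e] * (a + b)
    }
    d[i, j] <- d[j, i] <- if (normalized) {
      if (den == 0) 0 else num / den
    } else num
  }
  stats::as.dist(d)
}

# MNTD by exhaustive pairwise loops over the cophenetic matrix
bf_mntd <- function(abundance, tree, weighted = TRUE) {
  D <- stats::cophenetic(tree)
  present <- names(abundance)[abundance > 0]
  nn <- numeric(length(present))
  for (k in seq_along(present)) {
    ds <- vapply(setdiff(present, present[k]),
                 function(o) D[present[k], o], numeric(1))
    nn[k] <- min(ds)
  }
  if (weighted) sum(nn * abundance[present]) / sum(abundance[present])
  else mean(nn)
}

# AUC by concordant/discordant pair counting
bf_auc <- function(scores, labels, positive = "wild") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  total <- 0
  for (i in pos) for (j in neg)
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  total / (length(pos) * length(neg))
}

# two-sided Fisher p by full hypergeometric enumeration over the support
bf_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact conditional null distribution of the Fisher p-value given margins,
# for the randomized probability integral transform
fisher_p_pit <- function(m, u_draw) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  pvals <- vapply(support, function(k)
    sum(probs[probs <= stats::dhyper(k, r1, r2, c1) * (1 + 1e-7)]),
    numeric(1))
  p_obs <- bf_fisher_p(m)
  less <- sum(probs[pvals < p_obs - 1e-12])
  eq <- sum(probs[abs(pvals - p_obs) <= 1e-12])
  less + u_draw * eq
}

# small two-source metadata for a sample set split into batches
toy_metadata <- function(samples, sources, batches) {
  data.frame(sample_id = samples, source = sources, batch = batches,
             stringsAsFactors = FALSE)
}
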