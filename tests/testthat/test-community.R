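test_that("rarefaction hits the exact depth and drops shallow samples", {
  tab <- otu_mat(rbind(c(9000L, 6000L), c(5000L, 5000L), c(5000L, 4999L)))
  expect_warning(r <- rarefy(tab, 10000, seed = 1), "s3")
  expect_identical(unname(rowSums(r)), c(10000, 10000))
  expect_identical(attr(r, "dropped_samples"), "s3")
  # a sample already at depth is returned unchanged
  expect_identical(r["s2", ], tab["s2", ])
  expect_error(rarefy(tab, 0), "positive")
})

test_that("rarefaction is an unbiased subsample of the input proportions", {
  v <- otu_mat(matrix(c(300L, 200L, 100L), 1))
  draws <- vapply(seq_len(1000), function(s)
    rarefy(v, 60, seed = s)[1, ], integer(3))
  prop <- rowMeans(draws) / 60
  # multivariate hypergeometric mean = input proportions; 3 SE band
  se <- sqrt(prop * (1 - prop) / (60 * 1000))
  expect_true(all(abs(prop - c(0.5, 1 / 3, 1 / 6)) < 3 * se + 1e-9))
  # without replacement: no OTU can exceed its own count
  expect_true(all(draws <= c(300, 200, 100)))
})

test_that("Shannon diversity matches closed forms and direct summation", {
  tab <- otu_mat(rbind(c(5L, 5L, 5L, 5L), c(20L, 0L, 0L, 0L),
                       c(10L, 10L, 20L, 0L)))
  h <- shannon(tab)
  expect_equal(unname(h[1]), log(4))
  expect_equal(unname(h[2]), 0)
  p <- c(10, 10, 20) / 40
  expect_equal(unname(h[3]), -sum(p * log(p)))
  # bounds and permutation invariance in OTU order
  set.seed(1)
  tab2 <- otu_mat(matrix(rpois(60, 5) + 1L, 6))
  expect_true(all(shannon(tab2) >= 0 & shannon(tab2) <= log(ncol(tab2))))
  perm <- sample(ncol(tab2))
  expect_equal(shannon(tab2[, perm]), shannon(tab2))
})

test_that("Bray-Curtis has the textbook values on corner cases", {
  tab <- otu_mat(rbind(c(3L, 9L), c(3L, 9L), c(12L, 0L)))
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["s1", "s2"], 0)
  tab2 <- otu_mat(rbind(c(5L, 0L), c(0L, 7L)))
  expect_equal(as.vector(bray_curtis(tab2)), 1)
  # relative abundances [1,3]/4 vs [3,1]/4 -> (|.5|+|.5|)/2 = 0.5
  tab3 <- otu_mat(rbind(c(1L, 3L), c(3L, 1L)))
  expect_equal(as.vector(bray_curtis(tab3, use_relative = TRUE)), 0.5)
})

test_that("weighted UniFrac equals branch enumeration on all small trees", {
  # hand cases
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tab <- otu_mat(rbind(c(10L, 0L, 0L, 0L), c(0L, 0L, 10L, 0L)),
                 otus = c("A", "B", "C", "D"))
  expect_equal(as.vector(weighted_unifrac(tab, tr4)),
               as.vector(bf_weighted_unifrac(tab, tr4)))
  # identical samples -> 0; fully disjoint on a star tree -> 1
  twin <- tab[c(1, 1), ]
  rownames(twin) <- c("a", "b")
  expect_equal(as.vector(weighted_unifrac(twin, tr4)), 0)
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(as.vector(weighted_unifrac(tab, star)), 1)

  # exhaustive small-case oracle: random trees with 3..6 tips
  for (n in 3:6) for (rep in 1:3) {
    set.seed(100 * n + rep)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    tb <- otu_mat(matrix(rpois(3 * n, 4), 3), otus = tr$tip.label)
    tb[rowSums(tb) == 0, 1] <- 1L
    for (norm in c(TRUE, FALSE))
      expect_equal(as.matrix(weighted_unifrac(tb, tr, normalized = norm)),
                   as.matrix(bf_weighted_unifrac(tb, tr, normalized = norm)),
                   tolerance = 1e-12)
  }
})

test_that("weighted UniFrac prunes missing OTUs and flags emptied samples", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  tab <- otu_mat(rbind(c(5L, 5L, 3L), c(1L, 1L, 8L)),
                 otus = c("A", "B", "X"))
  expect_warning(d <- weighted_unifrac(tab, tr), "absent from tree")
  expect_equal(attr(d, "Size"), 2L)
  tab2 <- otu_mat(rbind(c(5L, 5L, 3L), c(0L, 0L, 8L)),
                  otus = c("A", "B", "X"))
  expect_error(suppressWarnings(weighted_unifrac(tab2, tr)), "empty")
})

test_that("AMOVA separates distant groups and respects exchangeability", {
  set.seed(7)
  x <- rbind(matrix(rnorm(40), 8), matrix(rnorm(40, mean = 8), 8))
  rownames(x) <- paste0("s", 1:16)
  d <- dist(x)
  g <- rep(c("a", "b"), each = 8)
  res <- amova(d, g, n_perm = 199, seed = 1)
  expect_equal(res$p, 1 / 200)
  expect_gt(res$Fs, 10)
  # permuting input labels together with rows leaves F invariant
  perm <- sample(16)
  res2 <- amova(as.dist(as.matrix(d)[perm, perm]), g[perm],
                n_perm = 199, seed = 1)
  expect_equal(res2$Fs, res$Fs)
  expect_error(amova(d, c(rep("a", 15), "b")), "fewer than 2")
  expect_error(amova(d, rep("a", 16)), "at least 2 groups")
})

test_that("sequential PERMANOVA partitions sum to one and detect nesting", {
  sim <- simulate_dataset(sim_config(
    n_otus = 80, n_samples_per_batch = 6,
    batches = data.frame(name = c("C", "F", "T", "H"),
                         source = rep(c("wild", "farmed"), each = 2)),
    seed = 5))
  d <- bray_curtis(sim$table)
  res <- permanova_r2(d, sim$metadata, c("batch", "source"),
                      n_perm = 99, seed = 1)
  expect_equal(sum(res$R2), 1, tolerance = 1e-9)
  # source is nested in batch: no independent contribution after batch
  src <- res[res$term == "source", ]
  expect_false(src$estimable)
  expect_equal(src$R2, 0)
  # source first is estimable and positive
  res2 <- permanova_r2(d, sim$metadata, c("source", "batch"),
                       n_perm = 99, seed = 1)
  expect_true(res2$R2[res2$term == "source"] > 0)
  expect_equal(sum(res2$R2), 1, tolerance = 1e-9)
})

test_that("PERMANOVA R2 of an unrelated factor matches its exchangeable mean", {
  # factor independent of the data: E[R2] = (g - 1)/(n - 1)
  n <- 24; g <- 3
  r2 <- vapply(1:60, function(s) {
    set.seed(s)
    x <- matrix(rnorm(n * 5), n)
    rownames(x) <- paste0("s", 1:n)
    md <- data.frame(sample_id = rownames(x),
                     fac = sample(rep(letters[1:g], n / g)))
    permanova_r2(dist(x), md, "fac", n_perm = 19, seed = s)$R2[1]
  }, numeric(1))
  expected <- (g - 1) / (n - 1)
  expect_lt(abs(mean(r2) - expected), 3 * sd(r2) / sqrt(length(r2)))
})

test_that("core taxa use a strict prevalence threshold", {
  tab <- otu_mat(rbind(c(1L, 1L, 4L), c(2L, 0L, 4L), c(3L, 1L, 4L)))
  res <- core_taxa(tab, prevalence_threshold = 0.70)
  expect_true("OTU1" %in% res$core_otu_ids) # 3/3
  expect_false("OTU2" %in% res$core_otu_ids) # 2/3 < 0.7? 0.667 no
  # exactly 7/10 under strict ">" is NOT core
  tab2 <- otu_mat(cbind(c(rep(1L, 7), 0L, 0L, 0L), rep(2L, 10)))
  res2 <- core_taxa(tab2, prevalence_threshold = 0.70)
  expect_false("OTU1" %in% res2$core_otu_ids)
  expect_true("OTU2" %in% res2$core_otu_ids)
  expect_equal(unname(res2$detection_frequency["OTU1"]), 0.7)
})

test_that("batches with disjoint dominants share no core taxa", {
  # four batches, each dominated by its own OTU block
  blocks <- lapply(0:3, function(b) {
    m <- matrix(0L, 5, 20)
    m[, b * 5 + seq_len(5)] <- matrix(rpois(25, 30) + 1L, 5)
    m
  })
  tab <- otu_mat(do.call(rbind, blocks),
                 samples = paste0("s", 1:20))
  cores <- lapply(0:3, function(b)
    core_taxa(tab, paste0("s", b * 5 + seq_len(5)), 0.70)$core_otu_ids)
  expect_length(Reduce(intersect, cores), 0)
  expect_true(all(lengths(cores) > 0))
})

test_that("prevalence/abundance filter applies strict thresholds", {
  set.seed(3)
  # 24 OTUs clearly passing (0.002, 0.20), 10 clearly failing
  good <- matrix(rpois(10 * 24, 40) + 10L, 10)
  bad <- matrix(0L, 10, 10)
  bad[1, ] <- 1L # prevalence 0.1, abundance tiny
  tab <- otu_mat(cbind(good, bad))
  kept <- prevalence_abundance_filter(tab, 0.002, 0.20)
  expect_identical(colnames(kept), paste0("OTU", 1:24))
  expect_identical(prevalence_abundance_filter(tab, 0, 0), tab)
  # boundary: prevalence exactly 0.20 removed under strict ">"
  tab2 <- otu_mat(cbind(rep(10L, 10), c(rep(5L, 2), rep(0L, 8))))
  expect_identical(colnames(prevalence_abundance_filter(tab2, 0, 0.20)),
                   "OTU1")
  expect_error(prevalence_abundance_filter(tab2, 0.999, 0.999), "relax")
})

test_that("16S copies per ng match the analytic expectation", {
  x <- gene_copies_per_ng(4e6, 4)
  # 4 / (4e6 * 650 / N_A, in ng); printed as 9.2e5 at two significant figures
  expect_gt(x, 9.15e5)
  expect_lt(x, 9.3e5)
  expect_equal(gene_copies_per_ng(4e6, 8), 2 * x)
  expect_equal(gene_copies_per_ng(2e6, 4), 2 * x)
  expect_error(gene_copies_per_ng(0, 4), ">= 1")
})

test_that("distance matrices export as square TSV and re-read", {
  tab <- otu_mat(matrix(rpois(30, 8) + 1L, 5))
  d <- bray_curtis(tab)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, f)
  back <- read.delim(f, row.names = 1)
  expect_equal(as.matrix(back), as.matrix(d), tolerance = 1e-12,
               ignore_attr = TRUE)
})
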