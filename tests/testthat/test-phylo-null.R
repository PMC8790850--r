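test_that("MNTD matches hand values and the exhaustive oracle", {
  # two sister tips at patristic distance 2
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(mntd(c(A = 3, B = 1), tr), 2)
  # symmetric community: weighting is irrelevant
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ab <- c(A = 2, B = 2, C = 2, D = 2)
  expect_equal(mntd(ab, tr4, weighted = TRUE),
               mntd(ab, tr4, weighted = FALSE))
  # 4-tip tree, 3 present, unequal abundances: full-matrix oracle
  ab2 <- c(A = 5, B = 0, C = 2, D = 1)
  expect_equal(mntd(ab2, tr4, weighted = TRUE), bf_mntd(ab2, tr4, TRUE))
  expect_equal(mntd(ab2, tr4, weighted = FALSE), bf_mntd(ab2, tr4, FALSE))
  expect_error(mntd(c(A = 1, B = 0, C = 0, D = 0), tr4), "at least 2")

  # exhaustive equivalence on all trees with <= 6 tips
  for (n in 3:6) for (rep in 1:4) {
    set.seed(10 * n + rep)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    ab <- setNames(rpois(n, 3), tr$tip.label)
    if (sum(ab > 0) < 2) ab[1:2] <- 1
    for (w in c(TRUE, FALSE))
      expect_equal(mntd(ab, tr, weighted = w), bf_mntd(ab, tr, w),
                   tolerance = 1e-12)
  }
})

test_that("MNTD and betaMNTD agree with picante", {
  set.seed(5)
  tr <- ape::rcoal(8)
  tr$tip.label <- paste0("t", 1:8)
  ab <- setNames(c(3, 0, 2, 5, 0, 1, 0, 4), tr$tip.label)
  ab2 <- setNames(c(0, 2, 1, 0, 3, 0, 2, 1), tr$tip.label)
  D <- stats::cophenetic(tr)
  expect_equal(mntd(ab, tr, weighted = TRUE),
               unname(picante::mntd(matrix(ab, 1, dimnames = list("s", names(ab))),
                                    D, abundance.weighted = TRUE)))
  expect_equal(beta_mntd(ab, ab2, tr, weighted = TRUE),
               as.vector(picante::comdistnt(rbind(s1 = ab, s2 = ab2), D,
                                            abundance.weighted = TRUE)))
})

test_that("clade-confined communities show strong phylogenetic clustering", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    fx <- clade_confined_fixture(s)
    r <- nti(fx$table, fx$tree, n_null = 199, seed = s, threshold = 0)
    hits <- hits + sum(r$z[fx$focal] > 2)
    total <- total + length(fx$focal)
  }
  expect_gte(hits / total, 0.95)
})

test_that("the null loop's observed MNTD equals the public computation", {
  fx <- clade_confined_fixture(4)
  r <- suppressWarnings(nti(fx$table, fx$tree, n_null = 9, seed = 1,
                            threshold = 0))
  keep <- sort(colnames(fx$table)[colMeans(fx$table / rowSums(fx$table)) > 0])
  tr <- ape::keep.tip(fx$tree, keep)
  direct <- vapply(rownames(fx$table), function(s)
    mntd(fx$table[s, keep], tr, weighted = TRUE), numeric(1))
  expect_equal(r$observed, direct, tolerance = 1e-12)
  # and betaMNTD likewise
  tb <- fx$table[1:3, ]
  rb <- suppressWarnings(beta_nti(tb, fx$tree, n_null = 9, seed = 1,
                                  threshold = 0))
  keep2 <- sort(colnames(tb)[colMeans(tb / rowSums(tb)) > 0])
  tr2 <- ape::keep.tip(fx$tree, keep2)
  expect_equal(rb$observed[1],
               beta_mntd(tb[1, keep2], tb[2, keep2], tr2, weighted = TRUE),
               tolerance = 1e-12)
})

test_that("NTI nulls are seed-reproducible and column-order invariant", {
  fx <- clade_confined_fixture(3)
  r1 <- nti(fx$table, fx$tree, n_null = 99, seed = 7, threshold = 0)
  r2 <- nti(fx$table, fx$tree, n_null = 99, seed = 7, threshold = 0)
  expect_identical(r1$z, r2$z)
  perm <- sample(ncol(fx$table))
  r3 <- nti(fx$table[, perm], fx$tree, n_null = 99, seed = 7, threshold = 0)
  expect_equal(r3$z, r1$z)
  # tiny n_null still yields finite z, with a quality warning
  expect_warning(r4 <- nti(fx$table, fx$tree, n_null = 2, seed = 1,
                           threshold = 0), "noisy null")
  expect_true(all(is.finite(r4$z) | is.nan(r4$z)))
})

test_that("degenerate star trees give zero-deviation z with a warning", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  tab <- otu_mat(rbind(c(2L, 3L, 1L, 4L), c(1L, 1L, 1L, 1L)),
                 otus = c("A", "B", "C", "D"))
  expect_warning(r <- nti(tab, tr, n_null = 49, seed = 1, threshold = 0),
                 "standard deviation ~0")
  expect_true(all(r$z == 0))
})

test_that("betaNTI separates conserved selection from neutral assembly", {
  fx <- selected_vs_neutral_fixture(1)
  bs <- beta_nti(fx$selected, fx$tree, n_null = 199, seed = 1, threshold = 0)
  bn <- beta_nti(fx$neutral, fx$tree, n_null = 199, seed = 1, threshold = 0)
  s_sel <- assembly_summary(bs)
  s_neu <- assembly_summary(bn)
  expect_gt(s_sel$frac_below, s_neu$frac_below)
  expect_gt(s_sel$frac_below, 0.5)
  expect_gt(s_neu$frac_within, 0.8)
  # per-sample reductions cover every sample and are fractions
  expect_equal(nrow(bs$per_sample_fractions), nrow(fx$selected))
  expect_true(all(bs$per_sample_fractions >= 0 &
                    bs$per_sample_fractions <= 1))
})

test_that("identical samples have zero betaMNTD and non-positive betaNTI", {
  fx <- selected_vs_neutral_fixture(2)
  tab <- fx$selected[c(1, 1), ]
  rownames(tab) <- c("a", "b")
  expect_warning(r <- beta_nti(tab, fx$tree, n_null = 49, seed = 1,
                               threshold = 0), "~0")
  expect_equal(r$observed, 0)
  expect_lte(as.vector(r$z), 0)
})

test_that("betaNTI nulls are deterministic under a fixed seed", {
  fx <- selected_vs_neutral_fixture(3)
  tab <- fx$selected[1:4, ]
  r1 <- beta_nti(tab, fx$tree, n_null = 99, seed = 5, threshold = 0)
  r2 <- beta_nti(tab, fx$tree, n_null = 99, seed = 5, threshold = 0)
  expect_identical(as.vector(r1$z), as.vector(r2$z))
})

test_that("assembly summaries count the threshold bands correctly", {
  res <- structure(list(z = c(-3, 0, 3)), class = "null_model_result")
  s <- assembly_summary(res)
  expect_equal(unlist(s[c("frac_below", "frac_within", "frac_above")]),
               c(frac_below = 1 / 3, frac_within = 1 / 3,
                 frac_above = 1 / 3))
  # closed interval at the thresholds
  s2 <- assembly_summary(structure(list(z = c(-2, 2)),
                                   class = "null_model_result"))
  expect_equal(s2$frac_within, 1)
  # NaN excluded but counted
  s3 <- assembly_summary(structure(list(z = c(NaN, -3)),
                                   class = "null_model_result"))
  expect_equal(s3$n_nan, 1L)
  expect_equal(s3$frac_below, 1)
  expect_error(assembly_summary(structure(list(z = NaN),
                                          class = "null_model_result")),
               "all z-scores")
})
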