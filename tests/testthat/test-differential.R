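# differential: fold changes, Welch tests, selection filter, CV, ANOVA.

test_that("fold_change arithmetic, reciprocity, and errors", {
  expect_equal(fold_change(c(180, 220), c(90, 110)), 2)
  expect_equal(fold_change(c(5, 5), c(5, 5)), 1)
  # a protein "increased 4.2 folds" has fold_change 4.2
  expect_equal(fold_change(420, 100), 4.2)
  expect_error(fold_change(c(NA, NA), c(1, 2)), "missing")
  expect_error(fold_change(c(1, 2), c(0, 0)), "not positive")
  # reciprocity property over random inputs
  panet:::with_seed(42, {
    for (i in 1:20) {
      a <- stats::rlnorm(5)
      b <- stats::rlnorm(7)
      expect_equal(fold_change(a, b) * fold_change(b, a), 1, tolerance = 1e-12)
    }
  })
})

test_that("Welch t-test matches stats::t.test and handles degenerate input", {
  expect_equal(independent_t_test(c(3, 3, 3), c(3, 3, 3)), 1)
  panet:::with_seed(7, {
    x <- stats::rnorm(20, 10, 1)
    y <- stats::rnorm(20, 5, 1)
    expect_lt(independent_t_test(x, y), 1e-6)
    # dual-route check against the reference implementation
    for (i in 1:10) {
      a <- stats::rnorm(8 + i, mean = i / 3)
      b <- stats::rnorm(12, sd = 1.5)
      expect_equal(independent_t_test(a, b),
                   stats::t.test(a, b, var.equal = FALSE)$p.value,
                   tolerance = 1e-10)
    }
  })
  expect_error(independent_t_test(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("coefficient of variation: values, scale invariance, errors", {
  expect_equal(coefficient_of_variation(c(5, 5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 100 * sqrt(2) / 2,
               tolerance = 1e-10)  # 70.71%
  panet:::with_seed(3, {
    x <- stats::rlnorm(10)
    expect_equal(coefficient_of_variation(3.7 * x),
                 coefficient_of_variation(x), tolerance = 1e-10)
  })
  expect_error(coefficient_of_variation(c(2)), ">= 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "mean is zero")
})

test_that("two_fold_filter boundary is inclusive, symmetric, idempotent", {
  d <- data.frame(gene = c("a", "b", "c", "d", "e"),
                  fold = c(2.0, 0.5, 1.5, 3.0, 2.5),
                  p = c(0.01, 0.01, 0.001, 0.2, 0.04))
  kept <- two_fold_filter(d)
  expect_setequal(kept$gene, c("a", "b", "e"))  # 2.0 kept, decrease kept,
  # sub-threshold fold and non-significant p dropped
  expect_identical(two_fold_filter(kept), kept)
  shuffled <- d[c(4, 2, 5, 1, 3), ]
  expect_setequal(two_fold_filter(shuffled)$gene, kept$gene)
})

test_that("group_differential recovers a planted fold and collapses spots", {
  st <- tiny_study(n_case = 10, n_control = 10, n_proteins = 30, fold = 4.2,
                   seed = 21)
  res <- group_differential(st, tiny_map(30), "CASE", "CONTROL")
  g1 <- res[res$gene == "G1", ]
  expect_gt(g1$fold, 3)
  expect_lt(g1$fold, 5.5)
  expect_lt(g1$p, 0.05)
  expect_true(g1$selected)

  # null identity: case == control group -> folds near 1, nothing selected
  null_res <- group_differential(st, tiny_map(30), "CONTROL", "CONTROL")
  expect_true(all(abs(log(null_res$fold)) < 0.5))

  # multi-spot -> gene min-p collapse: two proteins on one gene
  m <- st$intensities[1:2, ]
  rownames(m) <- c("P1", "P2")
  st2 <- intensity_study(m, st$groups)
  map2 <- protein_gene_map(c("P1", "P2"), c("G1", "G1"))
  res2 <- group_differential(st2, map2, "CASE", "CONTROL")
  expect_equal(nrow(res2), 1L)
  p1 <- independent_t_test(m[1, st$groups == "CASE"],
                           m[1, st$groups == "CONTROL"])
  p2 <- independent_t_test(m[2, st$groups == "CASE"],
                           m[2, st$groups == "CONTROL"])
  expect_equal(res2$p, min(p1, p2))

  # unmapped proteins excluded with a count
  map3 <- protein_gene_map(sprintf("P%d", 1:20), sprintf("G%d", 1:20))
  expect_message(res3 <- group_differential(st, map3, "CASE", "CONTROL"),
                 "10 unmapped")
  expect_equal(attr(res3, "n_unmapped"), 10L)
})

test_that("anova_pairwise: null gives corrected p 1, shifts are localised", {
  # three identical constant groups
  m <- matrix(5, nrow = 2, ncol = 9,
              dimnames = list(c("P1", "P2"), sprintf("s%d", 1:9)))
  st <- intensity_study(m, stats::setNames(rep(c("A", "B", "C"), each = 3),
                                           colnames(m)))
  res <- expect_silent(anova_pairwise(st))
  expect_true(all(res$p_corr == 1))
  expect_true(all(res$anova_p == 1))
  # 3 groups -> 3 pairs, correction factor 3
  expect_equal(nrow(res), 2L * 3L)
  expect_equal(res$p_corr, pmin(1, 3 * res$p_raw))

  # one group shifted by ~5 sd: its pairs significant, the other pair not
  st2 <- panet:::with_seed(9, {
    m2 <- matrix(stats::rnorm(3 * 24, 100, 2), nrow = 3)
    dimnames(m2) <- list(c("P1", "P2", "P3"), sprintf("s%d", 1:24))
    grp <- stats::setNames(rep(c("A", "B", "C"), each = 8), colnames(m2))
    m2[1, grp == "C"] <- m2[1, grp == "C"] + 10
    intensity_study(m2, grp)
  })
  res2 <- anova_pairwise(st2)
  p1 <- res2[res2$protein_id == "P1", ]
  expect_lt(p1$p_corr[p1$group_a == "A" & p1$group_b == "C"], 0.01)
  expect_lt(p1$p_corr[p1$group_a == "B" & p1$group_b == "C"], 0.01)
  expect_gt(p1$p_corr[p1$group_a == "A" & p1$group_b == "B"], 0.05)
})
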