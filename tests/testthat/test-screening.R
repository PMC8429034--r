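make_expr <- function(m, group = rep("tumor", ncol(m))) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  expression_matrix(m, group)
}

test_that("perfect and sub-threshold correlations are handled per contract", {
  set.seed(1)
  base <- rnorm(10)
  lnc <- rbind(l1 = base,                       # identical to the gene
               l2 = 0.747 * scale(base)[, 1] +  # engineered |r| < 0.8
                 sqrt(1 - 0.747^2) * scale(resid(lm(rnorm(10) ~ base)))[, 1])
  gene <- rbind(g1 = base)
  colnames(lnc) <- colnames(gene) <- sprintf("s%02d", 1:10)
  res <- correlate_immune(make_expr(lnc), make_expr(gene))
  expect_true("l1" %in% res$ids)                 # r = 1 retained
  expect_false("l2" %in% res$ids)                # max |r| < 0.8 excluded
  hit <- res$hits[res$hits$lnc_id == "l1", ]
  expect_equal(hit$r, 1, tolerance = 1e-12)
  expect_equal(hit$p, 0)
})

test_that("correlation p-values match the exact t-transform", {
  # toy vectors (1..5) vs (2,4,6,8,10): r = 1 exactly; and a noisy pair
  # checked against cor.test as the brute-force reference
  x <- c(1, 2, 3, 4, 5.5)
  y <- c(2, 4.5, 5, 9, 10)
  lnc <- rbind(l1 = x)
  gene <- rbind(g1 = y)
  colnames(lnc) <- colnames(gene) <- sprintf("s%d", 1:5)
  res <- correlate_immune(make_expr(lnc), make_expr(gene), r_min = 0,
                          p_adj_max = 1)
  ref <- cor.test(x, y)
  expect_equal(res$hits$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$hits$p, ref$p.value, tolerance = 1e-12)

  exact <- correlate_immune(make_expr(rbind(l1 = c(1, 2, 3, 4, 5))),
                            make_expr(rbind(g1 = c(2, 4, 6, 8, 10))),
                            r_min = 0, p_adj_max = 1)
  expect_equal(exact$hits$r, 1, tolerance = 1e-12)
  expect_equal(exact$hits$p, 0)
})

test_that("zero-variance features are excluded with a warning", {
  lnc <- rbind(l1 = rep(1, 5), l2 = c(1, 2, 3, 4, 5))
  gene <- rbind(g1 = c(2, 4, 6, 8, 10))
  colnames(lnc) <- colnames(gene) <- sprintf("s%d", 1:5)
  expect_warning(res <- correlate_immune(make_expr(lnc), make_expr(gene)),
                 "zero variance")
  expect_identical(res$ids, "l2")
})

test_that("relaxing screening thresholds never shrinks the retained set", {
  coh <- simulate_cohort(small_params(seed = 21, noise_sd = 0.6))
  parts <- split_by_biotype(coh$expression, cohort_annotation(coh),
                            cohort_immune_list(coh))
  strict <- correlate_immune(parts$lnc, parts$irgene, r_min = 0.8,
                             p_adj_max = 0.001)
  loose_r <- correlate_immune(parts$lnc, parts$irgene, r_min = 0.6,
                              p_adj_max = 0.001)
  loose_p <- correlate_immune(parts$lnc, parts$irgene, r_min = 0.8,
                              p_adj_max = 0.01)
  expect_true(all(strict$ids %in% loose_r$ids))
  expect_true(all(strict$ids %in% loose_p$ids))
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  set.seed(42)
  for (rep in 1:5) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  }
  # and the package applies BH over the full test family
  lnc <- matrix(rnorm(5 * 20), 5, 20,
                dimnames = list(paste0("l", 1:5), paste0("s", 1:20)))
  gene <- matrix(rnorm(3 * 20), 3, 20,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:20)))
  res <- correlate_immune(make_expr(lnc), make_expr(gene), r_min = 0,
                          p_adj_max = 1.1)
  expect_equal(sort(res$hits$p_adj), sort(brute_bh(res$hits$p)),
               tolerance = 1e-12)
  expect_true(all(res$hits$p_adj >= res$hits$p))
})

test_that("differential expression recovers the planted fold change", {
  coh <- simulate_cohort(small_params(seed = 31, de_log2fc = 2,
                                      noise_sd = 0.1))
  parts <- split_by_biotype(coh$expression, cohort_annotation(coh),
                            cohort_immune_list(coh))
  de <- differential_expression(parts$lnc)
  expect_true(all(coh$truth$de_ids %in% de$lnc_id[de$de]))
  # partition identity: every DE lncRNA is up or down
  expect_equal(sum(de$de & de$direction == "up") +
                 sum(de$de & de$direction == "down"), sum(de$de))
  expect_true(all(de$fdr >= de$p))
})

test_that("identical group means are never flagged", {
  m <- matrix(rep(c(1, 2, 3, 4), each = 3), 3, 4,
              dimnames = list(paste0("l", 1:3), paste0("s", 1:4)))
  de <- differential_expression(make_expr(m, c("tumor", "tumor",
                                               "normal", "normal")))
  # logFC: mean(1,2) - mean(3,4) = -2 for every row, so sign is planted;
  # now a truly null matrix:
  m0 <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3), 3, 4,
               dimnames = list(paste0("l", 1:3), paste0("s", 1:4)))
  de0 <- differential_expression(make_expr(m0, c("tumor", "tumor",
                                                 "normal", "normal")))
  expect_true(all(de0$logFC == 0))
  expect_true(all(!de0$de))
  expect_error(
    differential_expression(make_expr(m0, c("tumor", "tumor", "tumor",
                                            "normal"))),
    "at least 2 samples")
})

test_that("DE thresholds are monotone in the retained set", {
  coh <- simulate_cohort(small_params(seed = 41, de_log2fc = 1.2))
  parts <- split_by_biotype(coh$expression, cohort_annotation(coh),
                            cohort_immune_list(coh))
  strict <- differential_expression(parts$lnc, logfc_min = 1,
                                    fdr_max = 0.05)
  loose <- differential_expression(parts$lnc, logfc_min = 0.5,
                                   fdr_max = 0.1)
  expect_true(all(strict$lnc_id[strict$de] %in% loose$lnc_id[loose$de]))
})

test_that("label permutation keeps the DE flag rate at the null level", {
  set.seed(99)
  flagged <- total <- 0
  for (rep in 1:3) {
    coh <- simulate_cohort(small_params(seed = 200 + rep))
    em <- coh$expression
    perm <- expression_matrix(em$values,
                              sample(as.character(em$group)))
    de <- differential_expression(
      subset_expr(perm, features = grep("^LNC", rownames(perm$values),
                                        value = TRUE)))
    flagged <- flagged + sum(de$de)
    total <- total + nrow(de)
  }
  rate <- flagged / total
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})
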