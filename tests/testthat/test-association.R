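test_that("chi-square statistic matches the hand formula on a 2x2 table", {
  # table (10,0 / 0,10): expected counts all 5, X2 = sum (O-E)^2/E = 20
  clin <- data.frame(sample_id = sprintf("pt%02d", 1:20),
                     os_time = 1, os_event = 0,
                     gender = rep(c("female", "male"), each = 10))
  groups <- data.frame(sample_id = clin$sample_id,
                       risk_group = rep(c("high", "low"), each = 10))
  res <- chisq_clinical(groups, clin, variables = "gender")
  expect_equal(res$tests$statistic, 20, tolerance = 1e-12)
  expect_equal(res$tests$df, 1)
})

test_that("reference contingency counts reproduce the reported significance", {
  counts <- kirc_clinical_counts()
  for (v in c("grade", "stage")) {
    tab <- counts[counts$variable == v &
                    !counts$level %in% c("GX", "unknown", "NX", "MX"), ]
    m <- as.matrix(tab[, c("high_risk", "low_risk")])
    ct <- chisq.test(m, correct = FALSE)
    expect_lt(ct$p.value, 0.001)
  }
  # N stage (all three recorded levels) was reported at p = 0.004
  ntab <- counts[counts$variable == "n_stage", ]
  ct <- chisq.test(as.matrix(ntab[, c("high_risk", "low_risk")]),
                   correct = FALSE)
  expect_lt(ct$p.value, 0.01)
})

test_that("summary percentages are count/column-total to one decimal", {
  counts <- kirc_clinical_counts()
  gender <- counts[counts$variable == "gender", ]
  tab <- as.matrix(gender[, c("overall", "high_risk", "low_risk")])
  rownames(tab) <- gender$level
  sm <- contingency_summary(tab, variable = "gender")
  # 186/530 -> 35.1%, 76/220 -> 34.5%, 110/310 -> 35.5%
  fem <- sm[sm$level == "female", ]
  expect_equal(fem$pct[fem$group == "overall"], 35.1)
  expect_equal(fem$pct[fem$group == "high_risk"], 34.5)
  expect_equal(fem$pct[fem$group == "low_risk"], 35.5)
  expect_equal(sm$pct,
               unname(round(100 * sm$count / rep(colSums(tab), each = 2),
                            1)))
})

test_that("risk-group labels independent of a variable give null chi-square p", {
  set.seed(31)
  ps <- vapply(1:40, function(i) {
    clin <- data.frame(sample_id = sprintf("pt%03d", 1:60),
                       os_time = 1, os_event = 0,
                       gender = sample(c("female", "male"), 60, TRUE))
    groups <- data.frame(sample_id = clin$sample_id,
                         risk_group = sample(c("high", "low"), 60, TRUE))
    chisq_clinical(groups, clin, variables = "gender")$tests$p
  }, numeric(1))
  # null p-values: nominal rejection rate, no pile-up near zero
  expect_lte(mean(ps < 0.05), 0.15)
  expect_gte(mean(ps > 0.2), 0.5)
})

test_that("rank-sum statistic matches brute-force pair enumeration", {
  clin <- data.frame(sample_id = sprintf("pt%d", 1:6),
                     os_time = 1, os_event = 0,
                     age = c(70, 70, 70, 60, 60, 60))
  scores <- setNames(c(1, 2, 3, 4, 5, 6), clin$sample_id)
  res <- ranksum_by_subgroup(scores, clin, "age")
  # first subgroup alphabetically is age<=65 with scores (4,5,6):
  # W = #{(x, y): x > y} over the 9 cross pairs = 9
  brute <- sum(outer(c(4, 5, 6), c(1, 2, 3), ">")) +
    0.5 * sum(outer(c(4, 5, 6), c(1, 2, 3), "=="))
  expect_equal(unname(res$statistic), brute)
  expect_equal(res$effect, median(c(1, 2, 3)) - median(c(4, 5, 6)))
})

test_that("identical score distributions give rank-sum p of 1", {
  clin <- data.frame(sample_id = sprintf("pt%d", 1:8),
                     os_time = 1, os_event = 0,
                     gender = rep(c("female", "male"), each = 4))
  scores <- setNames(rep(c(1, 2, 3, 4), 2), clin$sample_id)
  res <- ranksum_by_subgroup(scores, clin, "gender")
  expect_equal(res$p, 1, tolerance = 1e-12)
  clin$gender <- "female"
  expect_error(ranksum_by_subgroup(scores, clin, "gender"), "empty")
})

test_that("risk score is an independent prognostic factor on planted data", {
  coh <- simulate_cohort(small_params(seed = 51, n_tumor = 300))
  rep <- run_pipeline_cohort(coh, pipeline_config(seed = 51))
  cx <- rep$associations$cox
  rs <- cx[cx$variable == "riskScore", ]
  expect_equal(nrow(rs), 2)
  expect_true(all(rs$p < 0.01))
  expect_true(all(rs$hr > 1))
  expect_equal(cx$hr, exp(cx$coef), tolerance = 1e-12)
})

test_that("duplicated covariates trigger a collinearity warning", {
  set.seed(32)
  n <- 80
  clin <- data.frame(sample_id = sprintf("pt%03d", 1:n),
                     os_time = rexp(n, 0.05), os_event = rbinom(n, 1, 0.8),
                     grade = sample(c("G1", "G2", "G3", "G4"), n, TRUE))
  clin$grade2 <- clin$grade  # identical ordinal coding => aliased
  scores <- setNames(rnorm(n), clin$sample_id)
  expect_warning(cox_independence(scores, clin,
                                  variables = c("grade", "grade2")),
                 "collinear")
})

test_that("whole-cohort subgroup reproduces the global log-rank result", {
  coh <- simulate_cohort(small_params(seed = 52))
  rep <- run_pipeline_cohort(coh, pipeline_config(seed = 52))
  clin <- coh$clinical
  clin$allgrp <- "all"
  # a constant dichotomy column: both sides identical to the full cohort
  clin$grade <- ifelse(is.na(clin$grade), NA, "G3")  # all G3-4 side
  sub <- subgroup_survival(rep$groups, clin, variables = "grade")
  expect_equal(sub$chisq[sub$subgroup == "G3-4"], rep$km$chisq,
               tolerance = 1e-9)
})

test_that("spearman on reversed ranks gives rho -1 and planted directions hold", {
  groups <- data.frame(sample_id = c("a", "b", "c"),
                       risk_score = c(1, 2, 3),
                       risk_group = c("low", "low", "high"))
  infil <- matrix(c(3, 2, 1), 1, 3,
                  dimnames = list("Tregs", c("a", "b", "c")))
  res <- immune_drug_correlations(groups, infiltration = infil)
  expect_equal(res$effect, -1, tolerance = 1e-12)
  expect_error(immune_drug_correlations(
    groups, infiltration = infil[, 1:2, drop = FALSE]), "fewer than 3")
})

test_that("annotation associations recover the planted sign pattern", {
  coh <- simulate_cohort(small_params(seed = 53, n_tumor = 300))
  rep <- run_pipeline_cohort(coh, pipeline_config(seed = 53))
  id <- rep$associations$immune_drug
  tregs <- id[id$variable == "Tregs", ]
  expect_gt(tregs$effect, 0)
  chk <- id[id$family == "checkpoint", ]
  expect_equal(nrow(chk), 5)
  expect_true(all(chk$effect > 0))
  drug <- id[id$family == "drug", ]
  expect_lt(drug$effect, 0)
  expect_true(all(id$p >= 0 & id$p <= 1))
})
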