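# pair matrix + clinical pair for direct signature-stage tests
toy_surv_pm <- function(values, time, event) {
  ids <- sprintf("pt%02d", seq_len(ncol(values)))
  colnames(values) <- ids
  pm <- structure(list(values = values, ones_fraction = rowMeans(values)),
                  class = "pair_mat")
  clin <- data.frame(sample_id = ids, os_time = time, os_event = event)
  list(pm = pm, clin = clin)
}

test_that("uni-Cox coefficient matches brute-force partial-likelihood", {
  # 6-subject toy, hand-checkable partial likelihood, Breslow ties
  x <- c(1, 0, 1, 0, 1, 0)
  d <- toy_surv_pm(rbind(`a|b` = x),
                   time = c(2, 4, 5, 7, 9, 11),
                   event = c(1, 1, 0, 1, 1, 0))
  res <- unicox_screen(d$pm, d$clin, alpha = 1.01)
  oracle <- optimize(function(b) brute_cox_nll(b, d$clin$os_time,
                                               d$clin$os_event, x),
                     c(-10, 10), tol = 1e-10)$minimum
  expect_equal(res$coef, oracle, tolerance = 1e-6)
  expect_equal(res$hr, exp(res$coef), tolerance = 1e-12)
  expect_equal(sqrt(res$hr_low * res$hr_high), res$hr, tolerance = 1e-9)
})

test_that("uni-Cox recovers a planted coefficient at n = 400", {
  set.seed(4)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.01 * exp(1.0 * x))
  cens <- rexp(n, 0.005)
  d <- toy_surv_pm(rbind(`a|b` = x), pmin(t_ev, cens),
                   as.numeric(t_ev <= cens))
  res <- unicox_screen(d$pm, d$clin)
  expect_equal(nrow(res), 1)
  expect_lt(abs(res$coef - 1.0), 0.25)
})

test_that("null covariates are retained at about the nominal rate", {
  set.seed(8)
  n <- 150
  retained <- vapply(1:40, function(i) {
    x <- rbinom(n, 1, 0.5)
    d <- toy_surv_pm(rbind(`a|b` = x), rexp(n, 0.01),
                     rbinom(n, 1, 0.8))
    nrow(unicox_screen(d$pm, d$clin, alpha = 0.05)) == 1
  }, logical(1))
  # 40 independent nulls at alpha = .05: <= 8 rejections has P > 0.999
  expect_lte(sum(retained), 8)
})

test_that("degenerate pairs are skipped or excluded with warnings", {
  set.seed(2)
  n <- 30
  vals <- rbind(flat = rep(1, n), ok = rbinom(n, 1, 0.5))
  d <- toy_surv_pm(vals, rexp(n, 0.1), rbinom(n, 1, 0.9))
  expect_warning(res <- unicox_screen(d$pm, d$clin, alpha = 1.01),
                 "without variation")
  expect_identical(res$pair_id, "ok")
})

test_that("L1 selection finds a strong pair among noise and is seeded", {
  hits <- vapply(1:6, function(rep) {
    set.seed(3000 + rep)
    n <- 400
    true <- rbinom(n, 1, 0.5)
    noise <- matrix(rbinom(30 * n, 1, 0.5), 30, n)
    vals <- rbind(`s01|s02` = true, noise)
    rownames(vals)[-1] <- sprintf("n%02d|m%02d", 1:30, 1:30)
    t_ev <- rexp(n, 0.01 * exp(1.2 * true))
    cens <- rexp(n, 0.004)
    d <- toy_surv_pm(vals, pmin(t_ev, cens), as.numeric(t_ev <= cens))
    sel <- lasso_cox_select(d$pm, d$clin, seed = rep)
    sel2 <- lasso_cox_select(d$pm, d$clin, seed = rep)
    expect_identical(as.character(sel), as.character(sel2))  # seeded
    "s01|s02" %in% sel
  }, logical(1))
  expect_gte(mean(hits), 5 / 6)
})

test_that("L1 selection enforces its preconditions", {
  set.seed(5)
  n <- 40
  d <- toy_surv_pm(rbind(a = rbinom(n, 1, 0.5)), rexp(n, 0.1),
                   rbinom(n, 1, 0.9))
  expect_error(lasso_cox_select(d$pm, d$clin), "at least 2")
  d2 <- toy_surv_pm(rbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5)),
                    rexp(n, 0.1), c(1, 1, rep(0, n - 2)))
  expect_error(lasso_cox_select(d2$pm, d2$clin), "fewer events")
})

test_that("stepwise keeps exactly one of two duplicated pairs", {
  set.seed(9)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.01 * exp(x))
  d <- toy_surv_pm(rbind(`a|b` = x, `c|d` = x), t_ev, rep(1, n))
  expect_warning(sig <- stepwise_multicox(c("a|b", "c|d"), d$pm, d$clin),
                 "identical")
  expect_identical(sig$pairs, "a|b")  # tie broken by order
  expect_equal(sig$n_pairs, 1)
})

test_that("stepwise selection is by AIC and reports Wald statistics", {
  set.seed(10)
  n <- 300
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5); x3 <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.01 * exp(1.2 * x1 - x2))
  cens <- rexp(n, 0.004)
  d <- toy_surv_pm(rbind(`a|b` = x1, `c|d` = x2, `e|f` = x3),
                   pmin(t_ev, cens), as.numeric(t_ev <= cens))
  sig <- stepwise_multicox(c("a|b", "c|d", "e|f"), d$pm, d$clin)
  expect_true(all(c("a|b", "c|d") %in% sig$pairs))
  expect_equal(sig$table$hr, exp(sig$table$coef), tolerance = 1e-12)
  expect_equal(sqrt(sig$table$hr_low * sig$table$hr_high), sig$table$hr,
               tolerance = 1e-9)
  # removing either informative pair must increase AIC
  y <- survival::Surv(d$clin$os_time, d$clin$os_event)
  for (drop_one in list(c("a|b", "e|f"), c("c|d", "e|f"))) {
    xr <- t(d$pm$values[drop_one, , drop = FALSE])
    aic_r <- stats::extractAIC(survival::coxph(y ~ xr, ties = "breslow"))[2]
    expect_gt(aic_r, sig$aic)
  }
})

test_that("risk scores are the plain indicator-coefficient dot product", {
  sig <- kirc_signature()
  model <- as_pair_signature(sig)
  n <- length(model$pairs)
  # sample 1: all-zero pattern; sample 2: only the first pair on;
  # sample 3: all pairs on
  vals <- matrix(0, n, 3, dimnames = list(model$pairs, c("z", "one", "all")))
  vals["AC016700.2|AC093001.1", "one"] <- 1
  vals[, "all"] <- 1
  pm <- structure(list(values = vals, ones_fraction = rowMeans(vals)),
                  class = "pair_mat")
  rs <- compute_risk_scores(model, pm)
  expect_equal(rs$risk_score[rs$sample_id == "z"], 0)
  expect_equal(rs$risk_score[rs$sample_id == "one"], -0.555606139437541,
               tolerance = 1e-12)
  expect_equal(rs$risk_score[rs$sample_id == "all"], sum(sig$coef),
               tolerance = 1e-12)
  expect_error(compute_risk_scores(model,
                                   subset_pairs(pm, model$pairs[1:3])),
               "missing")
})

test_that("risk scores are additive over indicator patterns", {
  set.seed(12)
  model <- list(pairs = c("a|b", "c|d", "e|f"), coefs = c(0.5, -1.2, 0.3))
  v1 <- diag(3); v2 <- 1 - diag(3)
  mk <- function(v, ids) {
    dimnames(v) <- list(model$pairs, ids)
    structure(list(values = v, ones_fraction = rowMeans(v)),
              class = "pair_mat")
  }
  s1 <- compute_risk_scores(model, mk(v1, c("x", "y", "z")))$risk_score
  s2 <- compute_risk_scores(model, mk(v2, c("x", "y", "z")))$risk_score
  s12 <- compute_risk_scores(model, mk(v1 + v2, c("x", "y", "z")))$risk_score
  expect_equal(s1 + s2, s12, tolerance = 1e-12)
})

test_that("published signature table satisfies its analytic identities", {
  sig <- kirc_signature()
  expect_equal(nrow(sig), 12)
  expect_true(all(abs(exp(sig$coef) - sig$hr) <= 1e-9 * sig$hr))
  expect_true(all(abs(sqrt(sig$hr_low * sig$hr_high) - sig$hr) <=
                    1e-6 * sig$hr))
  expect_true(all(sig$hr_low <= sig$hr & sig$hr <= sig$hr_high))
})
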