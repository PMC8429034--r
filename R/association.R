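#' Chi-square association of risk group with clinical variables
#'
#' Pearson chi-square test (no continuity correction) of the risk-group x
#' level contingency table for each categorical variable. Unknown / "X"
#' levels (`GX`, `NX`, `MX`, `unknown`, `NA`) are excluded from the test
#' but kept in the descriptive summary. Levels with an all-zero row or
#' column are dropped with a warning.
#'
#' @param groups data.frame with `sample_id`, `risk_group`.
#' @param clinical Clinical table.
#' @param variables Character vector of clinical column names (default:
#'   the standard grade/stage/T/N/M plus gender).
#' @return List with `tests` (data.frame `variable`, `test`, `statistic`,
#'   `df`, `p`) and `summary` (long data.frame of counts and within-group
#'   percentages per level, including the excluded levels).
#' @export
chisq_clinical <- function(groups, clinical,
                           variables = c("gender", "grade", "stage",
                                         "t_stage", "n_stage", "m_stage")) {
  stopifnot(all(c("sample_id", "risk_group") %in% names(groups)))
  idx <- match(groups$sample_id, clinical$sample_id)
  if (anyNA(idx)) stop("group sample(s) missing from the clinical table")
  unknown <- c("GX", "NX", "MX", "TX", "X", "unknown", "Unknown", "")
  tests <- list(); summaries <- list()
  for (v in variables) {
    if (!v %in% names(clinical)) next
    lev <- as.character(clinical[[v]][idx])
    grp <- groups$risk_group
    full <- table(level = ifelse(is.na(lev), "unknown", lev), group = grp)
    summaries[[v]] <- contingency_summary(full, variable = v)
    keep <- !is.na(lev) & !(lev %in% unknown)
    tab <- table(lev[keep], grp[keep])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      warning("degenerate level(s) dropped for ", v)
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      warning("variable ", v, " has <2 informative levels; test skipped")
      next
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tests[[v]] <- data.frame(variable = v, test = "chisq",
                             statistic = unname(ct$statistic),
                             df = unname(ct$parameter),
                             p = unname(ct$p.value),
                             stringsAsFactors = FALSE)
  }
  list(tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
       summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))))
}

#' Counts with within-column percentages from a contingency table
#'
#' Formats a level x group count table the way clinical baseline tables
#' are reported: each cell as a count plus its percentage of the column
#' total, rounded to one decimal.
#'
#' @param tab Matrix or table of counts (levels x groups).
#' @param variable Optional variable name echoed into the output.
#' @return Long data.frame `variable`, `level`, `group`, `count`, `pct`.
#' @export
contingency_summary <- function(tab, variable = NA_character_) {
  tab <- as.matrix(tab)
  tot <- colSums(tab)
  out <- expand.grid(level = rownames(tab), group = colnames(tab),
                     stringsAsFactors = FALSE)
  out$count <- as.vector(tab)
  out$pct <- round(100 * as.vector(tab) /
                     rep(pmax(tot, 1), each = nrow(tab)), 1)
  cbind(variable = variable, out)
}

# internal: dichotomize a clinical variable into the conventional
# prognostic subgroups
.dichotomize <- function(clinical, variable) {
  x <- clinical[[variable]]
  switch(variable,
    age = ifelse(x > 65, "age>65", "age<=65"),
    gender = ifelse(x %in% c("female", "male"), x, NA),
    grade = ifelse(x %in% c("G1", "G2"), "G1-2",
                   ifelse(x %in% c("G3", "G4"), "G3-4", NA)),
    stage = ifelse(x %in% c("I", "II"), "stage I-II",
                   ifelse(x %in% c("III", "IV"), "stage III-IV", NA)),
    t_stage = ifelse(grepl("^T[12]", x), "T1-2",
                     ifelse(grepl("^T[34]", x), "T3-4", NA)),
    n_stage = ifelse(x == "N0", "N0", ifelse(x == "N1", "N1", NA)),
    m_stage = ifelse(x == "M0", "M0", ifelse(x == "M1", "M1", NA)),
    stop("no subgroup rule for variable ", variable))
}

#' Rank test of the risk score across a clinical dichotomy
#'
#' Two-sample Mann-Whitney / Wilcoxon rank-sum test (tie-corrected normal
#' approximation, no continuity correction) of the risk score between the
#' two conventional prognostic subgroups of a clinical variable: age >65 vs
#' <=65, female vs male, G1-2 vs G3-4, T1-2 vs T3-4, N0 vs N1, M0 vs M1,
#' stage I-II vs III-IV. Unknown/X levels are excluded.
#'
#' @param scores Risk scores (vector or data.frame).
#' @param clinical Clinical table.
#' @param variable One of `age`, `gender`, `grade`, `stage`, `t_stage`,
#'   `n_stage`, `m_stage`.
#' @return data.frame row: `variable`, `test`, `statistic` (W), `p`,
#'   `effect` (difference of subgroup median scores, second minus first).
#' @export
ranksum_by_subgroup <- function(scores, clinical, variable) {
  rp <- as_risk_profile(scores)
  idx <- match(rp$sample_id, clinical$sample_id)
  if (anyNA(idx)) stop("score sample(s) missing from the clinical table")
  side <- .dichotomize(clinical[idx, , drop = FALSE], variable)
  keep <- !is.na(side)
  lv <- sort(unique(side[keep]))
  if (length(lv) < 2)
    stop("subgroup level empty for variable ", variable)
  x <- rp$risk_score[keep & side == lv[1]]
  y <- rp$risk_score[keep & side == lv[2]]
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  data.frame(variable = variable, test = "ranksum",
             statistic = unname(wt$statistic), p = unname(wt$p.value),
             effect = stats::median(y) - stats::median(x),
             stringsAsFactors = FALSE)
}

#' Univariate and multivariate Cox models of score and clinical covariates
#'
#' Tests whether the risk score is an independent prognostic factor: each
#' covariate (age as years, grade and stage as ordinal integers, gender as
#' binary, the risk score as a continuous predictor) enters a univariate
#' Cox model, then all enter one multivariate model. Hazard ratios carry
#' Wald 95% intervals. Aliased (collinear) covariates are reported with a
#' warning.
#'
#' @param scores Risk scores (vector or data.frame).
#' @param clinical Clinical table.
#' @param variables Clinical covariates to include alongside `riskScore`.
#' @return data.frame `variable`, `model` (`univariate`/`multivariate`),
#'   `coef`, `hr`, `hr_low`, `hr_high`, `p`.
#' @export
cox_independence <- function(scores, clinical,
                             variables = c("age", "gender", "grade",
                                           "stage")) {
  d <- align_scores_clinical(scores, clinical)
  idx <- match(d$sample_id, clinical$sample_id)
  covar <- data.frame(riskScore = d$score)
  for (v in variables) {
    x <- clinical[[v]][idx]
    covar[[v]] <- switch(v,
      age = as.numeric(x),
      gender = as.numeric(x == "male"),
      grade = as.numeric(factor(x, levels = c("G1", "G2", "G3", "G4"))),
      stage = as.numeric(factor(x, levels = c("I", "II", "III", "IV"))),
      t_stage = as.numeric(factor(substr(x, 1, 2),
                                  levels = c("T1", "T2", "T3", "T4"))),
      as.numeric(factor(x)))
  }
  y <- survival::Surv(d$time, d$event)
  one_row <- function(fit, v, model) {
    b <- stats::coef(fit)[v]
    se <- sqrt(diag(stats::vcov(fit))[v])
    if (!is.finite(b)) {
      warning("covariate ", v, " is aliased/collinear in the ", model,
              " model")
      return(NULL)
    }
    z <- stats::qnorm(0.975)
    data.frame(variable = v, model = model, coef = unname(b),
               hr = exp(unname(b)), hr_low = exp(unname(b - z * se)),
               hr_high = exp(unname(b + z * se)),
               p = 2 * stats::pnorm(abs(unname(b / se)),
                                    lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (v in names(covar)) {
    cc <- stats::complete.cases(covar[[v]])
    fit <- survival::coxph(y[cc] ~ covar[[v]][cc])
    names(fit$coefficients) <- v
    dimnames(fit$var) <- list(v, v)
    rows[[paste0("u_", v)]] <- one_row(fit, v, "univariate")
  }
  cc <- stats::complete.cases(covar)
  mfit <- survival::coxph(y[cc] ~ ., data = covar[cc, , drop = FALSE])
  for (v in names(covar))
    rows[[paste0("m_", v)]] <- one_row(mfit, v, "multivariate")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Log-rank tests within clinical subgroups
#'
#' Repeats the high/low-risk Kaplan-Meier comparison inside each
#' conventional clinical subgroup (both sides of age, gender, stage, grade,
#' T, N, M — 14 subgroups). Subgroups in which either risk group has no
#' usable samples, or with fewer than 2 events, are skipped with a note.
#'
#' @param groups data.frame `sample_id`, `risk_group`.
#' @param clinical Clinical table.
#' @param variables Variables whose dichotomies define the subgroups.
#' @return data.frame `subgroup`, `n`, `n_high`, `n_low`, `chisq`, `p`,
#'   `note`.
#' @export
subgroup_survival <- function(groups, clinical,
                              variables = c("age", "gender", "stage",
                                            "grade", "t_stage", "n_stage",
                                            "m_stage")) {
  idx <- match(groups$sample_id, clinical$sample_id)
  if (anyNA(idx)) stop("group sample(s) missing from the clinical table")
  clin_m <- clinical[idx, , drop = FALSE]
  rows <- list()
  for (v in variables) {
    side <- .dichotomize(clin_m, v)
    for (lv in sort(unique(side[!is.na(side)]))) {
      in_sub <- !is.na(side) & side == lv
      g_sub <- groups[in_sub, , drop = FALSE]
      n_hl <- table(factor(g_sub$risk_group, levels = c("high", "low")))
      ev <- sum(clin_m$os_event[in_sub], na.rm = TRUE)
      if (any(n_hl == 0) || ev < 2) {
        rows[[lv]] <- data.frame(subgroup = lv, n = sum(in_sub),
                                 n_high = n_hl[["high"]],
                                 n_low = n_hl[["low"]],
                                 chisq = NA_real_, p = NA_real_,
                                 note = "skipped: empty group or <2 events",
                                 stringsAsFactors = FALSE)
        next
      }
      kr <- km_logrank(g_sub, clinical)
      rows[[lv]] <- data.frame(subgroup = lv, n = sum(in_sub),
                               n_high = n_hl[["high"]],
                               n_low = n_hl[["low"]],
                               chisq = kr$chisq, p = kr$p, note = "",
                               stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Immune-infiltration, checkpoint and drug-sensitivity associations
#'
#' Three association families of the risk model: Spearman correlation of
#' the risk score with each infiltrating-cell fraction (all reported,
#' `p < 0.05` flagged); a rank-sum test of each checkpoint gene's
#' expression between risk groups; and a rank-sum test of the
#' drug-sensitivity score between risk groups, with direction (median
#' difference high - low; negative means the high-risk group is more drug
#' sensitive on an IC50-like scale). Sample ids are intersected across
#' tables; at least 3 shared samples are required.
#'
#' @param groups data.frame `sample_id`, `risk_score`, `risk_group`.
#' @param infiltration Cell type x sample fraction matrix (optional).
#' @param checkpoint_expr Gene x sample expression matrix (optional).
#' @param drug_scores Named per-sample numeric (optional).
#' @param checkpoints Checkpoint genes to test when present in
#'   `checkpoint_expr`.
#' @return data.frame `variable`, `family`, `test`, `statistic`, `p`,
#'   `effect` (Spearman rho, or median difference high - low),
#'   `significant`.
#' @export
immune_drug_correlations <- function(groups, infiltration = NULL,
                                     checkpoint_expr = NULL,
                                     drug_scores = NULL,
                                     checkpoints = c("PDCD1", "CD247",
                                                     "CTLA4", "TIGIT",
                                                     "LAG3")) {
  stopifnot(all(c("sample_id", "risk_score", "risk_group") %in%
                  names(groups)))
  rows <- list()
  shared <- function(ids) {
    keep <- intersect(groups$sample_id, ids)
    if (length(keep) < 3)
      stop("fewer than 3 samples shared with the risk table")
    keep
  }
  if (!is.null(infiltration)) {
    ids <- shared(colnames(infiltration))
    sc <- groups$risk_score[match(ids, groups$sample_id)]
    for (ct in rownames(infiltration)) {
      st <- suppressWarnings(
        stats::cor.test(sc, infiltration[ct, ids], method = "spearman",
                        exact = FALSE))
      rows[[paste0("i_", ct)]] <- data.frame(
        variable = ct, family = "infiltration", test = "spearman",
        statistic = unname(st$statistic), p = unname(st$p.value),
        effect = unname(st$estimate), stringsAsFactors = FALSE)
    }
  }
  two_group <- function(vals, ids, variable, family) {
    grp <- groups$risk_group[match(ids, groups$sample_id)]
    hi <- vals[grp == "high"]; lo <- vals[grp == "low"]
    if (!length(hi) || !length(lo))
      stop("a risk group is empty among the shared samples")
    wt <- stats::wilcox.test(hi, lo, exact = FALSE, correct = FALSE)
    data.frame(variable = variable, family = family, test = "ranksum",
               statistic = unname(wt$statistic), p = unname(wt$p.value),
               effect = stats::median(hi) - stats::median(lo),
               stringsAsFactors = FALSE)
  }
  if (!is.null(checkpoint_expr)) {
    ids <- shared(colnames(checkpoint_expr))
    for (g in intersect(checkpoints, rownames(checkpoint_expr)))
      rows[[paste0("c_", g)]] <-
        two_group(checkpoint_expr[g, ids], ids, g, "checkpoint")
  }
  if (!is.null(drug_scores)) {
    ids <- shared(names(drug_scores))
    rows[["drug"]] <- two_group(drug_scores[ids], ids, "drug_score", "drug")
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$significant <- out$p < 0.05
  out
}
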