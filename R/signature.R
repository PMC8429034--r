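# internal: survival response for the tumor samples present in a pair matrix
.pm_surv <- function(pm, clinical) {
  clinical <- validate_clinical(clinical)
  ids <- colnames(pm$values)
  idx <- match(ids, clinical$sample_id)
  if (anyNA(idx))
    stop("pair-matrix sample(s) missing from the clinical table: ",
         paste(ids[is.na(idx)], collapse = ", "))
  time <- clinical$os_time[idx]
  event <- clinical$os_event[idx]
  if (anyNA(time) || anyNA(event))
    stop("pair-matrix sample(s) lack survival data")
  survival::Surv(time, event)
}

#' Univariate Cox screen of lncRNA pairs
#'
#' Fits a one-covariate Cox proportional-hazards model (Breslow tie
#' handling by default) to every pair indicator and retains pairs with Wald
#' p below `alpha`. Pairs with no variation are skipped with a warning, and
#' pairs with a monotone likelihood (infinite coefficient) are flagged and
#' excluded.
#'
#' @param pm A `pair_mat` over the survival cohort.
#' @param clinical Clinical table with `os_time`/`os_event` for every
#'   pair-matrix sample.
#' @param alpha Wald p-value threshold (default 0.05).
#' @param ties Tie handling passed to [survival::coxph()] (`"breslow"`
#'   default, `"efron"` available).
#' @return data.frame with one row per retained pair: `pair_id`, `coef`,
#'   `hr`, `hr_low`, `hr_high`, `p`. The unfiltered table (all converged
#'   pairs) is attached as attribute `"all"`.
#' @export
unicox_screen <- function(pm, clinical, alpha = 0.05, ties = "breslow") {
  stopifnot(inherits(pm, "pair_mat"))
  y <- .pm_surv(pm, clinical)
  novar <- apply(pm$values, 1, function(x) length(unique(x)) < 2)
  if (any(novar))
    warning(sum(novar), " pair(s) without variation skipped ",
            "(did the stability filter run?)")
  rows <- lapply(rownames(pm$values)[!novar], function(pid) {
    x <- pm$values[pid, ]
    fit <- tryCatch(
      survival::coxph(y ~ x, ties = ties,
                      control = survival::coxph.control(iter.max = 50)),
      error = function(e) NULL, warning = function(w) {
        # monotone likelihood surfaces as a convergence/infinite-beta warning
        fit <- suppressWarnings(survival::coxph(y ~ x, ties = ties))
        if (abs(stats::coef(fit)) > 15) NULL else fit
      })
    if (is.null(fit)) return(NULL)
    b <- unname(stats::coef(fit))
    se <- sqrt(unname(fit$var[1, 1]))
    if (!is.finite(b) || !is.finite(se) || abs(b) > 15) return(NULL)
    z <- stats::qnorm(0.975)
    data.frame(pair_id = pid, coef = b, hr = exp(b),
               hr_low = exp(b - z * se), hr_high = exp(b + z * se),
               p = 2 * stats::pnorm(abs(b / se), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " pair(s) excluded for non-convergence ",
            "(monotone likelihood)")
  all_tab <- do.call(rbind, rows)
  if (is.null(all_tab))
    all_tab <- data.frame(pair_id = character(), coef = numeric(),
                          hr = numeric(), hr_low = numeric(),
                          hr_high = numeric(), p = numeric())
  rownames(all_tab) <- NULL
  out <- all_tab[all_tab$p < alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_tab
  out
}

#' Cross-validated L1 Cox selection of pairs
#'
#' Fits an L1-penalized Cox model over a descending lambda path and keeps
#' the pairs with nonzero coefficients at `lambda.min`, the penalty
#' minimizing the mean cross-validated partial-likelihood deviance. Fold
#' assignment is seeded and stratified by event status so every fold sees
#' events.
#'
#' @param pm A `pair_mat` restricted to the uni-Cox-retained pairs.
#' @param clinical Clinical table covering the pair-matrix samples.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Character vector of selected pair ids (attribute
#'   `"lambda.min"` carries the chosen penalty).
#' @export
lasso_cox_select <- function(pm, clinical, n_folds = 10, seed = 0) {
  stopifnot(inherits(pm, "pair_mat"))
  if (nrow(pm$values) < 2)
    stop("need at least 2 candidate pairs for penalized selection")
  y <- .pm_surv(pm, clinical)
  if (sum(y[, "status"]) < n_folds)
    stop("fewer events than folds; reduce `n_folds`")
  x <- t(pm$values)
  set.seed(as.integer(seed))
  foldid <- integer(nrow(x))
  for (s in c(0, 1)) {
    idx <- which(y[, "status"] == s)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                          foldid = foldid, type.measure = "deviance")
  b <- as.vector(stats::coef(cv, s = "lambda.min"))
  sel <- colnames(x)[b != 0]
  if (!length(sel))
    stop("no pair survives the L1 penalty at lambda.min; ",
         "consider a weaker penalty or a longer lambda path")
  structure(sel, lambda.min = cv$lambda.min)
}

#' Stepwise multivariate Cox model over the selected pairs
#'
#' Starting from the full model on the selected pairs, performs a
#' bidirectional stepwise search minimizing AIC (`2k - 2 logPL`). Selection
#' is by AIC, not per-term significance, so individually non-significant
#' pairs can stay in the final model. Exactly duplicated indicator columns
#' are collapsed to the first occurrence before fitting.
#'
#' @param pair_ids Candidate pair ids (e.g. from [lasso_cox_select()]).
#' @param pm The `pair_mat` containing them.
#' @param clinical Clinical table covering the pair-matrix samples.
#' @param ties Tie handling (`"breslow"` default).
#' @return A `pair_signature`: list with `pairs`, `coefs`, `n_pairs`,
#'   `table` (per-pair `coef`, `hr`, `hr_low`, `hr_high`, `p`) and `aic`.
#' @export
stepwise_multicox <- function(pair_ids, pm, clinical, ties = "breslow") {
  stopifnot(inherits(pm, "pair_mat"), length(pair_ids) >= 1)
  sub <- subset_pairs(pm, pairs = pair_ids)
  # collapse exactly duplicated columns (tie broken by input order)
  dup <- duplicated(as.data.frame(sub$values))
  if (any(dup)) {
    warning("dropping ", sum(dup), " pair(s) identical to an earlier pair")
    pair_ids <- pair_ids[!dup]
    sub <- subset_pairs(pm, pairs = pair_ids)
  }
  y <- .pm_surv(sub, clinical)
  dat <- as.data.frame(t(sub$values))
  safe <- paste0("p", seq_along(pair_ids))  # syntactic stand-in names
  names(dat) <- safe
  dat$.y <- y
  env <- new.env(parent = environment())
  assign("dat", dat, envir = env)
  full_fml <- stats::as.formula(
    paste(".y ~", paste(safe, collapse = " + ")), env = env)
  full <- survival::coxph(full_fml, data = dat, ties = ties,
                          model = TRUE)
  fit <- if (length(safe) > 1) {
    stats::step(full, direction = "both", trace = 0,
                scope = list(lower = ~1, upper = full_fml))
  } else full
  b <- stats::coef(fit)
  keep_safe <- names(b)[is.finite(b)]
  if (!length(keep_safe))
    stop("stepwise search removed every pair")
  b <- b[keep_safe]
  se <- sqrt(diag(stats::vcov(fit))[keep_safe])
  z <- stats::qnorm(0.975)
  pairs <- pair_ids[match(keep_safe, safe)]
  tab <- data.frame(pair_id = pairs, coef = unname(b), hr = exp(unname(b)),
                    hr_low = exp(unname(b) - z * unname(se)),
                    hr_high = exp(unname(b) + z * unname(se)),
                    p = 2 * stats::pnorm(abs(unname(b) / unname(se)),
                                         lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, coefs = unname(b), n_pairs = length(pairs),
                 table = tab, aic = stats::extractAIC(fit)[2]),
            class = "pair_signature")
}

#' @exportS3Method print pair_signature
print.pair_signature <- function(x, ...) {
  cat(sprintf("<pair_signature> %d pair(s), AIC %.2f\n", x$n_pairs, x$aic))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-sample risk score of a pair signature
#'
#' The risk score is the plain linear predictor
#' `sum_i value(i) * coef(i)` over the `N` signature pairs, with `value(i)`
#' the 0/1 indicator of pair *i* in the sample — no intercept, no
#' normalization. Scores therefore take at most `2^N` distinct values and
#' are additive over the indicator pattern.
#'
#' @param model A `pair_signature` (or any list with `pairs` and `coefs`).
#' @param pm A `pair_mat` containing every model pair.
#' @return data.frame `sample_id`, `risk_score`.
#' @export
compute_risk_scores <- function(model, pm) {
  stopifnot(inherits(pm, "pair_mat"))
  miss <- setdiff(model$pairs, rownames(pm$values))
  if (length(miss))
    stop("pair(s) missing from the pair matrix: ",
         paste(miss, collapse = ", "))
  v <- pm$values[model$pairs, , drop = FALSE]
  data.frame(sample_id = colnames(v),
             risk_score = drop(crossprod(v, model$coefs)),
             stringsAsFactors = FALSE, row.names = NULL)
}
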