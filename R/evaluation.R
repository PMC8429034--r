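#' Time-dependent ROC at a fixed horizon
#'
#' Cumulative-case / dynamic-control ROC of a continuous risk score against
#' survival status at `horizon`: cases experienced the event by the
#' horizon, controls are still at risk beyond it, and censoring before the
#' horizon is handled by Kaplan-Meier reweighting. For each threshold `c`
#' (the distinct score values), writing `S(t)` for the overall KM survival
#' at the horizon, `S(t | X > c)` for the KM survival among samples scoring
#' above `c` and `F(c)` for the empirical score CDF:
#' \deqn{sens(c) = (1 - F(c)) (1 - S(t|X>c)) / (1 - S(t))}
#' \deqn{spec(c) = 1 - (1 - F(c)) S(t|X>c) / S(t)}
#' With no censoring before the horizon this reduces to the empirical ROC,
#' whose trapezoidal area equals the Mann-Whitney AUC. Sensitivity and
#' specificity are clipped to `[0, 1]` and made monotone along the
#' threshold grid (the raw KM-weighted estimates need not be).
#'
#' @param scores Named numeric vector or data.frame `(sample_id,
#'   risk_score)`.
#' @param clinical Clinical table with survival fields.
#' @param horizon Evaluation time (same unit as `os_time`).
#' @return A `timed_roc`: list with `horizon`, `thresholds`, `sens`,
#'   `spec`, `auc`.
#' @export
timed_roc <- function(scores, clinical, horizon) {
  d <- align_scores_clinical(scores, clinical)
  if (horizon <= 0 || horizon > max(d$time))
    stop("`horizon` must lie within the observed follow-up")
  if (!any(d$event == 1 & d$time <= horizon))
    stop("no events observed before the horizon")
  km_at <- function(time, event, t0) {
    if (!length(time)) return(NA_real_)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    s <- summary(fit, times = t0, extend = TRUE)$surv
    if (length(s)) s else 1
  }
  s_all <- km_at(d$time, d$event, horizon)
  thr <- sort(unique(d$score))
  n <- nrow(d)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    above <- d$score > thr[i]
    pF <- 1 - mean(above)               # F(c)
    s_c <- if (any(above)) km_at(d$time[above], d$event[above], horizon)
           else 1
    sens[i] <- (1 - pF) * (1 - s_c) / (1 - s_all)
    spec[i] <- 1 - (1 - pF) * s_c / s_all
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  # thresholds ascend => sens must fall, spec must rise; enforce
  sens <- rev(cummax(rev(sens)))
  spec <- cummax(spec)
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(horizon = horizon, thresholds = thr, sens = sens,
                 spec = spec, auc = auc),
            class = "timed_roc")
}

#' @exportS3Method print timed_roc
print.timed_roc <- function(x, ...) {
  cat(sprintf("<timed_roc> horizon %g: AUC = %.3f (%d thresholds)\n",
              x$horizon, x$auc, length(x$thresholds)))
  invisible(x)
}

#' Optimal risk-score cutoff
#'
#' Two selection rules for dichotomizing the risk score. `"aic"` (default):
#' every midpoint between consecutive distinct scores is a candidate; each
#' candidate's indicator enters a one-covariate Cox model and the cutoff
#' minimizing the model AIC wins (ties go to the smallest cutoff).
#' Candidates producing an empty group are skipped. `"youden"`: the
#' threshold maximizing `sens + spec - 1` on the horizon ROC. A cutoff is
#' flagged unstable when the AIC profile is flat (range below 2, i.e. no
#' candidate is decisively better than the worst).
#'
#' @param roc A [timed_roc()] result (used by the Youden rule).
#' @param scores Risk scores (vector or data.frame, as in [timed_roc()]).
#' @param clinical Clinical table.
#' @param method `"aic"` or `"youden"`.
#' @return A `cutoff_result`: list with `cutoff`, `method`,
#'   `criterion_value`, `stable`.
#' @export
find_cutoff <- function(roc, scores, clinical, method = c("aic", "youden")) {
  method <- match.arg(method)
  d <- align_scores_clinical(scores, clinical)
  sc <- sort(unique(d$score))
  if (length(sc) < 2) stop("need at least 2 distinct scores")
  if (method == "youden") {
    stopifnot(inherits(roc, "timed_roc"))
    j <- roc$sens + roc$spec - 1
    best <- which.max(j)
    return(structure(list(cutoff = roc$thresholds[best], method = "youden",
                          criterion_value = j[best], stable = TRUE),
                     class = "cutoff_result"))
  }
  candidates <- (utils::head(sc, -1) + utils::tail(sc, -1)) / 2
  y <- survival::Surv(d$time, d$event)
  aic <- vapply(candidates, function(cc) {
    g <- d$score > cc
    if (!any(g) || all(g)) return(NA_real_)
    fit <- tryCatch(survival::coxph(y ~ g), error = function(e) NULL,
                    warning = function(w) suppressWarnings(
                      survival::coxph(y ~ g)))
    if (is.null(fit)) NA_real_ else stats::extractAIC(fit)[2]
  }, numeric(1))
  if (all(is.na(aic))) stop("no admissible cutoff candidate")
  best <- which.min(aic)
  structure(list(cutoff = candidates[best], method = "aic",
                 criterion_value = aic[best],
                 stable = diff(range(aic, na.rm = TRUE)) >= 2),
            class = "cutoff_result")
}

#' Assign high/low risk groups
#'
#' Samples scoring strictly above the cutoff are `high` risk; scores at or
#' below it (including exact ties) are `low`.
#'
#' @param scores Risk scores (vector or data.frame).
#' @param cutoff Numeric cutoff (or a `cutoff_result`).
#' @return data.frame `sample_id`, `risk_score`, `risk_group` with the
#'   cutoff stored in attribute `"cutoff"`.
#' @export
assign_groups <- function(scores, cutoff) {
  if (inherits(cutoff, "cutoff_result")) cutoff <- cutoff$cutoff
  stopifnot(is.finite(cutoff))
  rp <- as_risk_profile(scores)
  rp$risk_group <- ifelse(rp$risk_score > cutoff, "high", "low")
  attr(rp, "cutoff") <- cutoff
  rp
}

#' Kaplan-Meier curves and log-rank test between risk groups
#'
#' Product-limit survival estimate per group plus the two-sample log-rank
#' chi-square test of curve equality.
#'
#' @param groups data.frame with `sample_id` and `risk_group` (e.g. from
#'   [assign_groups()]), or a named character vector of group labels.
#' @param clinical Clinical table with survival fields.
#' @return List with `curves` (data.frame `group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `chisq`, `df`, `p` and per-group sizes `n`.
#' @export
km_logrank <- function(groups, clinical) {
  if (is.character(groups) && !is.null(names(groups)))
    groups <- data.frame(sample_id = names(groups),
                         risk_group = unname(groups),
                         stringsAsFactors = FALSE)
  stopifnot(is.data.frame(groups),
            all(c("sample_id", "risk_group") %in% names(groups)))
  clinical <- validate_clinical(clinical)
  idx <- match(groups$sample_id, clinical$sample_id)
  if (anyNA(idx)) stop("group sample(s) missing from the clinical table")
  d <- data.frame(time = clinical$os_time[idx],
                  event = clinical$os_event[idx],
                  group = groups$risk_group)
  d <- d[!is.na(d$time) & !is.na(d$event), ]
  if (length(unique(d$group)) < 2)
    stop("need two non-empty groups")
  ev <- tapply(d$event, d$group, sum)
  if (any(ev == 0))
    warning("group(s) with zero events: ",
            paste(names(ev)[ev == 0], collapse = ", "))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sm <- summary(fit)
  curves <- data.frame(group = sub("^group=", "", as.character(sm$strata)),
                       time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, surv = sm$surv,
                       stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd$n) - 1
  list(curves = curves, chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = table(d$group))
}
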