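#' Pipeline configuration
#'
#' Collects every stage threshold and the global seed in one validated
#' list. The single seed is fanned out to per-stage child seeds by fixed
#' offsets so each stage is individually reproducible.
#'
#' @param r_min,p_adj_max Coexpression screen thresholds.
#' @param logfc_min,fdr_max Differential-expression thresholds.
#' @param stability_low,stability_high Pair stability bounds (exclusive).
#' @param alpha Univariate Cox retention threshold.
#' @param n_folds L1 Cox cross-validation folds.
#' @param horizons Evaluation horizons (same unit as `os_time`; defaults
#'   1/2/3 years in days).
#' @param cutoff_method `"aic"` or `"youden"`.
#' @param checkpoints Checkpoint genes for the association stage.
#' @param seed Global integer seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(r_min = 0.8, p_adj_max = 0.001,
                            logfc_min = 1, fdr_max = 0.05,
                            stability_low = 0.2, stability_high = 0.8,
                            alpha = 0.05, n_folds = 10,
                            horizons = c(365, 730, 1095),
                            cutoff_method = c("aic", "youden"),
                            checkpoints = c("PDCD1", "CD247", "CTLA4",
                                            "TIGIT", "LAG3"),
                            seed = 0) {
  cutoff_method <- match.arg(cutoff_method)
  cfg <- list(r_min = r_min, p_adj_max = p_adj_max, logfc_min = logfc_min,
              fdr_max = fdr_max, stability_low = stability_low,
              stability_high = stability_high, alpha = alpha,
              n_folds = n_folds, horizons = horizons,
              cutoff_method = cutoff_method, checkpoints = checkpoints,
              seed = as.integer(seed))
  if (!(cfg$r_min > 0 && cfg$r_min <= 1)) stop("r_min must be in (0, 1]")
  for (k in c("p_adj_max", "fdr_max", "alpha"))
    if (!(cfg[[k]] > 0 && cfg[[k]] <= 1))
      stop(k, " must be in (0, 1]")
  if (!(cfg$stability_low < cfg$stability_high))
    stop("stability_low must be smaller than stability_high")
  if (cfg$stability_low < 0 || cfg$stability_high > 1)
    stop("stability bounds must lie in [0, 1]")
  if (cfg$n_folds < 2) stop("n_folds must be >= 2")
  if (any(cfg$horizons <= 0)) stop("horizons must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Run the full pair-signature pipeline
#'
#' Executes the whole analysis in order — immune coexpression screen,
#' differential expression, pair construction and stability filter,
#' univariate Cox screen, cross-validated L1 Cox selection, stepwise
#' multivariate Cox, risk scoring, ROC/cutoff/grouping/Kaplan-Meier
#' evaluation, and (when annotation tables are supplied) the clinical and
#' immune/drug association tests. Any stage failure aborts with the stage
#' name and cause.
#'
#' @param expr An [expression_matrix()] with tumor and normal samples.
#' @param annotation Named biotype vector (see [extract_biotypes()]).
#' @param immune_list Character vector of immune-gene ids.
#' @param clinical Clinical table.
#' @param infiltration,checkpoint_expr,drug_scores Optional annotation
#'   tables for the association stage.
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list: `counts` (the stage funnel:
#'   `n_lnc`, `n_irlnc`, `n_de`, `n_de_up`, `n_de_down`, `n_pairs`,
#'   `n_stable`, `n_unicox`, `n_lasso`, `n_final`, `n_high`, `n_low`),
#'   `hits`, `de`, `unicox`, `signature`, `risk`, `cutoff`, `roc` (one
#'   [timed_roc()] per horizon), `km`, `associations`, `config`.
#' @export
run_pipeline <- function(expr, annotation, immune_list, clinical,
                         infiltration = NULL, checkpoint_expr = NULL,
                         drug_scores = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  counts <- list()

  parts <- stage("screen", function()
    split_by_biotype(expr, annotation, immune_list))
  counts$n_lnc <- nrow(parts$lnc$values)
  scr <- stage("screen", function()
    correlate_immune(parts$lnc, parts$irgene,
                     r_min = config$r_min, p_adj_max = config$p_adj_max))
  counts$n_irlnc <- length(scr$ids)
  if (counts$n_irlnc == 0)
    stop("stage 'screen': no immune-related lncRNA passes the ",
         "coexpression thresholds", call. = FALSE)
  de <- stage("screen", function()
    differential_expression(subset_expr(parts$lnc, features = scr$ids),
                            logfc_min = config$logfc_min,
                            fdr_max = config$fdr_max))
  de_ids <- de$lnc_id[de$de]
  counts$n_de <- length(de_ids)
  counts$n_de_up <- sum(de$de & de$direction == "up")
  counts$n_de_down <- sum(de$de & de$direction == "down")

  pm <- stage("pair", function() {
    surv_ok <- clinical$sample_id[!is.na(clinical$os_time) &
                                    !is.na(clinical$os_event)]
    tum <- tumor_samples(subset_expr(parts$lnc, features = de_ids))
    keep <- intersect(colnames(tum$values), surv_ok)
    build_pair_matrix(subset_expr(tum, samples = keep))
  })
  counts$n_pairs <- nrow(pm$values)
  pm_stable <- stage("pair", function()
    filter_stable_pairs(pm, config$stability_low, config$stability_high))
  counts$n_stable <- nrow(pm_stable$values)

  uni <- stage("fit", function()
    unicox_screen(pm_stable, clinical, alpha = config$alpha))
  counts$n_unicox <- nrow(uni)
  if (counts$n_unicox == 0)
    stop("stage 'fit': no pair passes the univariate Cox screen",
         call. = FALSE)
  sel <- stage("fit", function() {
    if (nrow(uni) == 1) uni$pair_id
    else lasso_cox_select(subset_pairs(pm_stable, pairs = uni$pair_id),
                          clinical, n_folds = config$n_folds,
                          seed = config$seed + 1L)
  })
  counts$n_lasso <- length(sel)
  sig <- stage("fit", function()
    stepwise_multicox(sel, pm_stable, clinical))
  counts$n_final <- sig$n_pairs
  risk <- stage("fit", function() compute_risk_scores(sig, pm_stable))

  rocs <- stage("evaluate", function()
    lapply(config$horizons, function(h) timed_roc(risk, clinical, h)))
  names(rocs) <- paste0("h", config$horizons)
  cut <- stage("evaluate", function()
    find_cutoff(rocs[[1]], risk, clinical, method = config$cutoff_method))
  grp <- stage("evaluate", function() assign_groups(risk, cut))
  counts$n_high <- sum(grp$risk_group == "high")
  counts$n_low <- sum(grp$risk_group == "low")
  km <- stage("evaluate", function() km_logrank(grp, clinical))

  assoc <- stage("associate", function() {
    out <- list(clinical = chisq_clinical(grp, clinical))
    sub_vars <- intersect(c("age", "gender", "grade", "stage", "t_stage",
                            "n_stage", "m_stage"), names(clinical))
    out$ranksum <- do.call(rbind, lapply(sub_vars, function(v)
      tryCatch(ranksum_by_subgroup(grp, clinical, v),
               error = function(e) NULL)))
    out$cox <- tryCatch(
      cox_independence(grp, clinical,
                       variables = intersect(c("age", "gender", "grade",
                                               "stage"), names(clinical))),
      error = function(e) NULL)
    out$subgroups <- tryCatch(
      subgroup_survival(grp, clinical, variables = sub_vars),
      error = function(e) NULL)
    if (!is.null(infiltration) || !is.null(checkpoint_expr) ||
        !is.null(drug_scores))
      out$immune_drug <- immune_drug_correlations(
        grp, infiltration, checkpoint_expr, drug_scores,
        checkpoints = config$checkpoints)
    out
  })

  structure(list(counts = counts, hits = scr$hits, de = de, unicox = uni,
                 signature = sig, risk = risk, cutoff = cut, roc = rocs,
                 groups = grp, km = km, associations = assoc,
                 config = config),
            class = "pipeline_report")
}

#' @exportS3Method print pipeline_report
print.pipeline_report <- function(x, ...) {
  c0 <- x$counts
  cat("<pipeline_report>\n")
  cat(sprintf("  funnel: %d lncRNA -> %d immune-related -> %d DE -> %d pairs -> %d stable -> %d uni-Cox -> %d L1 -> %d final\n",
              c0$n_lnc, c0$n_irlnc, c0$n_de, c0$n_pairs, c0$n_stable,
              c0$n_unicox, c0$n_lasso, c0$n_final))
  cat(sprintf("  risk groups: %d high / %d low (cutoff %.4f, %s)\n",
              c0$n_high, c0$n_low, x$cutoff$cutoff, x$cutoff$method))
  cat(sprintf("  log-rank: chisq %.2f, p %.3g; AUC at first horizon %.3f\n",
              x$km$chisq, x$km$p, x$roc[[1]]$auc))
  invisible(x)
}

#' Run the pipeline on a synthetic cohort
#'
#' Convenience wrapper wiring a [simulate_cohort()] result into
#' [run_pipeline()] using the generator's implied annotation and immune
#' list.
#'
#' @param cohort A `synthetic_cohort`.
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` (see [run_pipeline()]).
#' @export
run_pipeline_cohort <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  run_pipeline(cohort$expression, cohort_annotation(cohort),
               cohort_immune_list(cohort), cohort$clinical,
               infiltration = cohort$infiltration,
               checkpoint_expr = cohort$checkpoints,
               drug_scores = cohort$drug_scores, config = config)
}
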