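#' Identify immune-related lncRNAs by coexpression
#'
#' Tests every lncRNA x immune-gene combination for Pearson correlation
#' across the shared samples. A lncRNA is retained as immune-related when at
#' least one immune gene reaches `|r| >= r_min` with a Benjamini-Hochberg
#' adjusted p-value below `p_adj_max`; the adjustment family is the full
#' lncRNA x immune-gene grid. P-values come from the exact t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' Zero-variance features have undefined correlations; their tests are
#' excluded with a warning.
#'
#' @param lnc_expr,irgene_expr `expr_mat` objects over identical samples.
#' @param r_min Minimum absolute Pearson correlation (default 0.8, a "very
#'   strong" correlation).
#' @param p_adj_max Maximum BH-adjusted p-value (default 0.001).
#' @return List with `ids` (retained lncRNA ids, in input order) and `hits`
#'   (data.frame `lnc_id`, `irgene_id`, `r`, `p`, `p_adj` of the passing
#'   tests).
#' @export
correlate_immune <- function(lnc_expr, irgene_expr,
                             r_min = 0.8, p_adj_max = 0.001) {
  stopifnot(inherits(lnc_expr, "expr_mat"), inherits(irgene_expr, "expr_mat"))
  if (!identical(colnames(lnc_expr$values), colnames(irgene_expr$values)))
    stop("lncRNA and immune-gene matrices must share identical sample columns")
  n <- ncol(lnc_expr$values)
  if (n < 3) stop("need at least 3 samples for a correlation test")
  lv <- lnc_expr$values
  gv <- irgene_expr$values
  sd0_l <- apply(lv, 1, stats::sd) == 0
  sd0_g <- apply(gv, 1, stats::sd) == 0
  if (any(sd0_l) || any(sd0_g))
    warning("excluding ", sum(sd0_l), " lncRNA(s) and ", sum(sd0_g),
            " immune gene(s) with zero variance from correlation testing")
  r <- suppressWarnings(stats::cor(t(lv), t(gv)))
  r[sd0_l, ] <- NA_real_
  r[, sd0_g] <- NA_real_
  r2 <- pmin(r^2, 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  p_adj <- p
  p_adj[] <- stats::p.adjust(as.vector(p), method = "BH")
  pass <- !is.na(r) & abs(r) >= r_min & p_adj < p_adj_max
  idx <- which(pass, arr.ind = TRUE)
  hits <- data.frame(lnc_id = rownames(lv)[idx[, 1]],
                     irgene_id = rownames(gv)[idx[, 2]],
                     r = r[pass], p = p[pass], p_adj = p_adj[pass],
                     stringsAsFactors = FALSE)
  hits <- hits[order(match(hits$lnc_id, rownames(lv)),
                     match(hits$irgene_id, rownames(gv))), ]
  rownames(hits) <- NULL
  list(ids = rownames(lv)[rownames(lv) %in% unique(hits$lnc_id)],
       hits = hits)
}

#' Differential expression of immune-related lncRNAs
#'
#' Per-feature two-sample Wilcoxon rank-sum test of tumor versus normal
#' (tie-corrected normal approximation, no continuity correction) with
#' Benjamini-Hochberg adjustment across features. The log2 fold change is
#' the tumor - normal difference of means on the (already log2) expression
#' scale. A feature is flagged differentially expressed when
#' `|logFC| >= logfc_min` (or `logFC >= logfc_min` with
#' `absolute = FALSE`) and `fdr < fdr_max`.
#'
#' @param expr An `expr_mat` containing both tumor and normal samples
#'   (typically restricted to the immune-related lncRNAs).
#' @param logfc_min Minimum log2 fold change (default 1, i.e. two-fold).
#' @param fdr_max Maximum BH FDR (default 0.05).
#' @param absolute Use `|logFC|` (default) or the one-sided `logFC`.
#' @return data.frame with `lnc_id`, `logFC`, `p`, `fdr`, `direction`
#'   (`up`/`down`) and logical `de`.
#' @export
differential_expression <- function(expr, logfc_min = 1, fdr_max = 0.05,
                                    absolute = TRUE) {
  stopifnot(inherits(expr, "expr_mat"))
  tum <- expr$group == "tumor"
  nor <- expr$group == "normal"
  if (sum(tum) < 2 || sum(nor) < 2)
    stop("each group needs at least 2 samples for differential expression")
  v <- expr$values
  logFC <- rowMeans(v[, tum, drop = FALSE]) - rowMeans(v[, nor, drop = FALSE])
  p <- apply(v, 1, function(x) {
    if (stats::sd(x) == 0) return(1)
    stats::wilcox.test(x[tum], x[nor], exact = FALSE,
                       correct = FALSE)$p.value
  })
  fdr <- stats::p.adjust(p, method = "BH")
  thr <- if (absolute) abs(logFC) >= logfc_min else logFC >= logfc_min
  data.frame(lnc_id = rownames(v), logFC = unname(logFC), p = unname(p),
             fdr = unname(fdr),
             direction = ifelse(logFC >= 0, "up", "down"),
             de = unname(thr & fdr < fdr_max),
             stringsAsFactors = FALSE, row.names = NULL)
}
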