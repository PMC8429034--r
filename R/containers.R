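#' Construct a validated expression matrix
#'
#' Bundles a features x samples matrix of log-scale expression values with a
#' per-sample group label (`"tumor"` or `"normal"`). All downstream stages
#' (coexpression screening, differential expression, pairing) consume this
#' container.
#'
#' @param values Numeric matrix, features in rows (unique rownames), samples
#'   in columns (unique colnames). Values are assumed to be on a log scale
#'   (e.g. log2(FPKM+1)); all entries must be finite.
#' @param group Character or factor vector of `"tumor"`/`"normal"` labels,
#'   either named by sample id or in column order.
#' @return An object of class `expr_mat`: a list with elements `values`
#'   (the matrix) and `group` (named factor aligned to the columns).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, c("tumor", "tumor", "normal", "normal"))
#' em
#' @export
expression_matrix <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values`")
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries")
  group <- as.character(group)
  if (!is.null(names(group))) {
    missing <- setdiff(colnames(values), names(group))
    if (length(missing))
      stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    group <- group[colnames(values)]
  } else {
    if (length(group) != ncol(values))
      stop("`group` length does not match the number of samples")
    names(group) <- colnames(values)
  }
  bad <- setdiff(unique(group), c("tumor", "normal"))
  if (length(bad))
    stop("group labels must be 'tumor'/'normal'; found: ",
         paste(bad, collapse = ", "))
  structure(list(values = values,
                 group = factor(group, levels = c("tumor", "normal"))),
            class = "expr_mat")
}

#' @exportS3Method print expr_mat
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d features x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal")))
  invisible(x)
}

#' @exportS3Method dim expr_mat
dim.expr_mat <- function(x) dim(x$values)

#' Subset an expression matrix by features and/or samples
#'
#' @param x An `expr_mat`.
#' @param features Character vector of feature ids (or logical/integer index).
#' @param samples Character vector of sample ids (or logical/integer index).
#' @return A new `expr_mat` restricted to the requested rows/columns.
#' @export
subset_expr <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_mat"))
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, as.character(x$group[colnames(v)]))
}

#' Keep only tumor samples of an expression matrix
#'
#' The pair matrix and all survival modelling operate on the tumor cohort;
#' normal samples are only used by the screening stage.
#'
#' @param x An `expr_mat`.
#' @return An `expr_mat` with tumor columns only.
#' @export
tumor_samples <- function(x) {
  stopifnot(inherits(x, "expr_mat"))
  subset_expr(x, samples = names(x$group)[x$group == "tumor"])
}

# internal: validated clinical table. One row per sample; survival fields may
# be NA for normal samples, which never enter survival models.
validate_clinical <- function(clinical) {
  req <- c("sample_id", "os_time", "os_event")
  missing <- setdiff(req, names(clinical))
  if (length(missing))
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample ids in clinical table")
  ok <- !is.na(clinical$os_time)
  if (any(clinical$os_time[ok] < 0))
    stop("negative os_time")
  ev <- clinical$os_event[!is.na(clinical$os_event)]
  if (!all(ev %in% c(0, 1)))
    stop("os_event must be 0/1")
  clinical
}

# internal: align a risk-score table / named vector with clinical rows that
# have usable survival data; returns a data.frame with score, time, event.
align_scores_clinical <- function(scores, clinical) {
  scores <- as_risk_profile(scores)
  clinical <- validate_clinical(clinical)
  keep <- intersect(scores$sample_id,
                    clinical$sample_id[!is.na(clinical$os_time) &
                                         !is.na(clinical$os_event)])
  if (!length(keep))
    stop("no overlapping samples with survival data")
  idx_s <- match(keep, scores$sample_id)
  idx_c <- match(keep, clinical$sample_id)
  out <- data.frame(sample_id = keep,
                    score = scores$risk_score[idx_s],
                    time = clinical$os_time[idx_c],
                    event = clinical$os_event[idx_c],
                    stringsAsFactors = FALSE)
  if ("risk_group" %in% names(scores))
    out$risk_group <- scores$risk_group[idx_s]
  out
}

# internal: coerce named numeric vector or data.frame to a risk-profile
# data.frame(sample_id, risk_score [, risk_group]).
as_risk_profile <- function(scores) {
  if (is.numeric(scores) && !is.null(names(scores)))
    return(data.frame(sample_id = names(scores), risk_score = unname(scores),
                      stringsAsFactors = FALSE))
  if (is.data.frame(scores) &&
      all(c("sample_id", "risk_score") %in% names(scores)))
    return(scores)
  stop("`scores` must be a named numeric vector or a ",
       "data.frame(sample_id, risk_score)")
}
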