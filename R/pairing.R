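#' Build the binary lncRNA-pair matrix
#'
#' Encodes every unordered pair of features as a per-sample rank comparison:
#' for the pair `A|B` (canonical orientation: `A` precedes `B`
#' lexicographically) the value is 1 when `A`'s expression strictly exceeds
#' `B`'s in that sample, else 0 (ties score 0). Because only the
#' within-sample ordering enters, the matrix is invariant under any
#' strictly increasing per-sample transform of the expression values —
#' the signature built on it is independent of absolute expression levels.
#'
#' @param expr An `expr_mat`, normally restricted to the differentially
#'   expressed immune-related lncRNAs over the tumor (survival) cohort.
#' @return A `pair_mat`: list with `values` (k(k-1)/2 pairs x samples 0/1
#'   matrix, rownames `"A|B"`) and `ones_fraction` (per-pair mean).
#' @examples
#' m <- matrix(c(5, 1, 3, 4, 2, 6), 3, 2,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' build_pair_matrix(expression_matrix(m, c("tumor", "tumor")))
#' @export
build_pair_matrix <- function(expr) {
  stopifnot(inherits(expr, "expr_mat"))
  v <- expr$values
  ids <- sort(rownames(v))
  k <- length(ids)
  if (k < 2) stop("need at least 2 features to build pairs")
  v <- v[ids, , drop = FALSE]
  cmb <- utils::combn(k, 2)
  pm <- (v[cmb[1, ], , drop = FALSE] > v[cmb[2, ], , drop = FALSE]) * 1
  rownames(pm) <- paste(ids[cmb[1, ]], ids[cmb[2, ]], sep = "|")
  structure(list(values = pm, ones_fraction = rowMeans(pm)),
            class = "pair_mat")
}

#' @exportS3Method print pair_mat
print.pair_mat <- function(x, ...) {
  cat(sprintf("<pair_mat> %d pairs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Stability filter for lncRNA pairs
#'
#' Retains a pair only when its ones-fraction lies strictly between `low`
#' and `high` (defaults 20% and 80% of the patients). Pairs that are 0 or 1
#' in (almost) every patient carry no comparative information — if both
#' orderings never alternate there is nothing to pair on — and near-constant
#' indicators would also destabilize the downstream Cox fits.
#'
#' @param pm A `pair_mat` from [build_pair_matrix()].
#' @param low,high Exclusive bounds on the ones-fraction.
#' @return The filtered `pair_mat`.
#' @export
filter_stable_pairs <- function(pm, low = 0.2, high = 0.8) {
  stopifnot(inherits(pm, "pair_mat"))
  if (!(low < high)) stop("`low` must be smaller than `high`")
  keep <- pm$ones_fraction > low & pm$ones_fraction < high
  structure(list(values = pm$values[keep, , drop = FALSE],
                 ones_fraction = pm$ones_fraction[keep]),
            class = "pair_mat")
}

#' Restrict a pair matrix to given pairs and/or samples
#'
#' @param pm A `pair_mat`.
#' @param pairs Pair ids to keep (error if any is absent).
#' @param samples Sample ids to keep.
#' @return The restricted `pair_mat` (ones-fractions recomputed).
#' @export
subset_pairs <- function(pm, pairs = NULL, samples = NULL) {
  stopifnot(inherits(pm, "pair_mat"))
  v <- pm$values
  if (!is.null(pairs)) {
    miss <- setdiff(pairs, rownames(v))
    if (length(miss))
      stop("pair(s) absent from the pair matrix: ",
           paste(miss, collapse = ", "))
    v <- v[pairs, , drop = FALSE]
  }
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  structure(list(values = v, ones_fraction = rowMeans(v)),
            class = "pair_mat")
}
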