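# shared fixtures and brute-force oracles

# small cohort for fast unit tests
small_params <- function(seed = 1, ...) {
  defaults <- list(n_tumor = 120, n_normal = 40, n_lnc = 60, n_irgene = 30,
                   n_linked = 16, n_de = 8, de_log2fc = 2, n_true_pairs = 2,
                   pair_coefs = c(1, -1), noise_sd = 0.3, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

# the cohort regime used for parameter-recovery checks: 300 tumor samples,
# three planted pairs with |coef| >= 0.8, strong fold change, modest noise
recovery_params <- function(seed) {
  sim_params(n_tumor = 300, n_normal = 60, n_lnc = 120, n_irgene = 60,
             n_linked = 30, n_de = 12, de_log2fc = 2, n_true_pairs = 3,
             pair_coefs = c(1, -1, 0.9), noise_sd = 0.3, seed = seed)
}

# brute-force double-loop pair matrix (independent oracle)
brute_pair_matrix <- function(values) {
  ids <- sort(rownames(values))
  out <- NULL
  nm <- character(0)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) {
        row <- numeric(ncol(values))
        for (s in seq_len(ncol(values)))
          row[s] <- if (values[ids[i], s] > values[ids[j], s]) 1 else 0
        out <- rbind(out, row)
        nm <- c(nm, paste(ids[i], ids[j], sep = "|"))
      }
    }
  }
  rownames(out) <- nm
  colnames(out) <- colnames(values)
  out
}

# brute-force Benjamini-Hochberg step-up (independent of p.adjust)
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force Breslow negative log partial likelihood for one binary/numeric
# covariate; used to check the uni-Cox coefficient by direct maximization
brute_cox_nll <- function(beta, time, event, x) {
  eta <- beta * x
  nll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    nll <- nll - eta[i] + log(sum(exp(eta[risk])))
  }
  nll
}

# brute-force Mann-Whitney AUC by pair counting (ties count 1/2)
brute_mw_auc <- function(score_case, score_control) {
  tot <- 0
  for (a in score_case) for (b in score_control)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(score_case) * length(score_control))
}

# random expression matrix over tumor samples
random_expr <- function(nfeat, nsamp, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(nfeat * nsamp), nfeat, nsamp,
              dimnames = list(sprintf("f%02d", seq_len(nfeat)),
                              sprintf("s%02d", seq_len(nsamp))))
  expression_matrix(m, rep("tumor", nsamp))
}
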