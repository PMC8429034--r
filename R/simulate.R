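#' Simulation parameters for a synthetic cohort
#'
#' Defines the data-generating conditions for [simulate_cohort()]: a
#' tumor/normal expression matrix in which a subset of lncRNAs is tightly
#' coexpressed with immune genes, a subset of those is differentially
#' expressed between tumor and normal, and overall survival of the tumor
#' samples is driven by a small set of planted lncRNA *pairs* through a
#' proportional-hazards model on the binary within-sample rank indicators.
#'
#' Linked lncRNAs are generated as `gene + offset + N(0, noise_sd)` with a
#' unit-slope coupling to one immune gene, so their population Pearson
#' correlation with that gene is `1 / sqrt(1 + noise_sd^2 / var(gene))`.
#' The planted fold change is applied to the partner immune gene of each
#' differentially expressed (DE) lncRNA and inherited through the coupling,
#' which keeps the coexpression and DE screens jointly satisfiable. Planted
#' pair members share a baseline mean, so the pair indicator has a
#' ones-fraction near 0.5 and survives the stability filter.
#'
#' @param n_tumor,n_normal Tumor / normal sample counts.
#' @param n_lnc,n_irgene Number of lncRNA and immune-gene features.
#' @param n_linked Number of lncRNAs coupled to an immune gene.
#' @param n_de Number of differentially expressed lncRNAs (a subset of the
#'   linked ones).
#' @param de_log2fc Planted tumor - normal log2 fold change.
#' @param n_true_pairs Number of planted hazard-driving pairs (drawn from
#'   the DE lncRNAs, disjoint, so `n_de >= 2 * n_true_pairs` is required).
#' @param pair_coefs Log-hazard coefficients of the planted pairs (length
#'   `n_true_pairs`).
#' @param baseline_hazard Exponential baseline hazard rate per day.
#' @param censor_rate Exponential censoring rate per day (0 = no censoring).
#' @param noise_sd Residual SD of the lncRNA-gene coupling (log2 scale).
#' @param mixing_weight Weight in `[0, 1]` tying the infiltration /
#'   checkpoint / drug annotations to the survival linear predictor.
#' @param seed Integer seed; identical parameters give identical cohorts.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_tumor = 539, n_normal = 72,
                       n_lnc = 300, n_irgene = 120,
                       n_linked = 60, n_de = 16, de_log2fc = 2,
                       n_true_pairs = 3, pair_coefs = c(1, -1, 0.9),
                       baseline_hazard = 4e-4, censor_rate = 4e-4,
                       noise_sd = 0.3, mixing_weight = 0.6, seed = 1) {
  p <- list(n_tumor = n_tumor, n_normal = n_normal, n_lnc = n_lnc,
            n_irgene = n_irgene, n_linked = n_linked, n_de = n_de,
            de_log2fc = de_log2fc, n_true_pairs = n_true_pairs,
            pair_coefs = pair_coefs, baseline_hazard = baseline_hazard,
            censor_rate = censor_rate, noise_sd = noise_sd,
            mixing_weight = mixing_weight, seed = as.integer(seed))
  counts <- c("n_tumor", "n_normal", "n_lnc", "n_irgene", "n_linked",
              "n_de", "n_true_pairs")
  for (k in counts)
    if (length(p[[k]]) != 1 || p[[k]] < 1 || p[[k]] != round(p[[k]]))
      stop("`", k, "` must be a positive integer")
  if (p$n_linked > p$n_lnc)
    stop("n_linked exceeds n_lnc")
  if (p$n_de > p$n_linked)
    stop("n_de exceeds n_linked")
  if (p$n_true_pairs > p$n_de * (p$n_de - 1) / 2)
    stop("n_true_pairs exceeds the number of available DE pairs")
  if (2 * p$n_true_pairs > p$n_de)
    stop("planted pairs are disjoint: need n_de >= 2 * n_true_pairs")
  if (length(p$pair_coefs) != p$n_true_pairs)
    stop("pair_coefs must have length n_true_pairs")
  if (p$censor_rate < 0) stop("censor_rate must be >= 0")
  if (p$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$mixing_weight < 0 || p$mixing_weight > 1)
    stop("mixing_weight must lie in [0, 1]")
  structure(p, class = "sim_params")
}

# internal: zero-padded feature / sample ids so that lexicographic order
# equals numeric order (the pair-matrix canonicalization relies on it).
.sim_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

#' Generate the synthetic expression matrix
#'
#' @param params A [sim_params()] object.
#' @return An [expression_matrix()] with `n_lnc + n_irgene` rows and
#'   `n_tumor + n_normal` columns, plus a `truth` attribute recording the
#'   lncRNA-gene links, the DE lncRNA ids and the planted pairs
#'   (`data.frame(pair_id, lnc_a, lnc_b, coef)` in canonical orientation).
#' @export
generate_expression <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  lnc_ids <- .sim_ids("LNC", p$n_lnc)
  irg_ids <- .sim_ids("IRG", p$n_irgene)
  samp_ids <- c(.sim_ids("TUM", p$n_tumor), .sim_ids("NOR", p$n_normal))
  group <- rep(c("tumor", "normal"), c(p$n_tumor, p$n_normal))
  n_s <- length(samp_ids)
  is_tumor <- group == "tumor"

  # planted pairs: disjoint consecutive DE lncRNAs (1|2, 3|4, ...); zero-
  # padded ids make this the canonical lexicographic orientation.
  pair_a <- lnc_ids[seq(1, by = 2, length.out = p$n_true_pairs)]
  pair_b <- lnc_ids[seq(2, by = 2, length.out = p$n_true_pairs)]
  truth_pairs <- data.frame(pair_id = paste(pair_a, pair_b, sep = "|"),
                            lnc_a = pair_a, lnc_b = pair_b,
                            coef = p$pair_coefs, stringsAsFactors = FALSE)

  # immune genes: per-gene baseline mean, unit residual SD
  g_mean <- stats::runif(p$n_irgene, 2, 8)
  # partner gene of linked lncRNA i (recycled if n_linked > n_irgene)
  partner <- ((seq_len(p$n_linked) - 1) %% p$n_irgene) + 1
  # members of a planted pair share their partner gene's baseline mean so
  # the pair indicator is balanced
  for (k in seq_len(p$n_true_pairs))
    g_mean[partner[2 * k]] <- g_mean[partner[2 * k - 1]]
  # DE is planted on the partner genes of the first n_de linked lncRNAs
  de_genes <- unique(partner[seq_len(p$n_de)])
  gvals <- matrix(stats::rnorm(p$n_irgene * n_s), p$n_irgene, n_s) + g_mean
  gvals[de_genes, is_tumor] <- gvals[de_genes, is_tumor] + p$de_log2fc

  lvals <- matrix(NA_real_, p$n_lnc, n_s)
  l_off <- stats::runif(p$n_lnc, -1, 1)
  # planted pair members share their offset (balanced indicator)
  for (k in seq_len(p$n_true_pairs)) l_off[2 * k] <- l_off[2 * k - 1]
  linked <- seq_len(p$n_linked)
  lvals[linked, ] <- gvals[partner, , drop = FALSE] + l_off[linked] +
    matrix(stats::rnorm(p$n_linked * n_s, sd = p$noise_sd), p$n_linked, n_s)
  if (p$n_linked < p$n_lnc) {
    rest <- (p$n_linked + 1):p$n_lnc
    lvals[rest, ] <- matrix(stats::rnorm(length(rest) * n_s),
                            length(rest), n_s) +
      stats::runif(length(rest), 2, 8)
  }

  values <- rbind(lvals, gvals)
  dimnames(values) <- list(c(lnc_ids, irg_ids), samp_ids)
  em <- expression_matrix(values, stats::setNames(group, samp_ids))
  attr(em, "truth") <- list(
    links = data.frame(lnc_id = lnc_ids[linked],
                       irgene_id = irg_ids[partner],
                       stringsAsFactors = FALSE),
    de_ids = lnc_ids[seq_len(p$n_de)],
    pairs = truth_pairs)
  em
}

#' Generate survival and clinical covariates for the tumor samples
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(sum(coef_i * value_i))`, where `value_i` is the
#' 0/1 indicator of planted pair *i* computed from the emitted expression;
#' censoring is independent exponential. Grade/stage/T/N/M are drawn with
#' probabilities shifted toward advanced disease for samples in the top
#' tertile of the linear predictor, so clinical association tests have
#' planted signal. Normal samples get `NA` survival and staging fields.
#'
#' @param expression Output of [generate_expression()] (carries the truth
#'   attribute naming the planted pairs).
#' @param params The same [sim_params()].
#' @return Clinical data.frame with columns `sample_id`, `os_time` (days),
#'   `os_event`, `age`, `gender`, `grade`, `stage`, `t_stage`, `n_stage`,
#'   `m_stage` and `lp` (the true linear predictor; simulation ground truth,
#'   consumed by [generate_annotations()]).
#' @export
generate_survival <- function(expression, params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  truth <- attr(expression, "truth")
  if (is.null(truth))
    stop("`expression` lacks the simulation truth attribute")
  miss <- setdiff(c(truth$pairs$lnc_a, truth$pairs$lnc_b),
                  rownames(expression$values))
  if (length(miss))
    stop("planted pair references missing lncRNA(s): ",
         paste(miss, collapse = ", "))
  set.seed(p$seed + 1L)
  tum <- names(expression$group)[expression$group == "tumor"]
  nor <- names(expression$group)[expression$group == "normal"]
  v <- vapply(seq_len(nrow(truth$pairs)), function(k) {
    as.numeric(expression$values[truth$pairs$lnc_a[k], tum] >
                 expression$values[truth$pairs$lnc_b[k], tum])
  }, numeric(length(tum)))
  lp <- drop(v %*% truth$pairs$coef)
  n <- length(tum)
  t_event <- stats::rexp(n, rate = p$baseline_hazard * exp(lp))
  t_cens <- if (p$censor_rate > 0) stats::rexp(n, rate = p$censor_rate)
            else rep(Inf, n)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.numeric(t_event <= t_cens)

  top <- lp >= stats::quantile(lp, 2 / 3, names = FALSE)
  draw <- function(levels, p_base, p_top) {
    out <- character(n)
    out[!top] <- sample(levels, sum(!top), TRUE, p_base)
    out[top] <- sample(levels, sum(top), TRUE, p_top)
    out
  }
  grade <- draw(c("G1", "G2", "G3", "G4", "GX"),
                c(.04, .50, .33, .11, .02), c(.01, .24, .44, .29, .02))
  stage <- draw(c("I", "II", "III", "IV"),
                c(.58, .11, .19, .12), c(.30, .10, .29, .31))
  t_stage <- draw(c("T1", "T2", "T3", "T4"),
                  c(.58, .13, .27, .02), c(.33, .12, .49, .06))
  n_stage <- draw(c("N0", "N1", "NX"),
                  c(.45, .015, .535), c(.45, .06, .49))
  m_stage <- draw(c("M0", "M1", "MX"),
                  c(.86, .08, .06), c(.66, .28, .06))
  all_ids <- c(tum, nor)
  clin <- data.frame(
    sample_id = all_ids,
    os_time = c(os_time, rep(NA_real_, length(nor))),
    os_event = c(os_event, rep(NA_real_, length(nor))),
    age = pmin(90, pmax(26, round(stats::rnorm(length(all_ids), 60.5, 12)))),
    gender = sample(c("female", "male"), length(all_ids), TRUE, c(.35, .65)),
    grade = c(grade, rep(NA_character_, length(nor))),
    stage = c(stage, rep(NA_character_, length(nor))),
    t_stage = c(t_stage, rep(NA_character_, length(nor))),
    n_stage = c(n_stage, rep(NA_character_, length(nor))),
    m_stage = c(m_stage, rep(NA_character_, length(nor))),
    lp = c(lp, rep(NA_real_, length(nor))),
    stringsAsFactors = FALSE)
  validate_clinical(clin)
}

#' Generate immune-infiltration, checkpoint and drug-sensitivity annotations
#'
#' A `Tregs` infiltration fraction and five checkpoint genes (`PDCD1`,
#' `CD247`, `CTLA4`, `TIGIT`, `LAG3`) are generated positively correlated
#' with the survival linear predictor, and an IC50-like drug-sensitivity
#' score negatively correlated with it (higher risk, lower IC50 = more
#' sensitive); all couplings share the single `mixing_weight`: each latent
#' is `w * z + sqrt(1 - w^2) * noise` with `z` the standardized linear
#' predictor, so `w = 1` gives rank correlation 1 and `w = 0` independence.
#' Nine further cell types are independent noise.
#'
#' @param clinical Clinical table from [generate_survival()] (needs the
#'   `lp` column).
#' @param params The same [sim_params()].
#' @return List with `infiltration` (cell type x sample fractions in
#'   `[0, 1]`), `checkpoints` (gene x sample log-expression) and
#'   `drug_scores` (named per-sample numeric, lower = more sensitive).
#' @export
generate_annotations <- function(clinical, params) {
  stopifnot(inherits(params, "sim_params"))
  if (!"lp" %in% names(clinical))
    stop("clinical table lacks the `lp` linear-predictor column")
  p <- params
  set.seed(p$seed + 2L)
  keep <- !is.na(clinical$lp)
  ids <- clinical$sample_id[keep]
  n <- length(ids)
  z <- as.vector(scale(clinical$lp[keep]))
  if (anyNA(z)) z <- rep(0, n)  # degenerate: constant linear predictor
  w <- p$mixing_weight
  latent <- function() w * z + sqrt(1 - w^2) * stats::rnorm(n)

  other_cells <- c("CD8 T cells", "CD4 T cells", "NK cells", "B cells",
                   "Macrophages M1", "Macrophages M2", "Dendritic cells",
                   "Neutrophils", "Monocytes")
  infil <- rbind(Tregs = 0.05 + 0.25 * stats::pnorm(latent()),
                 t(vapply(other_cells,
                          function(ct) 0.05 + 0.25 *
                            stats::pnorm(stats::rnorm(n)),
                          numeric(n))))
  colnames(infil) <- ids
  checkpoint_genes <- c("PDCD1", "CD247", "CTLA4", "TIGIT", "LAG3")
  chk <- t(vapply(checkpoint_genes, function(g) 3 + latent(), numeric(n)))
  colnames(chk) <- ids
  drug <- stats::setNames(2 - latent(), ids)
  list(infiltration = infil, checkpoints = chk, drug_scores = drug)
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generate_expression()], [generate_survival()] and
#' [generate_annotations()] under one parameter set and bundles the result
#' with the planted ground truth, giving every downstream stage a testable
#' input without any external data.
#'
#' @param params A [sim_params()] object.
#' @return A `synthetic_cohort`: list with `expression`, `clinical`,
#'   `infiltration`, `checkpoints`, `drug_scores`, `truth` (links, DE ids,
#'   planted pairs with coefficients) and `params`.
#' @examples
#' coh <- simulate_cohort(sim_params(n_tumor = 60, n_normal = 20,
#'                                   n_lnc = 40, n_irgene = 20,
#'                                   n_linked = 12, n_de = 6, seed = 42))
#' coh$truth$pairs
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  expr <- generate_expression(params)
  clin <- generate_survival(expr, params)
  ann <- generate_annotations(clin, params)
  structure(list(expression = expr, clinical = clin,
                 infiltration = ann$infiltration,
                 checkpoints = ann$checkpoints,
                 drug_scores = ann$drug_scores,
                 truth = attr(expr, "truth"),
                 params = params),
            class = "synthetic_cohort")
}

#' @exportS3Method print synthetic_cohort
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d tumor + %d normal samples, ",
                     "%d lncRNAs / %d immune genes, %d planted pair(s)\n"),
              x$params$n_tumor, x$params$n_normal, x$params$n_lnc,
              x$params$n_irgene, nrow(x$truth$pairs)))
  invisible(x)
}

#' Biotype annotation and immune list implied by a synthetic cohort
#'
#' Convenience accessors mapping the generator's feature ids to the inputs
#' the screening stage expects.
#'
#' @param cohort A `synthetic_cohort`.
#' @return `cohort_annotation`: named biotype vector; `cohort_immune_list`:
#'   character vector of immune-gene ids.
#' @export
cohort_annotation <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ids <- rownames(cohort$expression$values)
  stats::setNames(ifelse(startsWith(ids, "LNC"), "lncRNA", "protein_coding"),
                  ids)
}

#' @rdname cohort_annotation
#' @export
cohort_immune_list <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ids <- rownames(cohort$expression$values)
  ids[startsWith(ids, "IRG")]
}
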