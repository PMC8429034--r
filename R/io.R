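#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids and whose
#' first column holds feature ids. Duplicate feature rows are collapsed by
#' their mean (with a message), matching the usual treatment of repeated
#' gene symbols after probe/locus collapsing.
#'
#' @param path Path to the TSV file.
#' @param group_map Named character vector mapping every sample id in the
#'   header to `"tumor"` or `"normal"`.
#' @param log2p1 If `TRUE`, apply `log2(x + 1)` to the values on read (for
#'   raw, non-log inputs). Default `FALSE`: values are taken as already
#'   log-scale.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, group_map, log2p1 = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (ncol(raw) < 2) stop("expression TSV needs a feature column plus samples")
  ids <- trimws(raw[[1]])
  samples <- trimws(colnames(raw)[-1])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-numeric value %s at feature row %d ('%s'), sample '%s'",
                 dQuote(vals[bad[1], bad[2]]), bad[1], ids[bad[1]],
                 samples[bad[2]]))
  }
  dimnames(num) <- list(ids, samples)
  if (anyDuplicated(ids)) {
    message("collapsing ", sum(duplicated(ids)),
            " duplicate feature row(s) by mean")
    num <- rowsum(num, group = ids) / as.vector(table(ids)[unique(ids)])
    num <- num[unique(ids), , drop = FALSE]
  }
  if (log2p1) num <- log2(num + 1)
  names(group_map) <- trimws(names(group_map))
  missing <- setdiff(samples, names(group_map))
  if (length(missing))
    stop("sample(s) missing from group_map: ", paste(missing, collapse = ", "))
  expression_matrix(num, group_map[samples])
}

#' Write an expression matrix to TSV
#'
#' @param x An `expr_mat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_mat"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table (TSV)
#'
#' The clinical table has one row per sample with columns `sample_id`,
#' `os_time` (follow-up time), `os_event` (0 censored / 1 death) and any
#' clinicopathological covariates (`age`, `gender`, `grade`, `stage`,
#' `t_stage`, `n_stage`, `m_stage`, ...).
#'
#' @param path Path to the TSV file.
#' @return `read_clinical`: a validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  df$sample_id <- trimws(as.character(df$sample_id))
  validate_clinical(df)
}

#' @rdname read_clinical
#' @param clinical Clinical data.frame to write.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an immune-gene list
#'
#' One identifier per line, blank lines and surrounding whitespace ignored.
#'
#' @param path Path to the plain-text list.
#' @return Character vector of unique ids.
#' @export
read_immune_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Extract gene biotypes from a GTF or two-column annotation file
#'
#' Maps every annotated gene to one of `protein_coding`, `lncRNA` or
#' `other`. For GTF input only `gene` feature lines are used; the biotype is
#' taken from the `gene_biotype` (Ensembl) or `gene_type` (GENCODE)
#' attribute and genes lacking both are skipped with a warning. The key is
#' `gene_name` when present, otherwise `gene_id`. With `legacy = TRUE` the
#' retired Ensembl classes `lincRNA`, `antisense`/`antisense_RNA` and
#' `processed_transcript` also count as lncRNA (annotation releases differ
#' in how they label long noncoding genes); the default recognizes the
#' modern `lncRNA` label only.
#'
#' @param path Path to a `.gtf`/`.gff` file or a two-column TSV
#'   (`feature_id`, `biotype`; header optional).
#' @param legacy Fold legacy long-noncoding biotypes into `lncRNA`.
#' @return Named character vector: feature id -> biotype
#'   (`protein_coding` / `lncRNA` / `other`).
#' @export
extract_biotypes <- function(path, legacy = FALSE) {
  lnc_labels <- "lncRNA"
  if (legacy)
    lnc_labels <- c(lnc_labels, "lincRNA", "antisense", "antisense_RNA",
                    "processed_transcript")
  if (grepl("\\.gtf(\\.gz)?$|\\.gff[23]?(\\.gz)?$", path,
            ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("rtracklayer is required to read GTF annotation")
    gr <- rtracklayer::import(path)
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    meta <- as.data.frame(gr)
    bt <- if ("gene_biotype" %in% names(meta)) meta$gene_biotype
          else if ("gene_type" %in% names(meta)) meta$gene_type
          else rep(NA_character_, nrow(meta))
    id <- if ("gene_name" %in% names(meta) && !all(is.na(meta$gene_name))) {
      ifelse(is.na(meta$gene_name) | !nzchar(meta$gene_name),
             meta$gene_id, meta$gene_name)
    } else meta$gene_id
    drop <- is.na(bt) | is.na(id)
    if (any(drop))
      warning(sum(drop), " gene record(s) lacking biotype/id attributes ",
              "were skipped")
    bt <- bt[!drop]; id <- id[!drop]
  } else {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "#")
    if (ncol(df) < 2) stop("annotation TSV needs two columns: id, biotype")
    # tolerate an optional header row
    if (identical(tolower(trimws(df[1, 1])), "feature_id") ||
        identical(tolower(trimws(df[1, 2])), "biotype"))
      df <- df[-1, , drop = FALSE]
    id <- trimws(df[[1]]); bt <- trimws(df[[2]])
  }
  out <- ifelse(bt %in% lnc_labels, "lncRNA",
                ifelse(bt == "protein_coding", "protein_coding", "other"))
  names(out) <- id
  out[!duplicated(names(out))]
}

#' Split an expression matrix into lncRNA and immune-gene submatrices
#'
#' Partitions the features into the two screening substrates: rows annotated
#' `lncRNA`, and rows annotated `protein_coding` that belong to the curated
#' immune-gene list. Row order is preserved; no feature can land in both
#' outputs.
#'
#' @param expr An [expression_matrix()].
#' @param annotation Named biotype vector from [extract_biotypes()].
#' @param immune_list Character vector of immune-gene ids.
#' @return List with elements `lnc` and `irgene`, both `expr_mat`.
#' @export
split_by_biotype <- function(expr, annotation, immune_list) {
  stopifnot(inherits(expr, "expr_mat"))
  ids <- rownames(expr$values)
  bt <- annotation[ids]
  lnc_ids <- ids[!is.na(bt) & bt == "lncRNA"]
  ir_ids <- ids[!is.na(bt) & bt == "protein_coding" & ids %in% immune_list]
  if (!length(ir_ids))
    stop("no protein-coding feature matches the immune list; ",
         "check that the list and the matrix use the same id space ",
         "(symbols vs Ensembl ids)")
  if (!length(lnc_ids))
    stop("no feature annotated as lncRNA")
  list(lnc = subset_expr(expr, features = lnc_ids),
       irgene = subset_expr(expr, features = ir_ids))
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits `expression.tsv`, `groups.tsv`, `clinical.tsv`,
#' `infiltration.tsv`, `checkpoints.tsv`, `drug_scores.tsv` and
#' `truth_pairs.tsv` in the same dialects the readers of this package
#' consume.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(sample_id = names(cohort$expression$group),
               group = as.character(cohort$expression$group)),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  wmat <- function(m, first, path) {
    utils::write.table(cbind(stats::setNames(data.frame(rownames(m)), first),
                             as.data.frame(m)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wmat(cohort$infiltration, "cell_type", file.path(dir, "infiltration.tsv"))
  wmat(cohort$checkpoints, "gene", file.path(dir, "checkpoints.tsv"))
  utils::write.table(
    data.frame(sample_id = names(cohort$drug_scores),
               drug_score = unname(cohort$drug_scores)),
    file.path(dir, "drug_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(cohort$truth$pairs, file.path(dir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read / write a binary pair matrix (TSV)
#'
#' `write_pair_matrix` emits one row per pair (`pair_id` column followed by
#' one 0/1 column per sample); `read_pair_matrix` reconstructs the
#' `pair_mat` object.
#'
#' @param pm A `pair_mat`.
#' @param path Path to the TSV file.
#' @return `read_pair_matrix`: a `pair_mat`; `write_pair_matrix`: `path`,
#'   invisibly.
#' @export
write_pair_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "pair_mat"))
  df <- data.frame(pair_id = rownames(pm$values), pm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$pair_id
  if (!all(m %in% c(0, 1))) stop("pair matrix values must be 0/1")
  structure(list(values = m, ones_fraction = rowMeans(m)),
            class = "pair_mat")
}
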