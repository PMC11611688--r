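# QC, normalization and feature selection turning raw counts into the
# model-ready matrices: log-normalized RNA restricted to highly variable
# genes, and a binarized ATAC matrix restricted to TF-IDF-informative peaks.

row_totals <- function(v) {
  if (inherits(v, "Matrix")) Matrix::rowSums(v) else rowSums(v)
}

col_totals <- function(v) {
  if (inherits(v, "Matrix")) Matrix::colSums(v) else colSums(v)
}

#' Filter low-quality RNA cells
#'
#' Removes cells with total counts below `min_counts` (default 200) and cells
#' flagged as doublets in `cell_meta$doublet_flag`. Doublet calling itself is
#' an upstream concern; the flag is a plain input column.
#'
#' @param m an RNA [omics_matrix()] of raw counts.
#' @param min_counts minimum total counts per cell.
#' @return the filtered matrix; features unchanged.
#' @export
qc_filter_rna <- function(m, min_counts = 200) {
  stopifnot(inherits(m, "omics_matrix"), m$modality == "RNA")
  v <- m$values
  if (any((if (inherits(v, "Matrix")) v@x else v) < 0)) {
    stop("negative counts in RNA matrix; qc_filter_rna expects raw counts")
  }
  keep <- row_totals(v) >= min_counts
  if (!is.null(m$cell_meta$doublet_flag)) {
    keep <- keep & !(m$cell_meta$doublet_flag %in% TRUE)
  }
  m[keep, ]
}

#' Log-normalize an RNA count matrix
#'
#' Each cell is scaled to a common library size (the median of per-cell
#' totals, unless `scale_factor` is given) and then `log1p`-transformed.
#'
#' @param m an RNA [omics_matrix()] of non-negative counts.
#' @param scale_factor target library size; default median per-cell total.
#' @return the log-normalized matrix (dense or sparse as per density).
#' @export
log_normalize <- function(m, scale_factor = NULL) {
  stopifnot(inherits(m, "omics_matrix"), m$modality == "RNA")
  tot <- row_totals(m$values)
  if (any(tot == 0)) {
    stop("zero-count cell present; run qc_filter_rna() first")
  }
  sf <- scale_factor %||% stats::median(tot)
  v <- m$values
  if (inherits(v, "Matrix")) {
    v <- Matrix::Diagonal(x = sf / tot) %*% v
    v@x <- log1p(v@x)
  } else {
    v <- log1p(v * (sf / tot))
  }
  m$values <- store_values(v)
  dimnames(m$values) <- list(m$cell_ids, m$feature_ids)
  m
}

#' Select highly variable genes
#'
#' Keeps the `n_genes` genes with the largest variance of log-normalized
#' expression (ties broken by ascending feature index); input gene order is
#' preserved among the kept genes. The dispersion statistic is pluggable via
#' `stat_fun` (a function of the values matrix returning one score per gene).
#'
#' @param m a log-normalized RNA [omics_matrix()].
#' @param n_genes number of genes to retain (default 3000).
#' @param stat_fun optional ranking statistic; default column variance.
#' @return matrix restricted to `min(n_genes, ncol)` genes.
#' @export
select_hvg <- function(m, n_genes = 3000, stat_fun = NULL) {
  stopifnot(inherits(m, "omics_matrix"), m$modality == "RNA")
  if (n_genes <= 0) stop("n_genes must be positive")
  q <- ncol(m$values)
  if (q <= n_genes) return(m)
  score <- if (is.null(stat_fun)) col_variances(m$values) else stat_fun(m$values)
  # order(-score, index) ranks by descending score, ascending index on ties
  keep <- sort(order(-score, seq_len(q))[seq_len(n_genes)])
  m[, keep]
}

col_variances <- function(v) {
  n <- nrow(v)
  if (n < 2) return(rep(0, ncol(v)))
  mu <- col_totals(v) / n
  ex2 <- if (inherits(v, "Matrix")) Matrix::colSums(v^2) else colSums(v^2)
  (ex2 - n * mu^2) / (n - 1)
}

#' Filter low-quality ATAC cells
#'
#' Removes cells with TSS enrichment below `min_tss` (default 2.0), sequencing
#' depth below `min_depth` (default 1000), or a doublet flag. TSS enrichment
#' is an input column in `cell_meta` (computing it from fragments is out of
#' scope here).
#'
#' @param m an ATAC [omics_matrix()]; `cell_meta` must carry
#'   `tss_enrichment` and `depth`.
#' @param min_tss,min_depth QC thresholds.
#' @return the filtered matrix.
#' @export
qc_filter_atac <- function(m, min_tss = 2.0, min_depth = 1000) {
  stopifnot(inherits(m, "omics_matrix"), m$modality == "ATAC")
  if (is.null(m$cell_meta$tss_enrichment)) {
    stop("cell_meta lacks a 'tss_enrichment' column")
  }
  if (is.null(m$cell_meta$depth)) stop("cell_meta lacks a 'depth' column")
  keep <- m$cell_meta$tss_enrichment >= min_tss &
    m$cell_meta$depth >= min_depth
  if (!is.null(m$cell_meta$doublet_flag)) {
    keep <- keep & !(m$cell_meta$doublet_flag %in% TRUE)
  }
  m[keep %in% TRUE, ]
}

#' TF-IDF peak selection
#'
#' Applies a TF-IDF transform (term frequency = count / cell total; IDF =
#' `log(1 + n_cells / (1 + n_cells_with_peak))`), scores each peak by the sum
#' of its TF-IDF weights over cells, keeps the `n_peaks` most informative
#' peaks (ties broken by ascending index, all-zero peaks ranked last), and
#' re-binarizes the output.
#'
#' @param m an ATAC [omics_matrix()], binary or counts.
#' @param n_peaks number of peaks to retain (default 100000).
#' @return binarized matrix restricted to `min(n_peaks, ncol)` peaks.
#' @export
tfidf_select_peaks <- function(m, n_peaks = 100000) {
  stopifnot(inherits(m, "omics_matrix"), m$modality == "ATAC")
  if (n_peaks <= 0) stop("n_peaks must be positive")
  p <- ncol(m$values)
  if (p > n_peaks) {
    score <- tfidf_peak_scores(m$values)
    keep <- sort(order(-score, seq_len(p))[seq_len(n_peaks)])
    m <- m[, keep]
  }
  binarize(m)
}

tfidf_peak_scores <- function(v) {
  n_cells <- nrow(v)
  tot <- row_totals(v)
  tot[tot == 0] <- 1
  tf <- if (inherits(v, "Matrix")) {
    Matrix::Diagonal(x = 1 / tot) %*% v
  } else {
    v / tot
  }
  n_with <- if (inherits(v, "Matrix")) {
    Matrix::colSums(v > 0)
  } else {
    colSums(v > 0)
  }
  idf <- log(1 + n_cells / (1 + n_with))
  as.numeric(col_totals(tf) * idf)
}

#' Binarize an ATAC matrix
#'
#' Values greater than zero become 1; idempotent, preserves the number of
#' nonzeros.
#'
#' @param m an ATAC [omics_matrix()].
#' @return the binarized matrix.
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  if (inherits(v, "Matrix")) {
    v@x <- as.numeric(v@x > 0)
    v <- Matrix::drop0(v)
  } else {
    v <- (v > 0) * 1
  }
  m$values <- v
  dimnames(m$values) <- list(m$cell_ids, m$feature_ids)
  m
}
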