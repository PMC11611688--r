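# On-disk forms: 10x-style Matrix Market directory (matrix.mtx stored
# features x cells, features.tsv, barcodes.tsv, optional cell_meta.tsv),
# or a single dense TSV (cells in rows) for toy inputs.

#' Read an omics matrix from a directory
#'
#' Accepts either a 10x-style sparse directory (`matrix.mtx` +
#' `features.tsv` + `barcodes.tsv`, matrix stored features x cells) or a
#' dense TSV (`dense.tsv`, cells in rows, row and column names present).
#' A `cell_meta.tsv` file, if present, is joined onto the cells. For ATAC,
#' feature names of the form `"chr1:100-200"` are parsed into peak
#' annotations.
#'
#' @param path directory produced by [write_matrix_dir()] or by 10x tooling.
#' @param modality `"RNA"` or `"ATAC"`.
#' @return an [omics_matrix()].
#' @export
read_matrix_dir <- function(path, modality = c("RNA", "ATAC")) {
  modality <- match.arg(modality)
  if (!dir.exists(path)) stop("no such directory: ", path)
  mtx <- file.path(path, "matrix.mtx")
  dense <- file.path(path, "dense.tsv")
  if (file.exists(mtx)) {
    feats <- file.path(path, "features.tsv")
    bars <- file.path(path, "barcodes.tsv")
    for (f in c(feats, bars)) {
      if (!file.exists(f)) stop("missing file: ", f)
    }
    values <- Matrix::t(Matrix::readMM(mtx))
    if (is(values, "nMatrix")) {      # pattern matrices read back as 0/1
      values <- as(values, "dMatrix")
    }
    feature_ids <- readLines(feats)
    cell_ids <- readLines(bars)
    if (nrow(values) != length(cell_ids) ||
        ncol(values) != length(feature_ids)) {
      stop("matrix dimensions (", ncol(values), " x ", nrow(values),
           " features x cells) do not match id tables (",
           length(feature_ids), " features, ", length(cell_ids), " cells)")
    }
  } else if (file.exists(dense)) {
    tab <- utils::read.table(dense, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    values <- as.matrix(tab)
    cell_ids <- rownames(tab)
    feature_ids <- colnames(tab)
  } else {
    stop("missing file: neither ", mtx, " nor ", dense, " exists")
  }
  meta_file <- file.path(path, "cell_meta.tsv")
  cell_meta <- if (file.exists(meta_file)) {
    utils::read.table(meta_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
  } else NULL
  omics_matrix(values, modality = modality, cell_ids = cell_ids,
               feature_ids = feature_ids, cell_meta = cell_meta)
}

#' Write an omics matrix to a directory
#'
#' Writes the 10x-style sparse triplet form (`matrix.mtx` features x cells,
#' `features.tsv`, `barcodes.tsv`) plus `cell_meta.tsv` when metadata is
#' present. Binary ATAC matrices are written with integer-coded triplets.
#' `read_matrix_dir(write_matrix_dir(m))` reproduces values, ids and
#' annotations exactly.
#'
#' @param m an [omics_matrix()].
#' @param path output directory (created if absent).
#' @export
write_matrix_dir <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  v <- m$values
  if (!inherits(v, "Matrix")) v <- Matrix::Matrix(v, sparse = TRUE)
  v <- as(as(v, "generalMatrix"), "CsparseMatrix")
  if (all(v@x == round(v@x))) {
    v <- as(v, "dMatrix") * 1      # Matrix Market integer-compatible values
  }
  Matrix::writeMM(Matrix::t(v), file.path(path, "matrix.mtx"))
  writeLines(m$feature_ids, file.path(path, "features.tsv"))
  writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
  if (ncol(m$cell_meta) > 1) {
    utils::write.table(m$cell_meta, file.path(path, "cell_meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Export peak annotations as BED
#'
#' BED uses the same 0-based half-open convention as the internal peak
#' annotation, so coordinates are written unchanged. An optional score per
#' peak goes in the BED score column.
#'
#' @param ann peak annotation data frame (`chrom`, `start`, `end`).
#' @param file output path.
#' @param scores optional numeric vector, one per peak.
#' @param names optional peak names; default `chrom:start-end`.
#' @export
write_bed <- function(ann, file, scores = NULL, names = NULL) {
  ann <- check_peak_annotation(ann, nrow(ann))
  out <- data.frame(ann$chrom, as.integer(ann$start), as.integer(ann$end),
                    names %||% format_peak_names(ann),
                    scores %||% rep(0, nrow(ann)))
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
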