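#' Cells-by-features omics matrix
#'
#' The central container of the package: a cells x features numeric matrix
#' tagged with a modality (`"RNA"` for cell-by-gene expression, `"ATAC"` for
#' cell-by-peak accessibility), per-cell metadata, and — for ATAC — one genomic
#' interval per peak. Values are stored sparse (\pkg{Matrix}) whenever density
#' is below 50%; the numeric contract is identical either way.
#'
#' @param values numeric matrix or `Matrix` sparse matrix, cells in rows.
#' @param modality `"RNA"` or `"ATAC"`.
#' @param cell_ids unique barcode strings, one per row. Defaults to rownames.
#' @param feature_ids unique feature names, one per column. For ATAC, names of
#'   the form `"chr1:100-200"` are parsed into peak annotations automatically.
#' @param cell_meta optional data frame keyed by a `cell_id` column; recognised
#'   columns include `cell_type`, `batch`, `depth`, `tss_enrichment`,
#'   `doublet_flag`.
#' @param feature_meta optional data frame of peak annotations with columns
#'   `chrom`, `start`, `end` (0-based half-open) and optional `strand`.
#' @return an `omics_matrix` object.
#' @export
omics_matrix <- function(values, modality = c("RNA", "ATAC"), cell_ids = NULL,
                         feature_ids = NULL, cell_meta = NULL,
                         feature_meta = NULL) {
  modality <- match.arg(modality)
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(feature_ids)) feature_ids <- colnames(values)
  if (is.null(cell_ids) && !is.null(cell_meta) &&
      !is.null(cell_meta$cell_id) && nrow(cell_meta) == nrow(values)) {
    cell_ids <- as.character(cell_meta$cell_id)
  }
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(values)))
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("feat_%d", seq_len(ncol(values)))
  }
  if (nrow(values) != length(cell_ids)) {
    stop("row count (", nrow(values), ") != number of cell ids (",
         length(cell_ids), ")")
  }
  if (ncol(values) != length(feature_ids)) {
    stop("column count (", ncol(values), ") != number of feature ids (",
         length(feature_ids), ")")
  }
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique")
  if (anyDuplicated(feature_ids)) stop("feature ids must be unique")

  values <- store_values(values)
  dimnames(values) <- list(cell_ids, feature_ids)

  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = cell_ids, stringsAsFactors = FALSE)
  } else {
    cell_meta <- check_cell_meta(cell_meta, cell_ids)
  }

  if (modality == "ATAC" && is.null(feature_meta) &&
      all(grepl("^[^:]+:[0-9]+-[0-9]+$", feature_ids))) {
    feature_meta <- parse_peak_names(feature_ids)
  }
  if (!is.null(feature_meta)) {
    feature_meta <- check_peak_annotation(feature_meta, length(feature_ids))
  }

  structure(
    list(values = values, modality = modality, cell_ids = cell_ids,
         feature_ids = feature_ids, cell_meta = cell_meta,
         feature_meta = feature_meta),
    class = "omics_matrix"
  )
}

# Sparse below 50% density, dense otherwise.
store_values <- function(values) {
  if (inherits(values, "Matrix")) {
    dens <- Matrix::nnzero(values) / max(1, prod(dim(values)))
    if (dens >= 0.5) return(as.matrix(values))
    return(as(as(values, "generalMatrix"), "CsparseMatrix"))
  }
  values <- as.matrix(values)
  if (prod(dim(values)) > 0 && mean(values != 0) < 0.5) {
    return(as(as(Matrix::Matrix(values, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix"))
  }
  values
}

check_cell_meta <- function(cell_meta, cell_ids) {
  cell_meta <- as.data.frame(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) {
    stop("cell_meta must have a 'cell_id' column")
  }
  if (anyDuplicated(cell_meta$cell_id)) {
    stop("duplicate keys in cell metadata: ",
         paste(unique(cell_meta$cell_id[duplicated(cell_meta$cell_id)]),
               collapse = ", "))
  }
  idx <- match(cell_ids, cell_meta$cell_id)
  out <- cell_meta[idx, , drop = FALSE]
  out$cell_id <- cell_ids
  rownames(out) <- NULL
  out
}

check_peak_annotation <- function(ann, p) {
  ann <- as.data.frame(ann)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(ann))) {
    stop("peak annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(ann) != p) stop("peak annotation has ", nrow(ann),
                           " rows but there are ", p, " features")
  if (any(!nzchar(ann$chrom))) stop("empty chromosome name in peak annotation")
  if (any(ann$start >= ann$end)) {
    stop("peak annotation requires start < end (0-based half-open)")
  }
  rownames(ann) <- NULL
  ann
}

#' Parse 10x-style peak names into genomic intervals
#'
#' `"chr1:100-200"` becomes the 0-based half-open interval
#' `[100, 200)` on `chr1`. [format_peak_names()] is the exact inverse.
#'
#' @param ids character vector of peak names.
#' @return data frame with columns `chrom`, `start`, `end`.
#' @export
parse_peak_names <- function(ids) {
  ok <- grepl("^[^:]+:[0-9]+-[0-9]+$", ids)
  if (!all(ok)) {
    stop("unparseable peak names: ",
         paste(utils::head(ids[!ok], 5), collapse = ", "))
  }
  chrom <- sub(":.*$", "", ids)
  rest <- sub("^[^:]+:", "", ids)
  start <- as.integer(sub("-.*$", "", rest))
  end <- as.integer(sub("^.*-", "", rest))
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' @rdname parse_peak_names
#' @param ann peak annotation data frame.
#' @export
format_peak_names <- function(ann) {
  sprintf("%s:%d-%d", ann$chrom, as.integer(ann$start), as.integer(ann$end))
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  dens <- if (prod(dim(x)) > 0) {
    if (inherits(x$values, "Matrix")) {
      Matrix::nnzero(x$values) / prod(dim(x))
    } else {
      mean(x$values != 0)
    }
  } else NA_real_
  cat(sprintf("<omics_matrix> %s: %d cells x %d features (density %.3f)\n",
              x$modality, nrow(x$values), ncol(x$values), dens))
  meta_cols <- setdiff(names(x$cell_meta), "cell_id")
  if (length(meta_cols)) {
    cat("  cell_meta:", paste(meta_cols, collapse = ", "), "\n")
  }
  if (!is.null(x$feature_meta)) {
    cat("  peaks on:", paste(unique(x$feature_meta$chrom), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Subset an omics matrix by cells and/or features
#'
#' @param x an `omics_matrix`.
#' @param i,j cell / feature index vectors (integer, logical or names).
#' @param ... ignored.
#' @export
`[.omics_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$cell_ids)
  if (is.character(j)) j <- match(j, x$feature_ids)
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  omics_matrix(
    values = x$values[i, j, drop = FALSE],
    modality = x$modality,
    cell_ids = x$cell_ids[i],
    feature_ids = x$feature_ids[j],
    cell_meta = x$cell_meta[i, , drop = FALSE],
    feature_meta = if (!is.null(x$feature_meta)) {
      x$feature_meta[j, , drop = FALSE]
    }
  )
}

#' Attach or replace per-cell metadata
#'
#' Left-joins `meta_table` (keyed by `cell_id`) onto the matrix's cells. Cells
#' absent from `meta_table` get `NA` metadata; cell order is preserved, and
#' the row order of `meta_table` is immaterial.
#'
#' @param m an `omics_matrix`.
#' @param meta_table data frame with a `cell_id` key column.
#' @return the matrix with updated `cell_meta`.
#' @export
align_metadata <- function(m, meta_table) {
  stopifnot(inherits(m, "omics_matrix"))
  m$cell_meta <- check_cell_meta(meta_table, m$cell_ids)
  m
}

#' Latent embedding of cells
#'
#' A cells x k matrix of latent coordinates produced by an encoder
#' (`mapped = FALSE`) or by a cross-modality mapper (`mapped = TRUE`).
#'
#' @param values numeric matrix, cells in rows.
#' @param source_modality modality the cells came from.
#' @param cell_ids barcodes aligned to the source matrix.
#' @param mapped whether the values passed through a cross-modality mapper.
#' @export
embedding <- function(values, source_modality = c("RNA", "ATAC"),
                      cell_ids = NULL, mapped = FALSE) {
  source_modality <- match.arg(source_modality)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("embedding values must be finite")
  if (is.null(cell_ids)) cell_ids <- rownames(values) %||%
      sprintf("cell_%d", seq_len(nrow(values)))
  rownames(values) <- cell_ids
  structure(
    list(values = values, k = ncol(values), source_modality = source_modality,
         mapped = mapped, cell_ids = cell_ids),
    class = "embedding"
  )
}

#' @export
dim.embedding <- function(x) dim(x$values)

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d cells x k=%d (%s%s)\n", nrow(x$values), x$k,
              x$source_modality, if (x$mapped) ", mapped" else ""))
  invisible(x)
}

#' Stack embeddings from several modalities into one joint embedding
#'
#' @param ... embeddings with equal `k`.
#' @return list with `values` (stacked matrix), `modality` (label per row)
#'   and `cell_ids`.
#' @export
bind_embeddings <- function(...) {
  embs <- list(...)
  stopifnot(length(embs) >= 1, all(vapply(embs, inherits, TRUE, "embedding")))
  ks <- vapply(embs, function(e) e$k, 1L)
  if (length(unique(ks)) != 1) stop("embeddings have different k")
  list(
    values = do.call(rbind, lapply(embs, function(e) e$values)),
    modality = unlist(lapply(embs, function(e) {
      rep(e$source_modality, nrow(e$values))
    })),
    cell_ids = unlist(lapply(embs, function(e) e$cell_ids))
  )
}
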