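# In-silico perturbation: integrated gradients of the deterministic
# ATAC -> RNA map with respect to the binary peak input, scoring each peak's
# importance for one target gene. The attribution path runs from a baseline
# (all-zeros: fully inaccessible chromatin) to the observed cell along the
# straight line, with a midpoint Riemann sum over n_steps; the completeness
# identity sum(IG) = F(x) - F(baseline) is computed and attached for every
# call. Bernoulli sampling never enters the attributed map (gradients of
# sampled outputs are undefined).

# scalar map: translated expression of `gene_idx` for a batch of ATAC inputs
atac_to_gene_forward <- function(model, X, gene_idx, keep_cache = FALSE) {
  fe <- atac_encode_forward(model$enc_atac, X, model$chrom_layout, keep_cache)
  fg <- mlp_forward(model$mapper_ar, fe$out, keep_cache)
  fd <- mlp_forward(model$dec_rna, fg$out, keep_cache)
  list(value = fd$out[, gene_idx], fe = fe, fg = fg, fd = fd)
}

# gradient of the gene output wrt every peak input, one row per batch row
atac_to_gene_grad <- function(model, X) {
  function(fw, gene_idx) {
    dOut <- matrix(0, nrow(fw$fd$out), ncol(fw$fd$out))
    dOut[, gene_idx] <- 1
    bd <- mlp_backward(model$dec_rna, fw$fd, dOut = dOut)
    bg <- mlp_backward(model$mapper_ar, fw$fg, dOut = bd$dX)
    be <- atac_encode_backward(model$enc_atac, fw$fe, model$chrom_layout,
                               dZ = bg$dX, need_dx = TRUE, p = model$p)
    be$dX
  }
}

#' Integrated-gradients attribution of one gene to all peaks
#'
#' Scores peak `i` as `(x_i - b_i)` times the midpoint Riemann approximation
#' of the path integral of `dF/dx_i` from baseline `b` to the cell `x`,
#' where `F` is the translated expression of `gene` under the deterministic
#' ATAC-to-RNA map.
#'
#' @param model a trained `scact_model`.
#' @param x one ATAC cell: numeric vector of length `p` (or 1-row matrix).
#' @param gene target gene id (must be in the model's RNA feature set) or
#'   column index.
#' @param baseline baseline vector (default all zeros, i.e. inaccessible
#'   chromatin) or `"celltype_mean"` handled by [group_attribution()].
#' @param n_steps Riemann steps (default 64).
#' @return an `attribution_result`: per-peak scores plus the completeness
#'   diagnostics `f_x`, `f_baseline` and `sum(scores)`.
#' @export
integrated_gradients <- function(model, x, gene, baseline = NULL,
                                 n_steps = 64) {
  stopifnot(inherits(model, "scact_model"))
  if (n_steps < 1) stop("n_steps must be >= 1")
  x <- as.numeric(x)
  if (length(x) != model$p) {
    stop("input has ", length(x), " peaks; model expects ", model$p)
  }
  gene_idx <- resolve_gene(model, gene)
  b <- if (is.null(baseline)) numeric(model$p) else as.numeric(baseline)
  stopifnot(length(b) == model$p)

  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  diff <- x - b
  Xs <- outer(alphas, diff) + matrix(b, n_steps, model$p, byrow = TRUE)
  fw <- atac_to_gene_forward(model, Xs, gene_idx, keep_cache = TRUE)
  dX <- atac_to_gene_grad(model, Xs)(fw, gene_idx)
  scores <- diff * colMeans(dX)

  f_x <- atac_to_gene_forward(model, matrix(x, 1), gene_idx)$value
  f_b <- atac_to_gene_forward(model, matrix(b, 1), gene_idx)$value
  structure(list(
    gene = if (is.character(gene)) gene else model$rna_features[gene_idx],
    scores = setNames(as.numeric(scores), model$atac_features),
    cell_scope = "cell", n_steps = as.integer(n_steps),
    baseline_kind = if (all(b == 0)) "zeros" else "custom",
    f_x = as.numeric(f_x), f_baseline = as.numeric(f_b),
    completeness_gap = abs(sum(scores) - (f_x - f_b))
  ), class = "attribution_result")
}

resolve_gene <- function(model, gene) {
  if (is.character(gene)) {
    idx <- match(gene, model$rna_features)
    if (is.na(idx)) stop("gene not found in RNA feature set: ", gene)
    idx
  } else {
    stopifnot(gene >= 1, gene <= model$q)
    as.integer(gene)
  }
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf(
    "<attribution_result> gene %s (%s), %d peaks, %d steps, baseline %s\n",
    x$gene, x$cell_scope, length(x$scores), x$n_steps, x$baseline_kind))
  cat(sprintf("  F(x)=%.4g F(baseline)=%.4g completeness gap %.3g\n",
              x$f_x, x$f_baseline, x$completeness_gap))
  invisible(x)
}

#' @method tidy attribution_result
#' @export
tidy.attribution_result <- function(x, ...) {
  tibble::tibble(peak_id = names(x$scores), peak_index = seq_along(x$scores),
                 score = as.numeric(x$scores), gene = x$gene)
}

#' Rank peaks by attribution score
#'
#' @param attr an `attribution_result`.
#' @param top_n how many peaks to return (default 5; capped at `p`).
#' @param annotations optional peak annotation data frame to attach
#'   coordinates.
#' @return tibble sorted by descending score; ties broken by ascending peak
#'   index.
#' @export
rank_peaks <- function(attr, top_n = 5, annotations = NULL) {
  stopifnot(inherits(attr, "attribution_result"))
  p <- length(attr$scores)
  top_n <- min(top_n, p)
  ord <- order(-attr$scores, seq_len(p))[seq_len(top_n)]
  out <- tibble::tibble(
    rank = seq_len(top_n), peak_index = ord,
    peak_id = names(attr$scores)[ord],
    score = as.numeric(attr$scores[ord]), gene = attr$gene)
  if (!is.null(annotations)) {
    out$chrom <- annotations$chrom[ord]
    out$start <- annotations$start[ord]
    out$end <- annotations$end[ord]
  }
  out
}

#' Group-wise mean attributions and top-peak accessibility
#'
#' Computes per-cell integrated gradients for (a subsample of) the cells of
#' each group, averages the scores within groups, and reports the mean
#' observed accessibility of each group's top-ranked peaks — the in-group
#' versus out-group contrast used to validate candidate regulatory peaks.
#'
#' @param model a trained `scact_model`.
#' @param cells binarized ATAC [omics_matrix()].
#' @param gene target gene id.
#' @param group_labels one label per cell; defaults to
#'   `cell_meta$cell_type`.
#' @param n_steps,baseline passed to [integrated_gradients()];
#'   `baseline = "celltype_mean"` uses each group's mean profile.
#' @param top_n peaks reported in the accessibility table.
#' @param max_cells_per_group per-group subsample cap (seeded).
#' @param seed subsampling seed.
#' @return a `group_attribution`: named list of mean `attribution_result`s
#'   (`$attributions`), plus `$accessibility`, a tibble of per-group mean
#'   accessibility of each group's top peaks.
#' @export
group_attribution <- function(model, cells, gene, group_labels = NULL,
                              n_steps = 32, baseline = NULL, top_n = 5,
                              max_cells_per_group = 50, seed = 1) {
  stopifnot(inherits(model, "scact_model"), inherits(cells, "omics_matrix"))
  group_labels <- group_labels %||% cells$cell_meta$cell_type
  if (is.null(group_labels)) stop("no group labels available")
  stopifnot(length(group_labels) == nrow(cells$values))
  groups <- unique(group_labels)
  Xd <- as_dense(cells$values)
  gene_name <- if (is.character(gene)) gene else
    model$rna_features[resolve_gene(model, gene)]

  attributions <- list()
  acc_rows <- list()
  for (grp in groups) {
    idx <- which(group_labels == grp)
    if (length(idx) == 0) stop("empty group: ", grp)
    use <- if (length(idx) > max_cells_per_group) {
      with_seed(derive_seed(seed, paste0("grp_", grp)),
                sample(idx, max_cells_per_group))
    } else idx
    base <- if (identical(baseline, "celltype_mean")) {
      colMeans(Xd[idx, , drop = FALSE])
    } else baseline
    score_sum <- numeric(model$p)
    gap <- 0
    for (i in use) {
      a <- integrated_gradients(model, Xd[i, ], gene, baseline = base,
                                n_steps = n_steps)
      score_sum <- score_sum + a$scores
      gap <- gap + a$completeness_gap
    }
    mean_attr <- structure(list(
      gene = gene_name,
      scores = setNames(score_sum / length(use), model$atac_features),
      cell_scope = as.character(grp), n_steps = as.integer(n_steps),
      baseline_kind = if (identical(baseline, "celltype_mean"))
        "celltype_mean" else if (is.null(baseline)) "zeros" else "custom",
      f_x = NA_real_, f_baseline = NA_real_,
      completeness_gap = gap / length(use)
    ), class = "attribution_result")
    attributions[[as.character(grp)]] <- mean_attr

    top <- rank_peaks(mean_attr, top_n = top_n,
                      annotations = model$peak_annotation)
    for (g2 in groups) {
      idx2 <- which(group_labels == g2)
      acc_rows[[length(acc_rows) + 1]] <- tibble::tibble(
        attribution_group = as.character(grp),
        accessibility_group = as.character(g2),
        peak_id = top$peak_id, peak_index = top$peak_index,
        rank = top$rank, score = top$score,
        mean_accessibility =
          colMeans(Xd[idx2, top$peak_index, drop = FALSE]))
    }
  }
  structure(list(gene = gene_name, attributions = attributions,
                 accessibility = do.call(rbind, acc_rows)),
            class = "group_attribution")
}

#' @export
print.group_attribution <- function(x, ...) {
  cat(sprintf("<group_attribution> gene %s, groups: %s\n", x$gene,
              paste(names(x$attributions), collapse = ", ")))
  invisible(x)
}
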