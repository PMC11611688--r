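# Benchmarking statistics: neighbourhood modality mixing, global homogeneity
# (silhouette / ARI / AMI), within-type pairwise cosine distances,
# translation AUROC and R-squared, motif activation scores over upstream
# TSS windows, and pseudo-bulk peak-to-gene linkage.

#' Modality mixing score
#'
#' For each cell type, repeatedly samples one of its cells from the joint
#' embedding, finds the `n_neighbors` nearest cells by cosine distance, and
#' computes `m = 1 - |c_A / (c_A + c_R) - 0.5|` where `c_A`/`c_R` count
#' ATAC/RNA neighbours. A perfectly balanced neighbourhood scores 1; an
#' all-one-modality neighbourhood scores 0.5. Scores are averaged over
#' `n_draws` seeded draws (the single first-draw value is reported
#' alongside). Cell types with fewer than `n_neighbors + 1` cells available
#' fall back to all available cells with a warning.
#'
#' @param emb_joint a joint embedding: either a [bind_embeddings()] result or
#'   a plain matrix.
#' @param modality_labels `"RNA"`/`"ATAC"` per row (taken from `emb_joint`
#'   when it carries them).
#' @param cell_type_labels cell-type label per row.
#' @param n_neighbors neighbourhood size (default 1000).
#' @param n_draws number of sampled probe cells per type (default 50).
#' @param seed sampling seed.
#' @return tibble with `cell_type`, `score` (mean over draws),
#'   `score_first_draw`, `n_draws`, `n_neighbors_used`.
#' @export
modality_mixing_score <- function(emb_joint, modality_labels = NULL,
                                  cell_type_labels, n_neighbors = 1000,
                                  n_draws = 50, seed = 1) {
  if (is.list(emb_joint) && !is.null(emb_joint$values)) {
    modality_labels <- modality_labels %||% emb_joint$modality
    emb <- emb_joint$values
  } else {
    emb <- as.matrix(emb_joint)
  }
  stopifnot(!is.null(modality_labels),
            length(modality_labels) == nrow(emb),
            length(cell_type_labels) == nrow(emb))
  if (!all(c("RNA", "ATAC") %in% modality_labels)) {
    stop("joint embedding must contain both modalities")
  }
  types <- unique(cell_type_labels)
  norm_emb <- l2_normalize_rows(emb)
  rows <- lapply(types, function(t) {
    idx <- which(cell_type_labels == t)
    k_use <- n_neighbors
    if (nrow(emb) - 1 < n_neighbors) {
      k_use <- nrow(emb) - 1
      warning("fewer than n_neighbors + 1 cells; using all ", k_use,
              " available cells for type ", t)
    }
    draws <- with_seed(derive_seed(seed, paste0("mix_", t)), {
      probes <- sample(idx, n_draws, replace = TRUE)
      vapply(probes, function(pi) {
        d <- 1 - as.numeric(norm_emb %*% norm_emb[pi, ])
        d[pi] <- Inf
        nn <- order(d)[seq_len(k_use)]
        c_a <- sum(modality_labels[nn] == "ATAC")
        c_r <- k_use - c_a
        mixing_score_from_counts(c_a, c_r)
      }, 1)
    })
    tibble::tibble(cell_type = t, score = mean(draws),
                   score_first_draw = draws[1], n_draws = n_draws,
                   n_neighbors_used = k_use)
  })
  do.call(rbind, rows)
}

#' @rdname modality_mixing_score
#' @param c_a,c_r ATAC and RNA neighbour counts.
#' @export
mixing_score_from_counts <- function(c_a, c_r) {
  1 - abs(c_a / (c_a + c_r) - 0.5)
}

#' Global homogeneity of a labelled embedding
#'
#' Mean silhouette width on cosine distance against the given labels, plus
#' adjusted Rand index and adjusted mutual information between the labels
#' and a clustering of the embedding (k-means with as many centres as
#' labels by default; pluggable via `cluster_fun`).
#'
#' @param emb_joint matrix or [bind_embeddings()] result.
#' @param labels ground-truth labels (>= 2 distinct values).
#' @param cluster_fun function(matrix, k) returning integer cluster ids.
#' @param seed clustering seed.
#' @return tibble with `silhouette`, `ari`, `ami`.
#' @export
global_homogeneity <- function(emb_joint, labels, cluster_fun = NULL,
                               seed = 1) {
  emb <- if (is.list(emb_joint) && !is.null(emb_joint$values)) {
    emb_joint$values
  } else {
    as.matrix(emb_joint)
  }
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("silhouette undefined for a single label")
  }
  d <- stats::as.dist(cosine_distance(emb))
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  cl <- if (is.null(cluster_fun)) {
    with_seed(seed,
              kmeans(emb, centers = length(unique(labels)),
                     nstart = 10)$cluster)
  } else {
    cluster_fun(emb, length(unique(labels)))
  }
  tibble::tibble(silhouette = mean(sil[, "sil_width"]),
                 ari = adjusted_rand_index(cl, labels),
                 ami = adjusted_mutual_information(cl, labels))
}

# ARI from the pair-counting form of the contingency table.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  as.numeric((sum_ij - expected) / (max_index - expected))
}

# AMI with the expected mutual information under the hypergeometric model of
# fixed marginals, normalized by max(H(U), H(V)).
adjusted_mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  p <- tab / n
  pi_ <- ai / n
  pj <- bj / n
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    if (tab[i, j] > 0) {
      mi <- mi + p[i, j] * log(p[i, j] / (pi_[i] * pj[j]))
    }
  }
  h_a <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h_b <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    lo <- max(ai[i] + bj[j] - n, 1)
    hi <- min(ai[i], bj[j])
    if (lo > hi) next
    for (nij in lo:hi) {
      term <- exp(lchoose(bj[j], nij) + lchoose(n - bj[j], ai[i] - nij) -
                    lchoose(n, ai[i]))
      emi <- emi + (nij / n) * log(n * nij / (ai[i] * bj[j])) * term
    }
  }
  denom <- max(h_a, h_b) - emi
  if (denom == 0) return(0)
  as.numeric((mi - emi) / denom)
}

#' Within-type pairwise cosine distance distributions and two-sample tests
#'
#' For each cell type, collects the pairwise cosine distances between its
#' cells under two embeddings of the same cells (e.g. two methods), with
#' seeded subsampling above `max_pairs` pairs, and compares the two
#' distributions with a t-test and an F-test.
#'
#' @param emb_a,emb_b embeddings (matrix or [embedding()]) over the same
#'   cells.
#' @param labels cell-type label per cell; types with fewer than 2 cells are
#'   skipped.
#' @param max_pairs subsampling cap per type (default 2000).
#' @param seed subsampling seed.
#' @return list with `distances` (tibble: cell_type, method, distance) and
#'   `tests` (tibble: cell_type, mean_a, mean_b, t_statistic, t_p_value,
#'   f_statistic, f_p_value).
#' @export
pairwise_cosine_test <- function(emb_a, emb_b, labels, max_pairs = 2000,
                                 seed = 1) {
  ma <- if (inherits(emb_a, "embedding")) emb_a$values else as.matrix(emb_a)
  mb <- if (inherits(emb_b, "embedding")) emb_b$values else as.matrix(emb_b)
  stopifnot(nrow(ma) == length(labels), nrow(mb) == length(labels))
  dist_rows <- list()
  test_rows <- list()
  for (t in unique(labels)) {
    idx <- which(labels == t)
    if (length(idx) < 2) next
    da <- sample_pair_distances(ma[idx, , drop = FALSE], max_pairs,
                                derive_seed(seed, paste0("pcda_", t)))
    db <- sample_pair_distances(mb[idx, , drop = FALSE], max_pairs,
                                derive_seed(seed, paste0("pcdb_", t)))
    dist_rows[[t]] <- tibble::tibble(
      cell_type = t,
      method = rep(c("a", "b"), c(length(da), length(db))),
      distance = c(da, db))
    tt <- t.test(da, db)
    ft <- var.test(da, db)
    test_rows[[t]] <- tibble::tibble(
      cell_type = t, mean_a = mean(da), mean_b = mean(db),
      t_statistic = unname(tt$statistic), t_p_value = tt$p.value,
      f_statistic = unname(ft$statistic), f_p_value = ft$p.value)
  }
  list(distances = do.call(rbind, dist_rows),
       tests = do.call(rbind, test_rows))
}

sample_pair_distances <- function(m, max_pairs, seed) {
  n <- nrow(m)
  n_pairs <- n * (n - 1) / 2
  if (n_pairs <= max_pairs) {
    return(as.numeric(stats::as.dist(cosine_distance(m))))
  }
  with_seed(seed, {
    i <- sample.int(n, max_pairs, replace = TRUE)
    j <- sample.int(n - 1, max_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1, j)
    nm <- l2_normalize_rows(m)
    1 - rowSums(nm[i, , drop = FALSE] * nm[j, , drop = FALSE])
  })
}

#' Translation AUROC
#'
#' Treats RNA-to-ATAC translation as per-entry binary classification:
#' AUROC of the predicted accessibility probabilities against the observed
#' binary matrix, over all (cell, peak) entries and per cell type.
#' Degenerate truth (all 0 or all 1) yields `NA`.
#'
#' @param p_matrix predicted probabilities, cells x peaks.
#' @param truth observed binary matrix, same shape.
#' @param group_labels optional cell-type label per cell.
#' @return tibble with `group` (`"overall"` plus one row per type),
#'   `auroc`, `n_entries`.
#' @export
translation_auroc <- function(p_matrix, truth, group_labels = NULL) {
  truth <- as_dense(truth)
  stopifnot(all(dim(p_matrix) == dim(truth)))
  one <- function(pm, tm, label) {
    y <- as.numeric(tm)
    s <- as.numeric(pm)
    a <- if (length(unique(y)) < 2) NA_real_ else auroc_rank(s, y)
    tibble::tibble(group = label, auroc = a, n_entries = length(y))
  }
  out <- list(one(p_matrix, truth, "overall"))
  for (t in unique(group_labels)) {
    idx <- which(group_labels == t)
    out[[length(out) + 1]] <- one(p_matrix[idx, , drop = FALSE],
                                  truth[idx, , drop = FALSE], t)
  }
  do.call(rbind, out)
}

# Mann-Whitney formulation (equals the trapezoidal ROC area); pROC is used
# as an independent check in the tests.
auroc_rank <- function(scores, y) {
  r <- rank(scores)
  n1 <- as.numeric(sum(y == 1))
  n0 <- length(y) - n1
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Translation R-squared
#'
#' Squared Pearson correlation between per-feature mean predicted and
#' observed signals, aggregated over all cells (`level = "cell"` uses the
#' grand per-feature means) or within cell types (`level = "celltype"`
#' correlates the stacked per-type pseudo-bulk profiles). Zero-variance
#' vectors yield `NA`.
#'
#' @param pred,truth matrices of identical shape, cells x features.
#' @param group_labels cell-type label per cell (needed for per-type rows).
#' @param level aggregation level.
#' @return tibble with `group`, `r_squared`, `n_features`.
#' @export
translation_r2 <- function(pred, truth, group_labels = NULL,
                           level = c("cell", "celltype")) {
  level <- match.arg(level)
  truth <- as_dense(truth)
  pred <- as_dense(pred)
  stopifnot(all(dim(pred) == dim(truth)))
  r2 <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)^2
  }
  if (level == "celltype" && !is.null(group_labels)) {
    types <- unique(group_labels)
    pb_p <- do.call(rbind, lapply(types, function(t) {
      colMeans(pred[group_labels == t, , drop = FALSE])
    }))
    pb_t <- do.call(rbind, lapply(types, function(t) {
      colMeans(truth[group_labels == t, , drop = FALSE])
    }))
    out <- list(tibble::tibble(group = "overall",
                               r_squared = r2(as.numeric(pb_p),
                                              as.numeric(pb_t)),
                               n_features = ncol(pred)))
    for (i in seq_along(types)) {
      out[[i + 1]] <- tibble::tibble(group = types[i],
                                     r_squared = r2(pb_p[i, ], pb_t[i, ]),
                                     n_features = ncol(pred))
    }
    return(do.call(rbind, out))
  }
  out <- list(tibble::tibble(group = "overall",
                             r_squared = r2(colMeans(pred), colMeans(truth)),
                             n_features = ncol(pred)))
  for (t in unique(group_labels)) {
    idx <- which(group_labels == t)
    out[[length(out) + 1]] <- tibble::tibble(
      group = t,
      r_squared = r2(colMeans(pred[idx, , drop = FALSE]),
                     colMeans(truth[idx, , drop = FALSE])),
      n_features = ncol(pred))
  }
  do.call(rbind, out)
}

#' Motif activation score
#'
#' Weighted mean accessibility of the peaks lying within `window_bp` base
#' pairs upstream of a gene's transcription start site, averaged within cell
#' type. "Upstream" is strand-aware; unstranded genes fall back to a
#' symmetric window around the TSS (with a message). Weights default to
#' uniform; `weights = "decay"` applies `exp(-d / tau)` with `d` the
#' peak-midpoint-to-TSS distance.
#'
#' @param atac binarized ATAC [omics_matrix()] with peak annotations.
#' @param tss data frame with columns `gene`, `chrom`, `pos` and optional
#'   `strand` (`"+"`/`"-"`).
#' @param weights `"uniform"`, `"decay"`, or a numeric vector over peaks.
#' @param window_bp upstream window size (default 750000).
#' @param cell_type_labels label per cell; defaults to
#'   `cell_meta$cell_type` (one pooled group if absent).
#' @param tau decay length scale in bp for `weights = "decay"`.
#' @return tibble with `gene`, `cell_type`, `score`, `n_peaks_in_window`;
#'   genes with an empty window get `NA` with a warning.
#' @export
motif_activation_score <- function(atac, tss, weights = "uniform",
                                   window_bp = 750000,
                                   cell_type_labels = NULL, tau = 100000) {
  stopifnot(inherits(atac, "omics_matrix"), !is.null(atac$feature_meta))
  ann <- atac$feature_meta
  mid <- (ann$start + ann$end) / 2
  labels <- cell_type_labels %||% atac$cell_meta$cell_type %||%
    rep("all", nrow(atac$values))
  Xd <- as_dense(atac$values)
  rows <- list()
  for (i in seq_len(nrow(tss))) {
    g <- tss$gene[i]
    strand <- if ("strand" %in% names(tss)) tss$strand[i] else NA
    pos <- tss$pos[i]
    on_chrom <- ann$chrom == tss$chrom[i]
    inw <- if (is.na(strand) || !strand %in% c("+", "-")) {
      message("gene ", g, " unstranded; using symmetric window")
      on_chrom & abs(mid - pos) <= window_bp
    } else if (strand == "+") {
      on_chrom & mid >= pos - window_bp & mid <= pos
    } else {
      on_chrom & mid >= pos & mid <= pos + window_bp
    }
    idx <- which(inw)
    if (length(idx) == 0) {
      warning("no peaks within ", window_bp, " bp upstream of gene ", g)
      for (t in unique(labels)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene = g, cell_type = t, score = NA_real_, n_peaks_in_window = 0L)
      }
      next
    }
    w <- if (identical(weights, "uniform")) {
      rep(1, length(idx))
    } else if (identical(weights, "decay")) {
      exp(-abs(mid[idx] - pos) / tau)
    } else {
      as.numeric(weights)[idx]
    }
    for (t in unique(labels)) {
      cells <- which(labels == t)
      acc <- colMeans(Xd[cells, idx, drop = FALSE])
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = g, cell_type = t, score = sum(w * acc) / length(idx),
        n_peaks_in_window = length(idx))
    }
  }
  do.call(rbind, rows)
}

#' Peak-to-gene linkage on pseudo-bulk profiles
#'
#' For every peak within `span_bp` of the gene position, computes the
#' Pearson correlation (with test p-value) between per-group mean
#' accessibility and per-group mean expression. Per-cell binary
#' accessibility makes per-cell correlations degenerate, so links are
#' computed on per-cell-type pseudo-bulk; at least 3 groups are required
#' for the test.
#'
#' @param atac binarized ATAC [omics_matrix()] with peak annotations.
#' @param rna RNA [omics_matrix()] containing `gene`.
#' @param gene gene feature id.
#' @param gene_pos list or data frame row with `chrom` and `pos` for the
#'   gene (e.g. its TSS).
#' @param span_bp linkage span around the gene (default 100000).
#' @param cell_groups list with per-modality group labels
#'   (`list(rna =, atac =)`); defaults to each matrix's `cell_type`.
#' @param alpha significance threshold for flagging links (default 0.05).
#' @return tibble with one row per in-span peak: `peak_id`, `correlation`,
#'   `p_value`, `significant`.
#' @export
peak_gene_linkage <- function(atac, rna, gene, gene_pos, span_bp = 100000,
                              cell_groups = NULL, alpha = 0.05) {
  stopifnot(inherits(atac, "omics_matrix"), inherits(rna, "omics_matrix"),
            !is.null(atac$feature_meta))
  gi <- match(gene, rna$feature_ids)
  if (is.na(gi)) stop("gene not found: ", gene)
  grp_r <- cell_groups$rna %||% rna$cell_meta$cell_type
  grp_a <- cell_groups$atac %||% atac$cell_meta$cell_type
  groups <- intersect(unique(grp_r), unique(grp_a))
  if (length(groups) < 3) {
    stop("peak-to-gene linkage needs >= 3 cell groups; got ",
         length(groups))
  }
  ann <- atac$feature_meta
  mid <- (ann$start + ann$end) / 2
  idx <- which(ann$chrom == gene_pos$chrom & abs(mid - gene_pos$pos) <= span_bp)
  if (length(idx) == 0) {
    return(tibble::tibble(peak_id = character(), peak_index = integer(),
                          correlation = numeric(), p_value = numeric(),
                          significant = logical()))
  }
  Xa <- as_dense(atac$values)
  expr <- vapply(groups, function(t) {
    mean(rna$values[grp_r == t, gi])
  }, 1)
  rows <- lapply(idx, function(pi) {
    acc <- vapply(groups, function(t) mean(Xa[grp_a == t, pi]), 1)
    if (sd(acc) == 0 || sd(expr) == 0) {
      return(tibble::tibble(peak_id = atac$feature_ids[pi], peak_index = pi,
                            correlation = NA_real_, p_value = NA_real_,
                            significant = FALSE))
    }
    ct <- cor.test(acc, expr)
    tibble::tibble(peak_id = atac$feature_ids[pi], peak_index = pi,
                   correlation = unname(ct$estimate), p_value = ct$p.value,
                   significant = ct$p.value < alpha)
  })
  do.call(rbind, rows)
}
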