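# Shared fixtures, all generated in code. Trained models are memoized per
# session so several test files can reuse one training run.

.fixtures <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# Desk-scale study preset: 600 cells/modality, 300 genes, 1000 peaks on 3
# chromosomes, 4 types, 2 batches, one planted peak->gene link driven by
# cell type 1.
desk_cfg <- function(seed) {
  sim_config(planted_links = list(list(peak = 11, gene = 7, effect = 3,
                                       type = 1)),
             seed = seed)
}

desk_fixture <- function(seed) {
  memoize(paste0("desk_fix_", seed), {
    sim <- simulate_multiome(desk_cfg(seed))
    up <- unpair(sim$rna, sim$atac, sim$truth, seed = seed)
    rna <- log_normalize(qc_filter_rna(up$rna, min_counts = 200))
    atac <- binarize(up$atac)
    pair <- up$truth$pairing
    pair <- pair[pair$rna_id %in% rna$cell_ids &
                   pair$atac_id %in% atac$cell_ids, ]
    list(rna = rna, atac = atac, pair = pair, truth = up$truth)
  })
}

trained_desk <- function(seed) {
  memoize(paste0("desk_model_", seed), {
    fix <- desk_fixture(seed)
    layout <- chrom_layout_from_annotation(fix$atac$feature_meta)
    model0 <- build_model(ncol(fix$rna$values), ncol(fix$atac$values),
                          layout, unique(fix$rna$cell_meta$cell_type),
                          seed = seed)
    res <- train(model0, fix$rna, fix$atac, train_config(seed = seed))
    c(fix, list(model0 = model0, model = res$model, history = res$history))
  })
}

# Small toy (2 chromosomes, 2 types) that trains in seconds; enough for
# shape/contract checks and attribution quadrature.
toy_fixture <- function() {
  memoize("toy_fix", {
    cfg <- sim_config(n_cells = 150, n_genes = 40, n_peaks = 60, n_types = 2,
                      n_chroms = 2, n_batches = 2, seed = 5,
                      planted_links = list(list(peak = 3, gene = 2,
                                                effect = 3, type = 1)))
    sim <- simulate_multiome(cfg)
    up <- unpair(sim$rna, sim$atac, sim$truth, seed = 5)
    rna <- log_normalize(qc_filter_rna(up$rna, min_counts = 5))
    atac <- binarize(up$atac)
    list(rna = rna, atac = atac, pair = up$truth$pairing)
  })
}

trained_toy <- function() {
  memoize("toy_model", {
    fix <- toy_fixture()
    layout <- chrom_layout_from_annotation(fix$atac$feature_meta)
    model0 <- build_model(40, 60, layout,
                          unique(fix$rna$cell_meta$cell_type), k = 8,
                          seed = 5)
    res <- train(model0, fix$rna, fix$atac,
                 train_config(pretrain_epochs = 15, adversarial_epochs = 25,
                              batch_size = 32, seed = 5, k = 8))
    c(fix, list(model0 = model0, model = res$model, history = res$history))
  })
}

# hand-made omics matrices for unit tests
make_rna <- function(values, cell_type = NULL, doublet = NULL) {
  n <- nrow(values)
  meta <- data.frame(cell_id = sprintf("c%02d", seq_len(n)))
  if (!is.null(cell_type)) meta$cell_type <- cell_type
  if (!is.null(doublet)) meta$doublet_flag <- doublet
  omics_matrix(values, "RNA", cell_ids = meta$cell_id, cell_meta = meta)
}

make_atac <- function(values, n_chroms = 2, cell_type = NULL,
                      tss = NULL, depth = NULL) {
  n <- nrow(values)
  p <- ncol(values)
  per <- ceiling(p / n_chroms)
  chrom <- rep(sprintf("chr%d", seq_len(n_chroms)), each = per)[seq_len(p)]
  start <- unlist(lapply(table(chrom)[unique(chrom)], function(np) {
    1000 + (seq_len(np) - 1) * 2000
  }))
  ids <- sprintf("%s:%d-%d", chrom, start, start + 500)
  meta <- data.frame(cell_id = sprintf("c%02d", seq_len(n)))
  if (!is.null(cell_type)) meta$cell_type <- cell_type
  if (!is.null(tss)) meta$tss_enrichment <- tss
  if (!is.null(depth)) meta$depth <- depth
  omics_matrix(values, "ATAC", cell_ids = meta$cell_id, feature_ids = ids,
               cell_meta = meta)
}

# 1-nearest-neighbour classifier used as an independent oracle
knn1_accuracy <- function(train_x, train_y, test_x, test_y) {
  pred <- apply(test_x, 1, function(v) {
    train_y[which.min(colSums((t(train_x) - v)^2))]
  })
  mean(pred == test_y)
}
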