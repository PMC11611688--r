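# Synthetic paired multiome generator. Emulates the statistical structure
# the model assumes: shared per-cell-type latent programs driving both
# modalities, batch confounders in both, negative-binomial RNA counts with
# lognormal library sizes, Bernoulli-logit chromatin accessibility over
# chromosome-structured peak coordinates, and optional planted peak-to-gene
# links with a known driving cell type.

#' Simulation configuration
#'
#' Defaults are the desk-scale preset: 600 cells per modality, 300 genes,
#' 1000 peaks over 3 chromosomes, 4 cell types, 2 batches — a fixture that
#' trains in minutes on one CPU while preserving the qualitative structure
#' of real multiome data.
#'
#' @param n_cells cells per modality.
#' @param n_genes,n_peaks feature counts.
#' @param n_types,n_chroms,n_batches structure counts.
#' @param type_separation distance between cell-type latent programs, in
#'   units of the within-type latent radius; values of 2 or more give
#'   cleanly separable types.
#' @param batch_effect_size standard deviation of per-batch feature shifts
#'   (log-mean scale for RNA, logit scale for ATAC).
#' @param depth_dispersion lognormal sigma of RNA library sizes.
#' @param rna_noise negative-binomial dispersion (NB size = 1/rna_noise).
#' @param atac_base_logit baseline peak logit; more negative = sparser.
#' @param latent_dim dimension of the generative latent programs.
#' @param planted_links list of `list(peak =, gene =, effect =, type =)`
#'   entries. Each makes the peak a marker enhancer of cell type `type`
#'   (its logit shifted by `+2 * effect` in the driving type and
#'   `-2 * effect` elsewhere; no shift when `type` is `NULL`) and adds a
#'   peak-program-tracking component to the gene's log-mean, scaled so
#'   `effect = 1` matches the strength of the gene's own type structure.
#' @param seed generator seed; everything is seed-deterministic.
#' @export
sim_config <- function(n_cells = 600, n_genes = 300, n_peaks = 1000,
                       n_types = 4, n_chroms = 3, n_batches = 2,
                       type_separation = 2, batch_effect_size = 0.3,
                       depth_dispersion = 0.3, rna_noise = 0.5,
                       atac_base_logit = -2, latent_dim = 10,
                       planted_links = list(), seed = 1) {
  stopifnot(n_cells > 0, n_genes > 0, n_peaks > 0, n_types > 0,
            n_chroms > 0, n_batches > 0, n_peaks >= n_chroms,
            latent_dim > 0, all(vapply(planted_links, function(l) {
              is.finite(l$effect)
            }, TRUE)))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a paired multiome fixture
#'
#' Draws one latent program per cell type (separated by
#' `type_separation`), one latent vector per cell around its type's
#' program, and generates RNA counts (negative binomial, lognormal
#' library sizes, batch shifts) and binary ATAC (Bernoulli over a logit
#' linear in the latent, batch shifts) from the SAME latent per cell —
#' paired ground truth. Peaks receive contiguous coordinate blocks per
#' chromosome (2 kb spacing, 500 bp width). Planted links turn one peak
#' into a marker enhancer whose accessibility program the linked gene's
#' expression tracks.
#'
#' @param cfg a [sim_config()].
#' @return list with `rna` and `atac` (paired [omics_matrix()]es sharing
#'   barcodes), and `truth`: a list with the pairing table (tibble of
#'   `cell_id`, `cell_type`, `batch`), the latent factor matrix, and the
#'   planted-link table.
#' @export
simulate_multiome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cells
    L <- cfg$latent_dim
    # separation is in units of the within-type latent radius sqrt(L), so
    # type_separation = 2 yields programs a cell-type classifier on the true
    # latent can resolve almost perfectly
    type_means <- matrix(rnorm(cfg$n_types * L), cfg$n_types, L)
    type_means <- l2_normalize_rows(type_means) *
      cfg$type_separation * sqrt(L)
    cell_type <- sample(cfg$n_types, n, replace = TRUE)
    batch <- sample(cfg$n_batches, n, replace = TRUE)
    U <- type_means[cell_type, , drop = FALSE] + matrix(rnorm(n * L), n, L)

    gene_load <- matrix(rnorm(cfg$n_genes * L, sd = 1 / sqrt(L)),
                        cfg$n_genes, L)
    # most peaks are only weakly cell-type-specific (broad accessibility);
    # strong marker enhancers are the exception, injected via planted_links
    peak_load <- matrix(rnorm(cfg$n_peaks * L, sd = 0.5 / sqrt(L)),
                        cfg$n_peaks, L)
    gene_base <- rnorm(cfg$n_genes, sd = 0.5)
    batch_gene <- matrix(rnorm(cfg$n_batches * cfg$n_genes,
                               sd = cfg$batch_effect_size),
                         cfg$n_batches, cfg$n_genes)
    batch_peak <- matrix(rnorm(cfg$n_batches * cfg$n_peaks,
                               sd = cfg$batch_effect_size),
                         cfg$n_batches, cfg$n_peaks)

    log_mu <- sweep(U %*% t(gene_load), 2, gene_base, "+") +
      batch_gene[batch, , drop = FALSE]
    logit_p <- U %*% t(peak_load) + cfg$atac_base_logit +
      batch_peak[batch, , drop = FALSE]

    link_tab <- NULL
    if (length(cfg$planted_links)) {
      link_tab <- do.call(rbind, lapply(cfg$planted_links, function(l) {
        tibble::tibble(peak = as.integer(l$peak), gene = as.integer(l$gene),
                       effect = l$effect,
                       type = if (is.null(l$type)) NA_integer_ else
                         as.integer(l$type))
      }))
      for (i in seq_len(nrow(link_tab))) {
        pk <- link_tab$peak[i]
        gn <- link_tab$gene[i]
        eff <- link_tab$effect[i]
        # the peak becomes a marker enhancer of the driving type (logit
        # +/- 2*effect) and the gene's log-mean tracks the peak's
        # accessibility propensity — a dependence on the peak's program,
        # not an independent factor. The gene-side coupling is in units of
        # the gene's intrinsic program strength, so links at effect >= 1
        # dominate the gene's variance.
        if (!is.na(link_tab$type[i])) {
          logit_p[, pk] <- logit_p[, pk] +
            2 * eff * (2 * (cell_type == link_tab$type[i]) - 1)
        }
        s <- as.numeric(scale(logit_p[, pk]))
        intrinsic_sd <- stats::sd(as.numeric(U %*% gene_load[gn, ]))
        log_mu[, gn] <- log_mu[, gn] + eff * intrinsic_sd * s
      }
    }

    # RNA counts: per-cell relative abundances scaled to a lognormal depth
    depth <- rlnorm(n, meanlog = log(2000), sdlog = cfg$depth_dispersion)
    rel <- exp(log_mu)
    rel <- rel / rowSums(rel)
    mu <- rel * depth
    size <- 1 / cfg$rna_noise
    counts <- matrix(rnbinom(n * cfg$n_genes, mu = as.numeric(mu),
                             size = size), n, cfg$n_genes)

    acc <- matrix(rbinom(n * cfg$n_peaks, 1,
                         as.numeric(sigmoid(logit_p))), n, cfg$n_peaks)

    cell_ids <- sprintf("cell_%04d", seq_len(n))
    gene_ids <- sprintf("gene_%03d", seq_len(cfg$n_genes))
    peak_ann <- peak_coordinates(cfg$n_peaks, cfg$n_chroms)
    peak_ids <- format_peak_names(peak_ann)
    type_labels <- sprintf("type%d", cell_type)
    atac_depth <- rowSums(acc)

    rna <- omics_matrix(
      counts, "RNA", cell_ids = cell_ids, feature_ids = gene_ids,
      cell_meta = data.frame(cell_id = cell_ids, cell_type = type_labels,
                             batch = sprintf("batch%d", batch),
                             depth = rowSums(counts), doublet_flag = FALSE))
    atac <- omics_matrix(
      acc, "ATAC", cell_ids = cell_ids, feature_ids = peak_ids,
      cell_meta = data.frame(
        cell_id = cell_ids, cell_type = type_labels,
        batch = sprintf("batch%d", batch), depth = atac_depth,
        tss_enrichment = pmax(rnorm(n, mean = 6, sd = 1.5), 0.1),
        doublet_flag = FALSE),
      feature_meta = peak_ann)

    truth <- list(
      pairing = tibble::tibble(cell_id = cell_ids, cell_type = type_labels,
                               batch = sprintf("batch%d", batch)),
      latent = U, type_means = type_means,
      gene_loadings = gene_load, peak_loadings = peak_load,
      planted_links = link_tab)
    list(rna = rna, atac = atac, truth = truth)
  })
}

# contiguous 2kb-spaced 500bp peaks, distributed as evenly as possible
peak_coordinates <- function(n_peaks, n_chroms) {
  per <- rep(n_peaks %/% n_chroms, n_chroms)
  extra <- n_peaks %% n_chroms
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  do.call(rbind, lapply(seq_len(n_chroms), function(c) {
    start <- 1000 + (seq_len(per[c]) - 1) * 2000
    data.frame(chrom = sprintf("chr%d", c), start = start,
               end = start + 500, stringsAsFactors = FALSE)
  }))
}

#' Break the cell pairing of a simulated fixture
#'
#' Re-keys both modalities with disjoint barcodes and shuffles the ATAC cell
#' order, so no pairing is inferable from the data; the true correspondence
#' is retained separately in the returned truth table for evaluation only.
#'
#' @param rna,atac paired matrices from [simulate_multiome()].
#' @param truth the paired truth list.
#' @param seed shuffle seed.
#' @return list with `rna`, `atac` (disjoint barcodes) and `truth` extended
#'   by a `pairing` table mapping `rna_id` to `atac_id`; `atac_order` gives
#'   the permutation applied to the ATAC cells.
#' @export
unpair <- function(rna, atac, truth, seed = 1) {
  n <- nrow(rna$values)
  perm <- with_seed(derive_seed(seed, "unpair"), sample.int(n))
  rna_ids <- sprintf("rna_%04d", seq_len(n))
  atac_ids_in_new_order <- sprintf("atac_%04d", seq_len(n))

  rna$cell_ids <- rna_ids
  rownames(rna$values) <- rna_ids
  rna$cell_meta$cell_id <- rna_ids

  atac <- atac[perm, ]
  atac$cell_ids <- atac_ids_in_new_order
  rownames(atac$values) <- atac_ids_in_new_order
  atac$cell_meta$cell_id <- atac_ids_in_new_order

  # original cell i sits at position match(i, perm) in the new ATAC order
  pairing <- tibble::tibble(
    original_id = truth$pairing$cell_id,
    rna_id = rna_ids,
    atac_id = atac_ids_in_new_order[match(seq_len(n), perm)],
    cell_type = truth$pairing$cell_type,
    batch = truth$pairing$batch)
  truth$pairing <- pairing
  truth$atac_order <- perm
  list(rna = rna, atac = atac, truth = truth)
}
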