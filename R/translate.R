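# Cross-modality translation: ATAC -> RNA through g and the RNA decoder
# (deterministic), RNA -> ATAC through f and the ATAC decoder, which yields
# Bernoulli accessibility probabilities and, optionally, a seeded binary
# sample.

#' Translate ATAC cells into RNA expression
#'
#' Computes `x_AR = F_DecR(g(F_EncA(x_A)))`: each ATAC cell is encoded,
#' mapped into the RNA latent space and decoded into the model's gene set.
#' Deterministic.
#'
#' @param model a trained `scact_model`.
#' @param atac binarized ATAC [omics_matrix()] with the model's peak set.
#' @return an RNA-like [omics_matrix()] (dense real values) carrying the
#'   ATAC cells' ids and metadata.
#' @export
translate_atac_to_rna <- function(model, atac) {
  stopifnot(inherits(model, "scact_model"), inherits(atac, "omics_matrix"),
            atac$modality == "ATAC")
  if (ncol(atac$values) != model$p) {
    stop("peak set mismatch: matrix has ", ncol(atac$values),
         " peaks, model expects ", model$p)
  }
  z_a <- encode(model, atac)
  z_ar <- map_embedding(model, z_a, "AR")
  xr <- decode(model, z_ar, "RNA")
  omics_matrix(xr, modality = "RNA", cell_ids = atac$cell_ids,
               feature_ids = model$rna_features, cell_meta = atac$cell_meta)
}

#' Translate RNA cells into chromatin accessibility
#'
#' Computes the per-peak Bernoulli probabilities
#' `p_RA = F_DecA(f(F_EncR(x_R)))` and, when `sample = TRUE`, draws a binary
#' matrix `x_RA ~ Bernoulli(p_RA)` elementwise with a seeded generator. The
#' probability matrix is always returned (evaluation by ROC needs it);
#' sampling is opt-in.
#'
#' @param model a trained `scact_model`.
#' @param rna log-normalized RNA [omics_matrix()] with the model's gene set.
#' @param sample draw a binarized sample as well?
#' @param seed seed for the Bernoulli draw.
#' @return list with `prob` (dense cells x peaks matrix in `[0,1]`) and
#'   `sample` (binary ATAC-like [omics_matrix()], or `NULL`).
#' @export
translate_rna_to_atac <- function(model, rna, sample = FALSE, seed = 1) {
  stopifnot(inherits(model, "scact_model"), inherits(rna, "omics_matrix"),
            rna$modality == "RNA")
  if (ncol(rna$values) != model$q) {
    stop("gene set mismatch: matrix has ", ncol(rna$values),
         " genes, model expects ", model$q)
  }
  z_r <- encode(model, rna)
  z_ra <- map_embedding(model, z_r, "RA")
  prob <- decode(model, z_ra, "ATAC")
  samp <- NULL
  if (sample) {
    draw <- with_seed(seed, {
      matrix(rbinom(length(prob), 1, as.numeric(prob)), nrow(prob), ncol(prob))
    })
    dimnames(draw) <- dimnames(prob)
    samp <- omics_matrix(draw, modality = "ATAC", cell_ids = rna$cell_ids,
                         feature_ids = model$atac_features,
                         cell_meta = rna$cell_meta,
                         feature_meta = model$peak_annotation)
  }
  list(prob = prob, sample = samp)
}
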