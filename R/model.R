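#' Build the cross-modality model
#'
#' Constructs the full parameter bundle: an RNA autoencoder (unmasked MLP,
#' hidden widths 256/64 by default), a chromosome-masked ATAC autoencoder
#' (one sub-network per chromosome with hidden widths 128/64/32, concatenated
#' and projected to a `k`-dimensional latent; the decoder mirrors this with a
#' sigmoid accessibility probability per peak), two cross-modality mapper
#' MLPs `f` (RNA latent to ATAC latent) and `g` (ATAC latent to RNA latent),
#' and one discriminator pair per cell type. The ATAC latent uses a sigmoid
#' output so its coordinates live in (0,1), which makes the binary
#' cross-entropy cycle term well defined; `f` ends in a sigmoid for the same
#' reason.
#'
#' Inter-chromosomal connections do not exist in the ATAC encoder/decoder:
#' each chromosome's peaks feed a private sub-network, so the materialized
#' first-layer weight matrix ([masked_weight_matrix()]) is block-diagonal
#' with exact zeros off the blocks, at initialization and after any number
#' of training updates.
#'
#' @param q number of genes (RNA features).
#' @param p number of peaks (ATAC features).
#' @param chrom_layout named list mapping chromosome to the integer indices
#'   of its peaks; must partition `1:p`.
#' @param cell_types character vector of cell-type labels (one discriminator
#'   pair per type).
#' @param k latent dimension (default 20).
#' @param seed integer; initialization is fully seed-deterministic.
#' @param gamma,lambda_con loss weights for the adversarial and confounder
#'   terms, stored with the model.
#' @param rna_hidden hidden widths of the RNA autoencoder.
#' @param atac_hidden per-chromosome hidden widths of the ATAC autoencoder.
#' @param hidden_act hidden-layer activation (default `"tanh"`; smooth
#'   activations keep the integrated-gradients path integral well behaved).
#' @return a `scact_model` object.
#' @export
build_model <- function(q, p, chrom_layout, cell_types, k = 20, seed = 1,
                        gamma = 1, lambda_con = 0.1,
                        rna_hidden = c(256, 64), atac_hidden = c(128, 64, 32),
                        hidden_act = "tanh") {
  stopifnot(q >= 1, p >= 1, k >= 1, length(cell_types) >= 1)
  chrom_layout <- lapply(chrom_layout, as.integer)
  idx <- sort(unlist(chrom_layout, use.names = FALSE))
  if (length(idx) != p || !identical(idx, seq_len(p))) {
    stop("chrom_layout must partition peak indices 1..p without overlap")
  }
  cell_types <- as.character(unique(cell_types))
  with_seed(seed, {
    model <- structure(list(
      enc_rna = mlp_init(c(q, rna_hidden, k),
                         c(rep(hidden_act, length(rna_hidden)), "linear")),
      dec_rna = mlp_init(c(k, rev(rna_hidden), q),
                         c(rep(hidden_act, length(rna_hidden)), "linear")),
      enc_atac = atac_encoder_init(chrom_layout, atac_hidden, k, hidden_act),
      dec_atac = atac_decoder_init(chrom_layout, atac_hidden, k, hidden_act),
      mapper_ra = mlp_init(c(k, 2 * k, 2 * k, k),
                           c(hidden_act, hidden_act, "sigmoid")),
      mapper_ar = mlp_init(c(k, 2 * k, 2 * k, k),
                           c(hidden_act, hidden_act, "linear")),
      discriminators = setNames(lapply(cell_types, function(t) {
        list(d_atac = mlp_init(c(k, k, k, 1), c(hidden_act, hidden_act, "sigmoid")),
             d_rna = mlp_init(c(k, k, k, 1), c(hidden_act, hidden_act, "sigmoid")))
      }), cell_types),
      gamma = gamma, lambda_con = lambda_con, k = k, hidden_act = hidden_act,
      chrom_layout = chrom_layout, cell_types = cell_types,
      q = q, p = p, seed = seed,
      rna_features = sprintf("gene_%d", seq_len(q)),
      atac_features = sprintf("peak_%d", seq_len(p)),
      peak_annotation = NULL
    ), class = "scact_model")
    model
  })
}

#' @export
print.scact_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<scact_model> k=%d latent, %d genes, %d peaks on %d chromosomes\n",
    "  %d cell types (discriminator pairs), gamma=%g, lambda_con=%g\n"),
    x$k, x$q, x$p, length(x$chrom_layout), length(x$cell_types),
    x$gamma, x$lambda_con))
  invisible(x)
}

#' Encode cells into the shared latent space
#'
#' @param model a [build_model()] result (trained or not).
#' @param m an [omics_matrix()] whose feature count matches the model.
#' @return an [embedding()] with `mapped = FALSE`.
#' @export
encode <- function(model, m) {
  stopifnot(inherits(model, "scact_model"), inherits(m, "omics_matrix"))
  X <- m$values
  if (m$modality == "RNA") {
    if (ncol(X) != model$q) {
      stop("RNA matrix has ", ncol(X), " genes; model expects ", model$q)
    }
    z <- mlp_forward(model$enc_rna, X)$out
  } else {
    if (ncol(X) != model$p) {
      stop("ATAC matrix has ", ncol(X), " peaks; model expects ", model$p)
    }
    z <- atac_encode_forward(model$enc_atac, X, model$chrom_layout)$out
  }
  embedding(z, source_modality = m$modality, cell_ids = m$cell_ids)
}

#' Decode latent embeddings back to feature space
#'
#' RNA decoding returns a real-valued expression matrix; ATAC decoding
#' returns per-peak accessibility probabilities in `[0, 1]` (the Bernoulli
#' parameters used by [translate_rna_to_atac()]).
#'
#' @param model a `scact_model`.
#' @param z an [embedding()] with `k` matching the model.
#' @param target_modality `"RNA"` or `"ATAC"`.
#' @return a dense cells x features matrix.
#' @export
decode <- function(model, z, target_modality = c("RNA", "ATAC")) {
  stopifnot(inherits(model, "scact_model"), inherits(z, "embedding"))
  target_modality <- match.arg(target_modality)
  if (z$k != model$k) {
    stop("embedding k=", z$k, " does not match model k=", model$k)
  }
  out <- if (target_modality == "RNA") {
    mlp_forward(model$dec_rna, z$values)$out
  } else {
    atac_decode_forward(model$dec_atac, z$values, model$chrom_layout)$out
  }
  rownames(out) <- z$cell_ids
  colnames(out) <- if (target_modality == "RNA") model$rna_features else
    model$atac_features
  out
}

#' Map an embedding across modalities
#'
#' Applies the mapper MLP `f` (`direction = "RA"`, RNA latent into the ATAC
#' latent space) or `g` (`direction = "AR"`).
#'
#' @param model a `scact_model`.
#' @param z an [embedding()].
#' @param direction `"RA"` or `"AR"`.
#' @return the mapped [embedding()] (`mapped = TRUE`), same shape.
#' @export
map_embedding <- function(model, z, direction = c("RA", "AR")) {
  stopifnot(inherits(model, "scact_model"), inherits(z, "embedding"))
  direction <- match.arg(direction)
  net <- if (direction == "RA") model$mapper_ra else model$mapper_ar
  out <- mlp_forward(net, z$values)$out
  emb <- embedding(out, source_modality = z$source_modality,
                   cell_ids = z$cell_ids, mapped = TRUE)
  emb
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding every parameter tensor, the
#' chromosome layout, cell-type list, latent dimension, loss weights and
#' seed; loading is bit-exact.
#'
#' @param model a `scact_model`.
#' @param file checkpoint path.
#' @export
save_checkpoint <- function(model, file) {
  stopifnot(inherits(model, "scact_model"))
  saveRDS(model, file)
  invisible(file)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(file) {
  model <- readRDS(file)
  if (!inherits(model, "scact_model")) stop("not a model checkpoint: ", file)
  model
}

#' Materialize a masked ATAC weight matrix
#'
#' Returns the peaks x hidden-units weight matrix of the ATAC encoder's first
#' layer (`which = "encoder"`) or the ATAC decoder's last layer transposed to
#' the same orientation (`which = "decoder"`). Entries connecting a peak to
#' another chromosome's sub-network are exactly zero.
#'
#' @param model a `scact_model`.
#' @param which `"encoder"` or `"decoder"`.
#' @export
masked_weight_matrix <- function(model, which = c("encoder", "decoder")) {
  which <- match.arg(which)
  atac_first_layer_matrix(
    if (which == "encoder") model$enc_atac else model$dec_atac,
    model$chrom_layout, decoder = which == "decoder")
}

# logical mask of permitted (intra-chromosomal) entries, same shape
masked_weight_mask <- function(model, which = c("encoder", "decoder")) {
  which <- match.arg(which)
  layout <- model$chrom_layout
  module <- if (which == "encoder") model$enc_atac else model$dec_atac
  units <- if (which == "decoder") {
    vapply(module$chrom_nets,
           function(n) nrow(n$layers[[length(n$layers)]]$W), 1L)
  } else {
    vapply(module$chrom_nets, function(n) ncol(n$layers[[1]]$W), 1L)
  }
  M <- matrix(FALSE, sum(lengths(layout)), sum(units))
  off <- 0L
  for (c in seq_along(layout)) {
    M[layout[[c]], (off + 1L):(off + units[c])] <- TRUE
    off <- off + units[c]
  }
  M
}

#' @method glance scact_model
#' @export
glance.scact_model <- function(x, ...) {
  n_par <- 0
  count <- function(t) {
    tree_map(function(v) {
      n_par <<- n_par + length(v)
      v
    }, t)
    invisible(NULL)
  }
  count(x[c("enc_rna", "dec_rna", "enc_atac", "dec_atac",
            "mapper_ra", "mapper_ar", "discriminators")])
  tibble::tibble(
    k = x$k, n_genes = x$q, n_peaks = x$p,
    n_chromosomes = length(x$chrom_layout),
    n_cell_types = length(x$cell_types),
    gamma = x$gamma, lambda_con = x$lambda_con,
    n_parameters = n_par, trained_epochs = x$trained_epochs %||% 0L
  )
}

#' @importFrom generics tidy glance
NULL
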