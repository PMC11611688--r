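# Alternating optimization: phase 1 pretrains the two autoencoders on
# reconstruction + confounder loss; phase 2 alternates discriminator ascent
# on the per-cell-type GAN log-likelihood with generator descent on
# reconstruction + gamma * cycle/adversarial + lambda_con * confounder.
# The discriminator step touches only discriminator parameters and the
# generator step only encoder/decoder/mapper parameters. All gradients are
# the exact backprop of the loss values in losses.R, except that the cycle
# targets (z_R in the MSE term, z_A in the BCE term) and the pooled
# confounder moments are treated as constants (stop-gradient), the usual
# convention for cycle and moment-matching penalties.

#' Training configuration
#'
#' @param gamma,lambda_con adversarial and confounder loss weights.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size (>= 2: stratum moments need two cells).
#' @param pretrain_epochs autoencoder-only epochs (phase 1).
#' @param adversarial_epochs alternating GAN epochs (phase 2).
#' @param d_steps_per_g_step discriminator updates per generator update.
#' @param seed master seed for shuffling and initialization.
#' @param k latent dimension used when the search builds models.
#' @param early_stop stop a phase once the relative change of the total loss
#'   over `patience` epochs falls below `tol`.
#' @param patience,tol early-stopping window and threshold.
#' @param grid_gamma,grid_lambda,grid_lr,grid_batch search ranges for
#'   [grid_search()]; gamma/lambda are searched uniformly on `[0.1, 2]`,
#'   the learning rate uniformly in log-space on `[1e-5, 1e-3]`, the batch
#'   size uniformly on `[16, 256]`.
#' @return a `train_config` list.
#' @export
train_config <- function(gamma = 1, lambda_con = 0.1, lr = 1e-3,
                         batch_size = 64, pretrain_epochs = 30,
                         adversarial_epochs = 60, d_steps_per_g_step = 1,
                         seed = 1, k = 20, early_stop = TRUE, patience = 10,
                         tol = 1e-4,
                         grid_gamma = c(0.1, 2), grid_lambda = c(0.1, 2),
                         grid_lr = c(1e-5, 1e-3), grid_batch = c(16, 256)) {
  stopifnot(gamma > 0 || gamma == 0, lambda_con >= 0, lr > 0,
            batch_size >= 2, pretrain_epochs >= 0, adversarial_epochs >= 0,
            d_steps_per_g_step >= 1)
  structure(list(gamma = gamma, lambda_con = lambda_con, lr = lr,
                 batch_size = as.integer(batch_size),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 adversarial_epochs = as.integer(adversarial_epochs),
                 d_steps_per_g_step = as.integer(d_steps_per_g_step),
                 seed = as.integer(seed), k = as.integer(k),
                 early_stop = early_stop, patience = patience, tol = tol,
                 grid_gamma = grid_gamma, grid_lambda = grid_lambda,
                 grid_lr = grid_lr, grid_batch = grid_batch),
            class = "train_config")
}

#' Derive a chromosome layout from peak annotations
#'
#' @param ann peak annotation data frame (column `chrom`), row order matching
#'   the peak features.
#' @return named list of peak index vectors, one per chromosome.
#' @export
chrom_layout_from_annotation <- function(ann) {
  split(seq_len(nrow(ann)), ann$chrom)
}

confounder_table <- function(m) {
  keep <- intersect(c("batch", "depth"), names(m$cell_meta))
  m$cell_meta[, keep, drop = FALSE]
}

generator_params <- function(model) {
  model[c("enc_rna", "dec_rna", "enc_atac", "dec_atac",
          "mapper_ra", "mapper_ar")]
}

zero_generator_grads <- function(model) {
  tree_map(function(x) x * 0, generator_params(model))
}

#' Train the model
#'
#' Runs the two-phase schedule described above and records a per-epoch loss
#' history (`rec`, `con`, `adv_g` = cycle/generator term, `adv_d` =
#' discriminator term, `total` with the model's `gamma`/`lambda_con`)
#' evaluated on the full data. Fully reproducible given `cfg$seed`.
#'
#' @param model a [build_model()] result.
#' @param rna preprocessed RNA [omics_matrix()] with `cell_type` labels.
#' @param atac preprocessed binary ATAC [omics_matrix()] with `cell_type`
#'   labels; the label sets of the two modalities must coincide.
#' @param cfg a [train_config()].
#' @return list with `model` (trained) and `history` (tibble).
#' @export
train <- function(model, rna, atac, cfg = train_config()) {
  stopifnot(inherits(model, "scact_model"),
            inherits(rna, "omics_matrix"), inherits(atac, "omics_matrix"))
  lab_r <- rna$cell_meta$cell_type
  lab_a <- atac$cell_meta$cell_type
  if (is.null(lab_r) || is.null(lab_a)) {
    stop("both modalities need a cell_type column in cell_meta")
  }
  sdiff <- union(setdiff(unique(lab_r), unique(lab_a)),
                 setdiff(unique(lab_a), unique(lab_r)))
  if (length(sdiff)) {
    stop("cell-type label sets differ between modalities: ",
         paste(sdiff, collapse = ", "))
  }
  model$gamma <- cfg$gamma
  model$lambda_con <- cfg$lambda_con
  model$rna_features <- rna$feature_ids
  model$atac_features <- atac$feature_ids
  model$peak_annotation <- atac$feature_meta

  Xr <- as_dense(rna$values)
  Xa <- atac$values                      # stays sparse through the first layer
  conf_r <- confounder_table(rna)
  conf_a <- confounder_table(atac)
  n_r <- nrow(Xr)
  n_a <- nrow(Xa)
  lam <- cfg$lambda_con
  gam <- cfg$gamma

  gen <- generator_params(model)
  gen_state <- adam_init(gen)
  disc <- model$discriminators
  disc_state <- adam_init(disc)

  history <- list()
  record <- function(phase, epoch) {
    model_now <- model
    model_now[names(gen)] <- gen
    model_now$discriminators <- disc
    rep <- full_losses(model_now, Xr, Xa, conf_r, conf_a, lab_r, lab_a,
                       gam, lam)
    history[[length(history) + 1]] <<- c(list(phase = phase, epoch = epoch),
                                         rep[c("rec", "con", "adv_g",
                                               "adv_d", "total")])
    rep$total
  }

  plateau <- function(tot) {
    cfg$early_stop && length(tot) > cfg$patience && {
      w <- utils::tail(tot, cfg$patience + 1)
      abs(w[length(w)] - w[1]) / max(abs(w[1]), 1e-12) < cfg$tol
    }
  }

  with_seed(cfg$seed, {
    ## ---- phase 1: autoencoder pretraining --------------------------------
    totals <- numeric(0)
    for (epoch in seq_len(cfg$pretrain_epochs)) {
      ord_r <- sample.int(n_r)
      ord_a <- sample.int(n_a)
      nb <- max(ceiling(n_r / cfg$batch_size), ceiling(n_a / cfg$batch_size))
      for (b in seq_len(nb)) {
        ir <- batch_slice(ord_r, b, cfg$batch_size)
        ia <- batch_slice(ord_a, b, cfg$batch_size)
        g <- zero_generator_grads(model)
        g[c("enc_rna", "dec_rna")] <-
          ae_grads_rna(gen, Xr[ir, , drop = FALSE],
                       conf_r[ir, , drop = FALSE], lam)
        g[c("enc_atac", "dec_atac")] <-
          ae_grads_atac(gen, Xa[ia, , drop = FALSE],
                        conf_a[ia, , drop = FALSE], lam, model$chrom_layout)
        st <- adam_step(gen, g, gen_state, cfg$lr)
        gen <- st$params
        gen_state <- st$state
      }
      totals <- c(totals, record("pretrain", epoch))
      if (plateau(totals)) break
    }
    ## ---- phase 2: alternating adversarial training -----------------------
    totals <- numeric(0)
    for (epoch in seq_len(cfg$adversarial_epochs)) {
      ord_r <- sample.int(n_r)
      ord_a <- sample.int(n_a)
      nb <- max(ceiling(n_r / cfg$batch_size), ceiling(n_a / cfg$batch_size))
      for (b in seq_len(nb)) {
        ir <- batch_slice(ord_r, b, cfg$batch_size)
        ia <- batch_slice(ord_a, b, cfg$batch_size)
        xb_r <- Xr[ir, , drop = FALSE]
        xb_a <- Xa[ia, , drop = FALSE]
        lb_r <- lab_r[ir]
        lb_a <- lab_a[ia]
        for (s in seq_len(cfg$d_steps_per_g_step)) {
          dg <- disc_grads(gen, disc, model, xb_r, xb_a, lb_r, lb_a)
          st <- adam_step(disc, dg, disc_state, cfg$lr)
          disc <- st$params
          disc_state <- st$state
        }
        g <- gen_grads(gen, disc, model, xb_r, xb_a, lb_r, lb_a,
                       conf_r[ir, , drop = FALSE], conf_a[ia, , drop = FALSE],
                       gam, lam)
        st <- adam_step(gen, g, gen_state, cfg$lr)
        gen <- st$params
        gen_state <- st$state
      }
      totals <- c(totals, record("adversarial", epoch))
      if (plateau(totals)) break
    }
  })

  model[names(gen)] <- gen
  model$discriminators <- disc
  model$trained_epochs <- length(history)
  hist <- tibble::as_tibble(do.call(rbind, lapply(history, function(h) {
    as.data.frame(h, stringsAsFactors = FALSE)
  })))
  list(model = model, history = hist)
}

batch_slice <- function(ord, b, bs) {
  n <- length(ord)
  idx <- ((b - 1) * bs + seq_len(bs) - 1) %% n + 1
  ord[unique(idx)]
}

full_losses <- function(model, Xr, Xa, conf_r, conf_a, lab_r, lab_a,
                        gam, lam) {
  z_r <- mlp_forward(model$enc_rna, Xr)$out
  z_a <- atac_encode_forward(model$enc_atac, Xa, model$chrom_layout)$out
  xr_hat <- mlp_forward(model$dec_rna, z_r)$out
  xa_hat <- atac_decode_forward(model$dec_atac, z_a, model$chrom_layout)$out
  rec <- mse_mean(Xr, xr_hat) + bce_mean(Xa, xa_hat)
  con <- suppressWarnings(
    loss_confounder(model, z_r, conf_r) + loss_confounder(model, z_a, conf_a))
  z_ra <- mlp_forward(model$mapper_ra, z_r)$out
  z_ar <- mlp_forward(model$mapper_ar, z_a)$out
  labels <- list(rna = lab_r, atac = lab_a)
  adv_g <- loss_cycle(model, z_r, z_a, z_ra, z_ar, labels)
  adv_d <- loss_discriminator(model, z_r, z_a, z_ra, z_ar, labels)
  loss_total(rec = rec, con = con, adv_g = adv_g, adv_d = adv_d,
             gamma = gam, lambda_con = lam)
}

# ---- gradient blocks -------------------------------------------------------

ae_grads_rna <- function(gen, xb, conf, lam) {
  fe <- mlp_forward(gen$enc_rna, xb, keep_cache = TRUE)
  fd <- mlp_forward(gen$dec_rna, fe$out, keep_cache = TRUE)
  n_entries <- length(fd$out)
  bd <- mlp_backward(gen$dec_rna, fd,
                     dOut = 2 * (fd$out - as_dense(xb)) / n_entries)
  dz <- bd$dX
  if (lam > 0 && ncol(conf)) dz <- dz + lam * grad_confounder(fe$out, conf)
  be <- mlp_backward(gen$enc_rna, fe, dOut = dz, need_dx = FALSE)
  list(enc_rna = be$grads, dec_rna = bd$grads)
}

ae_grads_atac <- function(gen, xb, conf, lam, layout) {
  fe <- atac_encode_forward(gen$enc_atac, xb, layout, keep_cache = TRUE)
  fd <- atac_decode_forward(gen$dec_atac, fe$out, layout, keep_cache = TRUE)
  n_entries <- length(fd$out)
  xb_d <- as_dense(xb)
  d_pre <- lapply(seq_along(layout), function(c) {
    (fd$chrom_caches[[c]]$out -
       xb_d[, layout[[c]], drop = FALSE]) / n_entries
  })
  bd <- atac_decode_backward(gen$dec_atac, fd, layout, d_pre)
  dz <- bd$dX
  if (lam > 0 && ncol(conf)) dz <- dz + lam * grad_confounder(fe$out, conf)
  be <- atac_encode_backward(gen$enc_atac, fe, layout, dZ = dz)
  list(enc_atac = be$grads, dec_atac = bd$grads)
}

# Gradients of the NEGATIVE discriminator objective (so Adam descent
# maximizes Eq. 7) for one minibatch pair; returns a tree shaped like
# model$discriminators with zeros for absent types.
disc_grads <- function(gen, disc, model, xb_r, xb_a, lb_r, lb_a) {
  z_r <- mlp_forward(gen$enc_rna, xb_r)$out
  z_a <- atac_encode_forward(gen$enc_atac, xb_a, model$chrom_layout)$out
  z_ra <- mlp_forward(gen$mapper_ra, z_r)$out
  z_ar <- mlp_forward(gen$mapper_ar, z_a)$out
  grads <- tree_map(function(x) x * 0, disc)
  for (t in model$cell_types) {
    ir <- which(lb_r == t)
    ia <- which(lb_a == t)
    if (length(ir) == 0 && length(ia) == 0) next
    # D_A^t : real = z_A (type-t ATAC cells), fake = z_RA (type-t RNA cells)
    grads[[t]]$d_atac <- disc_pair_grads(
      disc[[t]]$d_atac,
      real = z_a[ia, , drop = FALSE], fake = z_ra[ir, , drop = FALSE])
    # D_R^t : real = z_R, fake = z_AR
    grads[[t]]$d_rna <- disc_pair_grads(
      disc[[t]]$d_rna,
      real = z_r[ir, , drop = FALSE], fake = z_ar[ia, , drop = FALSE])
  }
  grads
}

disc_pair_grads <- function(net, real, fake) {
  n_real <- nrow(real)
  n_fake <- nrow(fake)
  if (n_real + n_fake == 0) return(tree_map(function(x) x * 0, net))
  X <- rbind(real, fake)
  fw <- mlp_forward(net, X, keep_cache = TRUE)
  D <- as.numeric(fw$out)
  # minimize -[mean log D(real) + mean log(1 - D(fake))]
  d_pre <- numeric(length(D))
  if (n_real) d_pre[seq_len(n_real)] <- (D[seq_len(n_real)] - 1) / n_real
  if (n_fake) d_pre[n_real + seq_len(n_fake)] <-
      D[n_real + seq_len(n_fake)] / n_fake
  mlp_backward(net, fw, dPre_last = matrix(d_pre, ncol = 1),
               need_dx = FALSE)$grads
}

# Full generator-step gradients: reconstruction + gamma * cycle/adversarial
# + lambda * confounder, with discriminators frozen.
gen_grads <- function(gen, disc, model, xb_r, xb_a, lb_r, lb_a,
                      conf_r, conf_a, gam, lam) {
  layout <- model$chrom_layout
  fe_r <- mlp_forward(gen$enc_rna, xb_r, keep_cache = TRUE)
  z_r <- fe_r$out
  fe_a <- atac_encode_forward(gen$enc_atac, xb_a, layout, keep_cache = TRUE)
  z_a <- fe_a$out
  fd_r <- mlp_forward(gen$dec_rna, z_r, keep_cache = TRUE)
  fd_a <- atac_decode_forward(gen$dec_atac, z_a, layout, keep_cache = TRUE)
  f_f <- mlp_forward(gen$mapper_ra, z_r, keep_cache = TRUE)   # z_RA
  f_g <- mlp_forward(gen$mapper_ar, z_a, keep_cache = TRUE)   # z_AR
  z_ra <- f_f$out
  z_ar <- f_g$out
  f_gf <- mlp_forward(gen$mapper_ar, z_ra, keep_cache = TRUE) # g(f(z_R))
  f_fg <- mlp_forward(gen$mapper_ra, z_ar, keep_cache = TRUE) # f(g(z_A))

  k <- ncol(z_r)
  dz_ra <- matrix(0, nrow(z_ra), k)
  dz_ar <- matrix(0, nrow(z_ar), k)

  ## adversarial generator terms: -log D^t on mapped embeddings
  for (t in model$cell_types) {
    ir <- which(lb_r == t)
    ia <- which(lb_a == t)
    if (length(ir)) {
      fw <- mlp_forward(disc[[t]]$d_atac, z_ra[ir, , drop = FALSE],
                        keep_cache = TRUE)
      D <- as.numeric(fw$out)
      bk <- mlp_backward(disc[[t]]$d_atac, fw,
                         dPre_last = matrix(gam * (D - 1) / length(ir),
                                            ncol = 1))
      dz_ra[ir, ] <- dz_ra[ir, ] + bk$dX
    }
    if (length(ia)) {
      fw <- mlp_forward(disc[[t]]$d_rna, z_ar[ia, , drop = FALSE],
                        keep_cache = TRUE)
      D <- as.numeric(fw$out)
      bk <- mlp_backward(disc[[t]]$d_rna, fw,
                         dPre_last = matrix(gam * (D - 1) / length(ia),
                                            ncol = 1))
      dz_ar[ia, ] <- dz_ar[ia, ] + bk$dX
    }
  }

  ## cycle terms (targets stop-gradded); per-type mean weighting by rows
  w_r <- type_row_weights(lb_r, model$cell_types)
  w_a <- type_row_weights(lb_a, model$cell_types)
  d_cyc_r <- gam * 2 * (f_gf$out - z_r) * (w_r / k)        # MSE d/d out
  bk_gf <- mlp_backward(gen$mapper_ar, f_gf, dOut = d_cyc_r)
  dz_ra <- dz_ra + bk_gf$dX
  cyc_a <- clamp_prob(f_fg$out)
  d_cyc_a_pre <- gam * (cyc_a - z_a) * (w_a / k)           # sigmoid+BCE d/d pre
  bk_fg <- mlp_backward(gen$mapper_ra, f_fg, dPre_last = d_cyc_a_pre)
  dz_ar <- dz_ar + bk_fg$dX

  ## primary mapper passes
  bk_f <- mlp_backward(gen$mapper_ra, f_f, dOut = dz_ra)
  bk_g <- mlp_backward(gen$mapper_ar, f_g, dOut = dz_ar)
  grads_f <- tree_add(bk_fg$grads, bk_f$grads)
  grads_g <- tree_add(bk_gf$grads, bk_g$grads)

  ## reconstruction
  bd_r <- mlp_backward(gen$dec_rna, fd_r,
                       dOut = 2 * (fd_r$out - as_dense(xb_r)) /
                         length(fd_r$out))
  xb_a_d <- as_dense(xb_a)
  d_pre_a <- lapply(seq_along(layout), function(c) {
    (fd_a$chrom_caches[[c]]$out -
       xb_a_d[, layout[[c]], drop = FALSE]) / length(fd_a$out)
  })
  bd_a <- atac_decode_backward(gen$dec_atac, fd_a, layout, d_pre_a)

  ## accumulate into encoders
  dz_r <- bd_r$dX + bk_f$dX
  dz_a <- bd_a$dX + bk_g$dX
  if (lam > 0 && ncol(conf_r)) dz_r <- dz_r + lam * grad_confounder(z_r, conf_r)
  if (lam > 0 && ncol(conf_a)) dz_a <- dz_a + lam * grad_confounder(z_a, conf_a)
  be_r <- mlp_backward(gen$enc_rna, fe_r, dOut = dz_r, need_dx = FALSE)
  be_a <- atac_encode_backward(gen$enc_atac, fe_a, layout, dZ = dz_a)

  list(enc_rna = be_r$grads, dec_rna = bd_r$grads,
       enc_atac = be_a$grads, dec_atac = bd_a$grads,
       mapper_ra = grads_f, mapper_ar = grads_g)
}

# diagonal row weights: cell of type t gets 1/n_t (0 for types absent)
type_row_weights <- function(labels, types) {
  w <- numeric(length(labels))
  for (t in types) {
    idx <- which(labels == t)
    if (length(idx)) w[idx] <- 1 / length(idx)
  }
  w
}

#' Grid search over loss weights, then learning rate and batch size
#'
#' Stage 1 trains a fresh model for every point of a uniform
#' `n_points x n_points` grid over `(gamma, lambda_con)` on `[0.1, 2]^2` and
#' keeps the pair with the lowest converged total loss. Stage 2 repeats the
#' procedure over the learning rate (uniform in log-space on
#' `[1e-5, 1e-3]`) and the batch size (uniform integers on `[16, 256]`).
#' With `n_points = 1` the midpoint configuration is returned for each axis.
#'
#' @param rna,atac preprocessed, labelled matrices as for [train()].
#' @param cfg a [train_config()]; its epoch counts control how long each grid
#'   point trains.
#' @param n_points grid resolution per axis (default 5).
#' @return the selected `train_config`.
#' @export
grid_search <- function(rna, atac, cfg = train_config(), n_points = 5) {
  stopifnot(n_points >= 1)
  axis <- function(range, n, log_scale = FALSE) {
    if (n == 1) {
      if (log_scale) return(sqrt(range[1] * range[2]))
      return(mean(range))
    }
    vals <- if (log_scale) {
      exp(seq(log(range[1]), log(range[2]), length.out = n))
    } else {
      seq(range[1], range[2], length.out = n)
    }
    pmin(pmax(vals, range[1]), range[2])
  }
  layout <- chrom_layout_from_annotation(atac$feature_meta)
  types <- unique(rna$cell_meta$cell_type)
  fit_total <- function(cf) {
    model <- build_model(ncol(rna$values), ncol(atac$values), layout, types,
                         k = cfg$k, seed = cfg$seed,
                         gamma = cf$gamma, lambda_con = cf$lambda_con)
    res <- train(model, rna, atac, cf)
    utils::tail(res$history$total, 1)
  }
  gammas <- axis(cfg$grid_gamma, n_points)
  lambdas <- axis(cfg$grid_lambda, n_points)
  best <- NULL
  best_val <- Inf
  for (gm in gammas) for (lb in lambdas) {
    cf <- cfg
    cf$gamma <- gm
    cf$lambda_con <- lb
    val <- fit_total(cf)
    if (val < best_val) {
      best_val <- val
      best <- cf
    }
  }
  lrs <- axis(cfg$grid_lr, n_points, log_scale = TRUE)
  batches <- unique(as.integer(round(axis(cfg$grid_batch, n_points))))
  best2 <- best
  best_val <- Inf
  for (lr in lrs) for (bs in batches) {
    cf <- best
    cf$lr <- lr
    cf$batch_size <- as.integer(bs)
    val <- fit_total(cf)
    if (val < best_val) {
      best_val <- val
      best2 <- cf
    }
  }
  best2
}
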