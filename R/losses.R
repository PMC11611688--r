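# The four loss terms of the objective
#   L = L_rec + gamma * L_adv + lambda_con * L_con
# with L_adv the min-max adversarial pair: per-cell-type discriminator
# log-likelihood (maximized by the discriminators) and the cycle-consistency
# generator loss (minimized by encoders + mappers). Reductions are means over
# matrix entries for MSE/BCE and means over cells for expectations, so gamma
# and lambda_con stay scale-comparable across dataset sizes. Probabilities
# are clamped to [1e-7, 1 - 1e-7] before any log.

mse_mean <- function(x, x_hat) mean((as_dense(x) - x_hat)^2)

bce_mean <- function(x, p_hat) {
  p_hat <- clamp_prob(p_hat)
  x <- as_dense(x)
  -mean(x * log(p_hat) + (1 - x) * log(1 - p_hat))
}

#' Reconstruction loss
#'
#' Mean squared error on the RNA reconstruction plus binary cross-entropy on
#' the ATAC reconstruction, both mean-reduced over matrix entries.
#' Probabilities outside `[0,1]` are clamped (with a warning) at `1e-7`.
#'
#' @param xr,xr_hat observed and reconstructed RNA matrices.
#' @param xa,xa_hat observed binary ATAC matrix and reconstructed
#'   accessibility probabilities.
#' @return scalar loss.
#' @export
loss_reconstruction <- function(xr, xr_hat, xa, xa_hat) {
  stopifnot(all(dim(xr) == dim(xr_hat)), all(dim(xa) == dim(xa_hat)))
  if (any(xa_hat < 0 | xa_hat > 1)) {
    warning("ATAC reconstruction probabilities outside [0,1]; clamping")
  }
  mse_mean(xr, xr_hat) + bce_mean(xa, xa_hat)
}

# Bin a numeric confounder into quartile strata; categorical passes through.
confounder_strata <- function(x) {
  if (is.numeric(x)) {
    qs <- unique(quantile(x, probs = c(0.25, 0.5, 0.75), na.rm = TRUE))
    cut(x, breaks = unique(c(-Inf, qs, Inf)), labels = FALSE)
  } else {
    as.integer(factor(x))
  }
}

# KL( N(mu_s, diag v_s) || N(mu_p, diag v_p) ) with population variances.
diag_gaussian_kl <- function(mu_s, v_s, mu_p, v_p, eps = 1e-8) {
  v_s <- v_s + eps
  v_p <- v_p + eps
  sum(0.5 * (log(v_p / v_s) + (v_s + (mu_s - mu_p)^2) / v_p - 1))
}

#' Confounder (mutual-information surrogate) loss
#'
#' Penalizes dependence between the latent embedding and nuisance covariates
#' (batch, sequencing depth). For each confounder the cells are stratified
#' (categorical levels as-is; numeric covariates binned into quartiles), each
#' stratum is moment-matched to a diagonal Gaussian, and the loss is the sum
#' over strata of the KL divergence from the stratum Gaussian to the pooled
#' Gaussian of the whole batch. The loss is zero exactly when every stratum
#' has the pooled mean and variance — an embedding uninformative of the
#' confounder — and is invariant to permuting cells within a stratum.
#' Strata with fewer than 2 cells contribute 0 (with a warning).
#'
#' @param model a `scact_model` (unused by the value computation; kept so the
#'   surrogate is swappable per-model).
#' @param z an [embedding()] or plain matrix, cells x k.
#' @param confounders data frame with one column per confounder, rows aligned
#'   to the cells of `z`.
#' @return scalar loss, `>= 0`.
#' @export
loss_confounder <- function(model = NULL, z, confounders) {
  zm <- if (inherits(z, "embedding")) z$values else as.matrix(z)
  confounders <- as.data.frame(confounders)
  stopifnot(nrow(confounders) == nrow(zm))
  n <- nrow(zm)
  if (n < 2) return(0)
  mu_p <- colMeans(zm)
  v_p <- colMeans(zm^2) - mu_p^2
  total <- 0
  for (col in names(confounders)) {
    s <- confounder_strata(confounders[[col]])
    for (lev in unique(s)) {
      idx <- which(s == lev)
      if (length(idx) < 2) {
        warning("confounder '", col, "' stratum with < 2 cells contributes 0")
        next
      }
      zs <- zm[idx, , drop = FALSE]
      mu_s <- colMeans(zs)
      v_s <- colMeans(zs^2) - mu_s^2
      total <- total + diag_gaussian_kl(mu_s, v_s, mu_p, v_p)
    }
  }
  total
}

# Gradient of loss_confounder wrt z, treating the pooled moments as constants
# (stop-gradient); pushes each stratum's moments toward the pooled ones.
grad_confounder <- function(zm, confounders, eps = 1e-8) {
  n <- nrow(zm)
  dZ <- matrix(0, n, ncol(zm))
  if (n < 2) return(dZ)
  mu_p <- colMeans(zm)
  v_p <- colMeans(zm^2) - mu_p^2 + eps
  for (col in names(confounders)) {
    s <- confounder_strata(confounders[[col]])
    for (lev in unique(s)) {
      idx <- which(s == lev)
      if (length(idx) < 2) next
      zs <- zm[idx, , drop = FALSE]
      ns <- length(idx)
      mu_s <- colMeans(zs)
      v_s <- colMeans(zs^2) - mu_s^2 + eps
      d_mu <- (mu_s - mu_p) / v_p              # dKL/dmu_s
      d_v <- 0.5 * (1 / v_p - 1 / v_s)         # dKL/dv_s
      # chain: dmu_s/dz_i = 1/ns ; dv_s/dz_i = 2 (z_i - mu_s)/ns
      dZ[idx, ] <- dZ[idx, ] +
        matrix(d_mu / ns, ns, length(d_mu), byrow = TRUE) +
        sweep(sweep(zs, 2, mu_s, "-"), 2, 2 * d_v / ns, "*")
    }
  }
  dZ
}

disc_forward <- function(net, z) {
  as.numeric(mlp_forward(net, z)$out)
}

split_labels <- function(labels, n_r, n_a) {
  if (is.list(labels)) {
    stopifnot(length(labels$rna) == n_r, length(labels$atac) == n_a)
    list(rna = as.character(labels$rna), atac = as.character(labels$atac))
  } else {
    stopifnot(length(labels) == n_r, length(labels) == n_a)
    list(rna = as.character(labels), atac = as.character(labels))
  }
}

#' Per-cell-type discriminator loss
#'
#' For each cell type `t` with discriminator pair `(D_A^t, D_R^t)`:
#' `E[log D_A^t(z_A)] + E[log(1 - D_A^t(z_RA))] + E[log D_R^t(z_R)] +
#' E[log(1 - D_R^t(z_AR))]`, expectations over the type's cells, summed over
#' types. This is the quantity the discriminator step maximizes; it
#' approaches 0 (its supremum under clamping) for perfect discriminators.
#' Types with no member cells in the batch are skipped.
#'
#' @param model a `scact_model`.
#' @param z_r,z_a encoder embeddings of RNA and ATAC cells.
#' @param z_ra,z_ar mapped embeddings (`f(z_r)`, `g(z_a)`).
#' @param labels cell-type labels: either one vector (when RNA and ATAC cells
#'   are aligned) or `list(rna =, atac =)`.
#' @return scalar (non-positive).
#' @export
loss_discriminator <- function(model, z_r, z_a, z_ra, z_ar, labels) {
  zr <- if (inherits(z_r, "embedding")) z_r$values else z_r
  za <- if (inherits(z_a, "embedding")) z_a$values else z_a
  zra <- if (inherits(z_ra, "embedding")) z_ra$values else z_ra
  zar <- if (inherits(z_ar, "embedding")) z_ar$values else z_ar
  lab <- split_labels(labels, nrow(zr), nrow(za))
  total <- 0
  for (t in model$cell_types) {
    ir <- which(lab$rna == t)
    ia <- which(lab$atac == t)
    if (length(ir) == 0 && length(ia) == 0) next
    d <- model$discriminators[[t]]
    val <- 0
    if (length(ia)) {
      val <- val +
        mean(log(clamp_prob(disc_forward(d$d_atac, za[ia, , drop = FALSE])))) +
        mean(log(1 - clamp_prob(disc_forward(d$d_rna, zar[ia, , drop = FALSE]))))
    }
    if (length(ir)) {
      val <- val +
        mean(log(clamp_prob(disc_forward(d$d_rna, zr[ir, , drop = FALSE])))) +
        mean(log(1 - clamp_prob(disc_forward(d$d_atac, zra[ir, , drop = FALSE]))))
    }
    total <- total + val
  }
  total
}

#' Cycle-consistency (generator) loss
#'
#' Per cell type `t`: over its ATAC cells,
#' `E[-log D_R^t(z_AR) + BCE(f(g(z_A)), z_A)]`, and over its RNA cells,
#' `E[-log D_A^t(z_RA) + MSE(g(f(z_R)), z_R)]`, summed over types. The
#' adversarial terms reward fooling the discriminators on mapped embeddings;
#' the cycle terms require the round trip through both mappers to reproduce
#' the original latent. The ATAC latent is sigmoid-bounded in (0,1), so its
#' BCE cycle term is well defined; the generator step minimizes this loss.
#'
#' @inheritParams loss_discriminator
#' @return scalar.
#' @export
loss_cycle <- function(model, z_r, z_a, z_ra, z_ar, labels) {
  zr <- if (inherits(z_r, "embedding")) z_r$values else z_r
  za <- if (inherits(z_a, "embedding")) z_a$values else z_a
  zra <- if (inherits(z_ra, "embedding")) z_ra$values else z_ra
  zar <- if (inherits(z_ar, "embedding")) z_ar$values else z_ar
  lab <- split_labels(labels, nrow(zr), nrow(za))
  cyc_a <- mlp_forward(model$mapper_ra, zar)$out   # f(g(z_A)), in (0,1)
  cyc_r <- mlp_forward(model$mapper_ar, zra)$out   # g(f(z_R))
  total <- 0
  for (t in model$cell_types) {
    ir <- which(lab$rna == t)
    ia <- which(lab$atac == t)
    if (length(ir) == 0 && length(ia) == 0) next
    d <- model$discriminators[[t]]
    val <- 0
    if (length(ia)) {
      adv <- -mean(log(clamp_prob(
        disc_forward(d$d_rna, zar[ia, , drop = FALSE]))))
      bce <- bce_mean(za[ia, , drop = FALSE], cyc_a[ia, , drop = FALSE])
      val <- val + adv + bce
    }
    if (length(ir)) {
      adv <- -mean(log(clamp_prob(
        disc_forward(d$d_atac, zra[ir, , drop = FALSE]))))
      mse <- mse_mean(zr[ir, , drop = FALSE], cyc_r[ir, , drop = FALSE])
      val <- val + adv + mse
    }
    total <- total + val
  }
  total
}

#' Combine loss terms into a report
#'
#' `total = rec + gamma * adv + lambda_con * con`, where `adv` combines the
#' generator and discriminator terms of the adversarial min-max. The split
#' terms can be supplied for bookkeeping; `adv` defaults to their sum.
#'
#' @param rec,con scalar loss terms.
#' @param adv combined adversarial term; defaults to `adv_g + adv_d`.
#' @param adv_g,adv_d optional split adversarial terms.
#' @param gamma,lambda_con non-negative weights.
#' @return a `scact_loss_report` (list with `rec`, `con`, `adv_g`, `adv_d`,
#'   `total`).
#' @export
loss_total <- function(rec, adv = NULL, con = 0, gamma = 1, lambda_con = 0,
                       adv_g = NA_real_, adv_d = NA_real_) {
  stopifnot(gamma >= 0, lambda_con >= 0)
  if (is.null(adv)) adv <- sum(c(adv_g, adv_d), na.rm = TRUE)
  structure(list(rec = rec, con = con, adv_g = adv_g, adv_d = adv_d,
                 adv = adv, gamma = gamma, lambda_con = lambda_con,
                 total = rec + gamma * adv + lambda_con * con),
            class = "scact_loss_report")
}

#' @export
print.scact_loss_report <- function(x, ...) {
  cat(sprintf("loss: total=%.5g rec=%.5g adv=%.5g (g=%.5g d=%.5g) con=%.5g\n",
              x$total, x$rec, x$adv, x$adv_g, x$adv_d, x$con))
  invisible(x)
}
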