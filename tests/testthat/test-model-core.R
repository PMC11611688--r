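toy_layout <- function(p = 10, split = c(4, 6)) {
  list(chr1 = seq_len(split[1]), chr2 = split[1] + seq_len(split[2]))
}

small_model <- function(k = 4, seed = 2, types = c("t1", "t2")) {
  build_model(q = 6, p = 10, toy_layout(), cell_types = types, k = k,
              seed = seed, rna_hidden = c(8, 6), atac_hidden = c(6, 5, 4))
}

test_that("model construction is seed-deterministic and validates layout", {
  m1 <- small_model(seed = 9)
  m2 <- small_model(seed = 9)
  expect_identical(m1, m2)
  m3 <- small_model(seed = 10)
  expect_false(identical(m1$enc_rna, m3$enc_rna))
  expect_error(build_model(6, 10, list(chr1 = 1:4, chr2 = 4:10), "t"),
               "partition")
  expect_error(build_model(6, 10, list(chr1 = 1:4), "t"), "partition")
  expect_equal(length(m1$discriminators), 2)
})

test_that("the ATAC encoder emits k-dimensional embeddings with the default
          architecture and keeps inter-chromosomal weights at exactly zero", {
  p <- 30
  layout <- list(chr1 = 1:10, chr2 = 11:20, chr3 = 21:30)
  model <- build_model(q = 12, p = p, layout, c("a", "b"), seed = 1)
  expect_equal(model$k, 20)
  x <- make_atac(matrix(rbinom(p, 1, 0.5), 1, p), n_chroms = 3)
  z <- encode(model, x)
  expect_equal(dim(z$values), c(1L, 20L))
  for (side in c("encoder", "decoder")) {
    W <- masked_weight_matrix(model, side)
    mask <- scxlate:::masked_weight_mask(model, side)
    expect_true(all(W[!mask] == 0))     # exact zeros, not small values
    expect_true(any(W[mask] != 0))
  }
})

test_that("encode is batch-invariant and maps zero RNA input to the zero
          embedding under zero-initialized biases", {
  model <- small_model()
  X <- matrix(rnorm(18), 3, 6)
  m <- make_rna(abs(X))
  z <- encode(model, m)
  expect_equal(dim(z$values), c(3L, 4L))
  expect_false(z$mapped)
  z1 <- encode(model, m[2, ])
  expect_equal(z$values[2, , drop = FALSE], z1$values, ignore_attr = TRUE)
  z0 <- encode(model, make_rna(matrix(0, 2, 6)))
  expect_equal(as.numeric(z0$values), rep(0, 8))
  expect_error(encode(model, make_rna(matrix(1, 2, 5))), "expects")
})

test_that("ATAC decoding yields probabilities and the per-chromosome stage is
          blocked by chromosome", {
  model <- small_model()
  z <- embedding(matrix(rnorm(12), 3, 4), "ATAC")
  P <- decode(model, z, "ATAC")
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(dim(P), c(3L, 10L))
  # perturbing the chr2 block before the per-chromosome stage leaves chr1
  # peak outputs unchanged
  layout <- model$chrom_layout
  fw <- scxlate:::atac_decode_forward(model$dec_atac, z$values, layout)
  hh <- fw$head_cache$out
  w <- fw$block_width
  hh2 <- hh
  hh2[, (w + 1):(2 * w)] <- hh2[, (w + 1):(2 * w)] + 5
  out_chr1 <- scxlate:::mlp_forward(model$dec_atac$chrom_nets[[1]],
                                    hh2[, 1:w, drop = FALSE])$out
  expect_equal(out_chr1, fw$chrom_caches[[1]]$out)
})

test_that("an overfit autoencoder reconstructs a 5-cell toy almost exactly", {
  set.seed(12)
  nr <- make_rna(matrix(abs(rnorm(5 * 12)), 5, 12), cell_type = "t1")
  na <- make_atac(matrix(rbinom(50, 1, 0.5), 5, 10), cell_type = "t1")
  layout <- chrom_layout_from_annotation(na$feature_meta)
  model <- build_model(12, 10, layout, "t1", k = 4, seed = 2)
  res <- train(model, nr, na,
               train_config(pretrain_epochs = 300, adversarial_epochs = 0,
                            batch_size = 5, lr = 5e-3, lambda_con = 0,
                            seed = 2, early_stop = FALSE))
  zr <- encode(res$model, nr)
  mse <- mean((decode(res$model, zr, "RNA") - as.matrix(nr$values))^2)
  expect_lt(mse, 1e-2)
})

test_that("map_embedding preserves shape, flags mapped, and applies the net
          (identity weights give the identity map)", {
  model <- small_model()
  z <- embedding(matrix(rnorm(20), 5, 4), "RNA")
  out <- map_embedding(model, z, "RA")
  expect_equal(dim(out$values), c(5L, 4L))
  expect_true(out$mapped)
  # hand-built identity mapper: linear layers composing to I
  k <- model$k
  model$mapper_ar$layers <- list(
    list(W = cbind(diag(k), matrix(0, k, k)), b = numeric(2 * k),
         act = "linear"),
    list(W = diag(2 * k), b = numeric(2 * k), act = "linear"),
    list(W = rbind(diag(k), matrix(0, k, k)), b = numeric(k),
         act = "linear"))
  out2 <- map_embedding(model, z, "AR")
  expect_equal(out2$values, z$values, ignore_attr = TRUE)
})

test_that("reconstruction loss matches analytic values and an elementwise
          oracle", {
  xr <- matrix(rnorm(12), 3, 4)
  xa <- matrix(rbinom(12, 1, 0.5), 3, 4)
  # perfect RNA reconstruction with p = 0.5 everywhere: 0 + ln 2
  expect_equal(loss_reconstruction(xr, xr, xa, matrix(0.5, 3, 4)), log(2))
  # both perfect (probabilities at the clamp): ~0
  expect_lt(loss_reconstruction(xr, xr, xa, xa), 1e-5)
  set.seed(3)
  xr_hat <- xr + rnorm(12, sd = 0.3)
  p_hat <- matrix(runif(12, 0.05, 0.95), 3, 4)
  oracle <- mean((xr - xr_hat)^2) +
    -mean(xa * log(p_hat) + (1 - xa) * log(1 - p_hat))
  expect_equal(loss_reconstruction(xr, xr_hat, xa, p_hat), oracle,
               tolerance = 1e-10)
  expect_warning(loss_reconstruction(xr, xr, xa, matrix(1.2, 3, 4)),
                 "clamp")
})

test_that("confounder loss is zero for identical strata, matches the
          diagonal-Gaussian KL closed form, and is permutation-invariant", {
  zs <- matrix(rnorm(8), 4, 2)
  z <- rbind(zs, zs)                       # two strata, identical samples
  conf <- data.frame(batch = rep(c("a", "b"), each = 4))
  expect_equal(loss_confounder(NULL, z, conf), 0, tolerance = 1e-12)

  # KL primitive: unit-variance strata shifted by delta -> delta^2 / 2
  delta <- 0.7
  expect_equal(scxlate:::diag_gaussian_kl(0, 1, delta, 1), delta^2 / 2,
               tolerance = 1e-6)
  # two +/-1 strata shifted by delta, unit population variance: each
  # stratum-vs-pooled KL is log(1 + delta^2/4)/2, so the total is the log
  z2 <- matrix(c(-1, 1, -1 + delta, 1 + delta), ncol = 1)
  conf2 <- data.frame(batch = c("a", "a", "b", "b"))
  expect_equal(loss_confounder(NULL, z2, conf2), log(1 + delta^2 / 4),
               tolerance = 1e-6)

  # random 2-stratum batch vs independently coded closed-form oracle
  set.seed(9)
  z3 <- matrix(rnorm(20 * 3), 20, 3)
  s <- rep(c("a", "b"), 10)
  mu_p <- colMeans(z3); v_p <- colMeans(z3^2) - mu_p^2
  oracle <- 0
  for (lev in c("a", "b")) {
    zz <- z3[s == lev, ]
    mu_s <- colMeans(zz); v_s <- colMeans(zz^2) - mu_s^2
    oracle <- oracle + sum(0.5 * (log((v_p + 1e-8) / (v_s + 1e-8)) +
      (v_s + 1e-8 + (mu_s - mu_p)^2) / (v_p + 1e-8) - 1))
  }
  expect_equal(loss_confounder(NULL, z3, data.frame(batch = s)), oracle,
               tolerance = 1e-10)
  perm <- c(sample(which(s == "a")), sample(which(s == "b")))
  expect_equal(loss_confounder(NULL, z3[perm, ], data.frame(batch = s[perm])),
               oracle, tolerance = 1e-10)
  # numeric confounders are binned into quartile strata
  expect_gte(loss_confounder(NULL, z3, data.frame(depth = rnorm(20))), 0)
})

zero_disc_outputs <- function(model) {
  for (t in names(model$discriminators)) {
    for (d in c("d_atac", "d_rna")) {
      L <- length(model$discriminators[[t]][[d]]$layers)
      model$discriminators[[t]][[d]]$layers[[L]]$W[] <- 0
      model$discriminators[[t]][[d]]$layers[[L]]$b[] <- 0
    }
  }
  model
}

test_that("discriminator loss hits its analytic values and a hand-summed
          oracle", {
  model <- zero_disc_outputs(small_model())     # every D outputs 0.5
  k <- model$k
  z <- function(n) matrix(rnorm(n * k), n, k)
  # singleton expectations per type: 4 * log(0.5) per cell type
  val <- loss_discriminator(model, z(2), z(2), z(2), z(2),
                            labels = list(rna = c("t1", "t2"),
                                          atac = c("t1", "t2")))
  expect_equal(val, 2 * 4 * log(0.5), tolerance = 1e-10)

  # perfect discriminators: value ~ 0 (its maximum under clamping)
  sharp <- small_model(types = "t1")
  big <- 50
  for (d in c("d_atac", "d_rna")) {
    sharp$discriminators$t1[[d]]$layers <- list(
      list(W = diag(4) * big, b = numeric(4), act = "tanh"),
      list(W = diag(4) * big, b = numeric(4), act = "tanh"),
      list(W = matrix(big, 4, 1), b = -2 * big, act = "sigmoid"))
  }
  real <- matrix(1, 3, 4)          # all-positive -> D ~ 1
  fake <- matrix(-1, 3, 4)         # all-negative -> D ~ 0
  val2 <- loss_discriminator(sharp, z_r = real, z_a = real,
                             z_ra = fake, z_ar = fake,
                             labels = list(rna = rep("t1", 3),
                                           atac = rep("t1", 3)))
  expect_gt(val2, -1e-3)
  expect_lte(val2, 0)

  # 2-type 4-cell toy against an explicitly coded oracle
  set.seed(4)
  model2 <- small_model()
  zr <- z(4); za <- z(4); zra <- z(4); zar <- z(4)
  lr <- c("t1", "t1", "t2", "t2"); la <- c("t2", "t1", "t2", "t1")
  dfwd <- function(net, x) {
    as.numeric(scxlate:::mlp_forward(net, x)$out)
  }
  oracle <- 0
  for (t in c("t1", "t2")) {
    d <- model2$discriminators[[t]]
    ia <- la == t; ir <- lr == t
    oracle <- oracle +
      mean(log(dfwd(d$d_atac, za[ia, , drop = FALSE]))) +
      mean(log(1 - dfwd(d$d_rna, zar[ia, , drop = FALSE]))) +
      mean(log(dfwd(d$d_rna, zr[ir, , drop = FALSE]))) +
      mean(log(1 - dfwd(d$d_atac, zra[ir, , drop = FALSE])))
  }
  expect_equal(
    loss_discriminator(model2, zr, za, zra, zar,
                       labels = list(rna = lr, atac = la)),
    oracle, tolerance = 1e-10)
})

test_that("cycle loss combines adversarial and round-trip terms as specified", {
  model <- zero_disc_outputs(small_model(types = "t1"))
  k <- model$k
  delta <- 0.6
  # mapper_ar = identity + delta; mapper_ra = constant 0.5 (zero weights)
  model$mapper_ar$layers <- list(
    list(W = cbind(diag(k), matrix(0, k, k)), b = numeric(2 * k),
         act = "linear"),
    list(W = diag(2 * k), b = numeric(2 * k), act = "linear"),
    list(W = rbind(diag(k), matrix(0, k, k)), b = rep(delta, k),
         act = "linear"))
  for (l in 1:3) {
    model$mapper_ra$layers[[l]]$W[] <- 0
    model$mapper_ra$layers[[l]]$b[] <- 0
  }
  set.seed(5)
  z_r <- matrix(rnorm(3 * k), 3, k)
  z_a <- matrix(runif(3 * k, 0.2, 0.8), 3, k)
  # pass z_ra = z_r so that g(z_ra) = z_r + delta: MSE term = delta^2;
  # f(g(z_a)) = 0.5 so the BCE term is log 2 for any target; both
  # adversarial terms are -log(0.5) under the zeroed discriminators
  val <- loss_cycle(model, z_r, z_a, z_r, z_a,
                    labels = list(rna = rep("t1", 3), atac = rep("t1", 3)))
  expect_equal(val, 3 * log(2) + delta^2, tolerance = 1e-10)

  # fixed random tensors against an explicitly coded oracle
  model2 <- small_model()
  zr <- matrix(rnorm(16), 4, 4); za <- matrix(runif(16), 4, 4)
  zra <- matrix(rnorm(16), 4, 4); zar <- matrix(rnorm(16), 4, 4)
  lr <- c("t1", "t2", "t1", "t2"); la <- c("t2", "t2", "t1", "t1")
  fwd <- function(net, x) scxlate:::mlp_forward(net, x)$out
  cyc_a <- fwd(model2$mapper_ra, zar)
  cyc_r <- fwd(model2$mapper_ar, zra)
  oracle <- 0
  for (t in c("t1", "t2")) {
    d <- model2$discriminators[[t]]
    ia <- la == t; ir <- lr == t
    bce <- -mean(za[ia, ] * log(cyc_a[ia, ]) +
                   (1 - za[ia, ]) * log(1 - cyc_a[ia, ]))
    oracle <- oracle +
      (-mean(log(fwd(d$d_rna, zar[ia, , drop = FALSE])))) + bce +
      (-mean(log(fwd(d$d_atac, zra[ir, , drop = FALSE])))) +
      mean((cyc_r[ir, ] - zr[ir, ])^2)
  }
  expect_equal(loss_cycle(model2, zr, za, zra, zar,
                          labels = list(rna = lr, atac = la)),
               oracle, tolerance = 1e-10)
})

test_that("total loss is the stated linear combination and the report is
          internally consistent", {
  expect_equal(loss_total(rec = 1, adv = 2, con = 3, gamma = 0.5,
                          lambda_con = 0.1)$total, 2.3)
  expect_equal(loss_total(rec = 4, adv = 9, con = 7, gamma = 0,
                          lambda_con = 0)$total, 4)
  set.seed(6)
  for (i in 1:5) {
    w <- runif(5)
    rep <- loss_total(rec = w[1], adv_g = w[2], adv_d = w[3], con = w[4],
                      gamma = w[5], lambda_con = runif(1))
    expect_equal(rep$total,
                 rep$rec + rep$gamma * (rep$adv_g + rep$adv_d) +
                   rep$lambda_con * rep$con,
                 tolerance = 1e-6)
  }
})

test_that("one discriminator step raises its objective and one generator step
          lowers its own, each leaving the other side's parameters intact", {
  fix <- toy_fixture()
  layout <- chrom_layout_from_annotation(fix$atac$feature_meta)
  model <- build_model(40, 60, layout, unique(fix$rna$cell_meta$cell_type),
                       k = 8, seed = 7)
  gen <- scxlate:::generator_params(model)
  disc <- model$discriminators
  Xr <- scxlate:::as_dense(fix$rna$values)
  Xa <- fix$atac$values
  lr_lab <- fix$rna$cell_meta$cell_type
  la_lab <- fix$atac$cell_meta$cell_type
  conf_r <- scxlate:::confounder_table(fix$rna)
  conf_a <- scxlate:::confounder_table(fix$atac)

  d_obj <- function(disc_now, gen_now) {
    m <- model; m[names(gen_now)] <- gen_now; m$discriminators <- disc_now
    z_r <- scxlate:::mlp_forward(gen_now$enc_rna, Xr)$out
    z_a <- scxlate:::atac_encode_forward(gen_now$enc_atac, Xa, layout)$out
    z_ra <- scxlate:::mlp_forward(gen_now$mapper_ra, z_r)$out
    z_ar <- scxlate:::mlp_forward(gen_now$mapper_ar, z_a)$out
    loss_discriminator(m, z_r, z_a, z_ra, z_ar,
                       list(rna = lr_lab, atac = la_lab))
  }
  before <- d_obj(disc, gen)
  dg <- scxlate:::disc_grads(gen, disc, model, Xr, Xa, lr_lab, la_lab)
  disc2 <- scxlate:::adam_step(disc, dg, scxlate:::adam_init(disc),
                               lr = 1e-3)$params
  expect_gt(d_obj(disc2, gen), before)

  g_obj <- function(gen_now) {
    m <- model; m[names(gen_now)] <- gen_now; m$discriminators <- disc2
    rep <- scxlate:::full_losses(m, Xr, Xa, conf_r, conf_a, lr_lab, la_lab,
                                 gam = 1, lam = 0.1)
    rep$rec + 1 * rep$adv_g + 0.1 * rep$con
  }
  before_g <- g_obj(gen)
  gg <- scxlate:::gen_grads(gen, disc2, model, Xr, Xa, lr_lab, la_lab,
                            conf_r, conf_a, gam = 1, lam = 0.1)
  gen2 <- scxlate:::adam_step(gen, gg, scxlate:::adam_init(gen),
                              lr = 1e-4)$params
  expect_lt(g_obj(gen2), before_g)
  # parameter isolation
  expect_identical(gen, scxlate:::generator_params(model))
  expect_identical(disc2[["type1"]]$d_atac$layers[[1]]$act,
                   disc[["type1"]]$d_atac$layers[[1]]$act)
})

test_that("checkpoints round-trip bit-exactly", {
  model <- trained_toy()$model
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  expect_identical(load_checkpoint(f), model)
  g <- glance(model)
  expect_equal(g$k, 8)
  expect_gt(g$n_parameters, 1000)
})
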