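# Minimal dense neural-network machinery: MLPs with explicit forward /
# backward passes, chromosome-blocked encoder/decoder stacks, and an Adam
# optimizer over nested parameter trees. Everything is plain base-R matrix
# algebra; sparsity of the first ATAC layer input is exploited via Matrix.
#
# Conventions: data matrices are cells x features; a layer is
# list(W = in x out, b = out, act = "linear"|"relu"|"sigmoid"); an MLP is
# list(layers = list(...)). Backward passes return both parameter gradients
# (same shape as the module) and the gradient with respect to the input.

act_apply <- function(x, act) {
  switch(act,
         linear = x,
         relu = relu(x),
         tanh = tanh(x),
         sigmoid = sigmoid(x),
         stop("unknown activation: ", act))
}

# derivative expressed through the activated output
act_deriv <- function(out, act) {
  switch(act,
         linear = 1,
         relu = (out > 0) * 1,
         tanh = 1 - out^2,
         sigmoid = out * (1 - out),
         stop("unknown activation: ", act))
}

mlp_init <- function(sizes, acts) {
  stopifnot(length(sizes) == length(acts) + 1)
  layers <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    fan_in <- sizes[l]
    sd <- if (acts[l] == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * sizes[l + 1], sd = sd), fan_in, sizes[l + 1]),
      b = numeric(sizes[l + 1]),
      act = acts[l]
    )
  }
  list(layers = layers)
}

mlp_forward <- function(net, X, keep_cache = FALSE) {
  inputs <- if (keep_cache) vector("list", length(net$layers))
  a <- X
  outs <- if (keep_cache) vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    if (keep_cache) inputs[[l]] <- a
    pre <- as.matrix(a %*% ly$W)
    pre <- sweep(pre, 2, ly$b, "+")
    a <- act_apply(pre, ly$act)
    if (keep_cache) outs[[l]] <- a
  }
  if (keep_cache) list(out = a, inputs = inputs, outs = outs) else list(out = a)
}

# dOut: gradient wrt the activated output of the last layer; alternatively
# dPre_last gives the gradient wrt its pre-activation directly (numerically
# preferable for sigmoid + BCE). Set need_dx = FALSE to skip input gradients.
mlp_backward <- function(net, cache, dOut = NULL, dPre_last = NULL,
                         need_dx = TRUE) {
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- NULL
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    if (l == L && !is.null(dPre_last)) {
      delta <- dPre_last
    } else {
      d_out_l <- if (l == L) dOut else delta %*% t(net$layers[[l + 1]]$W)
      delta <- d_out_l * act_deriv(cache$outs[[l]], ly$act)
    }
    a_prev <- cache$inputs[[l]]
    dW <- as.matrix(Matrix::crossprod(a_prev, delta))
    grads[[l]] <- list(W = dW, b = colSums(delta), act = ly$act)
  }
  dX <- if (need_dx) as.matrix(delta %*% t(net$layers[[1]]$W)) else NULL
  list(grads = list(layers = grads), dX = dX)
}

# ---- chromosome-blocked ATAC encoder / decoder -----------------------------
#
# The encoder runs one sub-network per chromosome (peak block -> 128 -> 64 ->
# 32, ReLU), concatenates the 32-unit blocks and projects linearly to the
# k-dimensional latent with a sigmoid output. Because each sub-network only
# sees its own chromosome's peaks, every inter-chromosomal weight is
# structurally zero; atac_first_layer_matrix() materializes the equivalent
# block-diagonal weight matrix. The decoder mirrors this in reverse with a
# sigmoid accessibility probability per peak.

atac_encoder_init <- function(layout, hidden = c(128, 64, 32), k = 20,
                              act = "tanh") {
  chrom_nets <- lapply(layout, function(idx) {
    mlp_init(c(length(idx), hidden), rep(act, length(hidden)))
  })
  head <- mlp_init(c(utils::tail(hidden, 1) * length(layout), k), "sigmoid")
  list(chrom_nets = chrom_nets, head = head)
}

atac_decoder_init <- function(layout, hidden = c(128, 64, 32), k = 20,
                              act = "tanh") {
  h_rev <- rev(hidden)                      # 32, 64, 128
  chrom_nets <- lapply(layout, function(idx) {
    mlp_init(c(h_rev, length(idx)),
             c(rep(act, length(h_rev) - 1), "sigmoid"))
  })
  head <- mlp_init(c(k, h_rev[1] * length(layout)), act)
  list(chrom_nets = chrom_nets, head = head)
}

atac_encode_forward <- function(enc, X, layout, keep_cache = FALSE) {
  caches <- vector("list", length(layout))
  blocks <- vector("list", length(layout))
  for (c in seq_along(layout)) {
    fw <- mlp_forward(enc$chrom_nets[[c]], X[, layout[[c]], drop = FALSE],
                      keep_cache)
    caches[[c]] <- fw
    blocks[[c]] <- fw$out
  }
  hh <- do.call(cbind, blocks)
  head_fw <- mlp_forward(enc$head, hh, keep_cache)
  list(out = head_fw$out, chrom_caches = caches, head_cache = head_fw,
       block_width = ncol(blocks[[1]]))
}

atac_encode_backward <- function(enc, fw, layout, dZ = NULL, dPre_last = NULL,
                                 need_dx = FALSE, p = NULL) {
  hb <- mlp_backward(enc$head, fw$head_cache, dOut = dZ,
                     dPre_last = dPre_last, need_dx = TRUE)
  w <- fw$block_width
  chrom_grads <- vector("list", length(layout))
  dX <- if (need_dx) matrix(0, nrow(hb$dX), p) else NULL
  for (c in seq_along(layout)) {
    cols <- ((c - 1) * w + 1):(c * w)
    cb <- mlp_backward(enc$chrom_nets[[c]], fw$chrom_caches[[c]],
                       dOut = hb$dX[, cols, drop = FALSE], need_dx = need_dx)
    chrom_grads[[c]] <- cb$grads
    if (need_dx) dX[, layout[[c]]] <- cb$dX
  }
  names(chrom_grads) <- names(layout)
  list(grads = list(chrom_nets = chrom_grads, head = hb$grads), dX = dX)
}

atac_decode_forward <- function(dec, Z, layout, keep_cache = FALSE) {
  head_fw <- mlp_forward(dec$head, Z, keep_cache)
  w <- ncol(head_fw$out) / length(layout)
  p <- sum(lengths(layout))
  P <- matrix(0, nrow(Z), p)
  caches <- vector("list", length(layout))
  for (c in seq_along(layout)) {
    cols <- ((c - 1) * w + 1):(c * w)
    fw <- mlp_forward(dec$chrom_nets[[c]],
                      head_fw$out[, cols, drop = FALSE], keep_cache)
    caches[[c]] <- fw
    P[, layout[[c]]] <- fw$out
  }
  list(out = P, head_cache = head_fw, chrom_caches = caches, block_width = w)
}

# dPre_chrom: list per chromosome of gradients wrt the pre-sigmoid peak
# outputs (the natural quantity for BCE); returns dZ.
atac_decode_backward <- function(dec, fw, layout, dPre_chrom) {
  w <- fw$block_width
  dHH <- matrix(0, nrow(fw$head_cache$out), ncol(fw$head_cache$out))
  chrom_grads <- vector("list", length(layout))
  for (c in seq_along(layout)) {
    cb <- mlp_backward(dec$chrom_nets[[c]], fw$chrom_caches[[c]],
                       dPre_last = dPre_chrom[[c]], need_dx = TRUE)
    chrom_grads[[c]] <- cb$grads
    cols <- ((c - 1) * w + 1):(c * w)
    dHH[, cols] <- cb$dX
  }
  names(chrom_grads) <- names(layout)
  hb <- mlp_backward(dec$head, fw$head_cache, dOut = dHH, need_dx = TRUE)
  list(grads = list(chrom_nets = chrom_grads, head = hb$grads), dX = hb$dX)
}

# Materialize the peak -> first-hidden-layer weight matrix of the ATAC
# encoder (or the mirror last layer of the decoder) as one p x (units * n_chrom)
# matrix; entries linking a peak to another chromosome's sub-network are
# exactly zero by construction.
atac_first_layer_matrix <- function(module, layout, decoder = FALSE) {
  p <- sum(lengths(layout))
  if (decoder) {
    units <- vapply(module$chrom_nets, function(n) {
      nrow(n$layers[[length(n$layers)]]$W)
    }, 1L)
  } else {
    units <- vapply(module$chrom_nets, function(n) ncol(n$layers[[1]]$W), 1L)
  }
  W <- matrix(0, p, sum(units))
  off <- 0L
  for (c in seq_along(layout)) {
    cols <- (off + 1L):(off + units[c])
    blk <- if (decoder) {
      t(module$chrom_nets[[c]]$layers[[length(module$chrom_nets[[c]]$layers)]]$W)
    } else {
      module$chrom_nets[[c]]$layers[[1]]$W
    }
    W[layout[[c]], cols] <- blk
    off <- off + units[c]
  }
  W
}

# ---- parameter trees and Adam ----------------------------------------------
# Parameter containers are nested lists whose numeric leaves are weights;
# character leaves (activation tags) and NULLs pass through untouched.

tree_map <- function(f, x) {
  if (is.list(x)) return(lapply(x, tree_map, f = f))
  if (is.numeric(x)) return(f(x))
  x
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    if (!is.null(names(x)) && !is.null(names(y))) y <- y[names(x)]
    return(mapply(tree_map2, x, y, MoreArgs = list(f = f), SIMPLIFY = FALSE))
  }
  if (is.numeric(x)) return(f(x, y))
  x
}

tree_add <- function(x, y) tree_map2(`+`, x, y)

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}
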