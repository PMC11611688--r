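# Internal numeric and RNG helpers shared across modules.

#' @importFrom stats rnorm runif rbinom rnbinom rlnorm var cor cor.test
#'   t.test var.test kmeans quantile sd setNames
#' @importFrom methods as is
NULL

# Probability clamp applied before any log(); keeps BCE finite.
.PROB_EPS <- 1e-7

clamp_prob <- function(p, eps = .PROB_EPS) {
  pmin(pmax(p, eps), 1 - eps)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-stage seed derived from one pipeline seed; stays < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

# Row-wise L2-normalise; zero rows stay zero.
l2_normalize_rows <- function(x) {
  n <- sqrt(rowSums(x^2))
  n[n == 0] <- 1
  x / n
}

# Cosine distance matrix between rows of a and rows of b (1 - cosine similarity).
cosine_distance <- function(a, b = a) {
  d <- 1 - tcrossprod(l2_normalize_rows(a), l2_normalize_rows(b))
  pmin(pmax(d, 0), 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
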