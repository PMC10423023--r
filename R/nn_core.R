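# Minimal neural-network core: seeded uniform fan-in initialization, ReLU,
# dense layers, an MLP with sigmoid output and ratio-weighted cross entropy,
# and an Adam optimizer operating on flat named lists of parameter arrays.
# Forward passes return caches consumed by the matching backward passes; all
# randomness flows through the R RNG so runs are reproducible from a seed.

init_weight <- function(nin, nout) {
  s <- sqrt(1 / nin)
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

init_bias <- function(nout) numeric(nout)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Linear layer helpers on row-major batches (B x d).
linear_forward <- function(X, W, b) {
  sweep(X %*% W, 2L, b, "+")
}

# Given upstream gradient dY: returns dX and parameter grads.
linear_backward <- function(X, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function(params) {
  # p * 0 keeps each parameter's exact shape (matrix vs plain vector)
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Accumulate gradient lists (same structure).
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- (a[[nm]] %||% 0) + b[[nm]]
  a
}

# ---- MLP predictor ----------------------------------------------------------

mlp_init <- function(in_dim, hidden, seed = NULL) {
  build <- function() {
    list(W1 = init_weight(in_dim, hidden), b1 = init_bias(hidden),
         W2 = init_weight(hidden, 1L), b2 = init_bias(1L))
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

mlp_forward <- function(params, X) {
  H_pre <- linear_forward(X, params$W1, params$b1)
  H <- relu(H_pre)
  logit <- linear_forward(H, params$W2, params$b2)
  p <- 1 / (1 + exp(-logit))
  list(p = as.vector(p), logit = as.vector(logit), H = H, H_pre = H_pre, X = X)
}

# dlogit: vector of dL/dlogit per row.
mlp_backward <- function(params, cache, dlogit) {
  dlogit <- matrix(dlogit, ncol = 1L)
  g2 <- linear_backward(cache$H, params$W2, dlogit)
  dH <- g2$dX
  dH[cache$H_pre <= 0] <- 0
  g1 <- linear_backward(cache$X, params$W1, dH)
  list(grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db),
       dX = g1$dX)
}

# ---- batch standardization --------------------------------------------------

# Column-wise standardization of a feature batch (batch-norm without affine).
# Keeps entity-discriminating variance at O(1) ahead of the MLP head.
batchnorm_forward <- function(X, eps = 1e-5) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  v <- colMeans(Xc * Xc)
  std <- sqrt(v + eps)
  Xhat <- sweep(Xc, 2L, std, "/")
  list(Xhat = Xhat, cache = list(Xhat = Xhat, std = std, B = nrow(X)),
       mu = mu, var = v)
}

batchnorm_backward <- function(cache, dXhat) {
  B <- cache$B
  term <- sweep(dXhat, 2L, colMeans(dXhat)) -
    cache$Xhat * rep(colMeans(dXhat * cache$Xhat), each = B)
  sweep(term, 2L, cache$std, "/")
}

# Standardize with fixed statistics (evaluation mode).
standardize_with <- function(X, mu, var, eps = 1e-5) {
  sweep(sweep(X, 2L, mu), 2L, sqrt(var + eps), "/")
}

#' Ratio-weighted binary cross entropy
#'
#' Mean over examples of `w_i * ce_i` where `ce_i` is the cross entropy of
#' predicted probability `p_i` against label `y_i` and `w_i = pos_weight` for
#' positives, 1 for negatives. `pos_weight` is set to the negative-to-positive
#' ratio of the training data so the minority positive class is not swamped.
#'
#' @param p predicted probabilities in (0, 1).
#' @param y binary 0/1 labels.
#' @param pos_weight weight applied to positive examples.
#' @return list with `loss` and `dlogit`, the gradient with respect to the
#'   pre-sigmoid logits (already divided by the batch size).
#' @export
weighted_bce <- function(p, y, pos_weight = 1) {
  eps <- 1e-12
  y <- as.numeric(y)
  w <- ifelse(y == 1, pos_weight, 1)
  ce <- -(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  loss <- mean(w * ce)
  dlogit <- w * (p - y) / length(y)
  list(loss = loss, dlogit = dlogit)
}
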