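# Contrastive multiview coding machinery: a temperature-scaled cosine
# discriminator, the directed in-batch InfoNCE loss, its symmetrized total,
# and the pairwise extension to three or more views. Within a batch of k
# aligned rows, row n of each view is the congruent partner of row n of the
# other view; the remaining k - 1 rows act as non-congruent candidates.

#' Contrastive loss configuration
#'
#' @param temperature positive temperature `tau` dividing the cosine
#'   similarity inside the discriminator exponent (default 0.07, the best
#'   value on a 0.05-0.08 grid).
#' @param batch_size number of distinct keys per contrastive batch.
#' @return a `contrastive_config` list.
#' @export
contrastive_config <- function(temperature = 0.07, batch_size = 8L) {
  if (!is.numeric(temperature) || temperature <= 0) {
    stop_value("temperature must be > 0")
  }
  if (batch_size < 1L) stop_value("batch_size must be >= 1")
  structure(list(temperature = temperature,
                 batch_size = as.integer(batch_size)),
            class = "contrastive_config")
}

# Row-normalize with a hard error on exactly-zero rows and an epsilon floor
# against underflow.
normalize_rows <- function(Z, what = "embedding") {
  r <- sqrt(rowSums(Z * Z))
  if (any(r == 0)) stop_value("zero %s vector in contrastive loss", what)
  list(U = Z / pmax(r, 1e-12), r = pmax(r, 1e-12))
}

#' Temperature-scaled cosine discriminator
#'
#' `h_theta(z1, z2) = exp(cos(z1, z2) / tau)`: symmetric in its arguments,
#' invariant to positive rescaling of either vector, bounded in
#' `[exp(-1/tau), exp(1/tau)]`.
#'
#' @param z1,z2 nonzero numeric vectors of equal dimension.
#' @param tau positive temperature.
#' @return a positive scalar.
#' @export
discriminator <- function(z1, z2, tau = 0.07) {
  if (length(z1) != length(z2)) stop_value("dimension mismatch in discriminator")
  if (tau <= 0) stop_value("tau must be > 0")
  n1 <- sqrt(sum(z1 * z1))
  n2 <- sqrt(sum(z2 * z2))
  if (n1 == 0 || n2 == 0) stop_value("zero vector passed to discriminator")
  exp(sum(z1 * z2) / (n1 * n2) / tau)
}

check_batches <- function(Z1, Z2) {
  Z1 <- as.matrix(Z1)
  Z2 <- as.matrix(Z2)
  if (nrow(Z1) != nrow(Z2)) stop_value("batch size mismatch (%d vs %d)",
                                       nrow(Z1), nrow(Z2))
  if (ncol(Z1) != ncol(Z2)) stop_value("embedding dimension mismatch (%d vs %d)",
                                       ncol(Z1), ncol(Z2))
  list(Z1 = Z1, Z2 = Z2)
}

# Cosine similarity matrix S = U V^T and normalization caches.
cosine_matrix <- function(Z1, Z2) {
  n1 <- normalize_rows(Z1)
  n2 <- normalize_rows(Z2)
  list(S = tcrossprod(n1$U, n2$U), U = n1$U, V = n2$U, r1 = n1$r, r2 = n2$r)
}

#' Directed in-batch contrastive loss
#'
#' Anchoring view 1, the loss is the mean over the k anchors of
#' `-log( h(z1_n, z2_n) / sum_m h(z1_n, z2_m) )`, i.e. an InfoNCE softmax over
#' the k in-batch candidates (the congruent column included). It is 0 exactly
#' when `k = 1` and `log k` when all embeddings coincide.
#'
#' @param Z1,Z2 aligned k x m embedding matrices (row n of each is the
#'   congruent pair for key n).
#' @param tau positive temperature.
#' @return nonnegative scalar.
#' @export
contrastive_loss_directed <- function(Z1, Z2, tau = 0.07) {
  b <- check_batches(Z1, Z2)
  cm <- cosine_matrix(b$Z1, b$Z2)
  L <- cm$S / tau
  mean(row_logsumexp(L) - diag(L))
}

# Loss and gradients for the directed loss anchored on Z1.
# dS convention: dL/dS_nm = (P_nm - I_nm) / k with P = row softmax of S/tau.
directed_loss_grad_core <- function(cm, tau) {
  k <- nrow(cm$S)
  L <- cm$S / tau
  lse <- row_logsumexp(L)
  loss <- mean(lse - diag(L))
  P <- exp(L - lse)
  dS <- (P - diag(1, k)) / (k * tau)
  dU <- dS %*% cm$V
  dV <- crossprod(dS, cm$U)
  list(loss = loss, dU = dU, dV = dV)
}

# Chain a gradient on the row-normalized U back to Z.
denormalize_grad <- function(dU, U, r) {
  (dU - U * rowSums(dU * U)) / r
}

#' Symmetric total contrastive loss with gradients
#'
#' @inheritParams contrastive_loss_directed
#' @return list with `loss` (the symmetric total), `dZ1`, `dZ2`.
#' @export
total_loss_grad <- function(Z1, Z2, tau = 0.07) {
  b <- check_batches(Z1, Z2)
  cm <- cosine_matrix(b$Z1, b$Z2)
  fwd <- directed_loss_grad_core(cm, tau)
  # reverse direction: anchor Z2, similarity matrix is t(S)
  cm_rev <- list(S = t(cm$S), U = cm$V, V = cm$U)
  rev <- directed_loss_grad_core(cm_rev, tau)
  dU <- fwd$dU + rev$dV
  dV <- fwd$dV + rev$dU
  list(loss = fwd$loss + rev$loss,
       dZ1 = denormalize_grad(dU, cm$U, cm$r1),
       dZ2 = denormalize_grad(dV, cm$V, cm$r2))
}

#' Symmetric total contrastive loss
#'
#' Sum of the two directed losses (view 1 anchored plus view 2 anchored),
#' giving equal weight to both views; symmetric in its arguments.
#'
#' @inheritParams contrastive_loss_directed
#' @return nonnegative scalar.
#' @export
total_loss <- function(Z1, Z2, tau = 0.07) {
  total_loss_grad(Z1, Z2, tau)$loss
}

#' Pairwise multiview contrastive loss
#'
#' For three or more aligned views the loss is the sum of [total_loss()] over
#' all unordered view pairs (three pairwise terms for three views), each pair
#' weighted equally.
#'
#' @param batches list of >= 2 aligned k x m embedding matrices.
#' @param tau positive temperature.
#' @return nonnegative scalar.
#' @export
multiview_loss <- function(batches, tau = 0.07) {
  multiview_loss_grad(batches, tau)$loss
}

#' Pairwise multiview loss with gradients
#'
#' @inheritParams multiview_loss
#' @return list with `loss` and `dZ`, a list of gradients aligned with
#'   `batches`.
#' @export
multiview_loss_grad <- function(batches, tau = 0.07) {
  if (!is.list(batches) || length(batches) < 2L) {
    stop_value("multiview loss needs at least 2 views")
  }
  loss <- 0
  dZ <- vector("list", length(batches))
  for (a in seq_len(length(batches) - 1L)) {
    for (b in seq((a + 1L), length(batches))) {
      g <- total_loss_grad(batches[[a]], batches[[b]], tau)
      loss <- loss + g$loss
      dZ[[a]] <- (dZ[[a]] %||% 0) + g$dZ1
      dZ[[b]] <- (dZ[[b]] %||% 0) + g$dZ2
    }
  }
  list(loss = loss, dZ = dZ)
}

# Per-anchor diagnostics for the training log: rank of the congruent
# candidate within the batch and mean non-congruent similarity.
contrastive_diagnostics <- function(Z1, Z2, tau = 0.07) {
  b <- check_batches(Z1, Z2)
  cm <- cosine_matrix(b$Z1, b$Z2)
  k <- nrow(cm$S)
  ranks <- vapply(seq_len(k), function(n) {
    sum(cm$S[n, ] >= cm$S[n, n])
  }, 1L)
  neg_mean <- vapply(seq_len(k), function(n) {
    if (k == 1L) NA_real_ else mean(cm$S[n, -n])
  }, 1)
  list(congruent_rank = ranks, mean_negative_similarity = neg_mean)
}
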