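# 1D convolutional encoder for tokenized protein sequences: a learned residue
# embedding table, stacked same-padded convolution blocks with ReLU, a global
# max pool over positions and one fully connected output layer. A batch of B
# sequences of length L is processed as one stacked (B*L) x channels matrix so
# each convolution is a single im2col matrix multiplication. By default the
# convolutions run over the padded tensor; masking beyond the original length
# is available via `mask_padding`.

cnn_init <- function(vocab_size, embed_dim, channels, kernel_sizes, out_dim,
                     mask_padding = FALSE) {
  stopifnot(length(channels) == length(kernel_sizes),
            all(kernel_sizes %% 2L == 1L))
  params <- list(E = init_weight(vocab_size + 1L, embed_dim))
  cin <- embed_dim
  for (l in seq_along(channels)) {
    params[[paste0("Wc", l)]] <- init_weight(kernel_sizes[l] * cin, channels[l])
    params[[paste0("bc", l)]] <- init_bias(channels[l])
    cin <- channels[l]
  }
  params$Wf <- init_weight(cin, out_dim)
  params$bf <- init_bias(out_dim)
  structure(list(params = params, vocab_size = vocab_size,
                 embed_dim = embed_dim, channels = channels,
                 kernel_sizes = kernel_sizes, out_dim = out_dim,
                 mask_padding = mask_padding),
            class = "cnn_encoder")
}

# im2col row-index matrix for B sequences of length L and kernel k: entry
# [r, o] is the row of rbind(0, X) feeding offset o of output row r, with 1
# pointing at the zero pad row.
conv_index <- function(B, L, k) {
  h <- (k - 1L) %/% 2L
  pos <- rep(seq_len(L), times = B)
  seq_of_row <- rep(seq_len(B), each = L)
  idx <- matrix(1L, B * L, k)
  for (o in seq_len(k)) {
    src <- pos + (o - 1L - h)
    ok <- src >= 1L & src <= L
    idx[ok, o] <- (seq_of_row[ok] - 1L) * L + src[ok] + 1L
  }
  idx
}

conv_im2col <- function(X, idx) {
  Xp <- rbind(0, X)
  do.call(cbind, lapply(seq_len(ncol(idx)), function(o) {
    Xp[idx[, o], , drop = FALSE]
  }))
}

# tokens: B x L integer matrix (0 = padding).
cnn_forward <- function(enc, tokens) {
  p <- enc$params
  B <- nrow(tokens)
  L <- ncol(tokens)
  tok_vec <- as.integer(t(tokens))  # row-major: (b, pos) -> (b-1)*L + pos
  X <- p$E[tok_vec + 1L, , drop = FALSE]
  mask <- NULL
  if (enc$mask_padding) {
    mask <- tok_vec != 0L
    X[!mask, ] <- 0
  }
  caches <- vector("list", length(enc$channels))
  for (l in seq_along(enc$channels)) {
    k <- enc$kernel_sizes[l]
    idx <- conv_index(B, L, k)
    Xc <- conv_im2col(X, idx)
    pre <- sweep(Xc %*% p[[paste0("Wc", l)]], 2L, p[[paste0("bc", l)]], "+")
    H <- relu(pre)
    if (enc$mask_padding) H[!mask, ] <- 0
    caches[[l]] <- list(X = X, Xc = Xc, pre = pre, idx = idx)
    X <- H
  }
  C_last <- ncol(X)
  # global max pool per sequence per channel
  G <- matrix(0, B, C_last)
  argmax <- matrix(0L, B, C_last)
  for (ch in seq_len(C_last)) {
    m <- matrix(X[, ch], nrow = L)  # L x B (row-major stacking)
    am <- max.col(t(m), ties.method = "first")
    argmax[, ch] <- (seq_len(B) - 1L) * L + am
    G[, ch] <- m[cbind(am, seq_len(B))]
  }
  Z <- linear_forward(G, p$Wf, p$bf)
  list(Z = Z,
       cache = list(tok_vec = tok_vec, mask = mask, caches = caches,
                    H_last = X, G = G, argmax = argmax, B = B, L = L))
}

cnn_backward <- function(enc, cache, dZ) {
  p <- enc$params
  grads <- list()
  gf <- linear_backward(cache$G, p$Wf, dZ)
  grads$Wf <- gf$dW
  grads$bf <- gf$db
  dG <- gf$dX
  dH <- matrix(0, nrow(cache$H_last), ncol(cache$H_last))
  for (ch in seq_len(ncol(dH))) {
    dH[cbind(cache$argmax[, ch], ch)] <- dG[, ch]
  }
  for (l in rev(seq_along(enc$channels))) {
    cc <- cache$caches[[l]]
    dpre <- dH
    dpre[cc$pre <= 0] <- 0
    if (enc$mask_padding) dpre[!cache$mask, ] <- 0
    grads[[paste0("Wc", l)]] <- crossprod(cc$Xc, dpre)
    grads[[paste0("bc", l)]] <- colSums(dpre)
    dXc <- dpre %*% t(p[[paste0("Wc", l)]])
    cin <- ncol(cc$X)
    dX <- matrix(0, nrow(cc$X), cin)
    for (o in seq_len(ncol(cc$idx))) {
      block <- dXc[, ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
      sel <- cc$idx[, o] != 1L
      rows <- cc$idx[sel, o] - 1L
      dX[rows, ] <- dX[rows, ] + block[sel, , drop = FALSE]
    }
    dH <- dX
  }
  if (enc$mask_padding) dH[!cache$mask, ] <- 0
  dE <- matrix(0, nrow(p$E), ncol(p$E))
  agg <- rowsum(dH, group = cache$tok_vec + 1L)
  rows <- as.integer(rownames(agg))
  dE[rows, ] <- dE[rows, ] + agg
  grads$E <- dE
  grads
}
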