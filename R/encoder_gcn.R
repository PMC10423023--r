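# Graph convolutional encoder for molecules. Stacked Kipf-style layers
# H <- relu(A_hat H W + b) over the symmetrically normalized adjacency with
# self-loops, a symmetric pooling layer (mean/sum/max over nodes) and two
# fully connected layers. Message passing plus symmetric pooling makes the
# embedding invariant to node reindexing. Batches of molecules are processed
# as one block-diagonal sparse system.

gcn_init <- function(in_dim, hidden, n_layers, fc_hidden, out_dim,
                     pooling = "mean") {
  params <- list()
  d <- in_dim
  for (l in seq_len(n_layers)) {
    params[[paste0("Wg", l)]] <- init_weight(d, hidden)
    params[[paste0("bg", l)]] <- init_bias(hidden)
    d <- hidden
  }
  params$Wf1 <- init_weight(d, fc_hidden)
  params$bf1 <- init_bias(fc_hidden)
  params$Wf2 <- init_weight(fc_hidden, out_dim)
  params$bf2 <- init_bias(out_dim)
  structure(list(params = params, n_layers = n_layers, in_dim = in_dim,
                 hidden = hidden, fc_hidden = fc_hidden, out_dim = out_dim,
                 pooling = pooling),
            class = "gcn_encoder")
}

# Stack prepared graphs (from prepare_graph) into one block system:
# X (N x F), A block-diagonal sparse N x N, and a pooling operator.
gcn_batch_inputs <- function(prepared_list) {
  ns <- vapply(prepared_list, `[[`, 1, "n")
  X <- do.call(rbind, lapply(prepared_list, `[[`, "X"))
  A <- Matrix::bdiag(lapply(prepared_list, `[[`, "A_hat"))
  offsets <- cumsum(c(0, ns[-length(ns)]))
  graph_of_node <- rep.int(seq_along(ns), ns)
  list(X = X, A = A, ns = ns, graph_of_node = graph_of_node,
       B = length(ns), N = nrow(X))
}

# Pooling operator P (B x N sparse): rows average (mean), sum, or are handled
# separately for max pooling.
gcn_pool_matrix <- function(batch, pooling) {
  w <- if (pooling == "mean") 1 / batch$ns[batch$graph_of_node] else
    rep(1, batch$N)
  Matrix::sparseMatrix(i = batch$graph_of_node, j = seq_len(batch$N),
                       x = w, dims = c(batch$B, batch$N))
}

gcn_forward <- function(enc, batch) {
  p <- enc$params
  H <- batch$X
  Hs <- vector("list", enc$n_layers)
  pre <- vector("list", enc$n_layers)
  for (l in seq_len(enc$n_layers)) {
    Z <- as.matrix(batch$A %*% (H %*% p[[paste0("Wg", l)]]))
    Z <- sweep(Z, 2L, p[[paste0("bg", l)]], "+")
    Hs[[l]] <- H
    pre[[l]] <- Z
    H <- relu(Z)
  }
  if (enc$pooling == "max") {
    G <- matrix(0, batch$B, ncol(H))
    argmax <- matrix(0L, batch$B, ncol(H))
    for (b in seq_len(batch$B)) {
      rows <- which(batch$graph_of_node == b)
      sub <- H[rows, , drop = FALSE]
      am <- max.col(t(sub), ties.method = "first")
      argmax[b, ] <- rows[am]
      G[b, ] <- sub[cbind(am, seq_len(ncol(sub)))]
    }
    P <- NULL
  } else {
    P <- gcn_pool_matrix(batch, enc$pooling)
    G <- as.matrix(P %*% H)
    argmax <- NULL
  }
  F1_pre <- linear_forward(G, p$Wf1, p$bf1)
  F1 <- relu(F1_pre)
  Z_out <- linear_forward(F1, p$Wf2, p$bf2)
  list(Z = Z_out,
       cache = list(batch = batch, Hs = Hs, pre = pre, H_last = H, G = G,
                    P = P, argmax = argmax, F1 = F1, F1_pre = F1_pre))
}

gcn_backward <- function(enc, cache, dZ) {
  p <- enc$params
  grads <- list()
  g2 <- linear_backward(cache$F1, p$Wf2, dZ)
  grads$Wf2 <- g2$dW
  grads$bf2 <- g2$db
  dF1 <- g2$dX
  dF1[cache$F1_pre <= 0] <- 0
  g1 <- linear_backward(cache$G, p$Wf1, dF1)
  grads$Wf1 <- g1$dW
  grads$bf1 <- g1$db
  dG <- g1$dX
  if (enc$pooling == "max") {
    dH <- matrix(0, nrow(cache$H_last), ncol(cache$H_last))
    for (b in seq_len(cache$batch$B)) {
      dH[cbind(cache$argmax[b, ], seq_len(ncol(dH)))] <-
        dH[cbind(cache$argmax[b, ], seq_len(ncol(dH)))] + dG[b, ]
    }
  } else {
    dH <- as.matrix(Matrix::crossprod(cache$P, dG))
  }
  for (l in rev(seq_len(enc$n_layers))) {
    dpre <- dH
    dpre[cache$pre[[l]] <= 0] <- 0
    AtD <- as.matrix(Matrix::crossprod(cache$batch$A, dpre))
    grads[[paste0("Wg", l)]] <- crossprod(cache$Hs[[l]], AtD)
    grads[[paste0("bg", l)]] <- colSums(dpre)
    dH <- AtD %*% t(p[[paste0("Wg", l)]])
  }
  grads
}
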