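# No-stratification baseline: the same GCN and CNN encoder architectures,
# concatenated and trained end to end jointly with the MLP (no contrastive
# phase, no freezing), on identical splits and negative sets as the
# stratified model for a given master seed.

#' Train the end-to-end baseline interaction model
#'
#' GCN(compound) and CNN(sequence) embeddings are concatenated and fed to the
#' MLP; all parameters train jointly with ratio-weighted cross entropy and
#' early stopping on validation loss. Given the same `config$seed` it uses
#' exactly the same splits and sampled negatives as [train_phase2()].
#'
#' @param dataset a [csi_dataset()].
#' @param config a [train_config()] (`phase2_epochs` bounds the epochs).
#' @param encoder_cfg an [encoder_config()]; each encoder emits
#'   `2 * embed_dim` so total capacity mirrors one stratified phase.
#' @param log_path optional path for JSON-lines epoch records.
#' @return a `baseline_model` with `encoders`, `mlp`, `data`, `history`.
#' @export
train_baseline <- function(dataset, config = train_config(),
                           encoder_cfg = encoder_config(), log_path = NULL) {
  d_out <- 2L * encoder_cfg$embed_dim
  gcn <- new_gcn_from_config(encoder_cfg, d_out, derive_seed(config$seed, 21))
  cnn <- new_cnn_from_config(encoder_cfg, d_out, derive_seed(config$seed, 22))
  mlp <- mlp_init(2L * d_out, config$mlp_hidden, derive_seed(config$seed, 23))
  states <- list(gcn = adam_state(gcn$params), cnn = adam_state(cnn$params),
                 mlp = adam_state(mlp))
  # running statistics of the batch-standardization layer ahead of the MLP
  bn <- list(mu = numeric(2L * d_out), var = rep(1, 2L * d_out))
  data <- assemble_prediction_data(dataset, config)
  y_train <- data$train$label
  n <- nrow(data$train)
  pos_w <- config$neg_pos_ratio_train
  best <- list(loss = Inf, gcn = gcn, cnn = cnn, mlp = mlp, bn = bn,
               epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())

  forward_pairs <- function(gcn, cnn, pairs) {
    uc <- unique(pairs$compound_id)
    us <- unique(pairs$sequence_id)
    mc <- match(pairs$compound_id, uc)
    ms <- match(pairs$sequence_id, us)
    gb <- gcn_batch_inputs(dataset$graphs[uc])
    fg <- gcn_forward(gcn, gb)
    fc <- cnn_forward(cnn, dataset$tokens[us, , drop = FALSE])
    X <- cbind(fg$Z[mc, , drop = FALSE], fc$Z[ms, , drop = FALSE])
    list(X = X, fg = fg, fc = fc, mc = mc, ms = ms,
         n_uc = length(uc), n_us = length(us))
  }

  val_loss_of <- function(gcn, cnn, mlp, bn) {
    fw <- forward_pairs(gcn, cnn, data$val)
    Xh <- standardize_with(fw$X, bn$mu, bn$var)
    weighted_bce(mlp_forward(mlp, Xh)$p, data$val$label, pos_w)$loss
  }

  with_seed(derive_seed(config$seed, 24), {
    for (epoch in seq_len(config$phase2_epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      start <- 1L
      while (start <= n) {
        idx <- perm[start:min(start + config$minibatch - 1L, n)]
        start <- start + config$minibatch
        batch <- data$train[idx, , drop = FALSE]
        fw <- forward_pairs(gcn, cnn, batch)
        bnf <- batchnorm_forward(fw$X)
        mf <- mlp_forward(mlp, bnf$Xhat)
        l <- weighted_bce(mf$p, y_train[idx], pos_w)
        bw <- mlp_backward(mlp, mf, l$dlogit)
        dX <- batchnorm_backward(bnf$cache, bw$dX)
        bn$mu <- 0.9 * bn$mu + 0.1 * bnf$mu
        bn$var <- 0.9 * bn$var + 0.1 * bnf$var
        d_out_dim <- ncol(fw$fg$Z)
        dZg_pairs <- dX[, seq_len(d_out_dim), drop = FALSE]
        dZc_pairs <- dX[, d_out_dim + seq_len(d_out_dim), drop = FALSE]
        # aggregate pair gradients onto the unique entities of the batch
        dZg <- rowsum(dZg_pairs, group = fw$mc)
        dZg <- dZg[order(as.integer(rownames(dZg))), , drop = FALSE]
        dZc <- rowsum(dZc_pairs, group = fw$ms)
        dZc <- dZc[order(as.integer(rownames(dZc))), , drop = FALSE]
        g_gcn <- gcn_backward(gcn, fw$fg$cache, dZg)
        g_cnn <- cnn_backward(cnn, fw$fc$cache, dZc)
        upd <- adam_step(gcn$params, g_gcn, states$gcn, lr = config$lr)
        gcn$params <- upd$params
        states$gcn <- upd$state
        upd <- adam_step(cnn$params, g_cnn, states$cnn, lr = config$lr)
        cnn$params <- upd$params
        states$cnn <- upd$state
        upd <- adam_step(mlp, bw$grads, states$mlp, lr = config$lr)
        mlp <- upd$params
        states$mlp <- upd$state
        ep_loss <- ep_loss + l$loss
        nb <- nb + 1L
      }
      vl <- val_loss_of(gcn, cnn, mlp, bn)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                  val_loss = vl))
      log_epoch(log_path, list(phase = "baseline", epoch = epoch,
                               train_loss = ep_loss / nb, val_loss = vl))
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, gcn = gcn, cnn = cnn, mlp = mlp, bn = bn,
                     epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
  })
  structure(list(encoders = list(gcn = best$gcn, cnn = best$cnn),
                 mlp = best$mlp, bn = best$bn, config = config, data = data,
                 history = history),
            class = c("baseline_model", "predictor_model"))
}

#' @export
predict.baseline_model <- function(object, dataset, pairs, ...) {
  pairs <- data.frame(compound_id = as.character(pairs$compound_id),
                      sequence_id = as.character(pairs$sequence_id),
                      stringsAsFactors = FALSE)
  uc <- unique(pairs$compound_id)
  us <- unique(pairs$sequence_id)
  gb <- gcn_batch_inputs(dataset$graphs[uc])
  Zg <- gcn_forward(object$encoders$gcn, gb)$Z
  Zc <- cnn_forward(object$encoders$cnn, dataset$tokens[us, , drop = FALSE])$Z
  X <- cbind(Zg[match(pairs$compound_id, uc), , drop = FALSE],
             Zc[match(pairs$sequence_id, us), , drop = FALSE])
  X <- standardize_with(X, object$bn$mu, object$bn$var)
  mlp_forward(object$mlp, X)$p
}
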