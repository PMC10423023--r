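# Two-phase training. Phase 1 pretrains view encoders contrastively over
# strata: each batch holds one sampled view tuple from each of k distinct
# keys, so the in-batch candidates of the InfoNCE softmax are non-congruent
# by construction. Phase 2 freezes the encoders and trains an MLP on the
# concatenated view embeddings of (compound, sequence) pairs against
# positives and randomly sampled negatives, with ratio-weighted cross
# entropy and early stopping on validation loss. A no-stratification
# baseline trains the same encoder architectures end to end.

#' Training configuration
#'
#' @param phase1_epochs contrastive pretraining epochs (default 700; one
#'   epoch visits every key once in expectation).
#' @param phase2_epochs predictor training epochs (default 200).
#' @param lr Adam learning rate.
#' @param batch_size k, the number of distinct keys per contrastive batch.
#' @param tau InfoNCE temperature (default 0.07).
#' @param neg_pos_ratio_train negative-to-positive sampling ratio for
#'   training (default 5).
#' @param test_neg_ratio negative-to-positive ratio of the evaluation test
#'   set (default 1; 5/10/25 probe harder regimes).
#' @param split_ratios train/validation/test ratios (default 8:1:1).
#' @param patience early-stopping patience on validation loss.
#' @param minibatch predictor minibatch size.
#' @param mlp_hidden hidden width of the prediction MLP.
#' @param seed master seed; all internal seeds derive from it.
#' @return a `train_config` list.
#' @export
train_config <- function(phase1_epochs = 700L, phase2_epochs = 200L,
                         lr = 1e-3, batch_size = 32L, tau = 0.07,
                         neg_pos_ratio_train = 5L, test_neg_ratio = 1L,
                         split_ratios = c(8, 1, 1), patience = 10L,
                         minibatch = 32L, mlp_hidden = 512L, seed = 0L) {
  stopifnot(phase1_epochs >= 1L, phase2_epochs >= 1L, lr > 0,
            batch_size >= 1L, tau > 0, neg_pos_ratio_train >= 1L,
            test_neg_ratio >= 1L, all(split_ratios > 0),
            length(split_ratios) == 3L, patience >= 1L)
  structure(list(phase1_epochs = as.integer(phase1_epochs),
                 phase2_epochs = as.integer(phase2_epochs),
                 lr = lr, batch_size = as.integer(batch_size), tau = tau,
                 neg_pos_ratio_train = as.integer(neg_pos_ratio_train),
                 test_neg_ratio = as.integer(test_neg_ratio),
                 split_ratios = split_ratios,
                 patience = as.integer(patience),
                 minibatch = as.integer(minibatch),
                 mlp_hidden = as.integer(mlp_hidden),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- phase 1 ---------------------------------------------------------------

init_phase1_encoders <- function(mode, ecfg, seed) {
  d <- ecfg$embed_dim
  switch(mode,
    compound_key = list(
      gcn_lone = new_gcn_from_config(ecfg, 2L * d, derive_seed(seed, 101)),
      cnn_arm = new_cnn_from_config(ecfg, d, derive_seed(seed, 102))),
    sequence_key = list(
      gcn_arm = new_gcn_from_config(ecfg, d, derive_seed(seed, 103)),
      cnn_lone = new_cnn_from_config(ecfg, 2L * d, derive_seed(seed, 104))),
    reaction_feature = list(
      gcn_v1_arm = new_gcn_from_config(ecfg, d, derive_seed(seed, 105)),
      gcn_v2 = new_gcn_from_config(ecfg, d, derive_seed(seed, 106)),
      cnn_v2 = new_cnn_from_config(ecfg, d, derive_seed(seed, 107)),
      cnn_v3_arm = new_cnn_from_config(ecfg, d, derive_seed(seed, 108))),
    stop_value("unknown mode %s", mode))
}

# Sample one view tuple per stratum in `chunk`; returns id vectors.
sample_views <- function(strata, chunk) {
  lapply(chunk, function(i) {
    s <- strata[[i]]
    if (s$kind %in% c("compound", "sequence")) {
      row <- s$views[sample.int(nrow(s$views), 1L), ]
      list(key = s$key_value, i = row[[1L]], j = row[[2L]])
    } else {
      pick <- function(m) m[sample.int(nrow(m), 1L), ]
      list(key = s$key_value,
           v1 = pick(s$views$reactant_product),
           v2 = pick(s$views$compound_sequence),
           v3 = pick(s$views$sequence_pair))
    }
  })
}

siamese_concat <- function(Z) {
  k <- nrow(Z) / 2L
  cbind(Z[seq_len(k), , drop = FALSE], Z[k + seq_len(k), , drop = FALSE])
}

siamese_split_grad <- function(dZ) {
  d <- ncol(dZ) / 2L
  rbind(dZ[, seq_len(d), drop = FALSE], dZ[, d + seq_len(d), drop = FALSE])
}

#' Phase 1: contrastive pretraining of view encoders over strata
#'
#' Each step samples `batch_size` distinct keys and one congruent view tuple
#' per key, encodes both (or all three) views and takes one Adam step on the
#' symmetric (multiview) contrastive loss. One epoch passes over all keys in
#' shuffled order; a final short chunk runs at reduced batch size with a
#' logged message. The returned encoders are flagged frozen.
#'
#' @param dataset a [csi_dataset()].
#' @param strata strata of one kind (from [stratify_by_compound()],
#'   [stratify_by_sequence()] or [stratify_by_reaction_feature()]).
#' @param mode `"compound_key"`, `"sequence_key"` or `"reaction_feature"`;
#'   defaults to the kind of the strata.
#' @param config a [train_config()].
#' @param encoder_cfg an [encoder_config()].
#' @param views for reaction-feature mode, the subset of views to train on
#'   (default all three).
#' @param log_path optional path; one JSON record per epoch (phase, mode,
#'   epoch, mean loss) is appended.
#' @return a `phase1_model`: frozen `encoders`, `loss_history` (mean loss per
#'   epoch), `mode`, configs.
#' @export
train_phase1 <- function(dataset, strata, mode = NULL, config = train_config(),
                         encoder_cfg = encoder_config(),
                         views = c("v1", "v2", "v3"), log_path = NULL) {
  stopifnot(inherits(dataset, "csi_dataset"), length(strata) >= 1L)
  kind <- strata[[1L]]$kind
  mode <- mode %||% switch(kind, compound = "compound_key",
                           sequence = "sequence_key", "reaction_feature")
  views <- match.arg(views, several.ok = TRUE)
  if (mode == "reaction_feature" && length(views) < 2L) {
    stop_value("reaction-feature training needs at least 2 views")
  }
  encoders <- init_phase1_encoders(mode, encoder_cfg, config$seed)
  if (mode == "reaction_feature") {
    keep <- c(v1 = "gcn_v1_arm", v2 = "gcn_v2", v3 = "cnn_v3_arm")
    drop_names <- setdiff(unname(keep[setdiff(names(keep), views)]), character())
    if (!("v2" %in% views)) drop_names <- c(drop_names, "cnn_v2")
    encoders[drop_names] <- NULL
  }
  states <- lapply(encoders, function(e) adam_state(e$params))
  n_keys <- length(strata)
  k <- min(config$batch_size, n_keys)
  loss_history <- numeric(config$phase1_epochs)
  warned_short <- FALSE

  with_seed(derive_seed(config$seed, 200), {
    for (epoch in seq_len(config$phase1_epochs)) {
      perm <- sample.int(n_keys)
      losses <- numeric(0)
      start <- 1L
      while (start <= n_keys) {
        chunk <- perm[start:min(start + k - 1L, n_keys)]
        start <- start + k
        if (length(chunk) < 2L) next  # k = 1 batches carry zero loss signal
        if (length(chunk) < k && !warned_short) {
          message(sprintf(
            "train_phase1: short final batch of %d key(s) (batch size %d)",
            length(chunk), k))
          warned_short <- TRUE
        }
        tuples <- sample_views(strata, chunk)
        step <- phase1_step(dataset, encoders, states, tuples, mode,
                            config, views)
        encoders <- step$encoders
        states <- step$states
        losses <- c(losses, step$loss)
      }
      loss_history[epoch] <- mean(losses)
      log_epoch(log_path, list(phase = "phase1", mode = mode,
                               epoch = epoch, loss = mean(losses)))
    }
  })
  encoders <- lapply(encoders, function(e) e)
  attr(encoders, "frozen") <- TRUE
  structure(list(mode = mode, encoders = encoders,
                 encoder_config = encoder_cfg, config = config,
                 views = if (mode == "reaction_feature") views else NULL,
                 loss_history = loss_history, seed = config$seed),
            class = "phase1_model")
}

phase1_step <- function(dataset, encoders, states, tuples, mode, config,
                        views = c("v1", "v2", "v3")) {
  kk <- length(tuples)
  tau <- config$tau
  if (mode == "compound_key") {
    cids <- vapply(tuples, `[[`, "", "key")
    si <- vapply(tuples, `[[`, "", "i")
    sj <- vapply(tuples, `[[`, "", "j")
    gb <- gcn_batch_inputs(dataset$graphs[cids])
    f1 <- gcn_forward(encoders$gcn_lone, gb)
    f2 <- cnn_forward(encoders$cnn_arm, dataset$tokens[c(si, sj), , drop = FALSE])
    g <- total_loss_grad(f1$Z, siamese_concat(f2$Z), tau)
    grads <- list(
      gcn_lone = gcn_backward(encoders$gcn_lone, f1$cache, g$dZ1),
      cnn_arm = cnn_backward(encoders$cnn_arm, f2$cache,
                             siamese_split_grad(g$dZ2)))
    loss <- g$loss
  } else if (mode == "sequence_key") {
    sids <- vapply(tuples, `[[`, "", "key")
    ci <- vapply(tuples, `[[`, "", "i")
    cj <- vapply(tuples, `[[`, "", "j")
    gb <- gcn_batch_inputs(dataset$graphs[c(ci, cj)])
    f1 <- gcn_forward(encoders$gcn_arm, gb)
    f2 <- cnn_forward(encoders$cnn_lone, dataset$tokens[sids, , drop = FALSE])
    g <- total_loss_grad(siamese_concat(f1$Z), f2$Z, tau)
    grads <- list(
      gcn_arm = gcn_backward(encoders$gcn_arm, f1$cache,
                             siamese_split_grad(g$dZ1)),
      cnn_lone = cnn_backward(encoders$cnn_lone, f2$cache, g$dZ2))
    loss <- g$loss
  } else {
    Zs <- list()
    fwd <- list()
    if ("v1" %in% views) {
      r_ids <- vapply(tuples, function(t) t$v1[[1L]], "")
      p_ids <- vapply(tuples, function(t) t$v1[[2L]], "")
      gb1 <- gcn_batch_inputs(dataset$graphs[c(r_ids, p_ids)])
      fwd$v1 <- gcn_forward(encoders$gcn_v1_arm, gb1)
      Zs <- c(Zs, list(siamese_concat(fwd$v1$Z)))
    }
    if ("v2" %in% views) {
      c_ids <- vapply(tuples, function(t) t$v2[[1L]], "")
      s_ids <- vapply(tuples, function(t) t$v2[[2L]], "")
      gb2 <- gcn_batch_inputs(dataset$graphs[c_ids])
      fwd$v2g <- gcn_forward(encoders$gcn_v2, gb2)
      fwd$v2c <- cnn_forward(encoders$cnn_v2, dataset$tokens[s_ids, , drop = FALSE])
      Zs <- c(Zs, list(cbind(fwd$v2g$Z, fwd$v2c$Z)))
    }
    if ("v3" %in% views) {
      sk <- vapply(tuples, function(t) t$v3[[1L]], "")
      sl <- vapply(tuples, function(t) t$v3[[2L]], "")
      fwd$v3 <- cnn_forward(encoders$cnn_v3_arm,
                            dataset$tokens[c(sk, sl), , drop = FALSE])
      Zs <- c(Zs, list(siamese_concat(fwd$v3$Z)))
    }
    g <- multiview_loss_grad(Zs, tau)
    grads <- list()
    vi <- 1L
    if ("v1" %in% views) {
      grads$gcn_v1_arm <- gcn_backward(encoders$gcn_v1_arm, fwd$v1$cache,
                                       siamese_split_grad(g$dZ[[vi]]))
      vi <- vi + 1L
    }
    if ("v2" %in% views) {
      d <- ncol(g$dZ[[vi]]) / 2L
      grads$gcn_v2 <- gcn_backward(encoders$gcn_v2, fwd$v2g$cache,
                                   g$dZ[[vi]][, seq_len(d), drop = FALSE])
      grads$cnn_v2 <- cnn_backward(encoders$cnn_v2, fwd$v2c$cache,
                                   g$dZ[[vi]][, d + seq_len(d), drop = FALSE])
      vi <- vi + 1L
    }
    if ("v3" %in% views) {
      grads$cnn_v3_arm <- cnn_backward(encoders$cnn_v3_arm, fwd$v3$cache,
                                       siamese_split_grad(g$dZ[[vi]]))
    }
    loss <- g$loss
  }
  for (nm in names(grads)) {
    upd <- adam_step(encoders[[nm]]$params, grads[[nm]], states[[nm]],
                     lr = config$lr)
    encoders[[nm]]$params <- upd$params
    states[[nm]] <- upd$state
  }
  list(encoders = encoders, states = states, loss = loss)
}
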