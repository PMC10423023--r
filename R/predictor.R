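# Phase 2: frozen-encoder interaction prediction. Per-entity view embeddings
# are precomputed once (the encoders are frozen), composed per pair into the
# concatenated MLP input, and only the MLP trains. Inference-time composition
# for Siamese encoders uses the duplicated-pair convention: a lone entity is
# fed to both arms, preserving the dimensions the encoders were trained with.

embed_compounds_with <- function(enc, dataset, cids, chunk = 64L) {
  out <- matrix(0, length(cids), enc$out_dim, dimnames = list(cids, NULL))
  start <- 1L
  while (start <= length(cids)) {
    sel <- cids[start:min(start + chunk - 1L, length(cids))]
    gb <- gcn_batch_inputs(dataset$graphs[sel])
    out[sel, ] <- gcn_forward(enc, gb)$Z
    start <- start + chunk
  }
  out
}

embed_sequences_with <- function(enc, dataset, sids, chunk = 64L) {
  out <- matrix(0, length(sids), enc$out_dim, dimnames = list(sids, NULL))
  start <- 1L
  while (start <= length(sids)) {
    sel <- sids[start:min(start + chunk - 1L, length(sids))]
    out[sel, ] <- cnn_forward(enc, dataset$tokens[sel, , drop = FALSE])$Z
    start <- start + chunk
  }
  out
}

#' Combine frozen phase-1 models for prediction
#'
#' @param phase1a compound-key `phase1_model` (GCN + Siamese CNN), or `NULL`.
#' @param phase1b sequence-key `phase1_model` (Siamese GCN + CNN), or `NULL`.
#' @param reaction reaction-feature `phase1_model`, or `NULL` (exclusive with
#'   the other two).
#' @return a `csi_encoders` object with a `mode` of `"compound_sequence"`,
#'   `"compound_only"`, `"sequence_only"` or `"reaction_feature"`.
#' @export
csi_encoders <- function(phase1a = NULL, phase1b = NULL, reaction = NULL) {
  if (!is.null(reaction)) {
    stopifnot(is.null(phase1a), is.null(phase1b),
              inherits(reaction, "phase1_model"))
    mode <- "reaction_feature"
    models <- list(reaction = reaction)
  } else {
    stopifnot(!is.null(phase1a) || !is.null(phase1b))
    mode <- if (!is.null(phase1a) && !is.null(phase1b)) "compound_sequence"
            else if (!is.null(phase1a)) "compound_only" else "sequence_only"
    models <- Filter(Negate(is.null), list(phase1a = phase1a, phase1b = phase1b))
  }
  frozen <- all(vapply(models, function(m) isTRUE(attr(m$encoders, "frozen")),
                       TRUE))
  structure(list(mode = mode, models = models, cache = NULL),
            class = "csi_encoders", frozen = frozen)
}

encoder_param_list <- function(encoders) {
  lapply(encoders$models, function(m) lapply(m$encoders, `[[`, "params"))
}

# Precompute per-entity embeddings for the requested ids (extending any
# existing cache).
build_embedding_cache <- function(encoders, dataset, cids, sids) {
  cache <- encoders$cache %||% list()
  need_c <- if (is.null(cache$comp)) cids else setdiff(cids, rownames(cache$comp[[1L]]))
  need_s <- if (is.null(cache$seq)) sids else setdiff(sids, rownames(cache$seq[[1L]]))
  comp_encoders <- list()
  seq_encoders <- list()
  m <- encoders$models
  if (encoders$mode %in% c("compound_sequence", "compound_only")) {
    comp_encoders$gcn_lone <- m$phase1a$encoders$gcn_lone
    seq_encoders$cnn_arm <- m$phase1a$encoders$cnn_arm
  }
  if (encoders$mode %in% c("compound_sequence", "sequence_only")) {
    comp_encoders$gcn_arm <- m$phase1b$encoders$gcn_arm
    seq_encoders$cnn_lone <- m$phase1b$encoders$cnn_lone
  }
  if (encoders$mode == "reaction_feature") {
    enc <- m$reaction$encoders
    for (nm in intersect(names(enc), c("gcn_v1_arm", "gcn_v2"))) {
      comp_encoders[[nm]] <- enc[[nm]]
    }
    for (nm in intersect(names(enc), c("cnn_v2", "cnn_v3_arm"))) {
      seq_encoders[[nm]] <- enc[[nm]]
    }
  }
  if (length(need_c)) {
    newc <- lapply(comp_encoders, embed_compounds_with, dataset = dataset,
                   cids = need_c)
    cache$comp <- if (is.null(cache$comp)) newc else
      Map(function(old, new) rbind(old, new), cache$comp, newc)
  }
  if (length(need_s)) {
    news <- lapply(seq_encoders, embed_sequences_with, dataset = dataset,
                   sids = need_s)
    cache$seq <- if (is.null(cache$seq)) news else
      Map(function(old, new) rbind(old, new), cache$seq, news)
  }
  cache
}

# Concatenated MLP input per pair, by mode. Duplication convention: Siamese
# views of a lone entity use the entity on both arms.
compose_features <- function(encoders, pairs) {
  cache <- encoders$cache
  ci <- pairs$compound_id
  si <- pairs$sequence_id
  blocks <- switch(encoders$mode,
    compound_sequence = list(
      cache$comp$gcn_lone[ci, , drop = FALSE],
      cache$seq$cnn_arm[si, , drop = FALSE],
      cache$seq$cnn_arm[si, , drop = FALSE],
      cache$comp$gcn_arm[ci, , drop = FALSE],
      cache$comp$gcn_arm[ci, , drop = FALSE],
      cache$seq$cnn_lone[si, , drop = FALSE]),
    compound_only = list(
      cache$comp$gcn_lone[ci, , drop = FALSE],
      cache$seq$cnn_arm[si, , drop = FALSE],
      cache$seq$cnn_arm[si, , drop = FALSE]),
    sequence_only = list(
      cache$comp$gcn_arm[ci, , drop = FALSE],
      cache$comp$gcn_arm[ci, , drop = FALSE],
      cache$seq$cnn_lone[si, , drop = FALSE]),
    reaction_feature = {
      b <- list()
      if (!is.null(cache$comp$gcn_v1_arm)) {
        b <- c(b, list(cache$comp$gcn_v1_arm[ci, , drop = FALSE],
                       cache$comp$gcn_v1_arm[ci, , drop = FALSE]))
      }
      if (!is.null(cache$comp$gcn_v2)) {
        b <- c(b, list(cache$comp$gcn_v2[ci, , drop = FALSE],
                       cache$seq$cnn_v2[si, , drop = FALSE]))
      }
      if (!is.null(cache$seq$cnn_v3_arm)) {
        b <- c(b, list(cache$seq$cnn_v3_arm[si, , drop = FALSE],
                       cache$seq$cnn_v3_arm[si, , drop = FALSE]))
      }
      b
    })
  unname(do.call(cbind, blocks))
}

# Shared phase-2/baseline data assembly so both models see identical splits
# and negative sets for a given master seed. Labeled negatives from the
# input table join the training negatives as-is (the sampler already
# excludes them).
assemble_prediction_data <- function(dataset, config) {
  table <- dataset$table
  sp <- split_positives(table, config$split_ratios, derive_seed(config$seed, 11))
  n_neg <- c(train = config$neg_pos_ratio_train * nrow(sp$train),
             val = config$neg_pos_ratio_train * nrow(sp$val),
             test = config$test_neg_ratio * nrow(sp$test))
  pool <- sample_negative_pairs(table, sum(n_neg), derive_seed(config$seed, 12))
  pool <- with_seed(derive_seed(config$seed, 13),
                    pool[sample.int(nrow(pool)), , drop = FALSE])
  neg_train <- pool[seq_len(n_neg["train"]), , drop = FALSE]
  neg_val <- pool[n_neg["train"] + seq_len(n_neg["val"]), , drop = FALSE]
  neg_test <- pool[n_neg["train"] + n_neg["val"] + seq_len(n_neg["test"]), ,
                   drop = FALSE]
  if (nrow(table$negatives)) {
    neg_train <- rbind(neg_train, table$negatives)
  }
  mk <- function(pos, neg, stream) {
    df <- rbind(pos, neg)
    df$label <- rep(c(1L, 0L), c(nrow(pos), nrow(neg)))
    # label-agnostic row order, so tied scores cannot inherit the labels
    df <- with_seed(derive_seed(config$seed, stream),
                    df[sample.int(nrow(df)), , drop = FALSE])
    rownames(df) <- NULL
    df
  }
  list(train = mk(sp$train, neg_train, 16),
       val = mk(sp$val, neg_val, 17),
       test = mk(sp$test, neg_test, 18))
}

#' Phase 2: train the frozen-encoder interaction predictor
#'
#' Splits the positives 8:1:1 (by default), samples negatives at the training
#' ratio, composes the concatenated frozen view embeddings per pair and
#' trains the MLP with ratio-weighted cross entropy, early stopping on
#' validation loss (best weights restored). Encoder parameters are
#' checksummed before and after; a change aborts.
#'
#' @param encoders a frozen [csi_encoders()] (or a single `phase1_model`,
#'   which is wrapped).
#' @param dataset a [csi_dataset()].
#' @param config a [train_config()].
#' @param log_path optional path for JSON-lines epoch records.
#' @return a `predictor_model`: `encoders` (with embedding cache), `mlp`,
#'   `data` (train/val/test pairs with labels), `history`,
#'   `encoder_checksum`.
#' @export
train_phase2 <- function(encoders, dataset, config = train_config(),
                         log_path = NULL) {
  if (inherits(encoders, "phase1_model")) {
    encoders <- switch(encoders$mode,
                       compound_key = csi_encoders(phase1a = encoders),
                       sequence_key = csi_encoders(phase1b = encoders),
                       csi_encoders(reaction = encoders))
  }
  stopifnot(inherits(encoders, "csi_encoders"))
  if (!isTRUE(attr(encoders, "frozen"))) {
    stop_value("encoders must be frozen before Phase 2 (contract violation)")
  }
  checksum_before <- weight_checksum(encoder_param_list(encoders))
  data <- assemble_prediction_data(dataset, config)
  all_c <- unique(c(data$train$compound_id, data$val$compound_id,
                    data$test$compound_id))
  all_s <- unique(c(data$train$sequence_id, data$val$sequence_id,
                    data$test$sequence_id))
  encoders$cache <- build_embedding_cache(encoders, dataset, all_c, all_s)

  X_train <- compose_features(encoders, data$train)
  # standardize the frozen features with training-set statistics so the MLP
  # sees O(1)-scale inputs (evaluation reuses the same statistics)
  feature_stats <- list(mu = colMeans(X_train),
                        var = apply(X_train, 2L, stats::var))
  X_train <- standardize_with(X_train, feature_stats$mu, feature_stats$var)
  X_val <- standardize_with(compose_features(encoders, data$val),
                            feature_stats$mu, feature_stats$var)
  y_train <- data$train$label
  y_val <- data$val$label

  mlp <- mlp_init(ncol(X_train), config$mlp_hidden, derive_seed(config$seed, 14))
  state <- adam_state(mlp)
  pos_w <- config$neg_pos_ratio_train
  best <- list(loss = Inf, mlp = mlp, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  n <- nrow(X_train)
  with_seed(derive_seed(config$seed, 15), {
    for (epoch in seq_len(config$phase2_epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      start <- 1L
      while (start <= n) {
        idx <- perm[start:min(start + config$minibatch - 1L, n)]
        start <- start + config$minibatch
        fw <- mlp_forward(mlp, X_train[idx, , drop = FALSE])
        l <- weighted_bce(fw$p, y_train[idx], pos_w)
        bw <- mlp_backward(mlp, fw, l$dlogit)
        upd <- adam_step(mlp, bw$grads, state, lr = config$lr)
        mlp <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + l$loss
        nb <- nb + 1L
      }
      val_loss <- weighted_bce(mlp_forward(mlp, X_val)$p, y_val, pos_w)$loss
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                  val_loss = val_loss))
      log_epoch(log_path, list(phase = "phase2", epoch = epoch,
                               train_loss = ep_loss / nb,
                               val_loss = val_loss))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, mlp = mlp, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
  })
  checksum_after <- weight_checksum(encoder_param_list(encoders))
  if (!identical(checksum_before, checksum_after)) {
    stop_value("encoder weights changed during Phase 2")
  }
  structure(list(encoders = encoders, mlp = best$mlp,
                 feature_stats = feature_stats,
                 input_dim = ncol(X_train), config = config, data = data,
                 history = history, encoder_checksum = checksum_after),
            class = "predictor_model")
}

#' Predict interaction probabilities for compound-sequence pairs
#'
#' @param object a `predictor_model` from [train_phase2()] or
#'   [train_baseline()].
#' @param dataset the [csi_dataset()] providing featurized inputs (needed for
#'   entities outside the embedding cache).
#' @param pairs data.frame with `compound_id`, `sequence_id`.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.predictor_model <- function(object, dataset, pairs, ...) {
  pairs <- data.frame(compound_id = as.character(pairs$compound_id),
                      sequence_id = as.character(pairs$sequence_id),
                      stringsAsFactors = FALSE)
  object$encoders$cache <- build_embedding_cache(
    object$encoders, dataset,
    unique(pairs$compound_id), unique(pairs$sequence_id))
  X <- compose_features(object$encoders, pairs)
  X <- standardize_with(X, object$feature_stats$mu, object$feature_stats$var)
  mlp_forward(object$mlp, X)$p
}

#' Score a model's held-out test pairs
#'
#' @param model a `predictor_model` or `baseline_model`.
#' @param dataset the [csi_dataset()].
#' @param split which stored split to score (default `"test"`).
#' @param k_cut cutoff for MAP@k.
#' @return a [ranking_report()].
#' @export
evaluate_model <- function(model, dataset, split = "test", k_cut = 3L) {
  df <- model$data[[split]]
  p <- stats::predict(model, dataset, df)
  ranking_report(df$compound_id, df$sequence_id, df$label, p, k_cut = k_cut)
}
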