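# High-level workflows: full stratified training (compound + sequence keys),
# reaction-feature training, and the synthetic block-model benchmark
# comparing the stratified model against the end-to-end baseline.

#' Train the full stratified interaction model
#'
#' Builds compound-key and sequence-key strata, pretrains the two encoder
#' pairs contrastively (Phase 1A and 1B, independent weights), freezes them
#' and trains the MLP predictor (Phase 2).
#'
#' @param dataset a [csi_dataset()].
#' @param config a [train_config()].
#' @param encoder_cfg an [encoder_config()].
#' @param stratification `"both"` (default), `"compound"` or `"sequence"`
#'   (the ablation variants).
#' @return a `predictor_model`; its `encoders` field keeps the phase-1 models
#'   (with loss histories).
#' @export
train_csi <- function(dataset, config = train_config(),
                      encoder_cfg = encoder_config(),
                      stratification = c("both", "compound", "sequence")) {
  stratification <- match.arg(stratification)
  p1a <- p1b <- NULL
  if (stratification %in% c("both", "compound")) {
    strata_c <- stratify_by_compound(dataset$table)
    cfg_a <- config
    cfg_a$seed <- as.integer(derive_seed(config$seed, 31) %% 2147483647)
    p1a <- train_phase1(dataset, strata_c, "compound_key", cfg_a, encoder_cfg)
  }
  if (stratification %in% c("both", "sequence")) {
    strata_s <- stratify_by_sequence(dataset$table)
    cfg_b <- config
    cfg_b$seed <- as.integer(derive_seed(config$seed, 32) %% 2147483647)
    p1b <- train_phase1(dataset, strata_s, "sequence_key", cfg_b, encoder_cfg)
  }
  train_phase2(csi_encoders(phase1a = p1a, phase1b = p1b), dataset, config)
}

#' Train the reaction-feature stratified model
#'
#' Stratifies reactions by the requested key (reaction, RCLASS or EC number),
#' pretrains the three view encoders with the pairwise multiview loss, then
#' trains the predictor on the induced compound-enzyme interaction table.
#'
#' @param dataset a [csi_dataset()] whose table is the induced interaction
#'   table of the reactions.
#' @param reactions list of [reaction_record()] objects.
#' @param key_kind `"reaction"`, `"rclass"` or `"ec"`.
#' @param config a [train_config()].
#' @param encoder_cfg an [encoder_config()].
#' @param views subset of `c("v1", "v2", "v3")` to use (view ablation).
#' @return a `predictor_model`.
#' @export
train_reaction_csi <- function(dataset, reactions,
                               key_kind = c("reaction", "rclass", "ec"),
                               config = train_config(),
                               encoder_cfg = encoder_config(),
                               views = c("v1", "v2", "v3")) {
  key_kind <- match.arg(key_kind)
  strata <- stratify_by_reaction_feature(reactions, key_kind)
  cfg <- config
  cfg$seed <- as.integer(derive_seed(config$seed, 33) %% 2147483647)
  p1 <- train_phase1(dataset, strata, "reaction_feature", cfg, encoder_cfg,
                     views = views)
  train_phase2(csi_encoders(reaction = p1), dataset, config)
}

#' Desk-scale training configuration for the synthetic benchmark
#'
#' 50 contrastive epochs, 30 predictor epochs, contrastive batch size 8,
#' temperature 0.07 — the study conditions of the block-model benchmark.
#'
#' @param seed master seed.
#' @return a [train_config()].
#' @export
benchmark_train_config <- function(seed = 0L) {
  train_config(phase1_epochs = 50L, phase2_epochs = 30L, batch_size = 8L,
               tau = 0.07, seed = seed)
}

# Mean within-group minus between-group cosine similarity of compound
# embeddings under a phase-1A model (a direct readout of how well the
# contrastive phase separated the latent groups).
compound_group_cosine_gap <- function(phase1a, dataset, groups) {
  enc <- phase1a$encoders$gcn_lone
  cids <- names(dataset$graphs)
  Z <- embed_compounds_with(enc, dataset, cids)
  U <- Z / pmax(sqrt(rowSums(Z * Z)), 1e-12)
  S <- tcrossprod(U)
  same <- outer(groups[cids], groups[cids], "==")
  diag(S) <- NA
  diag(same) <- NA
  mean(S[same & !is.na(same)], na.rm = TRUE) -
    mean(S[!same & !is.na(same)], na.rm = TRUE)
}

#' Synthetic block-model benchmark: stratified model vs baseline
#'
#' Generates the block dataset, trains the stratified model and the
#' end-to-end baseline under identical splits and negatives, and scores both
#' on the held-out test pairs, per seed.
#'
#' @param seeds integer vector of master seeds (one full run per seed).
#' @param block_cfg a [block_model_config()] (its `seed` field is overridden
#'   per run).
#' @param config a [train_config()] template (its `seed` is overridden).
#' @param encoder_cfg an [encoder_config()].
#' @return data.frame with one row per seed: test AP of both models and the
#'   within/between-group cosine gap of the pretrained compound embeddings.
#' @export
run_block_benchmark <- function(seeds = 0:2,
                                block_cfg = block_model_config(),
                                config = benchmark_train_config(),
                                encoder_cfg = small_encoder_config()) {
  rows <- lapply(seeds, function(s) {
    bc <- block_cfg
    bc$seed <- as.integer(derive_seed(s, 41) %% 2147483647)
    block <- generate_block_dataset(bc)
    dataset <- csi_dataset(block$table, block$compounds, block$sequences,
                           L_max = encoder_cfg$L_max)
    cfg <- config
    cfg$seed <- as.integer(s)
    csi <- train_csi(dataset, cfg, encoder_cfg)
    base <- train_baseline(dataset, cfg, encoder_cfg)
    csi_rep <- evaluate_model(csi, dataset)
    base_rep <- evaluate_model(base, dataset)
    gap <- compound_group_cosine_gap(csi$encoders$models$phase1a, dataset,
                                     block$compound_groups)
    data.frame(seed = s,
               csi_test_ap = csi_rep$overall$AP,
               baseline_test_ap = base_rep$overall$AP,
               cosine_gap = gap)
  })
  do.call(rbind, rows)
}

#' Synthetic reaction-mode benchmark
#'
#' Generates the block + reaction datasets, trains the three-view
#' reaction-stratified model and reports convergence and test AP per seed.
#'
#' @inheritParams run_block_benchmark
#' @param reaction_cfg a [reaction_model_config()].
#' @param key_kind reaction-feature key.
#' @return data.frame with per-seed first/final phase-1 loss and test AP.
#' @export
run_reaction_benchmark <- function(seeds = 0:2,
                                   block_cfg = block_model_config(),
                                   reaction_cfg = reaction_model_config(),
                                   config = benchmark_train_config(),
                                   encoder_cfg = small_encoder_config(),
                                   key_kind = "reaction") {
  rows <- lapply(seeds, function(s) {
    bc <- block_cfg
    bc$seed <- as.integer(derive_seed(s, 42) %% 2147483647)
    block <- generate_block_dataset(bc)
    rc <- reaction_cfg
    rc$seed <- as.integer(derive_seed(s, 43) %% 2147483647)
    rxn <- generate_reaction_dataset(rc, block)
    dataset <- csi_dataset(rxn$table, block$compounds, block$sequences,
                           L_max = encoder_cfg$L_max)
    cfg <- config
    cfg$seed <- as.integer(s)
    model <- train_reaction_csi(dataset, rxn$reactions, key_kind, cfg,
                                encoder_cfg)
    rep <- evaluate_model(model, dataset)
    hist <- model$encoders$models$reaction$loss_history
    data.frame(seed = s,
               first_epoch_loss = hist[1L],
               final_epoch_loss = hist[length(hist)],
               test_ap = rep$overall$AP)
  })
  do.call(rbind, rows)
}
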