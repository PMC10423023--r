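# User-facing encoder layer. An encoder_config fixes architecture sizes; the
# dimension-matching convention is: a lone-object encoder emits 2*d' and each
# Siamese arm emits d', so the two views of a contrastive phase always share
# total dimension 2*d'.

#' Encoder architecture configuration
#'
#' @param embed_dim `d'`: dimension of one Siamese arm; lone-object encoders
#'   emit `2 * embed_dim` so both views of a phase match.
#' @param gcn_layers,gcn_hidden graph convolution depth and width.
#' @param fc_hidden width of the hidden fully connected layer after pooling.
#' @param cnn_channels,cnn_kernel_sizes channel counts and (odd) kernel sizes
#'   of the 1D convolution blocks.
#' @param residue_embed_dim learned residue embedding dimension.
#' @param pooling graph readout: `"mean"`, `"sum"` or `"max"`.
#' @param L_max fixed encoded sequence length.
#' @param mask_padding if `TRUE`, convolutions ignore positions beyond a
#'   sequence's original length.
#' @param seed integer seed for weight initialization.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(embed_dim = 64L,
                           gcn_layers = 3L,
                           gcn_hidden = 128L,
                           fc_hidden = 128L,
                           cnn_channels = c(32L, 64L, 96L),
                           cnn_kernel_sizes = c(7L, 7L, 7L),
                           residue_embed_dim = 32L,
                           pooling = c("mean", "sum", "max"),
                           L_max = 1000L,
                           mask_padding = FALSE,
                           seed = 0L) {
  pooling <- match.arg(pooling)
  stopifnot(embed_dim > 0, gcn_layers >= 1, gcn_hidden > 0,
            length(cnn_channels) == length(cnn_kernel_sizes))
  structure(list(embed_dim = as.integer(embed_dim),
                 gcn_layers = as.integer(gcn_layers),
                 gcn_hidden = as.integer(gcn_hidden),
                 fc_hidden = as.integer(fc_hidden),
                 cnn_channels = as.integer(cnn_channels),
                 cnn_kernel_sizes = as.integer(cnn_kernel_sizes),
                 residue_embed_dim = as.integer(residue_embed_dim),
                 pooling = pooling,
                 L_max = as.integer(L_max),
                 mask_padding = isTRUE(mask_padding),
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Compact encoder configuration for desk-scale benchmarks
#'
#' Sized for the synthetic block data (short sequences, small molecules):
#' `d' = 16`, 2 GCN layers of width 16, CNN channels 8/16 with kernel 7,
#' residue embedding 8.
#'
#' @param seed integer seed.
#' @param L_max encoded sequence length (default 128).
#' @return an [encoder_config()].
#' @export
small_encoder_config <- function(seed = 0L, L_max = 128L) {
  encoder_config(embed_dim = 16L, gcn_layers = 2L, gcn_hidden = 16L,
                 fc_hidden = 32L, cnn_channels = c(8L, 16L),
                 cnn_kernel_sizes = c(7L, 7L), residue_embed_dim = 8L,
                 L_max = L_max, seed = seed)
}

new_gcn_from_config <- function(config, out_dim, seed) {
  with_seed(seed, gcn_init(NODE_FEATURE_DIM, config$gcn_hidden,
                           config$gcn_layers, config$fc_hidden, out_dim,
                           pooling = config$pooling))
}

new_cnn_from_config <- function(config, out_dim, seed) {
  with_seed(seed, cnn_init(length(aa_alphabet()), config$residue_embed_dim,
                           config$cnn_channels, config$cnn_kernel_sizes,
                           out_dim, mask_padding = config$mask_padding))
}

#' Encode one compound
#'
#' Runs the GCN encoder on a featurized molecular graph. The result is
#' invariant to node reindexing (message passing plus symmetric pooling).
#'
#' @param encoder a `gcn_encoder`.
#' @param graph a `molecular_graph` (or a prepared graph).
#' @return numeric embedding of length `encoder$out_dim`.
#' @export
encode_compound <- function(encoder, graph) {
  stopifnot(inherits(encoder, "gcn_encoder"))
  prep <- if (inherits(graph, "molecular_graph")) prepare_graph(graph) else graph
  batch <- gcn_batch_inputs(list(prep))
  as.vector(gcn_forward(encoder, batch)$Z)
}

#' Encode one protein sequence
#'
#' @param encoder a `cnn_encoder`.
#' @param F an `encoded_sequence` (or integer token vector).
#' @return numeric embedding of length `encoder$out_dim`.
#' @export
encode_sequence_cnn <- function(encoder, F) {
  stopifnot(inherits(encoder, "cnn_encoder"))
  toks <- token_matrix(list(F))
  as.vector(cnn_forward(encoder, toks)$Z)
}

#' Encode a sequence pair with a Siamese CNN
#'
#' Both arms share the same weights; the output is the concatenation
#' `CNN(F_i) (+) CNN(F_j)` of dimension `2 * d`.
#'
#' @param encoder a `cnn_encoder` (the shared arm).
#' @param F_i,F_j encoded sequences.
#' @return numeric embedding of length `2 * encoder$out_dim`.
#' @export
encode_sequence_pair <- function(encoder, F_i, F_j) {
  c(encode_sequence_cnn(encoder, F_i), encode_sequence_cnn(encoder, F_j))
}

#' Encode a compound pair with a Siamese GCN
#'
#' Mirror of [encode_sequence_pair()]: `GCN(c_i) (+) GCN(c_j)` with shared
#' weights.
#'
#' @param encoder a `gcn_encoder` (the shared arm).
#' @param c_i,c_j molecular graphs.
#' @return numeric embedding of length `2 * encoder$out_dim`.
#' @export
encode_compound_pair <- function(encoder, c_i, c_j) {
  c(encode_compound(encoder, c_i), encode_compound(encoder, c_j))
}

# ---- checkpoints ------------------------------------------------------------

CHECKPOINT_FORMAT <- 1L

flatten_params <- function(params) {
  lapply(params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.vector(p)) else
      list(dim = length(p), data = as.vector(p))
  })
}

unflatten_params <- function(flat) {
  lapply(flat, function(p) {
    d <- unlist(p$dim)
    x <- unlist(p$data)
    if (length(d) == 2L) matrix(x, d[1L], d[2L]) else as.numeric(x)
  })
}

#' Save encoders (and optional predictor weights) to a JSON archive
#'
#' The archive is versioned plain text holding the architecture config, the
#' seed and every weight array, so a model can be reloaded exactly.
#'
#' @param model a list of encoder objects (and optionally `mlp` weights),
#'   e.g. the result of [train_phase1()] or [train_phase2()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  enc_names <- names(model$encoders %||% list())
  payload <- list(
    format = CHECKPOINT_FORMAT,
    seed = model$seed %||% NA,
    config = unclass(model$config %||% list()),
    encoders = stats::setNames(lapply(enc_names, function(nm) {
      e <- model$encoders[[nm]]
      meta <- unclass(e)
      meta$params <- NULL
      list(class = class(e), meta = meta, params = flatten_params(e$params))
    }), enc_names),
    mlp = if (!is.null(model$mlp)) flatten_params(model$mlp) else NULL,
    frozen = isTRUE(attr(model$encoders, "frozen"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model archive written by [save_model()]
#'
#' @param path archive path.
#' @return list with `encoders`, optional `mlp`, `config`, `seed`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path)
  if (!identical(as.integer(payload$format), CHECKPOINT_FORMAT)) {
    stop_value("unsupported checkpoint format %s", payload$format)
  }
  encoders <- lapply(payload$encoders, function(e) {
    obj <- lapply(e$meta, function(v) unlist(v, use.names = FALSE))
    obj$params <- unflatten_params(e$params)
    class(obj) <- unlist(e$class)
    obj
  })
  if (isTRUE(payload$frozen)) attr(encoders, "frozen") <- TRUE
  list(encoders = encoders,
       mlp = if (!is.null(payload$mlp)) unflatten_params(payload$mlp) else NULL,
       config = payload$config,
       seed = payload$seed)
}
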