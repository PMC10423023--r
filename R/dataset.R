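# A csi_dataset bundles an interaction table with featurized inputs: prepared
# molecular graphs for every registered compound and a fixed-length token
# matrix for every registered sequence, so training loops never re-parse raw
# inputs.

#' Assemble a featurized dataset
#'
#' Featurizes every compound (one batched SMILES-parser call) and encodes
#' every sequence to length `L_max`.
#'
#' @param table an [interaction_table()].
#' @param compounds named character vector of SMILES covering all registered
#'   compound ids.
#' @param sequences named character vector of amino-acid strings covering all
#'   registered sequence ids.
#' @param L_max fixed encoded sequence length.
#' @return a `csi_dataset` list: `table`, `graphs` (prepared graph per
#'   compound), `tokens` (n_seq x L_max integer matrix), `seq_lengths`,
#'   `smiles`, `sequences`.
#' @export
csi_dataset <- function(table, compounds, sequences, L_max = 1000L) {
  stopifnot(inherits(table, "interaction_table"))
  missing_c <- setdiff(table$compound_ids, names(compounds))
  missing_s <- setdiff(table$sequence_ids, names(sequences))
  if (length(missing_c)) {
    stop_value("no SMILES for compound(s): %s",
               paste(utils::head(missing_c, 5L), collapse = ", "))
  }
  if (length(missing_s)) {
    stop_value("no sequence for id(s): %s",
               paste(utils::head(missing_s, 5L), collapse = ", "))
  }
  compounds <- compounds[table$compound_ids]
  sequences <- sequences[table$sequence_ids]
  mols <- featurize_compounds(compounds)
  graphs <- lapply(mols, prepare_graph)
  encoded <- lapply(sequences, encode_sequence, L_max = L_max)
  tokens <- token_matrix(encoded)
  rownames(tokens) <- names(sequences)
  structure(list(table = table,
                 graphs = graphs,
                 tokens = tokens,
                 seq_lengths = vapply(encoded, `[[`, 1L, "original_length"),
                 smiles = compounds,
                 sequences = sequences,
                 L_max = as.integer(L_max)),
            class = "csi_dataset")
}

#' @export
print.csi_dataset <- function(x, ...) {
  cat(sprintf("csi_dataset: %d compounds, %d sequences, %d positives, L_max=%d\n",
              length(x$graphs), nrow(x$tokens), nrow(x$table$positives),
              x$L_max))
  invisible(x)
}

# Swap in a different interaction table (e.g. a training split) while keeping
# the featurized inputs.
dataset_with_table <- function(dataset, table) {
  dataset$table <- table
  dataset
}
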