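#' Interaction tables
#'
#' An `interaction_table` holds the set `I` of known positive
#' (compound, sequence) interactions over a compound set `C` and a sequence
#' set `S`, plus an optional set of labeled negative pairs (e.g. known
#' inhibitors). It is the substrate of every stratification and of predictor
#' training.
#'
#' Invariants enforced by the constructor:
#' * every id in positives/negatives is registered in `compound_ids` /
#'   `sequence_ids`;
#' * positives and negatives are disjoint as pair sets;
#' * no duplicate pairs within either set.
#'
#' @param positives data.frame with columns `compound_id`, `sequence_id`.
#' @param negatives optional data.frame with the same columns (labeled
#'   non-interactions); may be empty.
#' @param compound_ids,sequence_ids optional character vectors registering the
#'   full entity universe; defaults to the ids observed in the pairs.
#' @return an object of class `interaction_table`.
#' @export
interaction_table <- function(positives,
                              negatives = NULL,
                              compound_ids = NULL,
                              sequence_ids = NULL) {
  positives <- normalize_pairs(positives, "positives")
  negatives <- if (is.null(negatives) || nrow(as.data.frame(negatives)) == 0L) {
    data.frame(compound_id = character(), sequence_id = character(),
               stringsAsFactors = FALSE)
  } else {
    normalize_pairs(negatives, "negatives")
  }

  pos_keys <- pair_keys(positives)
  neg_keys <- pair_keys(negatives)
  if (anyDuplicated(pos_keys)) {
    stop_value("duplicate pairs within positives")
  }
  if (anyDuplicated(neg_keys)) {
    stop_value("duplicate pairs within negatives")
  }
  clash <- intersect(pos_keys, neg_keys)
  if (length(clash)) {
    stop_value("pair(s) labeled both positive and negative: %s",
               paste(clash, collapse = ", "))
  }

  observed_c <- unique(c(positives$compound_id, negatives$compound_id))
  observed_s <- unique(c(positives$sequence_id, negatives$sequence_id))
  compound_ids <- sort(unique(as.character(compound_ids %||% observed_c)))
  sequence_ids <- sort(unique(as.character(sequence_ids %||% observed_s)))
  missing_c <- setdiff(observed_c, compound_ids)
  missing_s <- setdiff(observed_s, sequence_ids)
  if (length(missing_c) || length(missing_s)) {
    stop_value("unregistered ids in pairs: %s",
               paste(c(missing_c, missing_s), collapse = ", "))
  }

  structure(
    list(positives = positives, negatives = negatives,
         compound_ids = compound_ids, sequence_ids = sequence_ids),
    class = "interaction_table"
  )
}

normalize_pairs <- function(df, what) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "sequence_id") %in% names(df))) {
    stop_value("%s must have columns compound_id and sequence_id", what)
  }
  out <- data.frame(compound_id = as.character(df$compound_id),
                    sequence_id = as.character(df$sequence_id),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    out <- out[order(out$compound_id, out$sequence_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

pair_keys <- function(df) {
  if (!nrow(df)) return(character())
  paste(df$compound_id, df$sequence_id, sep = "\r")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf(
    "interaction_table: %d positives, %d labeled negatives, %d compounds, %d sequences\n",
    nrow(x$positives), nrow(x$negatives),
    length(x$compound_ids), length(x$sequence_ids)))
  invisible(x)
}

#' Read an interaction table from a TSV file
#'
#' Expects one row per (compound, sequence) pair. An optional 0/1 label column
#' separates labeled negatives (0) from positives (1); without it every row is
#' a positive. Duplicate rows are collapsed with a message; a pair carrying
#' both labels is an error.
#'
#' @param path path to a tab-separated file with a header.
#' @param compound_column,sequence_column column names holding the ids.
#' @param label_column optional name of a 0/1 label column.
#' @inheritParams interaction_table
#' @return an [interaction_table()].
#' @export
read_interactions <- function(path,
                              compound_column = "compound_id",
                              sequence_column = "sequence_id",
                              label_column = NULL,
                              compound_ids = NULL,
                              sequence_ids = NULL) {
  if (!file.exists(path)) stop_value("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c(compound_column, sequence_column, label_column)
  absent <- setdiff(needed, names(df))
  if (length(absent)) {
    stop_value("missing column(s) in %s: %s", path,
               paste(absent, collapse = ", "))
  }
  pairs <- data.frame(compound_id = df[[compound_column]],
                      sequence_id = df[[sequence_column]],
                      stringsAsFactors = FALSE)
  if (is.null(label_column)) {
    label <- rep(1L, nrow(pairs))
  } else {
    label <- as.integer(df[[label_column]])
    if (nrow(pairs) && any(is.na(label) | !(label %in% c(0L, 1L)))) {
      stop_value("label column %s must be 0/1", label_column)
    }
  }

  key <- paste(pair_keys(pairs), label, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sprintf("read_interactions: collapsed %d duplicate row(s)", sum(dup)))
    pairs <- pairs[!dup, , drop = FALSE]
    label <- label[!dup]
  }
  both <- intersect(pair_keys(pairs[label == 1L, , drop = FALSE]),
                    pair_keys(pairs[label == 0L, , drop = FALSE]))
  if (length(both)) {
    stop_value("pair(s) labeled both 1 and 0: %s",
               paste(gsub("\r", "/", both), collapse = ", "))
  }
  interaction_table(pairs[label == 1L, , drop = FALSE],
                    pairs[label == 0L, , drop = FALSE],
                    compound_ids = compound_ids,
                    sequence_ids = sequence_ids)
}

#' Write an interaction table to TSV
#'
#' Inverse of [read_interactions()]: positives get label 1, labeled negatives
#' label 0.
#'
#' @param table an [interaction_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(table, path) {
  stopifnot(inherits(table, "interaction_table"))
  df <- rbind(
    cbind(table$positives, label = if (nrow(table$positives)) 1L else integer()),
    cbind(table$negatives, label = if (nrow(table$negatives)) 0L else integer())
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Interaction counts per entity over the positive pairs.
entity_counts <- function(table, side = c("compound", "sequence")) {
  side <- match.arg(side)
  ids <- if (side == "compound") table$compound_ids else table$sequence_ids
  col <- if (side == "compound") "compound_id" else "sequence_id"
  counts <- table(factor(table$positives[[col]], levels = ids))
  stats::setNames(as.integer(counts), ids)
}
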