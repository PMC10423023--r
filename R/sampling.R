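# Negative sampling and data splits. Negatives are uniform draws without
# replacement from C x S minus the known positives and labeled negatives,
# reflecting that most compound-protein pairs do not interact.

# Draw exactly n candidate pairs, seeded; errors if fewer are available.
sample_negative_pairs <- function(table, n, seed) {
  nc <- length(table$compound_ids)
  ns <- length(table$sequence_ids)
  total <- as.numeric(nc) * ns
  excluded_keys <- c(pair_keys(table$positives), pair_keys(table$negatives))
  avail <- total - length(excluded_keys)
  if (n > avail) {
    stop_value("insufficient negative candidates: need %d, have %.0f (deficit %d)",
               n, avail, n - avail)
  }
  with_seed(seed, {
    # linear indices over the C x S grid, excluding known pairs
    excl_idx <- sort(match_pair_index(excluded_keys, table))
    if (total <= 5e6) {
      pool <- setdiff(seq_len(total), excl_idx)
      picked <- if (length(pool) == n) pool else sample(pool, n)
    } else {
      picked <- integer(0)
      need <- n
      while (need > 0L) {
        cand <- unique(sample.int(total, min(total, need * 2L + 16L)))
        cand <- setdiff(cand, c(excl_idx, picked))
        picked <- c(picked, utils::head(cand, need))
        need <- n - length(picked)
      }
    }
    picked <- sort(picked[seq_len(n)])
    ci <- ((picked - 1L) %% nc) + 1L
    si <- ((picked - 1L) %/% nc) + 1L
    data.frame(compound_id = table$compound_ids[ci],
               sequence_id = table$sequence_ids[si],
               stringsAsFactors = FALSE)
  })
}

match_pair_index <- function(keys, table) {
  if (!length(keys)) return(integer())
  parts <- strsplit(keys, "\r", fixed = TRUE)
  ci <- match(vapply(parts, `[[`, "", 1L), table$compound_ids)
  si <- match(vapply(parts, `[[`, "", 2L), table$sequence_ids)
  (si - 1L) * length(table$compound_ids) + ci
}

#' Sample random negative pairs
#'
#' Draws `ratio * n_positives` pairs uniformly without replacement from
#' `C x S`, excluding known positives and labeled negatives. Deterministic
#' given the seed.
#'
#' @param table an [interaction_table()].
#' @param ratio negative-to-positive ratio (default 5, the training ratio).
#' @param seed integer seed.
#' @return data.frame of `compound_id`, `sequence_id`.
#' @export
sample_negatives <- function(table, ratio = 5L, seed = 0L) {
  stopifnot(inherits(table, "interaction_table"), ratio >= 1L)
  sample_negative_pairs(table, as.integer(ratio) * nrow(table$positives), seed)
}

#' Hold out the least frequent entities as an unseen test split
#'
#' Marks the `fraction` of compounds and the `fraction` of sequences with the
#' lowest positive-interaction counts as unseen (ties broken by id,
#' lexicographically); every positive touching an unseen entity moves to the
#' unseen table, the remainder forms the training table. The two tables
#' partition the positives.
#'
#' @param table an [interaction_table()].
#' @param fraction in (0, 1); the held-out count per side is
#'   `floor(fraction * n)`, at least 1.
#' @return list with `train_table`, `unseen_table`, `unseen_compounds`,
#'   `unseen_sequences`.
#' @export
make_unseen_split <- function(table, fraction = 0.05) {
  stopifnot(inherits(table, "interaction_table"))
  if (!(fraction > 0 && fraction < 1)) stop_value("fraction must be in (0, 1)")
  pick_unseen <- function(counts) {
    n_hold <- max(1L, floor(fraction * length(counts)))
    if (n_hold >= length(counts)) {
      stop_value("fraction %.2f would remove all entities", fraction)
    }
    ord <- order(counts, names(counts), method = "radix")
    names(counts)[ord][seq_len(n_hold)]
  }
  unseen_c <- pick_unseen(entity_counts(table, "compound"))
  unseen_s <- pick_unseen(entity_counts(table, "sequence"))
  pos <- table$positives
  touches <- pos$compound_id %in% unseen_c | pos$sequence_id %in% unseen_s
  neg <- table$negatives
  neg_touches <- if (nrow(neg)) {
    neg$compound_id %in% unseen_c | neg$sequence_id %in% unseen_s
  } else {
    logical(0)
  }
  list(
    train_table = interaction_table(
      pos[!touches, , drop = FALSE], neg[!neg_touches, , drop = FALSE],
      compound_ids = setdiff(table$compound_ids, unseen_c),
      sequence_ids = setdiff(table$sequence_ids, unseen_s)),
    unseen_table = interaction_table(
      pos[touches, , drop = FALSE], neg[neg_touches, , drop = FALSE],
      compound_ids = table$compound_ids,
      sequence_ids = table$sequence_ids),
    unseen_compounds = unseen_c,
    unseen_sequences = unseen_s)
}

# Split positive pairs into train/validation/test by the given ratios,
# seeded.
split_positives <- function(table, ratios = c(8, 1, 1), seed = 0L) {
  stopifnot(all(ratios > 0), length(ratios) == 3L)
  pos <- table$positives
  n <- nrow(pos)
  frac <- ratios / sum(ratios)
  n_train <- round(n * frac[1L])
  n_val <- round(n * frac[2L])
  with_seed(seed, {
    perm <- sample.int(n)
    list(train = pos[perm[seq_len(n_train)], , drop = FALSE],
         val = pos[perm[n_train + seq_len(n_val)], , drop = FALSE],
         test = pos[perm[(n_train + n_val + 1L):n], , drop = FALSE])
  })
}
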