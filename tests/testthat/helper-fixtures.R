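# Shared fixtures, built in code. Molecular featurization goes through a
# subprocess, so frequently used graphs are cached per test run.

tiny_table <- function() {
  interaction_table(data.frame(
    compound_id = c("c1", "c1", "c1", "c2"),
    sequence_id = c("s1", "s2", "s3", "s1")))
}

fixture_env <- new.env(parent = emptyenv())

# Graphs for a handful of small molecules, featurized once per session.
fixture_graphs <- function() {
  if (is.null(fixture_env$graphs)) {
    fixture_env$graphs <- featurize_compounds(c(
      methane = "C", ethanol = "CCO", benzene = "c1ccccc1",
      ethanol_reordered = "OCC", acetic = "CC(=O)O",
      butane = "CCCC", thioether = "CCSC"))
  }
  fixture_env$graphs
}

# A small block dataset + featurized csi_dataset, built once.
fixture_block <- function() {
  if (is.null(fixture_env$block)) {
    cfg <- block_model_config(n_compounds = 24L, n_sequences = 24L,
                              n_groups = 3L, p_in = 0.4, p_out = 0.02,
                              seq_length_range = c(30L, 60L),
                              mol_size_range = c(6L, 12L), seed = 11L)
    block <- generate_block_dataset(cfg)
    dataset <- csi_dataset(block$table, block$compounds, block$sequences,
                           L_max = 64L)
    fixture_env$block <- list(block = block, dataset = dataset)
  }
  fixture_env$block
}

# Random interaction table over given entity counts; every compound gets at
# least one partner.
random_table <- function(n_c, n_s, p = 0.2) {
  cids <- sprintf("c%02d", seq_len(n_c))
  sids <- sprintf("s%02d", seq_len(n_s))
  hit <- matrix(stats::runif(n_c * n_s) < p, n_c, n_s)
  for (i in which(rowSums(hit) == 0L)) hit[i, sample.int(n_s, 1L)] <- TRUE
  idx <- which(hit, arr.ind = TRUE)
  interaction_table(
    data.frame(compound_id = cids[idx[, 1L]], sequence_id = sids[idx[, 2L]]),
    compound_ids = cids, sequence_ids = sids)
}

# Independent brute-force metric oracles (loops over the ranked list, no
# shared code with the package implementations).
oracle_ap <- function(labels, scores, k = NULL) {
  ord <- order(-scores, seq_along(scores))
  l <- labels[ord]
  R <- sum(labels)
  if (R == 0) return(NA_real_)
  if (!is.null(k)) l <- l[seq_len(min(k, length(l)))]
  total <- 0
  hits <- 0
  for (r in seq_along(l)) {
    if (l[r] == 1) {
      hits <- hits + 1
      total <- total + hits / r
    }
  }
  total / if (is.null(k)) R else min(R, k)
}

oracle_rprec <- function(labels, scores) {
  ord <- order(-scores, seq_along(scores))
  R <- sum(labels)
  if (R == 0) return(NA_real_)
  sum(labels[ord][seq_len(R)]) / R
}

# Double-loop InfoNCE oracle built directly from the discriminator.
oracle_directed_loss <- function(Z1, Z2, tau) {
  k <- nrow(Z1)
  total <- 0
  for (n in seq_len(k)) {
    denom <- 0
    for (m in seq_len(k)) denom <- denom + discriminator(Z1[n, ], Z2[m, ], tau)
    total <- total - log(discriminator(Z1[n, ], Z2[n, ], tau) / denom)
  }
  total / k
}

oracle_total_loss <- function(Z1, Z2, tau) {
  oracle_directed_loss(Z1, Z2, tau) + oracle_directed_loss(Z2, Z1, tau)
}
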