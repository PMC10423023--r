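test_that("block model positive counts match the binomial expectation", {
  cfg <- block_model_config(n_compounds = 80L, n_sequences = 80L,
                            n_groups = 4L, p_in = 0.3, p_out = 0.01,
                            seed = 0L)
  block <- generate_block_dataset(cfg)
  # balanced groups: 4 * 20 * 20 within-group cells
  n_in <- sum(outer(block$compound_groups, block$sequence_groups, "=="))
  n_out <- 80 * 80 - n_in
  expect_equal(n_in, 1600)
  mu <- n_in * 0.3 + n_out * 0.01
  sigma <- sqrt(n_in * 0.3 * 0.7 + n_out * 0.01 * 0.99)
  expect_lt(abs(nrow(block$table$positives) - mu), 4 * sigma)
})

test_that("block generation is deterministic in the seed", {
  cfg <- block_model_config(n_compounds = 20L, n_sequences = 20L,
                            n_groups = 2L, seed = 5L)
  a <- generate_block_dataset(cfg)
  b <- generate_block_dataset(cfg)
  expect_identical(a$compounds, b$compounds)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$table$positives, b$table$positives)
  cfg2 <- cfg
  cfg2$seed <- 6L
  expect_false(identical(generate_block_dataset(cfg2)$compounds, a$compounds))
})

test_that("empirical rates approach p_in and p_out at large n", {
  cfg <- block_model_config(n_compounds = 500L, n_sequences = 500L,
                            n_groups = 4L, p_in = 0.3, p_out = 0.01,
                            seed = 3L)
  block <- generate_block_dataset(cfg)
  same <- outer(block$compound_groups, block$sequence_groups, "==")
  pos <- matrix(FALSE, 500, 500,
                dimnames = list(names(block$compound_groups),
                                names(block$sequence_groups)))
  pos[cbind(block$table$positives$compound_id,
            block$table$positives$sequence_id)] <- TRUE
  n_in <- sum(same)
  n_out <- length(same) - n_in
  rate_in <- sum(pos & same) / n_in
  rate_out <- sum(pos & !same) / n_out
  expect_lt(abs(rate_in - 0.3), 3 * sqrt(0.3 * 0.7 / n_in))
  expect_lt(abs(rate_out - 0.01), 3 * sqrt(0.01 * 0.99 / n_out))
})

test_that("generated inputs featurize and strata are non-degenerate", {
  fb <- fixture_block()
  # all SMILES parsed and sequences encoded during dataset assembly
  expect_length(fb$dataset$graphs, 24L)
  expect_equal(nrow(fb$dataset$tokens), 24L)
  counts <- entity_counts(fb$block$table, "compound")
  expect_gte(mean(counts >= 2L), 0.8)
})

test_that("oracle interaction probability reads the block structure", {
  cfg <- block_model_config()
  expect_equal(oracle_interaction_probability(cfg, 2, 2), cfg$p_in)
  expect_equal(oracle_interaction_probability(cfg, 1, 2), cfg$p_out)
  expect_error(oracle_interaction_probability(cfg, 0, 2))
})

test_that("config invariants are enforced", {
  expect_error(block_model_config(p_in = 0.1, p_out = 0.2), "p_out < p_in")
  expect_error(block_model_config(n_groups = 100L, n_compounds = 10L,
                                  n_sequences = 10L), "n_groups")
  expect_error(reaction_model_config(n_reactions = 4L, n_rclasses = 10L),
               "n_reactions")
})

test_that("reaction generator induces the compound x enzyme interactions", {
  fb <- fixture_block()
  rc <- reaction_model_config(n_reactions = 6L, n_rclasses = 3L,
                              n_ec_numbers = 3L, seed = 2L)
  rxn <- generate_reaction_dataset(rc, fb$block)
  expect_length(rxn$reactions, 6L)
  # induced table = union over reactions of (R u P) x E
  expected <- unique(do.call(rbind, lapply(rxn$reactions, function(r) {
    expand.grid(compound_id = union(r$reactant_ids, r$product_ids),
                sequence_id = r$enzyme_ids, stringsAsFactors = FALSE)
  })))
  expect_setequal(pair_keys(rxn$table$positives), pair_keys(expected))
  # reactions sharing an rclass share the group
  rcl <- vapply(rxn$reactions, `[[`, "", "rclass_id")
  for (cl in unique(rcl)) {
    expect_length(unique(rxn$reaction_groups[rcl == cl]), 1L)
  }
  # determinism
  rxn2 <- generate_reaction_dataset(rc, fb$block)
  expect_identical(rxn$table$positives, rxn2$table$positives)
})

test_that("one rclass per reaction yields singleton rclass strata", {
  fb <- fixture_block()
  rc <- reaction_model_config(n_reactions = 5L, n_rclasses = 5L,
                              n_ec_numbers = 5L, seed = 4L)
  rxn <- generate_reaction_dataset(rc, fb$block)
  st <- stratify_by_reaction_feature(rxn$reactions, "rclass")
  sizes <- table(vapply(rxn$reactions, `[[`, "", "rclass_id"))
  expect_equal(length(st), length(sizes))
})
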