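small_cfg <- function(seed = 3L) {
  encoder_config(embed_dim = 8L, gcn_layers = 2L, gcn_hidden = 12L,
                 fc_hidden = 16L, cnn_channels = c(6L, 8L),
                 cnn_kernel_sizes = c(5L, 7L), residue_embed_dim = 6L,
                 L_max = 40L, seed = seed)
}

test_that("encoders emit the contracted dimensions, deterministically", {
  cfg <- small_cfg()
  gcn <- csistrat:::new_gcn_from_config(cfg, 2L * cfg$embed_dim, 10)
  cnn <- csistrat:::new_cnn_from_config(cfg, cfg$embed_dim, 11)
  g <- fixture_graphs()$ethanol
  z <- encode_compound(gcn, g)
  expect_length(z, 16L)
  expect_true(all(is.finite(z)))
  expect_equal(z, encode_compound(gcn, g))
  F1 <- encode_sequence("ACDKLMNP", cfg$L_max)
  z2 <- encode_sequence_cnn(cnn, F1)
  expect_length(z2, 8L)
  expect_equal(z2, encode_sequence_cnn(cnn, F1))
})

test_that("GCN embeddings are invariant to node permutation", {
  cfg <- small_cfg()
  gcn <- csistrat:::new_gcn_from_config(cfg, 16L, 12)
  g <- fixture_graphs()$acetic
  z <- encode_compound(gcn, g)
  set.seed(1)
  for (rep in 1:5) {
    perm <- sample.int(g$n_nodes)
    gp <- g
    gp$node_features <- g$node_features[perm, , drop = FALSE]
    inv <- order(perm)
    gp$edges <- matrix(inv[g$edges], ncol = 2L)
    zp <- encode_compound(gcn, gp)
    expect_equal(zp, z, tolerance = 1e-5)
  }
  # canonical vs shuffled atom order of the same molecule
  z_a <- encode_compound(gcn, fixture_graphs()$ethanol)
  z_b <- encode_compound(gcn, fixture_graphs()$ethanol_reordered)
  expect_equal(z_a, z_b, tolerance = 1e-5)
})

test_that("Siamese pair encoders tie weights and concatenate in order", {
  cfg <- small_cfg()
  cnn <- csistrat:::new_cnn_from_config(cfg, cfg$embed_dim, 13)
  gcn <- csistrat:::new_gcn_from_config(cfg, cfg$embed_dim, 14)
  Fa <- encode_sequence("ACDKLM", cfg$L_max)
  Fb <- encode_sequence("WYVTSR", cfg$L_max)
  z_same <- encode_sequence_pair(cnn, Fa, Fa)
  d <- length(z_same) / 2
  expect_equal(z_same[1:d], z_same[(d + 1):(2 * d)])
  z_ab <- encode_sequence_pair(cnn, Fa, Fb)
  z_ba <- encode_sequence_pair(cnn, Fb, Fa)
  expect_length(z_ab, 2L * cfg$embed_dim)
  expect_equal(z_ab[1:d], z_ba[(d + 1):(2 * d)])
  expect_equal(z_ab[(d + 1):(2 * d)], z_ba[1:d])

  ga <- fixture_graphs()$ethanol
  gb <- fixture_graphs()$butane
  zg <- encode_compound_pair(gcn, ga, gb)
  expect_length(zg, 2L * cfg$embed_dim)
  expect_equal(zg[1:d], encode_compound(gcn, ga))
})

test_that("phase encoders are independent and dimensionally compatible", {
  cfg <- small_cfg()
  e1a <- csistrat:::init_phase1_encoders("compound_key", cfg, 0)
  e1b <- csistrat:::init_phase1_encoders("sequence_key", cfg, 0)
  # same-dimension views within each phase
  expect_equal(e1a$gcn_lone$out_dim, 2L * e1a$cnn_arm$out_dim)
  expect_equal(e1b$cnn_lone$out_dim, 2L * e1b$gcn_arm$out_dim)
  # no parameter sharing across phases
  expect_false(identical(e1a$gcn_lone$params, e1b$gcn_arm$params))
  expect_false(identical(e1a$cnn_arm$params, e1b$cnn_lone$params))
})

test_that("encoder outputs stay finite over random inputs", {
  cfg <- small_cfg()
  cnn <- csistrat:::new_cnn_from_config(cfg, 8L, 15)
  gcn <- csistrat:::new_gcn_from_config(cfg, 8L, 16)
  graphs <- fixture_graphs()
  set.seed(20)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    s <- paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
    z <- encode_sequence_cnn(cnn, encode_sequence(s, cfg$L_max))
    expect_true(all(is.finite(z)))
  }
  for (g in graphs) expect_true(all(is.finite(encode_compound(gcn, g))))
})

test_that("masked padding makes the tail beyond original length irrelevant", {
  cfg <- small_cfg()
  cfg$mask_padding <- TRUE
  cnn <- csistrat:::new_cnn_from_config(cfg, 8L, 17)
  # same residues under two padded lengths: masked convolutions must agree
  short <- encode_sequence("ACDKLMNPQR", 24L)
  long <- encode_sequence("ACDKLMNPQR", cfg$L_max)
  expect_equal(encode_sequence_cnn(cnn, short),
               encode_sequence_cnn(cnn, long))
})

test_that("empty graphs are rejected", {
  g <- fixture_graphs()$methane
  g$n_nodes <- 0L
  g$node_features <- g$node_features[0, , drop = FALSE]
  expect_error(csistrat:::prepare_graph(g), "empty")
})

test_that("model archives round-trip encoders exactly", {
  cfg <- small_cfg()
  strata <- stratify_by_compound(fixture_block()$dataset$table)
  tc <- train_config(phase1_epochs = 1L, phase2_epochs = 1L, batch_size = 4L,
                     seed = 1L)
  p1 <- train_phase1(fixture_block()$dataset, strata, "compound_key", tc, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(p1, f)
  back <- load_model(f)
  expect_equal(back$encoders$gcn_lone$params, p1$encoders$gcn_lone$params,
               tolerance = 1e-12)
  expect_equal(back$encoders$cnn_arm$params, p1$encoders$cnn_arm$params,
               tolerance = 1e-12)
  expect_true(isTRUE(attr(back$encoders, "frozen")))
  # reloaded encoder produces identical embeddings
  g <- fixture_block()$dataset$graphs[[1]]
  enc_back <- back$encoders$gcn_lone
  class(enc_back) <- "gcn_encoder"
  expect_equal(encode_compound(enc_back, g),
               encode_compound(p1$encoders$gcn_lone, g), tolerance = 1e-12)
})
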