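test_that("read_interactions collapses duplicates and keeps set semantics", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tsequence_id",
               "c1\ts1", "c1\ts2", "c2\ts1", "c1\ts1"), f)
  expect_message(tb <- read_interactions(f), "1 duplicate")
  expect_s3_class(tb, "interaction_table")
  expect_equal(nrow(tb$positives), 3L)
  expect_setequal(pair_keys(tb$positives),
                  c("c1\rs1", "c1\rs2", "c2\rs1"))
})

test_that("read_interactions handles empty files, labels and conflicts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("compound_id\tsequence_id", f)
  tb <- read_interactions(f)
  expect_equal(nrow(tb$positives), 0L)

  writeLines(c("compound_id\tsequence_id\tlabel",
               "c1\ts1\t1", "c1\ts2\t0"), f)
  tb <- read_interactions(f, label_column = "label")
  expect_equal(nrow(tb$positives), 1L)
  expect_equal(nrow(tb$negatives), 1L)

  writeLines(c("compound_id\tsequence_id\tlabel",
               "c1\ts1\t1", "c1\ts1\t0"), f)
  expect_error(read_interactions(f, label_column = "label"), "both 1 and 0")

  writeLines(c("compound\tsequence_id", "c1\ts1"), f)
  expect_error(read_interactions(f), "missing column")
})

test_that("interaction tables round-trip through TSV as sets", {
  tb <- interaction_table(
    data.frame(compound_id = c("c2", "c1", "c1"),
               sequence_id = c("s1", "s2", "s1")),
    negatives = data.frame(compound_id = "c3", sequence_id = "s1"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(tb, f)
  back <- read_interactions(f, label_column = "label")
  expect_setequal(pair_keys(back$positives), pair_keys(tb$positives))
  expect_setequal(pair_keys(back$negatives), pair_keys(tb$negatives))
})

test_that("interaction_table enforces its invariants", {
  expect_error(interaction_table(
    data.frame(compound_id = c("c1", "c1"), sequence_id = c("s1", "s1"))),
    "duplicate")
  expect_error(interaction_table(
    data.frame(compound_id = "c1", sequence_id = "s1"),
    negatives = data.frame(compound_id = "c1", sequence_id = "s1")),
    "both positive and negative")
  expect_error(interaction_table(
    data.frame(compound_id = "c1", sequence_id = "s1"),
    compound_ids = "cX"), "unregistered")
})

test_that("read_reactions parses multi-valued fields and flags empties", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\treactants\tproducts\tenzymes\trclass\tec",
               "r1\tm1\tm2\te1|e2\tRC1\t1.1.1.1",
               "r2\tm2|m3\tm4\te3\tRC1\t1.1.1.2"), f)
  recs <- read_reactions(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$enzyme_ids, c("e1", "e2"))
  expect_equal(vapply(recs, `[[`, "", "rclass_id"), c("RC1", "RC1"))

  writeLines(c("reaction_id\treactants\tproducts\tenzymes\trclass\tec",
               "r1\tm1\tm2\t\tRC1\t1.1.1.1"), f)
  expect_error(read_reactions(f), "r1")
})

test_that("reaction records round-trip through TSV", {
  recs <- list(
    reaction_record("r1", c("m1", "m2"), "m3", c("e1", "e2"), "RC1", "1.1.1.1"),
    reaction_record("r2", "m3", "m4", "e3"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reactions(recs, f)
  back <- read_reactions(f)
  expect_equal(back[[1]]$reactant_ids, c("m1", "m2"))
  expect_equal(back[[2]]$ec_number, NA_character_)
})

test_that("FASTA and compound tables round-trip", {
  seqs <- c(s1 = "ACDEFGH", s2 = "MKLVVW")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_sequences(seqs, f)
  expect_equal(read_sequences(f), seqs)

  smi <- c(c1 = "CCO", c2 = "CC(=O)O")
  g <- withr::local_tempfile(fileext = ".tsv")
  write_compounds(smi, g)
  expect_equal(read_compounds(g), smi)
})
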