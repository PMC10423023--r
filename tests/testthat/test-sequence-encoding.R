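test_that("encoding pads, truncates and preserves original length", {
  e <- encode_sequence("ACD", 5L)
  expect_equal(e$tokens, c(1L, 2L, 3L, 0L, 0L))
  expect_equal(e$original_length, 3L)

  long <- paste(rep("A", 1200), collapse = "")
  e2 <- encode_sequence(long, 1000L)
  expect_length(e2$tokens, 1000L)
  expect_equal(e2$original_length, 1200L)
  expect_true(all(e2$tokens == 1L))
})

test_that("unknown and ambiguity codes map to the unknown token", {
  x_idx <- match("X", aa_alphabet())
  e <- encode_sequence("AXA", 3L)
  expect_equal(e$tokens[2L], x_idx)
  for (code in c("B", "J", "O", "U", "Z", "*")) {
    expect_equal(encode_sequence(code, 1L)$tokens, x_idx)
  }
})

test_that("output length always equals L_max", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:300, 1)
    L <- sample(1:200, 1)
    s <- paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
    e <- encode_sequence(s, L)
    expect_length(e$tokens, L)
    expect_true(all(e$tokens >= 0L & e$tokens <= length(aa_alphabet())))
  }
})

test_that("empty input is rejected", {
  expect_error(encode_sequence("", 10L), "non-empty")
})
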