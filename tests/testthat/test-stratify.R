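test_that("compound stratification enumerates unordered sequence pairs", {
  st <- stratify_by_compound(tiny_table())
  expect_length(st, 2L)
  expect_equal(st[[1]]$key_value, "c1")
  expect_equal(nrow(st[[1]]$views), 3L)
  expect_setequal(apply(st[[1]]$views, 1L, paste, collapse = "-"),
                  c("s1-s2", "s1-s3", "s2-s3"))
  # singleton key keeps a self-pair view
  expect_equal(unname(st[[2]]$views[1L, ]), c("s1", "s1"))
})

test_that("sequence stratification mirrors compound stratification", {
  tb <- interaction_table(data.frame(compound_id = c("c1", "c2"),
                                     sequence_id = c("s1", "s1")))
  st <- stratify_by_sequence(tb)
  expect_length(st, 1L)
  expect_equal(unname(st[[1]]$views[1L, ]), c("c1", "c2"))
})

test_that("empty tables stratify to empty lists", {
  tb <- interaction_table(data.frame(compound_id = character(),
                                     sequence_id = character()))
  expect_length(stratify_by_compound(tb), 0L)
  expect_length(stratify_by_sequence(tb), 0L)
})

test_that("view counts match the combinatorial closed form on random tables", {
  set.seed(101)
  for (rep in 1:100) {
    tb <- random_table(sample(3:10, 1), sample(3:10, 1), p = stats::runif(1, 0.1, 0.5))
    for (side in c("compound", "sequence")) {
      st <- if (side == "compound") stratify_by_compound(tb) else
        stratify_by_sequence(tb)
      col <- if (side == "compound") "compound_id" else "sequence_id"
      counts <- table(tb$positives[[col]])
      expected <- sum(ifelse(counts == 1L, 1L, choose(counts, 2L)))
      expect_equal(sum(vapply(st, function(s) nrow(s$views), 1L)), expected)
    }
  }
})

test_that("every positive appears in its key stratum and keys are disjoint", {
  set.seed(55)
  tb <- random_table(8, 8, 0.3)
  st <- stratify_by_compound(tb)
  keys <- vapply(st, `[[`, "", "key_value")
  expect_false(anyDuplicated(keys) > 0)
  for (r in seq_len(nrow(tb$positives))) {
    c_id <- tb$positives$compound_id[r]
    s_id <- tb$positives$sequence_id[r]
    views <- st[[match(c_id, keys)]]$views
    expect_true(any(views == s_id))
  }
  # determinism: re-running gives identical strata
  expect_identical(st, stratify_by_compound(tb))
})

test_that("reaction-feature strata enumerate the three view lists", {
  rec <- reaction_record("r1", c("m1", "m2"), "m3", c("e1", "e2"),
                         "RC1", "1.1.1.1")
  st <- stratify_by_reaction_feature(list(rec), "reaction")
  expect_length(st, 1L)
  v <- st[[1]]$views
  expect_setequal(apply(v$reactant_product, 1L, paste, collapse = "-"),
                  c("m1-m3", "m2-m3"))
  expect_equal(nrow(v$compound_sequence), 6L)
  expect_equal(nrow(v$sequence_pair), 1L)
  expect_equal(unname(v$sequence_pair[1L, ]), c("e1", "e2"))

  # single enzyme -> self pair
  rec1 <- reaction_record("r2", "m1", "m2", "e1")
  st1 <- stratify_by_reaction_feature(list(rec1), "reaction")
  expect_equal(unname(st1[[1]]$views$sequence_pair[1L, ]), c("e1", "e1"))
})

test_that("rclass grouping pools and deduplicates views across reactions", {
  recs <- list(
    reaction_record("r1", "m1", "m2", c("e1", "e2"), "RC1", "1.1.1.1"),
    reaction_record("r2", "m1", "m3", c("e1", "e2"), "RC1", "1.1.1.2"))
  st <- stratify_by_reaction_feature(recs, "rclass")
  expect_length(st, 1L)
  v <- st[[1]]$views
  expect_setequal(apply(v$reactant_product, 1L, paste, collapse = "-"),
                  c("m1-m2", "m1-m3"))
  # enzyme pair (e1,e2) appears once despite both reactions sharing it
  expect_equal(nrow(v$sequence_pair), 1L)

  no_rc <- list(reaction_record("r3", "m1", "m2", "e1"))
  expect_error(stratify_by_reaction_feature(no_rc, "rclass"), "r3")
})

test_that("reaction-feature lists match exhaustive enumeration on random sets", {
  set.seed(77)
  for (rep in 1:50) {
    n_rxn <- sample(2:6, 1)
    recs <- lapply(seq_len(n_rxn), function(r) {
      reaction_record(sprintf("r%d", r),
                      sample(sprintf("m%d", 1:6), sample(1:2, 1)),
                      sample(sprintf("m%d", 1:6), sample(1:2, 1)),
                      sample(sprintf("e%d", 1:4), sample(1:3, 1)),
                      rclass_id = sample(c("RC1", "RC2"), 1))
    })
    st <- stratify_by_reaction_feature(recs, "rclass")
    for (s in st) {
      grp <- Filter(function(r) r$rclass_id == s$key_value, recs)
      exp_v1 <- unique(unlist(lapply(grp, function(r) {
        as.vector(outer(r$reactant_ids, r$product_ids, paste, sep = "-"))
      })))
      got_v1 <- apply(s$views$reactant_product, 1L, paste, collapse = "-")
      expect_setequal(got_v1, exp_v1)
      exp_v2 <- unique(unlist(lapply(grp, function(r) {
        as.vector(outer(sort(union(r$reactant_ids, r$product_ids)),
                        r$enzyme_ids, paste, sep = "-"))
      })))
      expect_setequal(apply(s$views$compound_sequence, 1L, paste, collapse = "-"),
                      exp_v2)
    }
  }
})

test_that("strata statistics match set arithmetic", {
  mk <- function(key, seqs) {
    tbl <- interaction_table(data.frame(compound_id = key,
                                        sequence_id = seqs))
    stratify_by_compound(tbl)[[1]]
  }
  s1 <- mk("c1", c("s1", "s2"))
  s2 <- mk("c2", c("s2", "s3"))
  st <- compute_strata_stats(list(s1, s2))
  expect_equal(st$mean_shared, 1)
  expect_equal(st$mean_jaccard, 1 / 3)

  st_same <- compute_strata_stats(list(s1, s1))
  expect_equal(st_same$mean_jaccard, 1)

  s3 <- mk("c3", c("s4", "s5"))
  st_disj <- compute_strata_stats(list(s1, s3))
  expect_equal(st_disj$mean_shared, 0)
  expect_equal(st_disj$mean_jaccard, 0)

  # fewer than 2 strata: undefined marker, no error
  st1 <- compute_strata_stats(list(s1))
  expect_true(is.na(st1$mean_jaccard))

  # random tables against a direct pairwise oracle
  set.seed(9)
  tb <- random_table(6, 6, 0.4)
  st <- stratify_by_compound(tb)
  got <- compute_strata_stats(st)
  members <- lapply(st, function(s) unique(as.vector(s$views)))
  pairs <- utils::combn(length(members), 2L)
  jac <- mean(apply(pairs, 2L, function(p) {
    length(intersect(members[[p[1]]], members[[p[2]]])) /
      length(union(members[[p[1]]], members[[p[2]]]))
  }))
  expect_equal(got$mean_jaccard, jac)
})

test_that("strata serialize to JSON lines", {
  st <- stratify_by_compound(tiny_table())
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_strata(st, f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  parsed <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  expect_equal(parsed$key, "c1")
  expect_length(parsed$views, 3L)
})
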