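test_that("average precision matches hand-computed rankings", {
  # perfectly ranked positives
  expect_equal(average_precision(c(1, 1, 0), c(3, 2, 1)), 1)
  # ranked label sequence [1, 0, 1]
  expect_equal(average_precision(c(1, 0, 1), c(3, 2, 1)), (1 + 2 / 3) / 2)
  # single positive at the bottom
  expect_equal(average_precision(c(0, 0, 1), c(3, 2, 1)), 1 / 3)
  # no positives: undefined marker, no exception
  expect_true(is.na(average_precision(c(0, 0), c(1, 2))))
})

test_that("R-precision counts positives in the top R", {
  expect_equal(r_precision(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1)
  expect_equal(r_precision(c(1, 0, 1, 0), c(4, 3, 2, 1)), 0.5)
})

test_that("AP and R-precision agree with brute-force oracles on random instances", {
  set.seed(1234)
  for (rep in 1:1000) {
    n <- sample(2:50, 1)
    labels <- stats::rbinom(n, 1, 0.4)
    if (sum(labels) == 0) labels[sample(n, 1)] <- 1
    scores <- stats::rnorm(n)
    expect_equal(average_precision(labels, scores),
                 oracle_ap(labels, scores), tolerance = 1e-12)
    expect_equal(r_precision(labels, scores),
                 oracle_rprec(labels, scores), tolerance = 1e-12)
    k <- sample(1:10, 1)
    expect_equal(average_precision(labels, scores, k = k),
                 oracle_ap(labels, scores, k = k), tolerance = 1e-12)
  }
})

test_that("AP is invariant to strictly monotone score transforms", {
  set.seed(7)
  labels <- stats::rbinom(30, 1, 0.3)
  labels[1] <- 1
  scores <- stats::rnorm(30)
  base <- average_precision(labels, scores)
  expect_equal(average_precision(labels, exp(scores)), base)
  expect_equal(average_precision(labels, 3 * scores + 10), base)
})

test_that("MAP@k with k >= list length equals MAP", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    labels <- stats::rbinom(n, 1, 0.5)
    if (sum(labels) == 0) labels[1] <- 1
    scores <- stats::rnorm(n)
    expect_equal(average_precision(labels, scores, k = n + sample(0:5, 1)),
                 average_precision(labels, scores))
  }
})

test_that("grouped metrics truncate, average and skip as documented", {
  # one group, ranking [1, 0, 1]
  g <- grouped_metrics(rep("c1", 3), paste0("s", 1:3),
                       labels = c(1, 0, 1), scores = c(3, 2, 1), "compound",
                       k_cut = 3L)
  expect_equal(g$MAP_at_k, (1 + 2 / 3) / 2)
  expect_equal(g$Precision_at_1, 1)
  expect_equal(g$n_groups, 1L)

  # two perfectly ranked groups
  g2 <- grouped_metrics(rep(c("c1", "c2"), each = 2), rep(c("s1", "s2"), 2),
                        labels = c(1, 0, 1, 0), scores = c(2, 1, 2, 1),
                        "compound")
  expect_equal(unlist(g2[c("MAP", "R_precision", "MAP_at_k", "Precision_at_1")]),
               c(MAP = 1, R_precision = 1, MAP_at_k = 1, Precision_at_1 = 1))

  # positive below the cutoff contributes 0 to MAP@k
  g3 <- grouped_metrics(rep("c1", 4), paste0("s", 1:4),
                        labels = c(0, 0, 0, 1), scores = 4:1, "compound",
                        k_cut = 3L)
  expect_equal(g3$MAP_at_k, 0)

  # group without positives is skipped and counted
  g4 <- grouped_metrics(c("c1", "c1", "c2"), c("s1", "s2", "s1"),
                        labels = c(1, 0, 0), scores = c(1, 2, 3), "compound")
  expect_equal(g4$n_skipped, 1L)
  expect_equal(g4$n_groups, 1L)
})

test_that("random scores on balanced labels give AP near one half", {
  set.seed(99)
  aps <- replicate(1000, {
    labels <- rep(c(1, 0), each = 100)
    average_precision(labels, stats::rnorm(200))
  })
  expect_gt(mean(aps), 0.45)
  expect_lt(mean(aps), 0.55)
})

test_that("ties break by stable original order", {
  expect_equal(average_precision(c(1, 0), c(1, 1)), 1)
  expect_equal(average_precision(c(0, 1), c(1, 1)), 0.5)
})

test_that("ranking reports aggregate both groupings and serialize", {
  set.seed(5)
  n <- 40
  df <- data.frame(compound_id = sample(paste0("c", 1:5), n, TRUE),
                   sequence_id = sample(paste0("s", 1:5), n, TRUE),
                   label = stats::rbinom(n, 1, 0.5),
                   score = stats::rnorm(n))
  df$label[1] <- 1
  rep <- ranking_report(df$compound_id, df$sequence_id, df$label, df$score)
  expect_true(all(unlist(rep$overall) >= 0 & unlist(rep$overall) <= 1))
  f_json <- withr::local_tempfile(fileext = ".json")
  f_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ranking_report(rep, tsv = f_tsv, json = f_json)
  back <- jsonlite::read_json(f_json)
  expect_equal(back$overall$AP, rep$overall$AP)
  expect_equal(nrow(utils::read.delim(f_tsv)), 3L)
})
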