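test_that("featurization recovers molecule topology", {
  g <- fixture_graphs()
  expect_equal(g$methane$n_nodes, 1L)
  expect_equal(nrow(g$methane$edges), 0L)
  expect_equal(g$ethanol$n_nodes, 3L)
  expect_equal(nrow(g$ethanol$edges), 2L)
  # benzene: 6-ring, all atoms aromatic and in-ring
  expect_equal(g$benzene$n_nodes, 6L)
  expect_equal(nrow(g$benzene$edges), 6L)
  arom <- g$benzene$node_features[, ncol(g$benzene$node_features)]
  expect_true(all(arom == 1))
  for (gr in g) validate_molecular_graph(gr)
})

test_that("same molecule under different atom orders gives isomorphic graphs", {
  g <- fixture_graphs()
  multiset <- function(m) sort(apply(m, 1L, paste, collapse = ","))
  expect_equal(multiset(g$ethanol$node_features),
               multiset(g$ethanol_reordered$node_features))
  expect_equal(multiset(g$ethanol$edge_features),
               multiset(g$ethanol_reordered$edge_features))
})

test_that("unparseable SMILES raises an error naming the string", {
  expect_error(featurize_compound("not-a-smiles((("), "not-a-smiles")
})

test_that("featurization is deterministic for a fixed input", {
  a <- featurize_compound("CC(=O)O")
  b <- fixture_graphs()$acetic
  expect_equal(a$node_features, b$node_features)
  expect_equal(a$edges, b$edges)
})
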