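# Molecular featurization. SMILES are converted to heavy-atom graphs with the
# standard cheminformatics toolkit (rdkit), invoked in batch through the
# bundled python helper so chemical perception (aromaticity, rings, stereo)
# is never re-derived here.

NODE_FEATURE_DIM <- 22L
EDGE_FEATURE_DIM <- 10L

featurizer_script <- function() {
  path <- system.file("python", "featurize_smiles.py", package = "csistrat")
  if (!nzchar(path)) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "python", "featurize_smiles.py")
  }
  if (!file.exists(path)) stop_value("featurizer script not found")
  path
}

#' Featurize a batch of compounds from SMILES
#'
#' Converts each SMILES string to a `molecular_graph`: per-atom feature
#' vectors (atom-type one-hot, atomic mass, valence, ring membership, formal
#' charge, radical electrons, chirality, degree, hydrogen count, aromaticity)
#' and per-bond feature vectors (bond-type one-hot, ring membership,
#' conjugation, stereo one-hot). Hydrogens are implicit; each bond is stored
#' once and interpreted symmetrically.
#'
#' @param smiles character vector of SMILES strings; names (if any) become the
#'   compound ids of the result.
#' @return named list of `molecular_graph` objects, each with `node_features`
#'   (n x 22 matrix), `edges` (m x 2, 1-based), `edge_features` (m x 10),
#'   `n_nodes` and `smiles`.
#' @export
featurize_compounds <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  ids <- names(smiles) %||% as.character(seq_along(smiles))
  records <- lapply(seq_along(smiles), function(i) {
    list(id = ids[i], smiles = unname(smiles[i]))
  })
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(records, fin, auto_unbox = TRUE)
  status <- system2("python", c(shQuote(featurizer_script()),
                                shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(fout)) {
    stop_value("SMILES featurizer subprocess failed (status %s)", status)
  }
  parsed <- jsonlite::read_json(fout)
  out <- vector("list", length(parsed))
  names(out) <- ids
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    if (!isTRUE(p$ok)) stop_value("%s", p$error)
    nf <- matrix(unlist(p$node_features, use.names = FALSE),
                 nrow = p$n_nodes, ncol = NODE_FEATURE_DIM, byrow = TRUE)
    m <- length(p$edges)
    edges <- if (m) {
      matrix(unlist(p$edges, use.names = FALSE), nrow = m, byrow = TRUE) + 1L
    } else {
      matrix(integer(), 0L, 2L)
    }
    ef <- if (m) {
      matrix(unlist(p$edge_features, use.names = FALSE),
             nrow = m, ncol = EDGE_FEATURE_DIM, byrow = TRUE)
    } else {
      matrix(numeric(), 0L, EDGE_FEATURE_DIM)
    }
    out[[i]] <- structure(
      list(node_features = nf, edges = edges, edge_features = ef,
           n_nodes = as.integer(p$n_nodes), smiles = unname(smiles[i])),
      class = "molecular_graph")
  }
  out
}

#' Featurize a single compound
#'
#' @param smiles one SMILES string.
#' @return a `molecular_graph`; see [featurize_compounds()].
#' @export
featurize_compound <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  featurize_compounds(stats::setNames(smiles, "x"))[[1L]]
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("molecular_graph: %d heavy atoms, %d bonds (%s)\n",
              x$n_nodes, nrow(x$edges), x$smiles))
  invisible(x)
}

validate_molecular_graph <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  if (g$n_nodes < 1L) stop_value("empty molecular graph")
  if (nrow(g$edges)) {
    if (any(g$edges < 1L) || any(g$edges > g$n_nodes)) {
      stop_value("edge index out of range")
    }
  }
  stopifnot(ncol(g$node_features) == NODE_FEATURE_DIM,
            ncol(g$edge_features) == EDGE_FEATURE_DIM,
            nrow(g$node_features) == g$n_nodes,
            nrow(g$edge_features) == nrow(g$edges))
  invisible(g)
}

#' Read a compound table (id, SMILES) from TSV
#'
#' @param path tab-separated file with header columns `compound_id`, `smiles`.
#' @return named character vector of SMILES keyed by compound id.
#' @export
read_compounds <- function(path) {
  if (!file.exists(path)) stop_value("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("compound_id", "smiles") %in% names(df))) {
    stop_value("compound table must have columns compound_id, smiles")
  }
  if (anyDuplicated(df$compound_id)) {
    stop_value("duplicate compound ids in %s", path)
  }
  stats::setNames(df$smiles, df$compound_id)
}

#' Write a compound table to TSV
#'
#' @param smiles named character vector of SMILES keyed by compound id.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(smiles, path) {
  utils::write.table(
    data.frame(compound_id = names(smiles), smiles = unname(smiles)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Precompute what the GCN needs per graph: node feature matrix and the
# symmetrically normalized adjacency with self-loops,
# A_hat = D^-1/2 (A + I) D^-1/2 (dense; molecules are small).
prepare_graph <- function(graph) {
  validate_molecular_graph(graph)
  n <- graph$n_nodes
  A <- diag(1, n)
  if (nrow(graph$edges)) {
    A[graph$edges] <- 1
    A[graph$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  dinv <- 1 / sqrt(rowSums(A))
  A_hat <- A * tcrossprod(dinv)
  list(X = graph$node_features, A_hat = A_hat, n = n)
}
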