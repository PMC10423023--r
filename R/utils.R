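#' @keywords internal
"_PACKAGE"

#' Evaluate code under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `code`, and restores the
#' previous state on exit, so seeded helpers do not perturb user-level
#' randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and a small stream label.
# Keeps results < 2^31 so they remain valid R integer seeds.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + as.numeric(stream) * 7919) %% 2147483647
}

#' Checksum of a serialized R object
#'
#' SHA-256 via the system `sha256sum` utility when available (MD5 through
#' [tools::md5sum()] otherwise). Used to assert that encoder weights are
#' bit-identical before and after predictor training.
#'
#' @param object any serializable R object.
#' @return a checksum string.
#' @export
weight_checksum <- function(object) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  writeBin(serialize(object, NULL, version = 2), tmp)
  sha <- Sys.which("sha256sum")
  if (nzchar(sha)) {
    out <- system2(sha, shQuote(tmp), stdout = TRUE)
    strsplit(out[1], "\\s+")[[1]][1]
  } else {
    unname(tools::md5sum(tmp))
  }
}

# Row-wise log-sum-exp with max subtraction.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_value <- function(...) stop(sprintf(...), call. = FALSE)

# Append one structured record to a JSON-lines training log.
log_epoch <- function(path, record) {
  if (is.null(path)) return(invisible(NULL))
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA), con)
  invisible(NULL)
}
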