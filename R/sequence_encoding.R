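# Protein sequences enter the 1D CNN as integer token vectors of a fixed
# length: the 20 standard residues plus a single unknown symbol X (ambiguity
# and rare codes B, J, O, U, Z collapse onto it), with 0 reserved for padding.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Token alphabet used by the sequence encoder
#'
#' @return character vector of the 21 content tokens (index 1..21; index 0 is
#'   padding). The last entry, `"X"`, absorbs unknown/ambiguous residues.
#' @export
aa_alphabet <- function() AA_ALPHABET

#' Encode a protein sequence as a fixed-length token vector
#'
#' Maps residues to integer tokens over [aa_alphabet()], right-pads with 0 to
#' `L_max`, and truncates to the first `L_max` residues when longer, so the
#' CNN always sees a fixed-length input.
#'
#' @param aa_string non-empty amino-acid string; unknown characters map to the
#'   unknown token.
#' @param L_max fixed encoded length (default 1000).
#' @return an `encoded_sequence`: list with integer `tokens` of length `L_max`
#'   and `original_length`.
#' @export
encode_sequence <- function(aa_string, L_max = 1000L) {
  if (!is.character(aa_string) || length(aa_string) != 1L || is.na(aa_string) ||
      nchar(aa_string) == 0L) {
    stop_value("aa_string must be a single non-empty string")
  }
  L_max <- as.integer(L_max)
  if (L_max < 1L) stop_value("L_max must be >= 1")
  chars <- strsplit(toupper(aa_string), "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  idx[is.na(idx)] <- match("X", AA_ALPHABET)
  n <- length(idx)
  tokens <- integer(L_max)
  keep <- min(n, L_max)
  tokens[seq_len(keep)] <- idx[seq_len(keep)]
  structure(list(tokens = tokens, original_length = n),
            class = "encoded_sequence")
}

#' @export
print.encoded_sequence <- function(x, ...) {
  cat(sprintf("encoded_sequence: L_max=%d, original_length=%d\n",
              length(x$tokens), x$original_length))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file; record ids are taken as sequence ids (text up to
#'   the first whitespace).
#' @return named character vector of amino-acid strings.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop_value("file not found: %s", path)
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) stop_value("duplicate FASTA ids in %s", path)
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs named character vector of amino-acid strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Stack encoded sequences (or raw token vectors) into a B x L integer matrix.
token_matrix <- function(encoded_list) {
  toks <- lapply(encoded_list, function(e) {
    if (inherits(e, "encoded_sequence")) e$tokens else as.integer(e)
  })
  L <- unique(vapply(toks, length, 1L))
  if (length(L) != 1L) stop_value("all encoded sequences must share L_max")
  do.call(rbind, toks)
}
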