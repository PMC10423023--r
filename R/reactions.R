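# Biochemical reactions R <-> E P: a set of reactants transformed into a set
# of products by one or more catalyzing enzyme sequences, optionally annotated
# with an RCLASS (biotransformation pattern) and an EC number. Reaction
# records are the substrate of reaction-feature stratification.

#' Construct a reaction record
#'
#' @param reaction_id identifier.
#' @param reactant_ids,product_ids non-empty character vectors of compound ids.
#' @param enzyme_ids non-empty character vector of sequence ids.
#' @param rclass_id,ec_number optional annotation strings (may be `NA`).
#' @return an object of class `reaction_record`.
#' @export
reaction_record <- function(reaction_id, reactant_ids, product_ids,
                            enzyme_ids, rclass_id = NA_character_,
                            ec_number = NA_character_) {
  reactant_ids <- unique(as.character(reactant_ids))
  product_ids <- unique(as.character(product_ids))
  enzyme_ids <- unique(as.character(enzyme_ids))
  for (side in list(reactant_ids, product_ids, enzyme_ids)) {
    if (!length(side) || any(is.na(side) | !nzchar(side))) {
      stop_value("reaction %s: reactants, products and enzymes must be non-empty",
                 reaction_id)
    }
  }
  structure(
    list(reaction_id = as.character(reaction_id),
         reactant_ids = sort(reactant_ids),
         product_ids = sort(product_ids),
         enzyme_ids = sort(enzyme_ids),
         rclass_id = as.character(rclass_id),
         ec_number = as.character(ec_number)),
    class = "reaction_record")
}

#' @export
print.reaction_record <- function(x, ...) {
  cat(sprintf("reaction %s: %d reactants <-> %d products, %d enzymes (rclass %s, ec %s)\n",
              x$reaction_id, length(x$reactant_ids), length(x$product_ids),
              length(x$enzyme_ids), x$rclass_id, x$ec_number))
  invisible(x)
}

#' Read reaction records from TSV
#'
#' Expects header columns `reaction_id`, `reactants`, `products`, `enzymes`,
#' `rclass`, `ec`; multi-valued fields are `|`-separated. Empty reactant,
#' product or enzyme fields are format errors naming the reaction.
#'
#' @param path tab-separated file.
#' @param compound_ids,sequence_ids optional registries; when given, every
#'   referenced id must resolve.
#' @return list of [reaction_record()] objects.
#' @export
read_reactions <- function(path, compound_ids = NULL, sequence_ids = NULL) {
  if (!file.exists(path)) stop_value("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("reaction_id", "reactants", "products", "enzymes", "rclass", "ec")
  absent <- setdiff(needed, names(df))
  if (length(absent)) {
    stop_value("missing column(s) in %s: %s", path, paste(absent, collapse = ", "))
  }
  split_field <- function(x) {
    parts <- strsplit(x, "|", fixed = TRUE)[[1]]
    parts[nzchar(parts)]
  }
  records <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    reaction_record(row$reaction_id,
                    split_field(row$reactants),
                    split_field(row$products),
                    split_field(row$enzymes),
                    rclass_id = if (nzchar(row$rclass)) row$rclass else NA_character_,
                    ec_number = if (nzchar(row$ec)) row$ec else NA_character_)
  })
  if (!is.null(compound_ids) || !is.null(sequence_ids)) {
    for (rec in records) {
      if (!is.null(compound_ids)) {
        bad <- setdiff(c(rec$reactant_ids, rec$product_ids), compound_ids)
        if (length(bad)) {
          stop_value("reaction %s references unregistered compound(s): %s",
                     rec$reaction_id, paste(bad, collapse = ", "))
        }
      }
      if (!is.null(sequence_ids)) {
        bad <- setdiff(rec$enzyme_ids, sequence_ids)
        if (length(bad)) {
          stop_value("reaction %s references unregistered sequence(s): %s",
                     rec$reaction_id, paste(bad, collapse = ", "))
        }
      }
    }
  }
  records
}

#' Write reaction records to TSV
#'
#' @param reactions list of [reaction_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(reactions, path) {
  join <- function(x) paste(x, collapse = "|")
  df <- data.frame(
    reaction_id = vapply(reactions, `[[`, "", "reaction_id"),
    reactants = vapply(reactions, function(r) join(r$reactant_ids), ""),
    products = vapply(reactions, function(r) join(r$product_ids), ""),
    enzymes = vapply(reactions, function(r) join(r$enzyme_ids), ""),
    rclass = vapply(reactions, function(r) {
      if (is.na(r$rclass_id)) "" else r$rclass_id
    }, ""),
    ec = vapply(reactions, function(r) {
      if (is.na(r$ec_number)) "" else r$ec_number
    }, ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
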