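# Data stratification: partition an interaction dataset into keyed strata of
# congruent views. A compound key pairs the compound with unordered pairs of
# its interacting sequences; a sequence key mirrors that with compound pairs;
# a reaction-feature key (reaction, RCLASS or EC number) yields three view
# lists per stratum: reactant-product pairs, compound-sequence pairs, and
# enzyme pairs. Views under the same key are congruent; views under different
# keys are the non-congruent candidates of the contrastive loss.

new_stratum <- function(kind, key_value, views) {
  structure(list(kind = kind, key_value = key_value, views = views),
            class = "stratum")
}

#' @export
print.stratum <- function(x, ...) {
  nv <- if (x$kind %in% c("compound", "sequence")) {
    nrow(x$views)
  } else {
    sum(vapply(x$views, nrow, 1L))
  }
  cat(sprintf("stratum [%s=%s]: %d view(s)\n", x$kind, x$key_value, nv))
  invisible(x)
}

# All unordered pairs (i <= j under the given sorted order) of ids; a single
# id yields the self-pair, so singleton keys keep their interaction data.
unordered_pairs <- function(ids) {
  ids <- sort(unique(ids))
  n <- length(ids)
  if (n == 1L) {
    return(matrix(c(ids, ids), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  }
  idx <- utils::combn(n, 2L)
  matrix(c(ids[idx[1L, ]], ids[idx[2L, ]]), ncol = 2L,
         dimnames = list(NULL, c("i", "j")))
}

#' Stratify an interaction table by compound
#'
#' One stratum per compound with at least one positive interaction; its views
#' are the unordered distinct pairs of sequences interacting with that
#' compound (`[c, (s_i, s_j)]`). A compound with a single partner `s` yields
#' the self-pair view `(s, s)`.
#'
#' @param table an [interaction_table()].
#' @return list of `stratum` objects (kind `"compound"`), ordered by key.
#' @export
stratify_by_compound <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  pos <- table$positives
  if (!nrow(pos)) return(list())
  by_c <- split(pos$sequence_id, pos$compound_id)
  keys <- sort(names(by_c))
  lapply(keys, function(k) new_stratum("compound", k, unordered_pairs(by_c[[k]])))
}

#' Stratify an interaction table by sequence
#'
#' Mirror image of [stratify_by_compound()]: one stratum per sequence, views
#' are unordered pairs of its interacting compounds (`[s, (c_i, c_j)]`).
#'
#' @param table an [interaction_table()].
#' @return list of `stratum` objects (kind `"sequence"`), ordered by key.
#' @export
stratify_by_sequence <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  pos <- table$positives
  if (!nrow(pos)) return(list())
  by_s <- split(pos$compound_id, pos$sequence_id)
  keys <- sort(names(by_s))
  lapply(keys, function(k) new_stratum("sequence", k, unordered_pairs(by_s[[k]])))
}

dedup_pair_matrix <- function(m) {
  if (!nrow(m)) return(m)
  m[!duplicated(paste(m[, 1L], m[, 2L], sep = "\r")), , drop = FALSE]
}

#' Stratify reaction records by a reaction feature
#'
#' Groups reactions by the requested key (the reaction itself, its RCLASS, or
#' its EC number) and builds, per stratum, three deduplicated view lists
#' pooled over the grouped reactions:
#' * `reactant_product`: every reactant x product pair of each reaction;
#' * `compound_sequence`: every (compound, enzyme) pair with the compound
#'   drawn from reactants union products;
#' * `sequence_pair`: unordered enzyme pairs of each reaction (self-pair when
#'   a reaction has a single enzyme).
#'
#' @param reactions list of [reaction_record()] objects.
#' @param key_kind `"reaction"`, `"rclass"` or `"ec"`.
#' @return list of `stratum` objects whose `views` field is a named list of
#'   the three pair matrices above.
#' @export
stratify_by_reaction_feature <- function(reactions,
                                         key_kind = c("reaction", "rclass", "ec")) {
  key_kind <- match.arg(key_kind)
  if (!length(reactions)) stop_value("reactions must be non-empty")
  keys <- vapply(reactions, function(r) {
    switch(key_kind,
           reaction = r$reaction_id,
           rclass = r$rclass_id,
           ec = r$ec_number)
  }, "")
  missing <- vapply(reactions, function(r) {
    v <- switch(key_kind, reaction = r$reaction_id,
                rclass = r$rclass_id, ec = r$ec_number)
    is.na(v) || !nzchar(v)
  }, TRUE)
  if (any(missing)) {
    stop_value("reaction(s) missing %s value: %s", key_kind,
               paste(vapply(reactions[missing], `[[`, "", "reaction_id"),
                     collapse = ", "))
  }
  groups <- split(reactions, keys)
  lapply(sort(names(groups)), function(k) {
    grp <- groups[[k]]
    v1 <- do.call(rbind, lapply(grp, function(r) {
      as.matrix(expand.grid(i = r$reactant_ids, j = r$product_ids,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
    }))
    v2 <- do.call(rbind, lapply(grp, function(r) {
      as.matrix(expand.grid(i = sort(union(r$reactant_ids, r$product_ids)),
                            j = r$enzyme_ids,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
    }))
    v3 <- do.call(rbind, lapply(grp, function(r) unordered_pairs(r$enzyme_ids)))
    new_stratum(key_kind, k,
                list(reactant_product = dedup_pair_matrix(v1),
                     compound_sequence = dedup_pair_matrix(v2),
                     sequence_pair = dedup_pair_matrix(v3)))
  })
}

# Member-id set of the non-key side of a stratum (sequences for a compound
# key, compounds for a sequence key, all referenced entities for a
# reaction-feature key).
stratum_members <- function(stratum) {
  if (stratum$kind %in% c("compound", "sequence")) {
    unique(as.vector(stratum$views))
  } else {
    unique(unlist(lapply(stratum$views, as.vector), use.names = FALSE))
  }
}

stratum_view_count <- function(stratum) {
  if (stratum$kind %in% c("compound", "sequence")) {
    nrow(stratum$views)
  } else {
    sum(vapply(stratum$views, nrow, 1L))
  }
}

#' Strata overlap statistics
#'
#' Per-stratum sizes plus the mean over all unordered stratum pairs of the
#' shared member count `|A intersect B|` and the Jaccard similarity
#' `|A intersect B| / |A union B|`, where `A`, `B` are the member-id sets of
#' the non-key side. With fewer than two strata the pairwise means are
#' reported as `NA` (undefined), not an error.
#'
#' @param strata list of `stratum` objects of one kind.
#' @return a `strata_stats` list: `n_strata`, per-stratum `member_counts` and
#'   `view_counts`, `mean_shared`, `mean_jaccard`.
#' @export
compute_strata_stats <- function(strata) {
  n <- length(strata)
  members <- lapply(strata, stratum_members)
  member_counts <- vapply(members, length, 1L)
  view_counts <- vapply(strata, stratum_view_count, 1L)
  if (n < 2L) {
    shared <- NA_real_
    jaccard <- NA_real_
  } else {
    pairs <- utils::combn(n, 2L)
    shared_v <- numeric(ncol(pairs))
    jaccard_v <- numeric(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      a <- members[[pairs[1L, p]]]
      b <- members[[pairs[2L, p]]]
      inter <- length(intersect(a, b))
      shared_v[p] <- inter
      jaccard_v[p] <- inter / length(union(a, b))
    }
    shared <- mean(shared_v)
    jaccard <- mean(jaccard_v)
  }
  structure(list(n_strata = n,
                 member_counts = member_counts,
                 view_counts = view_counts,
                 mean_shared = shared,
                 mean_jaccard = jaccard),
            class = "strata_stats")
}

#' @export
print.strata_stats <- function(x, ...) {
  cat(sprintf(
    "strata_stats: %d strata, mean size %.2f, mean views %.2f, mean shared %s, mean Jaccard %s\n",
    x$n_strata, mean(x$member_counts), mean(x$view_counts),
    format(x$mean_shared, digits = 4), format(x$mean_jaccard, digits = 4)))
  invisible(x)
}

#' Serialize strata to a JSON-lines file
#'
#' One stratum per line, for inspection and caching.
#'
#' @param strata list of `stratum` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_strata <- function(strata, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in strata) {
    views <- if (s$kind %in% c("compound", "sequence")) {
      apply(s$views, 1L, function(r) list(r[[1L]], r[[2L]]), simplify = FALSE)
    } else {
      lapply(s$views, function(m) {
        apply(m, 1L, function(r) list(r[[1L]], r[[2L]]), simplify = FALSE)
      })
    }
    writeLines(jsonlite::toJSON(list(kind = s$kind, key = s$key_value,
                                     views = views),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Write strata statistics as TSV
#'
#' @param stats_list named list of `strata_stats` (one row each).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_strata_stats <- function(stats_list, path) {
  df <- do.call(rbind, lapply(names(stats_list), function(nm) {
    s <- stats_list[[nm]]
    data.frame(stratification = nm, n_strata = s$n_strata,
               mean_members = mean(s$member_counts),
               mean_views = mean(s$view_counts),
               mean_shared = s$mean_shared,
               mean_jaccard = s$mean_jaccard)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
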