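# Ranking metrics for interaction prediction: overall average precision and
# R-precision, plus grouped variants (MAP, mean R-precision, MAP@k,
# Precision@1) where candidates are grouped by compound or by sequence and
# group metrics are averaged unweighted over groups holding at least one
# positive. Ties in scores are broken by stable original-order index so every
# reported value is reproducible.

rank_order <- function(scores) {
  # stable descending order: radix sort on (-score, index)
  order(-scores, seq_along(scores), method = "radix")
}

#' Average precision of a ranked list
#'
#' Items are ranked by descending score (ties broken by original order); AP is
#' the mean, over the positive items, of the precision at each positive's
#' rank. With an optional cutoff `k` the ranking is truncated to its top `k`
#' items first and the sum is normalized by `min(R, k)` where `R` is the
#' total number of positives.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric vector, same length.
#' @param k optional integer cutoff.
#' @return AP in `[0, 1]`, or `NA` if there are no positive labels (the group
#'   is skipped, not an error).
#' @export
average_precision <- function(labels, scores, k = NULL) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  R <- sum(labels)
  if (R == 0L) return(NA_real_)
  ord <- rank_order(scores)
  ranked <- labels[ord]
  if (!is.null(k)) {
    k <- as.integer(k)
    stopifnot(k >= 1L)
    ranked <- ranked[seq_len(min(k, length(ranked)))]
    denom <- min(R, k)
  } else {
    denom <- R
  }
  hits <- which(ranked == 1L)
  if (!length(hits)) return(0)
  sum(cumsum(ranked)[hits] / hits) / denom
}

#' R-precision of a ranked list
#'
#' Fraction of the positives found within the top-R ranked items, where R is
#' the number of positives.
#'
#' @inheritParams average_precision
#' @return value in `[0, 1]`, or `NA` with no positives.
#' @export
r_precision <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  R <- sum(labels)
  if (R == 0L) return(NA_real_)
  ord <- rank_order(scores)
  sum(labels[ord][seq_len(R)]) / R
}

precision_at_1 <- function(labels, scores) {
  labels <- as.integer(labels)
  if (sum(labels) == 0L) return(NA_real_)
  as.numeric(labels[rank_order(scores)][1L] == 1L)
}

#' Grouped ranking metrics
#'
#' Computes MAP, mean R-precision, MAP@k and Precision@1 within each group's
#' candidate list, then averages unweighted across the groups that contain at
#' least one positive. Groups without positives are skipped and counted.
#'
#' @param compound_id,sequence_id character vectors identifying each scored
#'   pair.
#' @param labels binary 0/1 vector.
#' @param scores numeric vector.
#' @param group_by `"compound"` or `"sequence"`: which id defines the query
#'   groups (the other side forms the ranked candidates).
#' @param k_cut cutoff for MAP@k (default 3).
#' @return list with `MAP`, `R_precision`, `MAP_at_k`, `Precision_at_1`,
#'   `k_cut`, `n_groups`, `n_skipped`.
#' @export
grouped_metrics <- function(compound_id, sequence_id, labels, scores,
                            group_by = c("compound", "sequence"),
                            k_cut = 3L) {
  group_by <- match.arg(group_by)
  n <- length(labels)
  stopifnot(length(compound_id) == n, length(sequence_id) == n,
            length(scores) == n, k_cut >= 1L)
  if (n == 0L) stop_value("grouped_metrics: empty input")
  key <- if (group_by == "compound") compound_id else sequence_id
  idx_by_group <- split(seq_len(n), key)
  ap <- rp <- apk <- p1 <- numeric(0)
  skipped <- 0L
  for (idx in idx_by_group) {
    l <- labels[idx]
    s <- scores[idx]
    if (sum(l) == 0L) {
      skipped <- skipped + 1L
      next
    }
    ap <- c(ap, average_precision(l, s))
    rp <- c(rp, r_precision(l, s))
    apk <- c(apk, average_precision(l, s, k = k_cut))
    p1 <- c(p1, precision_at_1(l, s))
  }
  if (!length(ap)) stop_value("grouped_metrics: no group contains a positive")
  list(MAP = mean(ap), R_precision = mean(rp), MAP_at_k = mean(apk),
       Precision_at_1 = mean(p1), k_cut = as.integer(k_cut),
       n_groups = length(ap), n_skipped = skipped)
}

#' Full ranking report for a scored pair set
#'
#' Overall AP and R-precision over the whole list, plus [grouped_metrics()]
#' by compound and by sequence.
#'
#' @inheritParams grouped_metrics
#' @return a `ranking_report` list with components `overall`, `by_compound`,
#'   `by_sequence`.
#' @export
ranking_report <- function(compound_id, sequence_id, labels, scores,
                           k_cut = 3L) {
  structure(list(
    overall = list(AP = average_precision(labels, scores),
                   R_precision = r_precision(labels, scores)),
    by_compound = grouped_metrics(compound_id, sequence_id, labels, scores,
                                  "compound", k_cut),
    by_sequence = grouped_metrics(compound_id, sequence_id, labels, scores,
                                  "sequence", k_cut),
    n_pairs = length(labels), n_positive = sum(as.integer(labels))
  ), class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  cat(sprintf("ranking_report over %d pairs (%d positive)\n",
              x$n_pairs, x$n_positive))
  cat(sprintf("  overall: AP %.4f  R-precision %.4f\n",
              x$overall$AP, x$overall$R_precision))
  for (side in c("by_compound", "by_sequence")) {
    g <- x[[side]]
    cat(sprintf("  %s (%d groups, %d skipped): MAP %.4f  R-prec %.4f  MAP@%d %.4f  P@1 %.4f\n",
                side, g$n_groups, g$n_skipped, g$MAP, g$R_precision,
                g$k_cut, g$MAP_at_k, g$Precision_at_1))
  }
  invisible(x)
}

#' Write a ranking report to TSV and/or JSON
#'
#' @param report a [ranking_report()].
#' @param tsv,json optional output paths.
#' @return `report`, invisibly.
#' @export
write_ranking_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(json)) {
    jsonlite::write_json(unclass(report), json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv)) {
    df <- data.frame(
      scope = c("overall", "compound", "sequence"),
      AP_or_MAP = c(report$overall$AP, report$by_compound$MAP,
                    report$by_sequence$MAP),
      R_precision = c(report$overall$R_precision,
                      report$by_compound$R_precision,
                      report$by_sequence$R_precision),
      MAP_at_k = c(NA, report$by_compound$MAP_at_k,
                   report$by_sequence$MAP_at_k),
      Precision_at_1 = c(NA, report$by_compound$Precision_at_1,
                         report$by_sequence$Precision_at_1))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
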