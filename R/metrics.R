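# Occurrence, agreement, and diagnostic metrics, plus cluster-level
# aggregation of per-gene expression coverage.

#' Percentage share with half-away-from-zero rounding
#'
#' `100 * count / total`, rounded half-away-from-zero to `digits` decimal
#' places (the convention used for the reported agreement percentages).
#'
#' @param count numerator count(s).
#' @param total denominator count(s); `NA` is returned where `total` is 0.
#' @param digits decimal places to keep (default 0).
#' @return numeric vector of percentages.
#' @export
percent_share <- function(count, total, digits = 0) {
  p <- 100 * count / total
  f <- 10^digits
  out <- sign(p) * floor(abs(p) * f + 0.5) / f
  out[total == 0] <- NA_real_
  out
}

#' Relative occurrence on the per-million scale
#'
#' The relative occurrence of a protein function is the ratio of the number
#' of proteins carrying a specific KO (`n_select`) to the total number of
#' proteins of the domain (`n_total`), scaled by a constant factor of 1e6
#' for graphical convenience.
#'
#' @param n_select count of proteins with the KO.
#' @param n_total total protein count of the domain (> 0).
#' @return numeric: `n_select / n_total * 1e6`.
#' @export
relative_occurrence <- function(n_select, n_total) {
  if (any(n_total <= 0)) validation_error("n_total must be positive")
  if (any(n_select < 0 | n_select > n_total)) {
    validation_error("n_select must lie in [0, n_total]")
  }
  n_select / n_total * 1e6
}

#' Build an occurrence table
#'
#' @param df data.frame with columns `label`, `ko_id`, `n_select`,
#'   `n_total`.
#' @return the same data.frame with a `relative_occurrence` column added.
#' @export
occurrence_table <- function(df) {
  df$relative_occurrence <- relative_occurrence(df$n_select, df$n_total)
  df
}

#' Diagnostic metrics over correct structure- vs sequence-based annotations
#'
#' With `n_str` and `n_seq` the numbers of correct structure- and
#' sequence-based annotations: sensitivity `= n_str / (n_str + n_seq)`,
#' specificity `= n_seq / (n_seq + n_str)`, positive likelihood ratio
#' `= sensitivity / (1 - specificity)`, negative likelihood ratio
#' `= (1 - sensitivity) / specificity`, exactly as printed. Because
#' specificity is the complement of sensitivity under these formulas, PLR
#' and NLR are identically 1 whenever both counts are positive; the
#' `degenerate` field records this, and undefined ratios (0/0) are returned
#' as `NA` with a flag.
#'
#' @param n_str count of correct structure-based annotations.
#' @param n_seq count of correct sequence-based annotations.
#' @return an object of class `diagnostic_metrics`: list with `n_str`,
#'   `n_seq`, `sensitivity`, `specificity`, `plr`, `nlr`, `flags`,
#'   `degenerate`.
#' @export
diagnostic_metrics <- function(n_str, n_seq) {
  if (length(n_str) != 1 || length(n_seq) != 1 ||
    n_str < 0 || n_seq < 0 || n_str != floor(n_str) || n_seq != floor(n_seq)) {
    validation_error("n_str and n_seq must be single non-negative counts")
  }
  if (n_str + n_seq == 0) {
    validation_error("n_str + n_seq must be positive")
  }
  sens <- n_str / (n_str + n_seq)
  spec <- n_seq / (n_seq + n_str)
  flags <- character(0)
  plr <- if (1 - spec == 0 && sens == 0) {
    flags <- c(flags, "plr_undefined_0_over_0")
    NA_real_
  } else {
    sens / (1 - spec)
  }
  nlr <- if (spec == 0 && 1 - sens == 0) {
    flags <- c(flags, "nlr_undefined_0_over_0")
    NA_real_
  } else {
    (1 - sens) / spec
  }
  structure(
    list(
      n_str = n_str, n_seq = n_seq,
      sensitivity = sens, specificity = spec,
      plr = plr, nlr = nlr, flags = flags,
      # formulas as printed are complementary, so PLR = NLR = 1 whenever
      # both counts are positive
      degenerate = TRUE
    ),
    class = "diagnostic_metrics"
  )
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.4f  specificity %.4f  PLR %s  NLR %s\n",
    x$sensitivity, x$specificity,
    format(x$plr), format(x$nlr)
  ))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  cat("note: printed formulas are complementary (PLR = NLR = 1 when both",
      "counts are positive)\n")
  invisible(x)
}

#' Summarize sequence/structure agreement per group
#'
#' Counts each agreement category per cluster group (`unique` /
#' `homologous`) with integer percentages (half-away-from-zero).
#'
#' @param consensus_table data.frame with columns `group` and `agreement`
#'   (from [annotate_all()]).
#' @return data.frame with columns `group`, `category`, `count`, `total`,
#'   `percent`; groups with zero members yield no rows.
#' @export
agreement_summary <- function(consensus_table) {
  categories <- c(
    "consistent", "disparate", "structure_only", "sequence_only",
    "unannotated"
  )
  groups <- unique(consensus_table$group)
  groups <- groups[!is.na(groups)]
  rows <- lapply(groups, function(g) {
    sub <- consensus_table[consensus_table$group %in% g, , drop = FALSE]
    total <- nrow(sub)
    counts <- vapply(
      categories, function(cat) sum(sub$agreement == cat), integer(1)
    )
    data.frame(
      group = g, category = categories, count = unname(counts),
      total = total, percent = percent_share(unname(counts), total)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-gene coverage to cluster level
#'
#' For each cluster and sample, the mean over the member genes' mean
#' coverage (genes absent from the coverage table are treated as missing,
#' never zero); the overall mean is then the mean over samples. A cluster
#' is flagged `high_expression` when its overall mean reaches the given
#' percentile of all clusters' overall means.
#'
#' @param coverage coverage records (`gene_id`, `sample_id`,
#'   `mean_coverage`).
#' @param membership data.frame mapping `label` (cluster label) to
#'   `gene_id`.
#' @param high_expr_percentile percentile (0-100) defining "relatively
#'   high" expression; default 75.
#' @return list with `per_sample` (data.frame `label`, `sample_id`,
#'   `mean_coverage`) and `summary` (data.frame `label`, `overall_mean`,
#'   `high_expression`); clusters with no covered member genes have
#'   `overall_mean = NA`.
#' @export
cluster_expression <- function(coverage, membership,
                               high_expr_percentile = 75) {
  if (high_expr_percentile < 0 || high_expr_percentile > 100) {
    config_error("high_expr_percentile must lie in [0, 100]")
  }
  merged <- merge(membership, coverage, by = "gene_id")
  per_sample <- if (nrow(merged) > 0) {
    agg <- stats::aggregate(
      mean_coverage ~ label + sample_id,
      data = merged, FUN = mean
    )
    agg[order(agg$label, agg$sample_id), , drop = FALSE]
  } else {
    data.frame(
      label = character(), sample_id = character(),
      mean_coverage = numeric()
    )
  }
  labels <- sort(unique(membership$label))
  overall <- vapply(labels, function(l) {
    v <- per_sample$mean_coverage[per_sample$label == l]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  threshold <- if (all(is.na(overall))) {
    NA_real_
  } else {
    stats::quantile(overall, probs = high_expr_percentile / 100,
      na.rm = TRUE, names = FALSE
    )
  }
  summary <- data.frame(
    label = labels,
    overall_mean = unname(overall),
    high_expression = unname(overall >= threshold)
  )
  rownames(per_sample) <- NULL
  list(per_sample = per_sample, summary = summary)
}
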