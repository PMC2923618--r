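#' Correlate every probe with a sample-level quantifier
#'
#' For each probe, the Pearson and/or Spearman correlation between its
#' expression across samples and a per-sample quantifier (e.g. normalized
#' entropy, or the JS divergence to a group reference). Probes whose
#' expression tracks divergence-from-normal or entropy across a cohort are
#' biomarker candidates. Missing cells are handled pairwise-complete;
#' Spearman uses average ranks for ties. A probe with zero variance over
#' its complete pairs, or fewer than 3 complete pairs, gets `NA`
#' ("undefined", deliberately distinct from uncorrelated) and is skipped
#' by the ranking helpers.
#'
#' @param m an [expr_matrix()].
#' @param q numeric quantifier vector named by sample ID (or aligned to
#'   `sample_ids(m)`), typically a column of a `quantifier_table`.
#' @param method `"pearson"`, `"spearman"` or `"both"` (default).
#' @param quantifier_name label recorded on the table (e.g. `"js_M-Normal"`).
#' @return a `correlation_table`: data.frame with `probe_id`, `pearson`
#'   and/or `spearman`, `n_used`.
#' @export
probe_correlations <- function(m, q, method = c("both", "pearson", "spearman"),
                               quantifier_name = "quantifier") {
  method <- match.arg(method)
  ids <- sample_ids(m)
  if (!is.null(names(q))) {
    if (!setequal(names(q), ids))
      stop("quantifier sample IDs do not match the matrix")
    q <- q[ids]
  } else if (length(q) != length(ids)) {
    stop("quantifier vector length does not match the number of samples")
  }
  v <- m$values
  ok <- !is.na(v) & !is.na(rep(q, each = nrow(v)))
  n_used <- rowSums(matrix(ok, nrow = nrow(v)))
  out <- data.frame(probe_id = rownames(v), stringsAsFactors = FALSE)
  corr_row <- function(meth) {
    r <- suppressWarnings(as.numeric(
      stats::cor(t(v), q, use = "pairwise.complete.obs", method = meth)))
    r[n_used < 3L] <- NA_real_
    r
  }
  if (method %in% c("both", "pearson")) out$pearson <- corr_row("pearson")
  if (method %in% c("both", "spearman")) out$spearman <- corr_row("spearman")
  out$n_used <- n_used
  structure(out, class = c("correlation_table", "data.frame"),
            quantifier_name = quantifier_name)
}

#' @export
print.correlation_table <- function(x, digits = 4, ...) {
  cat(sprintf("correlation_table vs '%s': %d probe(s), %d undefined\n",
              attr(x, "quantifier_name"), nrow(x),
              sum(!stats::complete.cases(as.data.frame(x)))))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = digits,
                   row.names = FALSE)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more probes\n")
  invisible(x)
}

.align_corr <- function(tA, tB, column) {
  for (t in list(tA, tB))
    if (!column %in% names(t)) stop("column '", column, "' absent from a table")
  if (!setequal(tA$probe_id, tB$probe_id))
    stop("the two correlation tables cover different probe sets")
  b <- tB[[column]][match(tA$probe_id, tB$probe_id)]
  data.frame(probe_id = tA$probe_id, corr_a = tA[[column]], corr_b = b,
             stringsAsFactors = FALSE)
}

#' Rank probes by the difference of two correlations
#'
#' Given correlations of each probe with two quantifiers (typically the JS
#' divergences to a "normal" and to a "metastasis" reference), ranks
#' probes by \eqn{\Delta = corr_A - corr_B}: `abs_desc` sorts by
#' \eqn{|\Delta|} descending (largest behavioural change regardless of
#' direction), `signed_desc` by \eqn{\Delta} descending. Ties break by
#' probe ID (stable); probes with an undefined correlation in either table
#' are excluded.
#'
#' @param tA,tB `correlation_table`s over the same probe universe.
#' @param mode `"abs_desc"` or `"signed_desc"`.
#' @param column which correlation column to difference (default
#'   `"spearman"`, falling back to `"pearson"` if absent).
#' @return data.frame `probe_id`, `corr_a`, `corr_b`, `diff`, `rank`,
#'   sorted by the declared key.
#' @export
rank_by_difference <- function(tA, tB, mode = c("abs_desc", "signed_desc"),
                               column = NULL) {
  mode <- match.arg(mode)
  if (is.null(column))
    column <- if ("spearman" %in% names(tA)) "spearman" else "pearson"
  d <- .align_corr(tA, tB, column)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$diff <- d$corr_a - d$corr_b
  key <- if (mode == "abs_desc") abs(d$diff) else d$diff
  d <- d[order(-key, d$probe_id), , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}

#' Flag sign-reversal biomarker candidates
#'
#' A sign-reversal probe correlates with opposite signs against the two
#' quantifiers — e.g. negatively with divergence-from-normal but
#' positively with divergence-from-metastasis — the signature of a marker
#' that switches regime along progression. Probes qualify when the two
#' correlations have strictly opposite signs and both magnitudes reach
#' `threshold`; the result is sorted by \eqn{|\Delta|} descending.
#'
#' @inheritParams rank_by_difference
#' @param threshold minimum magnitude both correlations must reach.
#' @return data.frame `probe_id`, `corr_a`, `corr_b`, `diff`, sorted by
#'   absolute difference descending (possibly zero rows).
#' @export
flag_sign_reversals <- function(tA, tB, threshold = 0.5, column = NULL) {
  if (is.null(column))
    column <- if ("spearman" %in% names(tA)) "spearman" else "pearson"
  d <- .align_corr(tA, tB, column)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  keep <- sign(d$corr_a) * sign(d$corr_b) < 0 &
    pmin(abs(d$corr_a), abs(d$corr_b)) >= threshold
  d <- d[keep, , drop = FALSE]
  d$diff <- d$corr_a - d$corr_b
  d <- d[order(-abs(d$diff), d$probe_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Summarize a probe panel per sample and per group
#'
#' Aggregates a chosen probe set (e.g. a ranked biomarker panel) into one
#' value per sample — the mean or sum of the panel probes' expression —
#' and then averages those per group: the numeric content of a group
#' heat-map / stacked-expression panel.
#'
#' @param m an [expr_matrix()].
#' @param probes probe IDs forming the panel.
#' @param ann annotation data.frame mapping samples to groups.
#' @param stat `"mean"` or `"sum"` across the panel probes.
#' @return list with `per_sample` (sample_id, group, value; ordered by
#'   group then value) and `per_group` (group, mean of per-sample values).
#' @export
group_panel <- function(m, probes, ann, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  unknown <- setdiff(probes, probe_ids(m))
  if (length(unknown))
    stop("unknown probe ID(s): ", paste(unknown, collapse = ", "))
  v <- m$values[probes, , drop = FALSE]
  val <- if (stat == "mean") colMeans(v, na.rm = TRUE) else colSums(v, na.rm = TRUE)
  grp <- ann$group[match(sample_ids(m), ann$sample_id)]
  per_sample <- data.frame(sample_id = sample_ids(m), group = grp, value = val,
                           row.names = NULL, stringsAsFactors = FALSE)
  per_sample <- per_sample[order(per_sample$group, per_sample$value), ]
  rownames(per_sample) <- NULL
  agg <- tapply(per_sample$value, per_sample$group, mean)
  per_group <- data.frame(group = names(agg), value = as.numeric(agg),
                          stringsAsFactors = FALSE)
  list(per_sample = per_sample, per_group = per_group)
}
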