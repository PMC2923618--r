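#' Impute missing expression values
#'
#' Replaces every missing cell so the matrix is usable by the quantifiers,
#' which require a complete probability profile per sample. `probe_mean`
#' fills a cell with the mean of the probe's observed values across samples
#' (the default conditioning choice for datasets with sporadic missing
#' spots); `sample_mean` uses the sample column's observed mean; `constant`
#' fills with a fixed value `c`.
#'
#' Probes with every cell missing cannot be imputed by `probe_mean` and are
#' dropped with a warning.
#'
#' @param m an [expr_matrix()].
#' @param method `"probe_mean"`, `"sample_mean"` or `"constant"`.
#' @param c fill value for `method = "constant"`.
#' @return the imputed `expr_matrix`; attributes `n_imputed` (cells filled)
#'   and `dropped_probes` (IDs removed under `probe_mean`) carry the report.
#' @export
impute_missing <- function(m, method = c("probe_mean", "sample_mean", "constant"),
                           c = 0) {
  method <- match.arg(method)
  v <- m$values
  miss <- is.na(v)
  dropped <- character(0)
  if (method == "probe_mean") {
    all_miss <- rowSums(!miss) == 0L
    if (any(all_miss)) {
      dropped <- rownames(v)[all_miss]
      warning("dropping ", length(dropped),
              " probe(s) with no observed values: ",
              paste(utils::head(dropped, 5), collapse = ", "))
      v <- v[!all_miss, , drop = FALSE]
      miss <- miss[!all_miss, , drop = FALSE]
      if (!is.null(m$probe_meta)) m$probe_meta <- m$probe_meta[!all_miss, , drop = FALSE]
    }
    fill <- rowMeans(v, na.rm = TRUE)[row(v)[miss]]
  } else if (method == "sample_mean") {
    if (any(colSums(!miss) == 0L)) stop("sample with no observed values")
    fill <- colMeans(v, na.rm = TRUE)[col(v)[miss]]
  } else {
    fill <- c
  }
  v[miss] <- fill
  out <- expr_matrix(v, value_scale = m$value_scale, probe_meta = m$probe_meta)
  attr(out, "n_imputed") <- sum(miss)
  attr(out, "dropped_probes") <- dropped
  out
}

#' Drop probes that have any missing value
#'
#' The alternative conditioning route to imputation: probes with one or
#' more missing cells are removed entirely, leaving a complete matrix.
#' Surviving probes keep their original order.
#'
#' @param m an [expr_matrix()].
#' @return list with `matrix` (the filtered `expr_matrix`) and `removed`
#'   (character vector of dropped probe IDs).
#' @export
drop_missing_probes <- function(m) {
  bad <- rowSums(is.na(m$values)) > 0L
  if (all(bad)) stop("every probe has a missing value; nothing would remain")
  meta <- if (is.null(m$probe_meta)) NULL else m$probe_meta[!bad, , drop = FALSE]
  list(matrix = expr_matrix(m$values[!bad, , drop = FALSE],
                            value_scale = m$value_scale, probe_meta = meta),
       removed = rownames(m$values)[bad])
}

#' Remove spike probes
#'
#' A spike probe carries an anomalously high value in only a few samples —
#' a hybridization artifact, not biology — and distorts probability
#' profiles. A probe is removed when between 1 and `support_k` samples
#' exceed `dominance_r` times the probe's median absolute value, all other
#' samples sitting inside that median-scale band. The rule is evaluated
#' per probe, so the filter is idempotent. Defaults (`support_k = 1`,
#' `dominance_r = 10`) are a working operationalization, not a canonical
#' published criterion.
#'
#' @param m an [expr_matrix()] (missing cells are ignored in the rule).
#' @param support_k maximum number of dominating samples (>= 1).
#' @param dominance_r dominance ratio over the probe's median scale (> 1).
#' @return list with `matrix` (filtered `expr_matrix`), `removed` (probe
#'   IDs) and `triggers` (named list: removed probe -> offending sample IDs).
#' @export
spike_filter <- function(m, support_k = 1L, dominance_r = 10) {
  stopifnot(support_k >= 1L, dominance_r > 1)
  v <- abs(m$values)
  med <- apply(v, 1L, stats::median, na.rm = TRUE)
  over <- v > dominance_r * med
  over[is.na(over)] <- FALSE
  n_over <- rowSums(over)
  hit <- n_over >= 1L & n_over <= support_k
  triggers <- lapply(which(hit), function(i) colnames(v)[over[i, ]])
  names(triggers) <- rownames(v)[hit]
  meta <- if (is.null(m$probe_meta)) NULL else m$probe_meta[!hit, , drop = FALSE]
  list(matrix = expr_matrix(m$values[!hit, , drop = FALSE],
                            value_scale = m$value_scale, probe_meta = meta),
       removed = rownames(v)[hit], triggers = triggers)
}

#' Exclude annotated samples
#'
#' Removes the columns of samples flagged `exclude = TRUE` in the
#' annotation. Exclusion is always analyst-driven via the annotation —
#' never automatic — because outlier calls are a judgment about the
#' experiment, not a property of the numbers alone.
#'
#' @param m an [expr_matrix()].
#' @param ann annotation data.frame from [read_sample_annotation()].
#' @return the `expr_matrix` without the excluded columns.
#' @export
exclude_samples <- function(m, ann) {
  ex <- ann$sample_id[ann$exclude]
  if (length(ex) == 0) return(m)
  unknown <- setdiff(ex, sample_ids(m))
  if (length(unknown))
    stop("excluded sample(s) not in matrix: ", paste(unknown, collapse = ", "))
  keep <- !(sample_ids(m) %in% ex)
  if (!any(keep)) stop("exclusion removes every sample")
  expr_matrix(m$values[, keep, drop = FALSE],
              value_scale = m$value_scale, probe_meta = m$probe_meta)
}
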