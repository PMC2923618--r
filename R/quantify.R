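#' Compute per-sample information-theoretic quantifiers
#'
#' The central computation: every sample column of a complete expression
#' matrix is turned into a probability profile over its N probes, and for
#' each the table records Shannon entropy `S` (nats), normalized entropy
#' `H`, MPR complexity `C_MPR`, and — for every supplied reference — the
#' Jensen-Shannon divergence `js_<name>` and M complexity `C_M_<name>`.
#' The (H, C_MPR) columns are the coordinates of the complexity-entropy
#' plane; any pair of `C_M_*` columns gives an M-complexity plane.
#'
#' @param m an [expr_matrix()] with no missing values (run the
#'   preprocessing steps first).
#' @param transform profile transform (see [transform_expression()]);
#'   default `exp2` for `value_scale = "log_ratio"`, else `identity_clip`.
#' @param refs list of [reference_profile()] objects (may be empty).
#' @param ann optional annotation data.frame; adds a `group` column.
#' @param eps positivity floor passed to [build_profile()].
#' @return a `quantifier_table`: a data.frame with one row per sample and
#'   attributes `n_probes`, `transform` and `references`.
#' @examples
#' qt <- quantify_samples(worked_example())
#' round(qt$H, 2)   # 0.82 0.82 0.92 1.00
#' @export
quantify_samples <- function(m, transform = NULL, refs = list(), ann = NULL,
                             eps = 1e-12) {
  if (anyNA(m$values)) stop("matrix has missing values; preprocess first")
  if (is.null(transform)) transform <- .default_transform(m$value_scale)
  if (inherits(refs, "reference_profile")) refs <- list(refs)
  N <- nrow(m$values)
  ids <- sample_ids(m)
  P <- vapply(ids, function(s) build_profile(m$values[, s], transform, eps),
              numeric(N))
  S <- apply(P, 2L, shannon_entropy)
  H <- S / log(N)
  pe <- uniform_profile(N)
  js_e <- apply(P, 2L, jensen_shannon, p2 = pe)
  out <- data.frame(sample_id = ids, S = S, H = H,
                    C_MPR = q0(pe) * js_e * H,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(ann))
    out$group <- ann$group[match(ids, ann$sample_id)]
  ref_info <- list()
  for (ref in refs) {
    if (!inherits(ref, "reference_profile")) stop("refs must be reference_profile objects")
    if (length(ref$p) != N)
      stop("reference '", ref$name, "' was built on a different probe set (N = ",
           length(ref$p), ", matrix has ", N, ")")
    js <- apply(P, 2L, jensen_shannon, p2 = ref$p)
    out[[paste0("js_", ref$name)]] <- js
    out[[paste0("C_M_", ref$name)]] <- q0(ref$p) * js * H
    ref_info[[ref$name]] <- ref$mode
  }
  structure(out, class = c("quantifier_table", "data.frame"),
            n_probes = N, transform = transform, references = ref_info)
}

#' @export
print.quantifier_table <- function(x, digits = 4, ...) {
  cat(sprintf("quantifier_table: %d sample(s) over %d probes (transform: %s)\n",
              nrow(x), attr(x, "n_probes"), attr(x, "transform")))
  refs <- attr(x, "references")
  if (length(refs))
    cat("  references:", paste(sprintf("%s [%s]", names(refs), unlist(refs)),
                               collapse = ", "), "\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.quantifier_table <- function(object, ...) {
  num <- vapply(object, is.numeric, TRUE)
  stats <- t(vapply(object[num], function(v)
    c(min = min(v), mean = mean(v), max = max(v)), numeric(3)))
  if (!is.null(object$group)) {
    byg <- tapply(object$H, object$group, mean)
    cat("Mean H by group (descending = closer to uniform/disordered):\n")
    print(round(sort(byg, decreasing = TRUE), 4))
    cat("\n")
  }
  cat("Quantifier ranges:\n")
  print(round(stats, 4))
  invisible(stats)
}

#' Plot a complexity-entropy plane
#'
#' Scatters samples by two quantifier columns, by default normalized
#' entropy (x) against MPR complexity (y) — the complexity-entropy plane
#' on which sample groups at different progression stages separate.
#'
#' @param x a `quantifier_table`.
#' @param x_col,y_col column names to plot.
#' @param col point colours; defaults to group if present.
#' @param ... passed to [graphics::plot()].
#' @export
plot.quantifier_table <- function(x, x_col = "H", y_col = "C_MPR", col = NULL, ...) {
  stopifnot(x_col %in% names(x), y_col %in% names(x))
  if (is.null(col))
    col <- if (is.null(x$group)) "black" else as.integer(factor(x$group))
  graphics::plot(x[[x_col]], x[[y_col]], xlab = x_col, ylab = y_col,
                 col = col, pch = 19, ...)
  if (!is.null(x$group))
    graphics::legend("topleft", legend = levels(factor(x$group)),
                     col = seq_along(levels(factor(x$group))), pch = 19, bty = "n")
  invisible(x)
}

#' Extract plane coordinates from a quantifier table
#'
#' @param qt a `quantifier_table`.
#' @param x_col,y_col quantifier column names (e.g. `"H"`, `"C_MPR"`, or
#'   two `C_M_*` columns for an M-complexity plane).
#' @return data.frame `sample_id` (+ `group` if present), `x`, `y`.
#' @export
plane_coordinates <- function(qt, x_col = "H", y_col = "C_MPR") {
  miss <- setdiff(c(x_col, y_col), names(qt))
  if (length(miss)) stop("unknown quantifier column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(sample_id = qt$sample_id, stringsAsFactors = FALSE)
  if (!is.null(qt$group)) out$group <- qt$group
  out$x <- qt[[x_col]]; out$y <- qt[[y_col]]
  names(out)[names(out) == "x"] <- x_col
  names(out)[names(out) == "y"] <- y_col
  out
}
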