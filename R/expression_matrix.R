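#' txentropy: information-theoretic quantifiers for transcriptome profiles
#'
#' Each sample of a probe-by-sample expression matrix is turned into a
#' discrete probability profile over its N probes; the package computes the
#' normalized Shannon entropy of that profile, its Jensen-Shannon divergence
#' to configurable reference profiles (the uniform distribution or the
#' average profile of a sample group), and the derived MPR- and M-statistical
#' complexities, which place samples on complexity-entropy planes. Around the
#' quantifiers it provides the conditioning steps such analyses need
#' (imputation, missing-probe removal, spike filtering, sample exclusion),
#' probe-vs-quantifier correlation rankings for biomarker discovery, a
#' seeded synthetic-matrix generator with planted ground truth, and an
#' end-to-end configurable pipeline.
#'
#' @keywords internal
"_PACKAGE"

# Tokens that parse as a missing cell; any other non-numeric token is a
# hard error (silent coercion hides data corruption).
.missing_tokens <- c("", "NA", "NaN", "null")

#' Construct an expression matrix object
#'
#' An `expr_matrix` holds a probes-by-samples numeric matrix. Missing cells
#' are stored as `NA`; the missing mask is therefore `is.na(values(m))`.
#'
#' @param values numeric matrix, probes in rows, samples in columns, with
#'   `rownames` (probe IDs) and `colnames` (sample IDs).
#' @param value_scale one of `"intensity"`, `"log_ratio"`, `"unknown"`;
#'   used to pick the default profile transform.
#' @param probe_meta optional data.frame of leading annotation columns
#'   (one row per probe); carried opaquely, never used in computation.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, value_scale = c("unknown", "intensity", "log_ratio"),
                        probe_meta = NULL) {
  value_scale <- match.arg(value_scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probe IDs as rownames and sample IDs as colnames")
  pid <- trimws(rownames(values))
  if (anyDuplicated(pid))
    stop("duplicate probe IDs: ", paste(unique(pid[duplicated(pid)]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  rownames(values) <- pid
  if (!is.null(probe_meta) && nrow(probe_meta) != nrow(values))
    stop("probe_meta must have one row per probe")
  structure(list(values = values, value_scale = value_scale,
                 probe_meta = probe_meta),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Probe and sample identifiers of an expression matrix
#' @param m an `expr_matrix`.
#' @return character vector of IDs.
#' @export
probe_ids <- function(m) rownames(m$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' @export
print.expr_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("expr_matrix: %d probes x %d samples (scale: %s, %d missing cells)\n",
              d[1], d[2], x$value_scale, sum(is.na(x$values))))
  if (!is.null(x$probe_meta))
    cat("  probe metadata columns:", paste(names(x$probe_meta), collapse = ", "), "\n")
  invisible(x)
}

.parse_cells <- function(tokens) {
  tokens <- trimws(tokens)
  out <- rep(NA_real_, length(tokens))
  miss <- tokens %in% .missing_tokens
  suppressWarnings(num <- as.numeric(tokens[!miss]))
  if (anyNA(num)) {
    bad <- tokens[!miss][is.na(num)]
    stop("non-numeric cell value(s): ", paste(utils::head(unique(bad), 5), collapse = ", "))
  }
  out[!miss] <- num
  out
}

#' Read a tab-delimited expression matrix
#'
#' Two dialects are supported. `plain`: one leading probe-ID column, then
#' one column per sample. `annotated_cluster`: several leading annotation
#' columns (e.g. CLID, NAME) of which `id_column` names the probe-ID column;
#' the remaining leading columns are kept as opaque probe metadata. Cells
#' equal to one of `""`, `"NA"`, `"NaN"`, `"null"` become missing; any other
#' non-numeric cell is an error. Parsing uses the decimal point regardless
#' of locale.
#'
#' @param path path to a tab-delimited file with a header row of sample IDs.
#' @param dialect `"plain"` or `"annotated_cluster"`.
#' @param id_column for `annotated_cluster`, the header name of the probe-ID
#'   column among the leading annotation columns.
#' @param n_annot for `annotated_cluster`, the number of leading annotation
#'   columns (default 2, as in Stanford-style clustered files).
#' @param value_scale declared scale of the values (see [expr_matrix()]).
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(path, dialect = c("plain", "annotated_cluster"),
                                   id_column = NULL, n_annot = 2L,
                                   value_scale = c("unknown", "intensity", "log_ratio")) {
  dialect <- match.arg(dialect)
  value_scale <- match.arg(value_scale)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("file has no data rows: ", path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(rows[[1]])
  nc <- length(header)
  widths <- lengths(rows[-1])
  # trailing empty cells are dropped by strsplit; pad those, flag the rest
  if (any(widths > nc | widths < 1))
    stop("ragged row at line ", which(widths > nc | widths < 1)[1] + 1L)
  body <- lapply(rows[-1], function(r) c(r, rep("", nc - length(r))))
  n_lead <- if (dialect == "plain") 1L else as.integer(n_annot)
  if (nc <= n_lead) stop("no sample columns found")
  if (dialect == "plain") {
    id_idx <- 1L
  } else {
    if (is.null(id_column)) stop("annotated_cluster dialect requires 'id_column'")
    id_idx <- match(id_column, header[seq_len(n_lead)])
    if (is.na(id_idx)) stop("id_column '", id_column, "' not among leading columns")
  }
  ids <- vapply(body, `[`, "", id_idx)
  samples <- header[(n_lead + 1L):nc]
  vals <- matrix(NA_real_, nrow = length(body), ncol = nc - n_lead,
                 dimnames = list(trimws(ids), samples))
  for (j in seq_len(ncol(vals)))
    vals[, j] <- .parse_cells(vapply(body, `[`, "", n_lead + j))
  meta <- NULL
  if (dialect == "annotated_cluster" && n_lead > 1L) {
    keep <- setdiff(seq_len(n_lead), id_idx)
    meta <- as.data.frame(lapply(keep, function(k) vapply(body, `[`, "", k)),
                          col.names = header[keep], stringsAsFactors = FALSE)
  }
  expr_matrix(vals, value_scale = value_scale, probe_meta = meta)
}

#' Read a sample annotation table
#'
#' Expects a tab-delimited file with header columns `sample_id`, `group`
#' and optionally `exclude` (logical-like: TRUE/FALSE, 1/0, yes/no).
#' Samples absent from any given matrix are allowed; matching is by ID.
#'
#' @param path path to the annotation TSV.
#' @return data.frame with columns `sample_id`, `group`, `exclude`.
#' @export
read_sample_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  if (any(!nzchar(ann$group))) stop("empty group labels in annotation")
  if (is.null(ann$exclude)) {
    ann$exclude <- FALSE
  } else {
    ann$exclude <- tolower(trimws(as.character(ann$exclude))) %in% c("true", "1", "yes")
  }
  ann[, c("sample_id", "group", "exclude")]
}

#' Write a result table as TSV
#'
#' Serializes quantifier or correlation tables (any data.frame) with a
#' header row, preserving row order, at full double precision so that a
#' write/read round trip reproduces values to better than 1e-9.
#'
#' @param table a non-empty data.frame (e.g. a `quantifier_table` or
#'   `correlation_table`).
#' @param path output file path.
#' @export
write_result_table <- function(table, path) {
  table <- as.data.frame(table)
  if (nrow(table) == 0) stop("refusing to write an empty table")
  num <- vapply(table, is.numeric, TRUE)
  table[num] <- lapply(table[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV (plain dialect)
#'
#' @param m an `expr_matrix`; missing cells are written as `NA`.
#' @param path output file path.
#' @export
write_expression_matrix <- function(m, path) {
  chr <- format(m$values, digits = 15, trim = TRUE)
  chr[is.na(m$values)] <- "NA"
  df <- data.frame(probe_id = probe_ids(m), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the bundled worked-example matrix
#'
#' A 5-probe by 4-sample intensity matrix in which sample 4 is uniform,
#' samples 1 and 2 are reverses of each other, and sample 3 is moderately
#' peaked; used throughout the documentation and tests.
#'
#' @return an `expr_matrix` with `value_scale = "intensity"`.
#' @export
worked_example <- function() {
  read_expression_matrix(system.file("extdata", "worked_example.tsv",
                                     package = "txentropy", mustWork = TRUE),
                         dialect = "plain", value_scale = "intensity")
}
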