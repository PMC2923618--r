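#' Run the full preprocess -> quantify -> rank pipeline
#'
#' Executes the per-dataset workflow from one declarative configuration:
#' read the matrix and annotation, condition the matrix (imputation or
#' missing-probe removal, optional spike filter, annotated sample
#' exclusion), build the requested group reference profiles, compute the
#' quantifier table, correlate every probe with the requested quantifier
#' columns, and export plane coordinate tables. All outputs are written
#' to `out_dir` together with a `metadata.json` recording every parameter,
#' filter count and input checksum, so each table is traceable to its
#' configuration. On any stage failure the partial outputs are removed.
#'
#' @param config a list, or path to a YAML/JSON file, with entries:
#'   `matrix` (path), `annotation` (path, optional), `dialect`,
#'   `id_column`, `value_scale`, `transform`, `preprocess` (sub-list:
#'   `impute` method or `NULL`, `drop_missing`, `spike_k`, `spike_r`,
#'   `exclude`), `references` (list of `(group, mode)`), `rank`
#'   (sub-list: `quantifiers` — column names or `"all"` —, `method`),
#'   `planes` (list of column-name pairs), `out_dir`, `seed`.
#' @return invisibly, a named list of the files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- list(dialect = "plain", id_column = NULL, value_scale = "unknown",
              transform = NULL, preprocess = list(), references = list(),
              rank = list(), planes = list(list("H", "C_MPR")),
              out_dir = ".", seed = 1L)
  cfg[names(config)] <- config
  if (is.null(cfg$matrix)) stop("config must name a 'matrix' file")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- "setup"
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    set.seed(as.integer(cfg$seed))
    stage <- "read"
    m <- read_expression_matrix(cfg$matrix, dialect = cfg$dialect,
                                id_column = cfg$id_column,
                                value_scale = cfg$value_scale)
    ann <- if (!is.null(cfg$annotation)) read_sample_annotation(cfg$annotation)
    meta <- list(package = "txentropy",
                 version = as.character(utils::packageVersion("txentropy")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 seed = cfg$seed,
                 inputs = as.list(tools::md5sum(c(cfg$matrix, cfg$annotation))),
                 config = cfg[setdiff(names(cfg), "out_dir")],
                 filters = list())

    stage <- "preprocess"
    pp <- cfg$preprocess
    if (isTRUE(pp$exclude) && !is.null(ann)) {
      n0 <- ncol(m$values)
      m <- exclude_samples(m, ann)
      meta$filters$samples_excluded <- n0 - ncol(m$values)
    }
    if (!is.null(pp$spike_k)) {
      sf <- spike_filter(m, support_k = pp$spike_k,
                         dominance_r = if (is.null(pp$spike_r)) 10 else pp$spike_r)
      m <- sf$matrix
      meta$filters$spike_probes_removed <- length(sf$removed)
      meta$filters$spike_probe_ids <- sf$removed
    }
    if (isTRUE(pp$drop_missing)) {
      dm <- drop_missing_probes(m)
      m <- dm$matrix
      meta$filters$missing_probes_removed <- length(dm$removed)
    }
    if (!is.null(pp$impute)) {
      m <- impute_missing(m, method = pp$impute,
                          c = if (is.null(pp$impute_constant)) 0 else pp$impute_constant)
      meta$filters$cells_imputed <- attr(m, "n_imputed")
      meta$filters$unimputable_probes <- attr(m, "dropped_probes")
    }

    stage <- "references"
    transform <- if (is.null(cfg$transform)) .default_transform(m$value_scale)
                 else cfg$transform
    refs <- lapply(cfg$references, function(r) {
      if (is.null(ann)) stop("references need an annotation file")
      reference_profile(m, ann, group = r$group,
                        mode = if (is.null(r$mode)) "mean_of_pdfs" else r$mode,
                        transform = transform,
                        name = if (is.null(r$name)) NULL else r$name)
    })
    meta$transform <- transform

    stage <- "quantify"
    qt <- quantify_samples(m, transform = transform, refs = refs, ann = ann)
    f <- file.path(cfg$out_dir, "quant.tsv")
    write_result_table(qt, f); written <- c(written, f)

    stage <- "rank"
    qcols <- cfg$rank$quantifiers
    if (identical(qcols, "all"))
      qcols <- setdiff(names(qt)[vapply(qt, is.numeric, TRUE)], "S")
    for (qc in qcols) {
      if (!qc %in% names(qt)) stop("unknown quantifier column '", qc, "'")
      ct <- probe_correlations(
        m, stats::setNames(qt[[qc]], qt$sample_id),
        method = if (is.null(cfg$rank$method)) "both" else cfg$rank$method,
        quantifier_name = qc)
      f <- file.path(cfg$out_dir, paste0("corr_", gsub("[^A-Za-z0-9._-]", "_", qc), ".tsv"))
      write_result_table(ct, f); written <- c(written, f)
    }

    stage <- "planes"
    for (pl in cfg$planes) {
      pl <- unlist(pl)
      pc <- plane_coordinates(qt, pl[1], pl[2])
      f <- file.path(cfg$out_dir, sprintf("plane_%s_%s.tsv",
                                          gsub("[^A-Za-z0-9._-]", "_", pl[1]),
                                          gsub("[^A-Za-z0-9._-]", "_", pl[2])))
      write_result_table(pc, f); written <- c(written, f)
    }

    stage <- "metadata"
    f <- file.path(cfg$out_dir, "metadata.json")
    jsonlite::write_json(meta, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    written <- c(written, f)
  }, error = on_fail)
  invisible(stats::setNames(as.list(written), basename(written)))
}

#' Write a simulated study to disk
#'
#' Emits the three files a pipeline run consumes and checks against:
#' `matrix.tsv`, `annotation.tsv` and `truth.json`.
#'
#' @param spec a [synthetic_spec()].
#' @param out_prefix directory to write into (created if needed).
#' @param seed integer seed forwarded to [simulate_expression()].
#' @return invisibly, the simulation list (see [simulate_expression()]).
#' @export
write_simulation <- function(spec, out_prefix, seed = 1L) {
  sim <- simulate_expression(spec, seed = seed)
  dir.create(out_prefix, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(sim$matrix, file.path(out_prefix, "matrix.tsv"))
  write_result_table(sim$annotation, file.path(out_prefix, "annotation.tsv"))
  jsonlite::write_json(sim$truth, file.path(out_prefix, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(sim)
}
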