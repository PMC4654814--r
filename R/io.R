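#' Construct a peak table
#'
#' A peak table holds the raw per-sample, per-probe signal of one assay run:
#' fluorescence peak heights for the capillary-electrophoresis MLPA readout,
#' or molecule counts for the hybridization-count confirmation assay.
#'
#' @param values numeric matrix, samples in rows (rownames are sample ids),
#'   probes in columns (colnames are probe ids); all values must be >= 0.
#' @param assay `"mlpa"` or `"count"`.
#' @param run_id batch label for the run.
#' @return a `peak_table` object.
#' @export
peak_table <- function(values, assay = c("mlpa", "count"), run_id = "run1") {
  assay <- match.arg(assay)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("peak table values must carry sample rownames and probe colnames")
  }
  if (!is.numeric(values)) stop("format error: peak values must be numeric")
  if (anyNA(values)) stop("format error: peak values must not be missing")
  if (any(values < 0)) stop("format error: negative peak value")
  structure(list(values = values, assay = assay, run_id = run_id),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> assay=%s run=%s: %d samples x %d probes\n",
              x$assay, x$run_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a peak table from CSV
#'
#' The first column must be `sample_id`; the remaining columns are probe ids.
#' When a manifest is supplied every probe column must appear in it.
#'
#' @param path CSV path.
#' @param assay `"mlpa"` or `"count"`.
#' @param manifest optional `probe_manifest` to reconcile probe ids against.
#' @param run_id batch label (defaults to the file name without extension).
#' @return a `peak_table`.
#' @export
read_peak_table <- function(path, assay = c("mlpa", "count"), manifest = NULL,
                            run_id = NULL) {
  assay <- match.arg(assay)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") stop("format error: first column must be sample_id")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df$sample_id)
  if (!is.null(manifest)) {
    unknown <- setdiff(colnames(values), manifest$probe_id)
    if (length(unknown) > 0) {
      stop("reconciliation error: probes absent from manifest: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (is.null(run_id)) run_id <- sub("\\.[^.]*$", "", basename(path))
  peak_table(values, assay = assay, run_id = run_id)
}

#' Write a peak table to CSV
#'
#' Inverse of [read_peak_table()]; the round trip is the identity on the
#' numeric values to full printed precision.
#'
#' @param peaks a `peak_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_table"))
  df <- data.frame(sample_id = rownames(peaks$values),
                   peaks$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a samples-by-columns numeric matrix from CSV
#'
#' Generic reader for ratio matrices, expression matrices and other tables
#' whose first column is `sample_id` and whose remaining columns are numeric.
#'
#' @param path CSV path.
#' @return numeric matrix with sample rownames.
#' @export
read_sample_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") stop("format error: first column must be sample_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$sample_id)
  m
}

#' Write a samples-by-columns numeric matrix to CSV
#'
#' @param m numeric matrix with sample rownames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort sample sheet from CSV
#'
#' Columns: `sample_id`, `hiv_positive` (TRUE/FALSE), `hdl`, `ldl`, `tchol`,
#' `trig` (mg/dL), `therapy`, `adherence`, `ancestry`. An empty `ldl` field
#' means LDL was not measured for that participant.
#'
#' @param path CSV path.
#' @return data frame of sample records.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  for (col in c("hdl", "tchol", "trig")) {
    if (any(!is.na(df[[col]]) & df[[col]] <= 0)) {
      stop("format error: nonpositive ", col)
    }
  }
  if (any(!is.na(df$ldl) & df$ldl <= 0)) stop("format error: nonpositive ldl")
  df
}

#' Write a cohort sample sheet to CSV
#'
#' @param records sample-sheet data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the copy-number call report
#'
#' Emits a TSV of per-(sample, gene) calls with ratios formatted to two
#' decimal places, and a JSON summary with the per-status call counts and
#' the cross-platform confirmation summary. Output is deterministic: the
#' call table is sorted by sample then gene, so identical inputs produce
#' byte-identical files.
#'
#' @param calls data frame of copy calls (from [call_matrix()]).
#' @param summary confirmation summary (from [confirmation_summary()]), or
#'   `NULL` when no orthogonal platform was run.
#' @param dir output directory, created if needed.
#' @param prefix file-name prefix for the `calls.tsv` / `summary.json` pair.
#' @return named character vector with the paths written, invisibly.
#' @export
write_call_report <- function(calls, summary = NULL, dir = ".",
                              prefix = "cnv") {
  if (is.null(calls) || nrow(calls) == 0) stop("report error: empty call list")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  calls <- calls[order(calls$sample_id, calls$gene), , drop = FALSE]
  out <- calls
  out$ratio <- sprintf("%.2f", calls$ratio)
  if ("sd" %in% names(out)) {
    out$sd <- ifelse(is.na(calls$sd), "", sprintf("%.3f", calls$sd))
  }
  tsv_path <- file.path(dir, paste0(prefix, "_calls.tsv"))
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  status_counts <- as.list(table(factor(
    calls$status,
    levels = c("normal", "loss", "borderline_loss", "gain", "borderline_gain"))))
  report <- list(
    n_calls = nrow(calls),
    n_samples = length(unique(calls$sample_id)),
    n_genes = length(unique(calls$gene)),
    status_counts = status_counts,
    flagged_samples = sort(unique(calls$sample_id[is_flagged(calls$status)])),
    flagged_genes = sort(unique(calls$gene[is_flagged(calls$status)]))
  )
  if (!is.null(summary)) report$confirmation <- summary
  json_path <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(calls = tsv_path, summary = json_path))
}

#' Read a pipeline configuration file
#'
#' The configuration is plain YAML with two optional top-level blocks,
#' `simulation` and `thresholds`, whose keys mirror the arguments of
#' [simulation_config()] and [cnv_thresholds()]. Absent keys take the
#' package defaults.
#'
#' @param path YAML file path.
#' @return list with elements `simulation` (a `simulation_config`) and
#'   `thresholds` (a `cnv_thresholds`).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  sim <- do.call(simulation_config, as.list(raw$simulation))
  thr <- do.call(cnv_thresholds, as.list(raw$thresholds))
  list(simulation = sim, thresholds = thr)
}

#' Echo a configuration to YAML
#'
#' @param config list as returned by [read_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  strip <- function(x) { attributes(x) <- list(names = names(x)); x }
  yaml::write_yaml(list(simulation = strip(config$simulation),
                        thresholds = strip(config$thresholds)), path)
  invisible(path)
}
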