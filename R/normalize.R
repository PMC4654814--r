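#' Intra-sample normalization against the reference probes
#'
#' Divides every probe's signal in a sample by the geometric mean of that
#' sample's reference-probe signals, removing the per-sample amplification
#' factor (the geometric mean is the natural location statistic under
#' multiplicative noise). Control probes are carried through unchanged for
#' QC but never enter the geometric mean. Samples in which any reference
#' probe is non-positive cannot be normalized and are excluded with reason
#' `unnormalizable`.
#'
#' @param peaks a [peak_table()].
#' @param manifest the probe manifest for the assay.
#' @return a `normalized_table`: `values` (samples x probes matrix, control
#'   probes raw), `excluded` (data frame `sample_id`, `reason`),
#'   `manifest`, `assay`.
#' @export
intra_sample_normalize <- function(peaks, manifest) {
  stopifnot(inherits(peaks, "peak_table"))
  ref_probes <- intersect(probes_of_role(manifest, "reference"),
                          colnames(peaks$values))
  if (length(ref_probes) < 2) {
    stop("normalization error: < 2 reference probes present in peak table")
  }
  ctrl_probes <- intersect(
    probes_of_role(manifest, c("ligation_control", "denaturation_control")),
    colnames(peaks$values))
  refs <- peaks$values[, ref_probes, drop = FALSE]
  bad <- apply(refs <= 0, 1, any)
  excluded <- data.frame(sample_id = rownames(peaks$values)[bad],
                         reason = if (any(bad)) "unnormalizable" else character(0),
                         stringsAsFactors = FALSE)
  keep <- peaks$values[!bad, , drop = FALSE]
  gm <- exp(rowMeans(log(keep[, ref_probes, drop = FALSE])))
  values <- keep / gm
  if (length(ctrl_probes) > 0) values[, ctrl_probes] <- keep[, ctrl_probes]
  structure(list(values = values, excluded = excluded,
                 manifest = manifest, assay = peaks$assay),
            class = "normalized_table")
}

#' Sample quality control on reference and control probe behaviour
#'
#' A sample is excluded when (a) the coefficient of variation of its raw
#' reference-probe signals exceeds `cv_max` (poor reference probe quality),
#' (b) its denaturation-control signal exceeds `ctrl_frac` of its mean
#' reference signal (incomplete denaturation), or (c) its ligation-control
#' signal falls below `ctrl_frac` of its mean reference signal (failed
#' ligation). These cut-offs are pragmatic defaults, recorded with each
#' exclusion reason.
#'
#' @param peaks the raw [peak_table()].
#' @param manifest probe manifest.
#' @param cv_max reference-probe CV limit (default 0.30).
#' @param ctrl_frac control-signal fraction of the mean reference signal
#'   (default 0.10).
#' @return data frame `sample_id`, `reason` (one row per failed check;
#'   empty when all samples pass).
#' @export
sample_qc <- function(peaks, manifest, cv_max = 0.30, ctrl_frac = 0.10) {
  stopifnot(inherits(peaks, "peak_table"))
  v <- peaks$values
  ref_probes <- intersect(probes_of_role(manifest, "reference"), colnames(v))
  denat_probes <- intersect(probes_of_role(manifest, "denaturation_control"),
                            colnames(v))
  lig_probes <- intersect(probes_of_role(manifest, "ligation_control"),
                          colnames(v))
  refs <- v[, ref_probes, drop = FALSE]
  ref_mean <- rowMeans(refs)
  ref_cv <- apply(refs, 1, stats::sd) / ref_mean
  out <- list()
  bad_cv <- is.na(ref_cv) | ref_cv > cv_max | ref_mean <= 0
  if (any(bad_cv)) {
    out$cv <- data.frame(sample_id = rownames(v)[bad_cv],
                         reason = "reference_cv", stringsAsFactors = FALSE)
  }
  if (length(denat_probes) > 0) {
    denat_hit <- rowMeans(v[, denat_probes, drop = FALSE]) > ctrl_frac * ref_mean
    if (any(denat_hit)) {
      out$denat <- data.frame(sample_id = rownames(v)[denat_hit],
                              reason = "denaturation", stringsAsFactors = FALSE)
    }
  }
  if (length(lig_probes) > 0) {
    lig_fail <- rowMeans(v[, lig_probes, drop = FALSE]) < ctrl_frac * ref_mean
    if (any(lig_fail)) {
      out$lig <- data.frame(sample_id = rownames(v)[lig_fail],
                            reason = "ligation", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(sample_id = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample_id, res$reason), , drop = FALSE]
}

#' Select in-cohort reference samples
#'
#' No external two-copy calibrators exist for these loci, so reference
#' samples are experimental samples whose normalized signal profile sits
#' closest to the cohort mean: `score(s) = mean_p |n(s,p) - m(p)| / m(p)`
#' over target and reference probes (controls excluded), with `m(p)` the
#' cohort mean. Returns the `k` lowest-scoring sample ids; ties break by
#' sample id order, making the choice invariant to input row order.
#'
#' @param normalized a `normalized_table` (or a bare samples x probes
#'   matrix, in which case all columns are used).
#' @param k number of reference samples; defaults to
#'   `max(5, ceiling(0.1 * n))`.
#' @return character vector of `k` sample ids.
#' @export
select_reference_samples <- function(normalized, k = NULL) {
  v <- if (inherits(normalized, "normalized_table")) {
    use <- intersect(probes_of_role(normalized$manifest, c("target", "reference")),
                     colnames(normalized$values))
    normalized$values[, use, drop = FALSE]
  } else {
    as.matrix(normalized)
  }
  n <- nrow(v)
  if (is.null(k)) k <- max(5L, ceiling(0.1 * n))
  if (k < 2 || k >= n) stop("parameter error: k must satisfy 2 <= k < n_samples")
  m <- colMeans(v)
  if (any(m <= 0)) stop("normalization error: non-positive cohort mean signal")
  score <- rowMeans(abs(sweep(v, 2, m, "-")) / matrix(m, n, ncol(v), byrow = TRUE))
  ord <- order(score, rownames(v))
  sort(rownames(v)[ord[seq_len(k)]])
}

#' Compute copy-number ratios against the reference samples
#'
#' `r(s, p) = n(s, p) / mean_{s' in references} n(s', p)` for target and
#' reference probes. By construction the reference samples' mean ratio per
#' probe is exactly 1, so a ratio of 1 corresponds to the modal two-copy
#' state and 0.5 to a single copy. Probes whose reference mean is zero
#' cannot be calibrated and are dropped, recorded in `uncallable`.
#'
#' @param normalized a `normalized_table` (or bare matrix).
#' @param reference_ids character vector of reference sample ids (subset of
#'   the table's samples).
#' @return a `ratio_matrix`: `ratios` (samples x probes), `sd` (optional,
#'   filled by [replicate_sd()]), `reference_samples`, `uncallable`.
#' @export
compute_ratios <- function(normalized, reference_ids) {
  v <- if (inherits(normalized, "normalized_table")) {
    use <- intersect(probes_of_role(normalized$manifest, c("target", "reference")),
                     colnames(normalized$values))
    normalized$values[, use, drop = FALSE]
  } else {
    as.matrix(normalized)
  }
  missing_ref <- setdiff(reference_ids, rownames(v))
  if (length(missing_ref) > 0) {
    stop("parameter error: reference ids absent from table: ",
         paste(missing_ref, collapse = ", "))
  }
  ref_mean <- colMeans(v[reference_ids, , drop = FALSE])
  uncallable <- colnames(v)[ref_mean <= 0]
  callable <- ref_mean > 0
  ratios <- sweep(v[, callable, drop = FALSE], 2, ref_mean[callable], "/")
  structure(list(ratios = ratios, sd = NULL,
                 reference_samples = reference_ids,
                 uncallable = uncallable),
            class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("<ratio_matrix> %d samples x %d probes; %d reference samples%s\n",
              nrow(x$ratios), ncol(x$ratios), length(x$reference_samples),
              if (length(x$uncallable)) paste0("; uncallable: ",
                paste(x$uncallable, collapse = ",")) else ""))
  invisible(x)
}

#' Per-probe dispersion QC of the ratio distribution
#'
#' Computes each probe's interquartile range of ratios across the cohort. A
#' target probe whose IQR exceeds `ref_iqr_inflation` times the median
#' reference-probe IQR is flagged as over-dispersed: its spread is beyond
#' the normal range of the experiment and may hide copy-number structure or
#' probe failure.
#'
#' @param ratios a `ratio_matrix`.
#' @param manifest probe manifest.
#' @param thresholds a [cnv_thresholds()] (uses `ref_iqr_inflation`).
#' @return data frame `probe_id`, `role`, `iqr`, `flagged`.
#' @export
probe_iqr_qc <- function(ratios, manifest, thresholds = cnv_thresholds()) {
  r <- ratios$ratios
  if (nrow(r) < 8) stop("probe QC requires >= 8 samples")
  iqr <- apply(r, 2, stats::IQR)
  role <- manifest$role[match(colnames(r), manifest$probe_id)]
  ref_iqr_med <- stats::median(iqr[role == "reference"])
  flagged <- role == "target" & iqr > thresholds$ref_iqr_inflation * ref_iqr_med
  data.frame(probe_id = colnames(r), role = role, iqr = unname(iqr),
             flagged = unname(flagged), stringsAsFactors = FALSE)
}

#' Across-replicate standard deviation of ratios
#'
#' Given ratio matrices from repeated runs sharing samples and probes,
#' computes the per-cell standard deviation across runs and marks a cell
#' consistent when its sd falls below `sd_genuine` -- small replicate sd at
#' a flagged cell is the evidence that a ratio departure is genuine rather
#' than run noise.
#'
#' @param runs list of `ratio_matrix` objects (>= 2) from repeated runs.
#' @param thresholds a [cnv_thresholds()] (uses `sd_genuine`).
#' @return list: `sd` (matrix over the common samples x probes),
#'   `consistent` (logical matrix), `mean` (across-run mean ratio).
#' @export
replicate_sd <- function(runs, thresholds = cnv_thresholds()) {
  if (length(runs) < 2) stop("replicate sd undefined for a single run")
  mats <- lapply(runs, function(x) if (inherits(x, "ratio_matrix")) x$ratios else as.matrix(x))
  samples <- Reduce(intersect, lapply(mats, rownames))
  probes <- Reduce(intersect, lapply(mats, colnames))
  if (length(samples) == 0 || length(probes) == 0) {
    stop("replicate runs share no samples or no probes")
  }
  arr <- simplify2array(lapply(mats, function(m) m[samples, probes, drop = FALSE]))
  sd_mat <- apply(arr, c(1, 2), stats::sd)
  mean_mat <- apply(arr, c(1, 2), mean)
  list(sd = sd_mat, consistent = sd_mat < thresholds$sd_genuine,
       mean = mean_mat)
}

#' Two-pass normalization of a cohort peak table
#'
#' The full normalization workflow: intra-sample normalization, provisional
#' reference-sample selection, sample QC exclusions, then a second pass in
#' which final references are selected among the surviving samples and
#' ratios are computed against them.
#'
#' @param peaks a [peak_table()].
#' @param manifest probe manifest.
#' @param k number of reference samples (default `max(5, ceiling(0.1 n))`).
#' @param cv_max,ctrl_frac passed to [sample_qc()].
#' @return a `ratio_matrix` with an `excluded` attribute recording the QC
#'   exclusions (`sample_id`, `reason`).
#' @export
normalize_cohort <- function(peaks, manifest, k = NULL, cv_max = 0.30,
                             ctrl_frac = 0.10) {
  norm1 <- intra_sample_normalize(peaks, manifest)
  qc <- sample_qc(peaks, manifest, cv_max = cv_max, ctrl_frac = ctrl_frac)
  drop <- union(norm1$excluded$sample_id, qc$sample_id)
  keep <- setdiff(rownames(peaks$values), drop)
  if (length(keep) < 10) stop("sample QC excluded too many samples to continue")
  peaks2 <- peak_table(peaks$values[keep, , drop = FALSE], assay = peaks$assay,
                       run_id = peaks$run_id)
  norm2 <- intra_sample_normalize(peaks2, manifest)
  refs <- select_reference_samples(norm2, k = k)
  ratios <- compute_ratios(norm2, refs)
  attr(ratios, "excluded") <- rbind(norm1$excluded, qc)
  ratios
}
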