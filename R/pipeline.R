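#' Run the full CNV screening pipeline on one cohort
#'
#' Chains the stages: MLPA normalization (two-pass, with sample QC),
#' threshold calling of every (sample, target gene), orthogonal count-assay
#' normalization, cross-platform confirmation of flagged calls, and the
#' confirmation summary. Inputs may come from files (via the readers in
#' this package) or from the synthetic-data generator.
#'
#' @param mlpa_peaks a [peak_table()] with `assay = "mlpa"`.
#' @param manifest probe manifest.
#' @param count_peaks optional orthogonal [peak_table()] with
#'   `assay = "count"`; when `NULL`, flagged calls remain untested.
#' @param thresholds a [cnv_thresholds()].
#' @param k,k_count reference-sample counts for the MLPA and the count
#'   platform (defaults: `max(5, ceiling(0.1 n))` and 34).
#' @param cohort_size denominator for the confirmed-CNV percentage; default
#'   the number of MLPA samples surviving QC.
#' @return list: `ratios`, `calls`, `ortho_ratios`, `confirmed`, `summary`,
#'   `excluded`.
#' @export
run_cnv_screen <- function(mlpa_peaks, manifest, count_peaks = NULL,
                           thresholds = cnv_thresholds(), k = NULL,
                           k_count = 34L, cohort_size = NULL) {
  ratios <- normalize_cohort(mlpa_peaks, manifest, k = k)
  calls <- call_matrix(ratios, manifest, thresholds)
  ortho_ratios <- NULL
  if (!is.null(count_peaks)) {
    k2 <- min(k_count, nrow(count_peaks$values) - 1L)
    norm_c <- intra_sample_normalize(count_peaks, manifest)
    refs_c <- select_reference_samples(norm_c, k = k2)
    ortho_ratios <- compute_ratios(norm_c, refs_c)
  }
  confirmed <- if (!is.null(ortho_ratios)) {
    confirm_calls(calls, ortho_ratios, thresholds, manifest = manifest)
  } else {
    flagged <- calls[is_flagged(calls$status), , drop = FALSE]
    if (nrow(flagged) > 0) {
      data.frame(sample_id = flagged$sample_id, gene = flagged$gene,
                 mlpa_ratio = flagged$ratio, ortho_ratio = NA_real_,
                 verdict = "untested", caveat = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      confirm_calls(calls, matrix(numeric(0), 0, 0), thresholds)
    }
  }
  if (is.null(cohort_size)) cohort_size <- nrow(ratios$ratios)
  summary <- confirmation_summary(confirmed, cohort_size)
  list(ratios = ratios, calls = calls, ortho_ratios = ortho_ratios,
       confirmed = confirmed, summary = summary,
       excluded = attr(ratios, "excluded"))
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper generating every artifact of a study cohort under
#' one configuration: ground truth, MLPA peaks, orthogonal counts, log2
#' expression and the sample sheet.
#'
#' @param config a [simulation_config()].
#' @param manifest probe manifest (default [rct_manifest()]).
#' @return list: `truth`, `mlpa`, `counts`, `expression`, `sheet`,
#'   `manifest`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            manifest = rct_manifest()) {
  truth <- simulate_truth(config)
  list(truth = truth,
       mlpa = simulate_mlpa_peaks(truth, manifest, config),
       counts = simulate_count_table(truth, manifest, config),
       expression = simulate_expression(truth, config),
       sheet = simulate_sample_sheet(config, truth),
       manifest = manifest, config = config)
}
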