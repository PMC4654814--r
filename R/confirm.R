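#' Confirm flagged MLPA calls against the orthogonal count platform
#'
#' Every flagged MLPA call receives exactly one verdict:
#' \describe{
#'   \item{confirmed_loss}{both platforms' ratios below the loss cut-off}
#'   \item{confirmed_gain}{both above the gain cut-off}
#'   \item{artifact_suspected}{a clear MLPA loss whose orthogonal ratio is
#'     normal -- the signature of a platform-specific binding/ligation-site
#'     artifact, since the two assays' probes bind different regions of the
#'     gene. A rare small CNV under only the MLPA probe would look the same,
#'     which the `caveat` field records.}
#'   \item{unconfirmed_borderline}{a borderline MLPA call (ratio on the
#'     cut-off) with a normal orthogonal ratio -- most likely not a true
#'     loss}
#'   \item{discordant_unexplained}{any other disagreement}
#'   \item{untested}{no orthogonal measurement for that (sample, gene)}
#' }
#'
#' @param mlpa_calls data frame of MLPA calls (from [call_matrix()]); only
#'   flagged rows are confirmed.
#' @param ortho_ratios a `ratio_matrix` from the count platform, or a bare
#'   samples x genes matrix; columns may be probe ids (mapped through
#'   `manifest`) or gene symbols.
#' @param thresholds a [cnv_thresholds()].
#' @param manifest optional manifest to map orthogonal probe columns to genes.
#' @return data frame `sample_id`, `gene`, `mlpa_ratio`, `ortho_ratio`,
#'   `verdict`, `caveat`.
#' @export
confirm_calls <- function(mlpa_calls, ortho_ratios,
                          thresholds = cnv_thresholds(), manifest = NULL) {
  flagged <- mlpa_calls[is_flagged(mlpa_calls$status), , drop = FALSE]
  if (nrow(flagged) == 0) {
    return(data.frame(sample_id = character(0), gene = character(0),
                      mlpa_ratio = numeric(0), ortho_ratio = numeric(0),
                      verdict = character(0), caveat = character(0),
                      stringsAsFactors = FALSE))
  }
  om <- if (inherits(ortho_ratios, "ratio_matrix")) ortho_ratios$ratios else as.matrix(ortho_ratios)
  if (!is.null(manifest)) {
    gmap <- target_gene_map(manifest)
    hit <- colnames(om) %in% names(gmap)
    colnames(om)[hit] <- unname(gmap[colnames(om)[hit]])
  }
  lc <- thresholds$loss_cut; gc <- thresholds$gain_cut
  res <- flagged[, c("sample_id", "gene")]
  res$mlpa_ratio <- flagged$ratio
  res$ortho_ratio <- mapply(function(s, g) {
    if (s %in% rownames(om) && g %in% colnames(om)) om[s, g] else NA_real_
  }, flagged$sample_id, flagged$gene)
  verdict <- character(nrow(res))
  caveat <- rep(NA_character_, nrow(res))
  for (i in seq_len(nrow(res))) {
    st <- flagged$status[i]; o <- res$ortho_ratio[i]
    ortho_normal <- !is.na(o) && o >= lc && o <= gc
    verdict[i] <- if (is.na(o)) {
      "untested"
    } else if (st == "loss" && o < lc) {
      "confirmed_loss"
    } else if (st == "gain" && o > gc) {
      "confirmed_gain"
    } else if (st == "loss" && ortho_normal) {
      caveat[i] <- paste("platform-specific signal loss; a rare small CNV",
                         "under only the MLPA probe cannot be excluded")
      "artifact_suspected"
    } else if (st %in% c("borderline_loss", "borderline_gain") && ortho_normal) {
      "unconfirmed_borderline"
    } else {
      "discordant_unexplained"
    }
  }
  res$verdict <- verdict
  res$caveat <- caveat
  rownames(res) <- NULL
  res
}

#' Summarize cross-platform confirmation over a cohort
#'
#' @param confirmed data frame from [confirm_calls()].
#' @param cohort_size number of samples screened (the denominator of the
#'   confirmed-CNV percentage; supplied by the caller since the two
#'   platforms may have typed different subsets).
#' @return list with per-verdict `counts`, `n_confirmed` (losses + gains),
#'   `cohort_size` and `confirmed_fraction_percent` (1 decimal place).
#' @export
confirmation_summary <- function(confirmed, cohort_size) {
  if (length(cohort_size) != 1 || is.na(cohort_size) || cohort_size <= 0) {
    stop("parameter error: cohort_size must be a positive number")
  }
  levels <- c("confirmed_loss", "confirmed_gain", "artifact_suspected",
              "unconfirmed_borderline", "discordant_unexplained", "untested")
  counts <- as.list(table(factor(confirmed$verdict, levels = levels)))
  n_confirmed <- counts$confirmed_loss + counts$confirmed_gain
  list(counts = counts,
       n_confirmed = n_confirmed,
       cohort_size = cohort_size,
       confirmed_fraction_percent = round(100 * n_confirmed / cohort_size, 1))
}

#' Sensitivity and specificity of artifact detection against ground truth
#'
#' Simulation-only validation of the artifact-suspected verdict: compares
#' the flagged calls' verdicts with the truth table's ligation-site
#' heterozygote flags. The unit is the (sample, gene) pair; a true
#' heterozygote that was never flagged by MLPA counts as a miss.
#'
#' @param confirmed data frame from [confirm_calls()].
#' @param truth a `truth_table` carrying `snp_artifact`.
#' @return list: `confusion` (tp, fp, fn, tn), `sensitivity`, `specificity`
#'   (either is `NA` when its denominator is empty).
#' @export
artifact_sensitivity <- function(confirmed, truth) {
  if (!all(confirmed$sample_id %in% rownames(truth$copies))) {
    stop("consistency error: confirmed calls reference samples absent from truth")
  }
  key <- function(s, g) paste(s, g, sep = "\r")
  true_art <- key(truth$snp_artifact$sample_id, truth$snp_artifact$gene)
  suspected <- key(confirmed$sample_id, confirmed$gene)[
    confirmed$verdict == "artifact_suspected"]
  tested <- key(confirmed$sample_id, confirmed$gene)
  tp <- sum(suspected %in% true_art)
  fp <- length(suspected) - tp
  fn <- sum(!true_art %in% suspected)
  tn <- sum(!tested %in% suspected & !tested %in% true_art)
  sens <- if (length(true_art) > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
       sensitivity = sens, specificity = spec)
}
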