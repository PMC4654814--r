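#' Copy-number calling thresholds
#'
#' The default ratio cut-offs follow standard MLPA interpretation guidance:
#' a normalized ratio below 0.7 indicates a loss and above 1.3 a gain,
#' relative to a two-copy reference. A ratio sitting exactly on a cut-off
#' (within `boundary_tol`) is classed as a borderline call -- a possible
#' loss/gain that still counts as flagged and is sent to the confirmation
#' platform rather than dismissed.
#'
#' @param loss_cut lower ratio cut-off, default 0.7.
#' @param gain_cut upper ratio cut-off, default 1.3.
#' @param boundary_tol numeric tolerance defining "exactly on the cut-off".
#' @param sd_genuine across-replicate standard deviation below which a
#'   flagged ratio is considered reproducible (genuine), default 0.05.
#' @param ref_iqr_inflation multiple of the median reference-probe IQR above
#'   which a target probe is flagged as over-dispersed, default 1.5.
#' @return a `cnv_thresholds` list.
#' @export
cnv_thresholds <- function(loss_cut = 0.7, gain_cut = 1.3,
                           boundary_tol = 1e-9, sd_genuine = 0.05,
                           ref_iqr_inflation = 1.5) {
  stopifnot(loss_cut > 0, loss_cut < 1, gain_cut > 1,
            boundary_tol > 0, sd_genuine > 0, ref_iqr_inflation > 0)
  structure(list(loss_cut = loss_cut, gain_cut = gain_cut,
                 boundary_tol = boundary_tol, sd_genuine = sd_genuine,
                 ref_iqr_inflation = ref_iqr_inflation),
            class = "cnv_thresholds")
}

#' Classify a copy-number ratio against the loss/gain thresholds
#'
#' Pure, vectorized threshold rule: `loss` strictly below the loss cut-off,
#' `gain` strictly above the gain cut-off, `borderline_loss`/`borderline_gain`
#' within `boundary_tol` of a cut-off, otherwise `normal`.
#'
#' @param ratio numeric vector of ratios, all >= 0.
#' @param thresholds a [cnv_thresholds()] object.
#' @return character vector of statuses.
#' @export
#' @examples
#' threshold_call(c(0.56, 0.70, 1.0, 1.35))
threshold_call <- function(ratio, thresholds = cnv_thresholds()) {
  if (anyNA(ratio)) stop("domain error: missing ratio")
  if (any(ratio < 0)) stop("domain error: negative ratio")
  tol <- thresholds$boundary_tol
  status <- rep("normal", length(ratio))
  status[ratio < thresholds$loss_cut - tol] <- "loss"
  status[abs(ratio - thresholds$loss_cut) <= tol] <- "borderline_loss"
  status[ratio > thresholds$gain_cut + tol] <- "gain"
  status[abs(ratio - thresholds$gain_cut) <= tol] <- "borderline_gain"
  status
}

#' Is a call status flagged (outside the two-copy range)?
#'
#' @param status character vector of statuses.
#' @return logical vector.
#' @export
is_flagged <- function(status) {
  status %in% c("loss", "borderline_loss", "gain", "borderline_gain")
}

#' Call copy-number status for every (sample, target gene) pair
#'
#' Applies [threshold_call()] to each target-probe column of a ratio matrix
#' and joins in the across-replicate standard deviation where available.
#' `replicate_consistent` is `TRUE` when the call's sd is below
#' `sd_genuine` -- the reproducibility argument for believing a small ratio
#' departure is genuine.
#'
#' @param ratios a `ratio_matrix` (see [compute_ratios()]).
#' @param manifest probe manifest mapping target probes to genes.
#' @param thresholds a [cnv_thresholds()] object.
#' @return data frame with one row per (sample, gene): `sample_id`, `gene`,
#'   `ratio`, `sd`, `status`, `discrete_copies`, `replicate_consistent`.
#' @export
call_matrix <- function(ratios, manifest, thresholds = cnv_thresholds()) {
  gmap <- target_gene_map(manifest)
  probe_ids <- intersect(colnames(ratios$ratios), names(gmap))
  if (length(probe_ids) == 0) stop("no target probes present in ratio matrix")
  samples <- rownames(ratios$ratios)
  calls <- do.call(rbind, lapply(probe_ids, function(p) {
    r <- ratios$ratios[, p]
    sdv <- if (!is.null(ratios$sd) && p %in% colnames(ratios$sd)) {
      ratios$sd[, p]
    } else {
      rep(NA_real_, length(samples))
    }
    data.frame(sample_id = samples, gene = unname(gmap[p]),
               ratio = unname(r), sd = unname(sdv),
               status = threshold_call(unname(r), thresholds),
               discrete_copies = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  calls$replicate_consistent <- ifelse(is.na(calls$sd), NA,
                                       calls$sd < thresholds$sd_genuine)
  rownames(calls) <- NULL
  calls[order(calls$sample_id, calls$gene), , drop = FALSE]
}

#' Anchored 1-D cluster calling of discrete copy numbers
#'
#' When samples with known discrete copies are available for a probe, raw
#' ratios can be converted to integer copies by clustering: cluster centers
#' are initialized at `(c/2) * scale`, where `scale` calibrates the anchor
#' samples' observed ratios to their known copies; each sample is assigned
#' to the nearest center on the log scale; copies outside the anchored range
#' are extrapolated by rounding `2 * ratio / scale`; centers are refined by
#' one cluster-mean update (with well-separated 1-D centers further passes
#' change nothing, and determinism is preserved).
#'
#' @param raw_ratios named numeric vector of raw copy-number ratios, one per
#'   sample (names are sample ids).
#' @param anchors data frame with columns `sample_id` and `copies`: the
#'   samples of known discrete copy number.
#' @param max_copies cap for extrapolated copies, default 12 (beyond the
#'   defensin-like range the known-copy QC panel targets).
#' @return a `cluster_model` list: `scale`, `centers` (named by copy number,
#'   covering every integer copy up to `max_copies`), `assignment` (named
#'   integer vector of copies per sample), `dispersion` (pooled
#'   within-cluster sd of log ratios).
#' @export
cluster_call <- function(raw_ratios, anchors, max_copies = 12L) {
  stopifnot(is.numeric(raw_ratios), !is.null(names(raw_ratios)))
  if (nrow(anchors) < 1) stop("anchor error: at least one anchor required")
  missing_anchor <- setdiff(anchors$sample_id, names(raw_ratios))
  if (length(missing_anchor) > 0) {
    stop("anchor error: anchor samples absent from ratios: ",
         paste(missing_anchor, collapse = ", "))
  }
  if (any(anchors$copies <= 0)) stop("anchor error: anchor copies must be > 0")
  implied <- raw_ratios[anchors$sample_id] / (anchors$copies / 2)
  if (max(implied) / min(implied) > 1.25) {
    stop("anchor error: anchors imply inconsistent scales (>25% disagreement)")
  }
  scale <- exp(mean(log(implied)))

  candidate_copies <- 1:max_copies
  assign_copies <- function(centers) {
    # nearest center on the log scale over all candidate integer copies;
    # zero copies wins when the ratio falls below half the one-copy center
    zero_cut <- centers[1] / 2
    vapply(raw_ratios, function(r) {
      if (r < zero_cut) return(0L)
      candidate_copies[which.min(abs(log(r) - log(centers)))]
    }, integer(1))
  }

  centers <- stats::setNames((candidate_copies / 2) * scale, candidate_copies)
  assignment <- assign_copies(centers)
  # one refinement pass: move occupied centers to their cluster means
  refined <- centers
  for (k in candidate_copies) {
    members <- raw_ratios[assignment == k]
    if (length(members) > 0) refined[as.character(k)] <- mean(members)
  }
  if (all(diff(refined) > 0)) {
    centers <- refined
    assignment <- assign_copies(centers)
  }
  pooled <- unlist(lapply(unique(assignment), function(k) {
    members <- raw_ratios[assignment == k]
    if (length(members) > 1) log(members) - mean(log(members)) else numeric(0)
  }))
  dispersion <- if (length(pooled) > 1) stats::sd(pooled) else 0
  structure(list(scale = scale, centers = centers, assignment = assignment,
                 anchors = anchors, dispersion = dispersion),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> scale=%.3f, %d centers, %d samples, dispersion=%.4f\n",
              x$scale, length(x$centers), length(x$assignment), x$dispersion))
  invisible(x)
}
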