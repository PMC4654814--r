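#' Classify a lipid phenotype under the NCEP ATP III extreme-strata rules
#'
#' Eligibility for an extreme-lipid screen holds when any single criterion
#' is met: HDL-C <= 40 or >= 60 mg/dL, or LDL-C <= 100 or >= 130 mg/dL.
#' The conjunctive phenotype groups are `atheroprotective`
#' (HDL-C >= 60 and LDL-C <= 100) and `atherogenic`
#' (HDL-C <= 40 and LDL-C >= 160); bounds are inclusive. With LDL not
#' measured the group is `unclassified` (HDL alone can still make the
#' sample eligible); otherwise `intermediate`.
#'
#' @param hdl numeric vector of HDL-C, mg/dL, > 0.
#' @param ldl numeric vector of LDL-C, mg/dL (NA = not measured).
#' @return data frame `hdl`, `ldl`, `eligible`, `group`.
#' @export
#' @examples
#' classify_phenotype(c(65, 35, 50), c(90, 170, 115))
classify_phenotype <- function(hdl, ldl = NA_real_) {
  if (length(ldl) == 1 && length(hdl) > 1) ldl <- rep(ldl, length(hdl))
  stopifnot(length(hdl) == length(ldl))
  if (anyNA(hdl) || any(hdl <= 0)) stop("domain error: HDL must be positive")
  if (any(!is.na(ldl) & ldl <= 0)) stop("domain error: LDL must be positive")
  eligible <- hdl <= 40 | hdl >= 60 |
    (!is.na(ldl) & (ldl <= 100 | ldl >= 130))
  group <- rep("intermediate", length(hdl))
  group[is.na(ldl)] <- "unclassified"
  group[!is.na(ldl) & hdl >= 60 & ldl <= 100] <- "atheroprotective"
  group[!is.na(ldl) & hdl <= 40 & ldl >= 160] <- "atherogenic"
  data.frame(hdl = hdl, ldl = ldl, eligible = eligible, group = group,
             stringsAsFactors = FALSE)
}

# stratum labels used by the demographic cross-tabulation
.hdl_stratum <- function(hdl) {
  ifelse(hdl <= 40, "<=40", ifelse(hdl < 60, "40-60", ">=60"))
}
.ldl_stratum <- function(ldl) {
  ifelse(is.na(ldl), "not_measured",
         ifelse(ldl <= 100, "<=100",
                ifelse(ldl < 130, "100-130",
                       ifelse(ldl < 160, "130-160", ">=160"))))
}

#' Cross-tabulate a cohort by lipid strata, HIV status and phenotype group
#'
#' Reproduces the demographic grouping scheme of an extreme-lipid screen:
#' HDL stratum (<=40, 40-60, >=60 mg/dL) by LDL stratum (<=100, 100-130,
#' 130-160, >=160, not measured) by HIV status, plus totals for the
#' conjunctive phenotype groups. Counts partition the cohort: they sum to
#' the number of records.
#'
#' @param records sample-sheet data frame with `hdl`, `ldl`, `hiv_positive`.
#' @return list: `strata` (data frame `hdl_stratum`, `ldl_stratum`,
#'   `hiv_positive`, `n`, including zero rows), `groups` (named counts of
#'   the phenotype classes), `n_total`.
#' @export
phenotype_group_counts <- function(records) {
  if (nrow(records) == 0) stop("records must be non-empty")
  hs <- factor(.hdl_stratum(records$hdl), levels = c("<=40", "40-60", ">=60"))
  ls <- factor(.ldl_stratum(records$ldl),
               levels = c("<=100", "100-130", "130-160", ">=160", "not_measured"))
  hiv <- factor(records$hiv_positive, levels = c(FALSE, TRUE))
  tab <- as.data.frame(table(hdl_stratum = hs, ldl_stratum = ls,
                             hiv_positive = hiv), stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  tab$hiv_positive <- as.logical(tab$hiv_positive)
  cls <- classify_phenotype(records$hdl, records$ldl)
  groups <- table(factor(cls$group, levels = c("atheroprotective", "atherogenic",
                                               "intermediate", "unclassified")))
  list(strata = tab, groups = stats::setNames(as.integer(groups), names(groups)),
       n_total = nrow(records))
}

#' Compare lipid levels between CNV carriers and non-carriers
#'
#' For each gene with at least one flagged call, reports median and IQR of
#' HDL-C and LDL-C among carriers and non-carriers. A two-sided Wilcoxon
#' rank-sum test (exact null distribution where sample size and ties
#' permit) is reported only when there are at least
#' `min_carriers` carriers; below that the comparison is marked
#' underpowered and no p-value is given -- with one or two carriers a test
#' would be uninterpretable.
#'
#' @param calls data frame of copy calls (from [call_matrix()]).
#' @param records sample-sheet data frame.
#' @param min_carriers minimum carriers for a test (default 3).
#' @return data frame, one row per gene with >= 1 carrier: carrier counts,
#'   median (IQR) lipid summaries, `p_hdl`, `p_ldl`, `underpowered`.
#' @export
cnv_lipid_comparison <- function(calls, records, min_carriers = 3L) {
  joined <- merge(calls, records, by = "sample_id")
  if (nrow(joined) == 0) stop("join error: calls and records share no samples")
  genes <- unique(joined$gene[is_flagged(joined$status)])
  if (length(genes) == 0) {
    return(data.frame(gene = character(0), n_carriers = integer(0),
                      stringsAsFactors = FALSE))
  }
  summ <- function(x) {
    if (all(is.na(x))) return("NA")
    sprintf("%.1f (%.1f-%.1f)", stats::median(x, na.rm = TRUE),
            stats::quantile(x, 0.25, na.rm = TRUE),
            stats::quantile(x, 0.75, na.rm = TRUE))
  }
  do.call(rbind, lapply(genes, function(g) {
    gg <- joined[joined$gene == g, ]
    carrier <- is_flagged(gg$status)
    n_car <- sum(carrier)
    underpowered <- n_car < min_carriers
    p_hdl <- p_ldl <- NA_real_
    if (!underpowered) {
      # exact null distribution where sample size and ties permit
      p_hdl <- stats::wilcox.test(gg$hdl[carrier], gg$hdl[!carrier])$p.value
      if (sum(!is.na(gg$ldl[carrier])) >= min_carriers) {
        p_ldl <- stats::wilcox.test(gg$ldl[carrier], gg$ldl[!carrier])$p.value
      }
    }
    data.frame(gene = g, n_carriers = n_car, n_noncarriers = sum(!carrier),
               hdl_carriers = summ(gg$hdl[carrier]),
               hdl_noncarriers = summ(gg$hdl[!carrier]),
               ldl_carriers = summ(gg$ldl[carrier]),
               ldl_noncarriers = summ(gg$ldl[!carrier]),
               p_hdl = p_hdl, p_ldl = p_ldl,
               underpowered = underpowered, stringsAsFactors = FALSE)
  }))
}

#' Associate copy-number ratios with log2 expression
#'
#' Per gene (and per transcript variant when several columns of the
#' expression matrix map to one gene via a `GENE_variant` naming scheme),
#' fits least squares of log2 expression on log2(ratio) over the
#' overlapping samples. On this scale the fitted slope estimates the
#' dosage effect per log2 copy unit directly (ratio 0.5 = one copy lost =
#' one log2 unit). Pearson correlation and its two-sided p-value accompany
#' the slope; genes whose ratios have (near) zero variance are reported as
#' not assessable, since no association can be estimated from a constant
#' regressor. A Benjamini-Hochberg adjusted p-value across assessable rows
#' is added alongside the unadjusted one.
#'
#' @param ratios a `ratio_matrix` whose target-probe columns are mapped to
#'   genes via `manifest`, or a bare samples x genes matrix of ratios.
#' @param expression samples x transcripts matrix, log2 scale; transcript
#'   names are gene symbols, optionally suffixed `_1`, `_2`, ... for splice
#'   variants.
#' @param manifest optional manifest to map probe columns to genes.
#' @param min_n minimum overlapping samples (default 3).
#' @return data frame `gene`, `variant`, `n`, `r`, `slope`, `p`, `p_adj`,
#'   `assessable`.
#' @export
cnv_expression_association <- function(ratios, expression, manifest = NULL,
                                       min_n = 3L) {
  rm_ <- if (inherits(ratios, "ratio_matrix")) ratios$ratios else as.matrix(ratios)
  if (!is.null(manifest)) {
    gmap <- target_gene_map(manifest)
    keep <- colnames(rm_) %in% names(gmap)
    rm_ <- rm_[, keep, drop = FALSE]
    colnames(rm_) <- unname(gmap[colnames(rm_)])
  }
  samples <- intersect(rownames(rm_), rownames(expression))
  if (length(samples) < min_n) stop("fewer than min_n overlapping samples")
  rm_ <- rm_[samples, , drop = FALSE]
  ex <- expression[samples, , drop = FALSE]
  base_gene <- sub("_[0-9]+$", "", colnames(ex))
  rows <- lapply(seq_len(ncol(ex)), function(j) {
    g <- base_gene[j]
    if (!g %in% colnames(rm_)) return(NULL)
    rat <- rm_[, g]
    y <- ex[, j]
    ok <- !is.na(rat) & !is.na(y) & rat > 0
    n <- sum(ok)
    if (n < min_n || stats::var(rat[ok]) < 1e-12) {
      return(data.frame(gene = g, variant = colnames(ex)[j], n = n,
                        r = NA_real_, slope = NA_real_, p = NA_real_,
                        assessable = FALSE, stringsAsFactors = FALSE))
    }
    x <- log2(rat[ok])
    fit <- stats::lm(y[ok] ~ x)
    ct <- stats::cor.test(x, y[ok])
    data.frame(gene = g, variant = colnames(ex)[j], n = n,
               r = unname(ct$estimate), slope = unname(stats::coef(fit)[2]),
               p = ct$p.value, assessable = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0) stop("no expression columns map to ratio genes")
  res$p_adj <- NA_real_
  res$p_adj[res$assessable] <- stats::p.adjust(res$p[res$assessable], method = "BH")
  rownames(res) <- NULL
  res[, c("gene", "variant", "n", "r", "slope", "p", "p_adj", "assessable")]
}
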