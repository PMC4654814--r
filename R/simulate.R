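# Run code under a fixed seed without disturbing the caller's RNG stream.
# Each generator draws from seed + a fixed stage offset so that the stages
# are individually reproducible and mutually independent.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.STAGE_OFFSET <- c(truth = 101L, mlpa = 202L, count = 303L,
                   expression = 404L, sheet = 505L, multicopy = 606L)

#' Configuration of the synthetic cohort generator
#'
#' Collects every tunable of the generative model for the dosage screen:
#' cohort size, per-gene copy-state frequencies, the ligation-site SNP
#' artifact rate, multiplicative noise levels of the two platforms,
#' per-sample amplification and per-probe efficiency spreads, the expression
#' dosage slope, and the known-copy control panel.
#'
#' Defaults emulate the study conditions of a ~320-sample targeted screen of
#' the 16 RCT genes in which single-copy losses are rare (per-gene frequency
#' 0.003, i.e. at most a handful of losses cohort-wide), gains are absent,
#' and a ligation-site SNP at the APOA4 probe occasionally halves the MLPA
#' signal of a heterozygous carrier without touching the count assay.
#'
#' @param n_samples cohort size, >= 10 (default 320).
#' @param genes character vector of target genes (default [RCT_GENES]).
#' @param loss_freq per-gene probability of a 1-copy state (default 0.003).
#' @param gain_freq per-gene probability of a 3-copy state (default 0).
#' @param snp_artifact_freq probability a sample is heterozygous for the
#'   ligation-site variant at `artifact_gene` (default 0.006).
#' @param artifact_gene gene whose MLPA probe carries the ligation-site
#'   variant (default `"APOA4"`).
#' @param sigma_mlpa lognormal noise sd of MLPA peaks, natural-log scale
#'   (default 0.05).
#' @param sigma_count same for the count assay (default 0.05).
#' @param amp_sd sd of the per-sample log amplification factor (default 0.3).
#' @param probe_eff_sd sd of the per-probe log efficiency (default 0.2).
#' @param denat_fail_freq probability a sample fails denaturation
#'   (default 0.01).
#' @param beta_expr expression dosage slope on log2(copies/2) (default 0:
#'   no dosage effect, the observed regime).
#' @param expr_sd expression noise sd, log2 scale (default 0.2).
#' @param multicopy_panel known copies of the control panel
#'   (default `c(2, 3, 4, 5, 6, 7)`).
#' @param seed integer seed driving every generator (default 1).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 320L, genes = RCT_GENES,
                              loss_freq = 0.003, gain_freq = 0,
                              snp_artifact_freq = 0.006,
                              artifact_gene = "APOA4",
                              sigma_mlpa = 0.05, sigma_count = 0.05,
                              amp_sd = 0.3, probe_eff_sd = 0.2,
                              denat_fail_freq = 0.01,
                              beta_expr = 0, expr_sd = 0.2,
                              multicopy_panel = c(2L, 3L, 4L, 5L, 6L, 7L),
                              seed = 1L) {
  probs <- c(loss_freq, gain_freq, snp_artifact_freq, denat_fail_freq)
  if (any(probs < 0 | probs > 1)) stop("config error: probabilities must lie in [0, 1]")
  if (loss_freq + gain_freq > 1) stop("config error: loss_freq + gain_freq > 1")
  sds <- c(sigma_mlpa, sigma_count, amp_sd, probe_eff_sd, expr_sd)
  if (any(sds < 0)) stop("config error: standard deviations must be >= 0")
  if (n_samples < 10) stop("config error: n_samples must be >= 10")
  if (any(multicopy_panel < 0)) stop("config error: multicopy_panel copies must be >= 0")
  structure(list(n_samples = as.integer(n_samples), genes = genes,
                 loss_freq = loss_freq, gain_freq = gain_freq,
                 snp_artifact_freq = snp_artifact_freq,
                 artifact_gene = artifact_gene,
                 sigma_mlpa = sigma_mlpa, sigma_count = sigma_count,
                 amp_sd = amp_sd, probe_eff_sd = probe_eff_sd,
                 denat_fail_freq = denat_fail_freq,
                 beta_expr = beta_expr, expr_sd = expr_sd,
                 multicopy_panel = as.integer(multicopy_panel),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate ground-truth copy states and artifact flags
#'
#' Draws, independently per (sample, gene), a 1-copy state with probability
#' `loss_freq` and a 3-copy state with probability `gain_freq` (2 copies
#' otherwise); per sample, heterozygosity for the ligation-site variant at
#' the artifact gene and denaturation failure; and the per-sample log-normal
#' amplification factor shared by all of that sample's MLPA peaks.
#'
#' @param config a [simulation_config()].
#' @return a `truth_table` list: `copies` (samples x genes integer matrix),
#'   `snp_artifact` (data frame `sample_id`, `gene`), `denaturation_failure`
#'   (character vector of sample ids), `amplification` (named numeric).
#' @export
simulate_truth <- function(config = simulation_config()) {
  n <- config$n_samples
  g <- length(config$genes)
  samples <- sprintf("S%03d", seq_len(n))
  with_seed(config$seed + .STAGE_OFFSET[["truth"]], {
    u <- matrix(stats::runif(n * g), n, g)
    copies <- matrix(2L, n, g, dimnames = list(samples, config$genes))
    copies[u < config$loss_freq] <- 1L
    copies[u >= config$loss_freq &
           u < config$loss_freq + config$gain_freq] <- 3L
    het <- stats::runif(n) < config$snp_artifact_freq
    denat <- stats::runif(n) < config$denat_fail_freq
    amp <- stats::setNames(exp(stats::rnorm(n, 0, config$amp_sd)), samples)
    snp <- if (any(het) && config$artifact_gene %in% config$genes) {
      data.frame(sample_id = samples[het], gene = config$artifact_gene,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = character(0), gene = character(0),
                 stringsAsFactors = FALSE)
    }
    structure(list(copies = copies, snp_artifact = snp,
                   denaturation_failure = samples[denat],
                   amplification = amp),
              class = "truth_table")
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("<truth_table> %d samples x %d genes; %d non-diploid cells, %d SNP-artifact hets, %d denaturation failures\n",
              nrow(x$copies), ncol(x$copies), sum(x$copies != 2L),
              nrow(x$snp_artifact), length(x$denaturation_failure)))
  invisible(x)
}

# multiplicative signal core shared by both platforms:
# sample factor x probe efficiency x (copies/2) x lognormal noise
.dosage_signal <- function(copies_over_2, sample_factor, probe_eff, sigma,
                           base = 1000) {
  n <- nrow(copies_over_2); p <- ncol(copies_over_2)
  eps <- if (sigma > 0) matrix(stats::rnorm(n * p, 0, sigma), n, p) else matrix(0, n, p)
  base * (sample_factor %o% probe_eff) * copies_over_2 * exp(eps)
}

#' Simulate an MLPA peak-height table
#'
#' Signal model for target/reference probe p in sample s:
#' `A_s * E_p * (c(s, gene(p))/2) * b(s, p) * exp(eps)` with
#' `eps ~ N(0, sigma_mlpa^2)`, where `A_s` is the sample amplification
#' factor, `E_p` the probe efficiency and `b(s, p) = 0.5` when the sample is
#' heterozygous for the ligation-site variant under probe p (the mutant
#' allele's impaired ligation halves that probe's signal). Reference and
#' ligation-control probes behave as two-copy loci. Denaturation-control
#' probes are silent in normal samples and fire at reference level in
#' denaturation-failure samples, whose target signal is additionally
#' globally depressed (x0.5) so sample QC has a failure mode to catch.
#'
#' @param truth a `truth_table` from [simulate_truth()].
#' @param manifest probe manifest; every truth gene must have a target probe.
#' @param config the [simulation_config()] used for `truth`.
#' @return a `peak_table` with `assay = "mlpa"`.
#' @export
simulate_mlpa_peaks <- function(truth, manifest, config = simulation_config()) {
  missing_genes <- setdiff(colnames(truth$copies), target_gene_map(manifest))
  if (length(missing_genes) > 0) {
    stop("consistency error: truth genes without a target probe: ",
         paste(missing_genes, collapse = ", "))
  }
  samples <- rownames(truth$copies)
  probes <- manifest$probe_id
  gmap <- target_gene_map(manifest)
  with_seed(config$seed + .STAGE_OFFSET[["mlpa"]], {
    eff <- stats::setNames(exp(stats::rnorm(length(probes), 0, config$probe_eff_sd)),
                           probes)
    c_over_2 <- matrix(1, length(samples), length(probes),
                       dimnames = list(samples, probes))
    for (p in names(gmap)) {
      if (p %in% probes) c_over_2[, p] <- truth$copies[, gmap[[p]]] / 2
    }
    # ligation-site heterozygotes: that probe's effective signal is halved
    if (nrow(truth$snp_artifact) > 0) {
      for (i in seq_len(nrow(truth$snp_artifact))) {
        p <- names(gmap)[gmap == truth$snp_artifact$gene[i]]
        c_over_2[truth$snp_artifact$sample_id[i], p] <-
          0.5 * c_over_2[truth$snp_artifact$sample_id[i], p]
      }
    }
    denat_probes <- probes_of_role(manifest, "denaturation_control")
    target_probes <- probes_of_role(manifest, "target")
    is_denat_sample <- samples %in% truth$denaturation_failure
    # denaturation controls silent unless denaturation failed
    c_over_2[, denat_probes] <- 0
    c_over_2[is_denat_sample, denat_probes] <- 1
    # failed samples lose half their target signal across the board
    c_over_2[is_denat_sample, target_probes] <-
      0.5 * c_over_2[is_denat_sample, target_probes]
    values <- .dosage_signal(c_over_2, truth$amplification[samples], eff,
                             config$sigma_mlpa)
    # fully silent probes must not carry residual noise
    values[c_over_2 == 0] <- 0
    peak_table(values, assay = "mlpa", run_id = paste0("sim_mlpa_", config$seed))
  })
}

#' Simulate an orthogonal molecular-count table
#'
#' Count-assay signal: `B_s * F_p * (c/2) * exp(eps)` with
#' `eps ~ N(0, sigma_count^2)`. The count probes bind in different regions
#' of each gene, so the MLPA ligation-site artifact has no effect here, and
#' the MLPA-specific control probes are not part of the codeset (only target
#' and reference probes are emitted).
#'
#' @inheritParams simulate_mlpa_peaks
#' @return a `peak_table` with `assay = "count"`.
#' @export
simulate_count_table <- function(truth, manifest, config = simulation_config()) {
  missing_genes <- setdiff(colnames(truth$copies), target_gene_map(manifest))
  if (length(missing_genes) > 0) {
    stop("consistency error: truth genes without a target probe: ",
         paste(missing_genes, collapse = ", "))
  }
  samples <- rownames(truth$copies)
  probes <- probes_of_role(manifest, c("target", "reference"))
  gmap <- target_gene_map(manifest)
  with_seed(config$seed + .STAGE_OFFSET[["count"]], {
    sample_factor <- stats::setNames(exp(stats::rnorm(length(samples), 0, config$amp_sd)),
                                     samples)
    eff <- stats::setNames(exp(stats::rnorm(length(probes), 0, config$probe_eff_sd)),
                           probes)
    c_over_2 <- matrix(1, length(samples), length(probes),
                       dimnames = list(samples, probes))
    for (p in names(gmap)) {
      if (p %in% probes) c_over_2[, p] <- truth$copies[, gmap[[p]]] / 2
    }
    values <- .dosage_signal(c_over_2, sample_factor, eff, config$sigma_count)
    values[c_over_2 == 0] <- 0
    peak_table(values, assay = "count", run_id = paste0("sim_count_", config$seed))
  })
}

#' Simulate a log2 expression matrix with a configurable dosage effect
#'
#' `x(s, g) = mu_g + beta_expr * log2(c(s, g)/2) + N(0, expr_sd^2)`, with
#' per-gene baselines `mu_g` drawn once from N(8, 0.5) (typical microarray
#' log2 intensities). For homozygous deletions (`c = 0`) the dosage term is
#' floored at -5 to keep the value finite.
#'
#' @param truth a `truth_table`.
#' @param config the matching [simulation_config()].
#' @return numeric matrix samples x genes, log2 scale.
#' @export
simulate_expression <- function(truth, config = simulation_config()) {
  copies <- truth$copies
  with_seed(config$seed + .STAGE_OFFSET[["expression"]], {
    mu <- stats::rnorm(ncol(copies), 8, 0.5)
    dosage <- log2(copies / 2)
    dosage[copies == 0] <- -5
    noise <- matrix(stats::rnorm(length(copies), 0, config$expr_sd),
                    nrow(copies), ncol(copies))
    x <- matrix(mu, nrow(copies), ncol(copies), byrow = TRUE) +
      config$beta_expr * dosage + noise
    dimnames(x) <- dimnames(copies)
    x
  })
}

#' Simulate a cohort sample sheet with lipid and therapy structure
#'
#' HDL-C is drawn from N(45, 12) and LDL-C from N(125, 25), both truncated
#' above 0 -- wide enough that the cohort contains both NCEP extreme strata
#' (HDL <= 40 and >= 60) alongside mid-range controls. 10% of LDL values are
#' missing ("not measured"). 60% of samples are HIV-positive; 70% of those
#' are on some antiretroviral therapy (predominantly potent ART), and about
#' three quarters of the treated report >= 95% adherence.
#'
#' @param config a [simulation_config()].
#' @param truth optional `truth_table`; when given, sample ids are taken
#'   from it so that sheet and assay tables align.
#' @return data frame of sample records (see [read_sample_sheet()]).
#' @export
simulate_sample_sheet <- function(config = simulation_config(), truth = NULL) {
  n <- config$n_samples
  samples <- if (!is.null(truth)) rownames(truth$copies) else sprintf("S%03d", seq_len(n))
  n <- length(samples)
  rtrunc_pos <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
    x
  }
  with_seed(config$seed + .STAGE_OFFSET[["sheet"]], {
    hdl <- rtrunc_pos(n, 45, 12)
    ldl <- rtrunc_pos(n, 125, 25)
    ldl[stats::runif(n) < 0.10] <- NA
    trig <- exp(stats::rnorm(n, log(130), 0.4))
    tchol <- hdl + ifelse(is.na(ldl), 125, ldl) + trig / 5
    hiv <- stats::runif(n) < 0.60
    therapy <- rep("na", n)
    therapy[hiv] <- sample(c("none", "mono", "combination", "potent_art"),
                           sum(hiv), replace = TRUE,
                           prob = c(0.30, 0.05, 0.10, 0.55))
    treated <- therapy %in% c("mono", "combination", "potent_art")
    adherence <- rep(NA_character_, n)
    adherence[treated] <- sample(c("100%", "95-99%", "<75%", "NA"),
                                 sum(treated), replace = TRUE,
                                 prob = c(0.30, 0.45, 0.08, 0.17))
    ancestry <- sample(c("EA", "AEA", "AsEA", "NA"), n, replace = TRUE,
                       prob = c(0.70, 0.25, 0.04, 0.01))
    data.frame(sample_id = samples, hiv_positive = hiv,
               hdl = round(hdl, 1), ldl = round(ldl, 1),
               tchol = round(tchol, 1), trig = round(trig, 1),
               therapy = therapy, adherence = adherence,
               ancestry = ancestry, stringsAsFactors = FALSE)
  })
}

#' Simulate the known-copy control panel
#'
#' Emits one control sample per entry of `multicopy_panel`, carrying that
#' many copies at the designated multicopy locus and two copies everywhere
#' else -- the panel used to verify that the assay resolves a range of
#' discrete copy numbers, not just losses from two.
#'
#' @param config a [simulation_config()].
#' @param manifest manifest containing a target probe for `gene`.
#' @param gene the multicopy locus (default `"DEFB103A"`).
#' @param n_replicates control samples per panel entry (default 1).
#' @return list with `peaks` (a `peak_table`) and `truth` (a `truth_table`).
#' @export
simulate_multicopy_controls <- function(config = simulation_config(),
                                        manifest = rct_manifest(multicopy = TRUE),
                                        gene = "DEFB103A", n_replicates = 1L) {
  gmap <- target_gene_map(manifest)
  if (!gene %in% gmap) {
    stop("manifest error: no target probe for multicopy locus ", gene)
  }
  panel <- rep(config$multicopy_panel, each = n_replicates)
  samples <- sprintf("CTRL%02d", seq_along(panel))
  other_genes <- setdiff(unname(gmap), gene)
  copies <- matrix(2L, length(samples), length(gmap),
                   dimnames = list(samples, c(other_genes, gene)))
  copies[, gene] <- as.integer(panel)
  truth <- with_seed(config$seed + .STAGE_OFFSET[["multicopy"]], {
    amp <- stats::setNames(exp(stats::rnorm(length(samples), 0, config$amp_sd)),
                           samples)
    structure(list(copies = copies,
                   snp_artifact = data.frame(sample_id = character(0),
                                             gene = character(0),
                                             stringsAsFactors = FALSE),
                   denaturation_failure = character(0),
                   amplification = amp),
              class = "truth_table")
  })
  peaks <- simulate_mlpa_peaks(truth, manifest, config)
  list(peaks = peaks, truth = truth)
}
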