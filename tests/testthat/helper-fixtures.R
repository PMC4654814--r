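# Shared fixtures: built in code, no stored binaries.

# a minimal but valid manifest: 3 target genes, 4 reference probes, controls
tiny_manifest <- function() {
  validate_manifest(data.frame(
    probe_id = c("CETP_T1", "ABCA1_T1", "APOA4_T1",
                 paste0("Ref_", 1:4), "Ref_17", "Ref_18"),
    gene = c("CETP", "ABCA1", "APOA4", paste0("REFLOC_", 1:4),
             "DENAT_CTRL_1", "LIG_CTRL_1"),
    role = c(rep("target", 3), rep("reference", 4),
             "denaturation_control", "ligation_control"),
    chrom = c("16", "9", "11", "1", "2", "3", "4", "5", "6"),
    start = 1000L + 10L * (1:9),
    end = 1060L + 10L * (1:9),
    known_copies = c(NA, NA, NA, 2L, 2L, 2L, 2L, NA, NA),
    stringsAsFactors = FALSE))
}

# a config with every stochastic element switched off; overrides allowed
noiseless_config <- function(...) {
  defaults <- list(loss_freq = 0, gain_freq = 0, snp_artifact_freq = 0,
                   sigma_mlpa = 0, sigma_count = 0, amp_sd = 0,
                   probe_eff_sd = 0, denat_fail_freq = 0, expr_sd = 0)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# wrap a bare matrix as a ratio_matrix
as_ratio_matrix <- function(m, refs = character(0)) {
  structure(list(ratios = as.matrix(m), sd = NULL,
                 reference_samples = refs, uncallable = character(0)),
            class = "ratio_matrix")
}

# the published 4x4 normalized-ratio block of the flagged cohort samples
flagged_block_path <- function() {
  system.file("extdata", "flagged_ratio_block.csv", package = "rctcnv")
}
confirmation_path <- function() {
  system.file("extdata", "count_confirmation_ratios.csv", package = "rctcnv")
}
strata_counts_path <- function() {
  system.file("extdata", "lipid_strata_counts.tsv", package = "rctcnv")
}

# expand the published stratum counts into representative sample records:
# one row per individual, with lipid values inside the stratum bounds
records_from_strata <- function() {
  tab <- utils::read.delim(strata_counts_path(), stringsAsFactors = FALSE)
  hdl_rep <- c("<=40" = 35, "40-60" = 50, ">=60" = 65)
  ldl_rep <- c("<=100" = 90, "100-130" = 115, "130-160" = 145,
               ">=160" = 170, "not_measured" = NA)
  rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    n_neg <- tab$hiv_negative_n[i]; n_pos <- tab$hiv_positive_n[i]
    data.frame(
      hiv_positive = rep(c(FALSE, TRUE), c(n_neg, n_pos)),
      hdl = hdl_rep[[tab$hdl_stratum[i]]],
      ldl = ldl_rep[[tab$ldl_stratum[i]]],
      stringsAsFactors = FALSE)
  }))
  rows$sample_id <- sprintf("P%03d", seq_len(nrow(rows)))
  rows
}
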