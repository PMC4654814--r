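make_peaks <- function(values, manifest, assay = "mlpa") {
  peak_table(values, assay = assay)
}

test_that("intra-sample normalization divides by the reference geometric mean", {
  m <- tiny_manifest()
  v <- matrix(c(100, 100, 100, 100, 100, 100, 100, 0, 100,
                50, 200, 100, 100, 100, 100, 100, 0, 100),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), m$probe_id))
  norm <- intra_sample_normalize(make_peaks(v, m), m)
  expect_equal(unname(norm$values["S1", "CETP_T1"]), 1.0)
  expect_equal(unname(norm$values["S2", "CETP_T1"]), 0.5)
  expect_equal(unname(norm$values["S2", "ABCA1_T1"]), 2.0)
  # control probes pass through untouched
  expect_equal(unname(norm$values[, "Ref_18"]), c(100, 100))
})

test_that("per-sample rescaling leaves normalized values and ratios unchanged", {
  m <- rct_manifest()
  cfg <- simulation_config(n_samples = 40, seed = 8, denat_fail_freq = 0)
  coh <- simulate_cohort(cfg, m)
  peaks2 <- coh$mlpa
  scale <- runif(nrow(peaks2$values), 0.2, 5)
  peaks2$values <- peaks2$values * scale
  n1 <- intra_sample_normalize(coh$mlpa, m)
  n2 <- intra_sample_normalize(peak_table(peaks2$values, "mlpa"), m)
  # control probes are carried raw, so compare the normalized probes only
  use <- m$probe_id[m$role %in% c("target", "reference")]
  expect_equal(n2$values[, use], n1$values[, use], tolerance = 1e-9)
  refs <- select_reference_samples(n1, k = 8)
  r1 <- compute_ratios(n1, refs)
  r2 <- compute_ratios(n2, refs)
  expect_equal(r2$ratios, r1$ratios, tolerance = 1e-9)
})

test_that("samples with non-positive reference signal are unnormalizable", {
  m <- tiny_manifest()
  v <- matrix(100, 3, 9, dimnames = list(paste0("S", 1:3), m$probe_id))
  v["S2", "Ref_3"] <- 0
  norm <- intra_sample_normalize(make_peaks(v, m), m)
  expect_equal(norm$excluded$sample_id, "S2")
  expect_equal(norm$excluded$reason, "unnormalizable")
  expect_false("S2" %in% rownames(norm$values))
})

test_that("sample QC catches simulated denaturation failures and leaves clean samples", {
  m <- rct_manifest()
  cfg <- simulation_config(n_samples = 100, seed = 17, denat_fail_freq = 0.05)
  truth <- simulate_truth(cfg)
  peaks <- simulate_mlpa_peaks(truth, m, cfg)
  qc <- sample_qc(peaks, m)
  denat_flagged <- qc$sample_id[qc$reason == "denaturation"]
  expect_setequal(denat_flagged, truth$denaturation_failure)
  expect_gt(length(truth$denaturation_failure), 0)
  # a cohort with simulated failure modes ends smaller than it started
  ratios <- normalize_cohort(peaks, m)
  expect_lt(nrow(ratios$ratios), cfg$n_samples)
  expect_setequal(attr(ratios, "excluded")$sample_id, denat_flagged)
})

test_that("reference-sample selection prefers mean-like samples and is order-invariant", {
  m <- rct_manifest()
  cfg <- noiseless_config(n_samples = 20, seed = 6)
  truth <- simulate_truth(cfg)
  truth$copies["S010", "CETP"] <- 1L
  peaks <- simulate_mlpa_peaks(truth, m, cfg)
  norm <- intra_sample_normalize(peaks, m)
  refs <- select_reference_samples(norm, k = 10)
  expect_false("S010" %in% refs)
  # noiseless all-diploid: scores tie at 0 and ids break the tie
  truth0 <- simulate_truth(noiseless_config(n_samples = 20, seed = 6))
  norm0 <- intra_sample_normalize(simulate_mlpa_peaks(truth0, m, cfg), m)
  expect_equal(select_reference_samples(norm0, k = 5),
               sprintf("S%03d", 1:5))
  # permutation invariance of the selected set
  perm <- sample(nrow(norm$values))
  norm_p <- norm
  norm_p$values <- norm$values[perm, , drop = FALSE]
  expect_equal(select_reference_samples(norm_p, k = 10), refs)
  expect_error(select_reference_samples(norm, k = 1), "parameter error")
  expect_error(select_reference_samples(norm, k = 20), "parameter error")
})

test_that("ratios are exact in the noiseless limit and mean 1 over references", {
  m <- rct_manifest()
  cfg <- noiseless_config(n_samples = 20, seed = 6)
  truth <- simulate_truth(cfg)
  truth$copies["S010", "CETP"] <- 1L
  peaks <- simulate_mlpa_peaks(truth, m, cfg)
  norm <- intra_sample_normalize(peaks, m)
  refs <- select_reference_samples(norm, k = 8)
  ratios <- compute_ratios(norm, refs)
  expect_equal(unname(ratios$ratios["S010", "CETP_T1"]), 0.5, tolerance = 1e-9)
  others <- setdiff(rownames(ratios$ratios), "S010")
  expect_true(all(abs(ratios$ratios[others, ] - 1) < 1e-9))
  expect_true(all(abs(colMeans(ratios$ratios[refs, ]) - 1) < 1e-12))
  # idempotence: re-normalizing the ratio matrix against the same reference
  # samples returns it unchanged
  again <- compute_ratios(ratios$ratios, refs)
  expect_equal(again$ratios, ratios$ratios, tolerance = 1e-12)
})

test_that("diploid ratios stay within the lognormal envelope at sigma 0.05", {
  m <- rct_manifest()
  cfg <- simulation_config(n_samples = 100, seed = 31, loss_freq = 0,
                           snp_artifact_freq = 0, denat_fail_freq = 0)
  coh <- simulate_cohort(cfg, m)
  ratios <- normalize_cohort(coh$mlpa, m)
  inside <- mean(ratios$ratios >= 0.85 & ratios$ratios <= 1.15)
  expect_gte(inside, 0.98)
})

test_that("probe IQR QC flags only over-dispersed target probes", {
  m <- rct_manifest()
  cfg <- noiseless_config(n_samples = 30, seed = 9)
  coh <- simulate_cohort(cfg, m)
  ratios <- normalize_cohort(coh$mlpa, m)
  qc0 <- probe_iqr_qc(ratios, m)
  expect_true(all(qc0$iqr < 1e-9))
  expect_false(any(qc0$flagged))

  cfg2 <- simulation_config(n_samples = 100, seed = 9, loss_freq = 0,
                            snp_artifact_freq = 0, denat_fail_freq = 0)
  coh2 <- simulate_cohort(cfg2, m)
  ratios2 <- normalize_cohort(coh2$mlpa, m)
  qc2 <- probe_iqr_qc(ratios2, m)
  # target IQRs sit within the reference-probe envelope
  expect_false(any(qc2$flagged))
  # tripling one probe's noise blows its IQR past the envelope
  noisy <- coh2$mlpa
  set.seed(99)
  noisy$values[, "LCAT_T1"] <- noisy$values[, "LCAT_T1"] *
    exp(rnorm(nrow(noisy$values), 0, 0.15))
  ratios3 <- normalize_cohort(peak_table(noisy$values, "mlpa"), m)
  qc3 <- probe_iqr_qc(ratios3, m)
  expect_true(qc3$flagged[qc3$probe_id == "LCAT_T1"])
})

test_that("replicate sd matches the two-point closed form and flags inconsistency", {
  m <- tiny_manifest()
  base <- matrix(1, 3, 7, dimnames = list(
    paste0("S", 1:3), m$probe_id[m$role %in% c("target", "reference")]))
  r1 <- as_ratio_matrix(base)
  r2 <- as_ratio_matrix(base)
  res0 <- replicate_sd(list(r1, r2))
  expect_true(all(res0$sd == 0))
  expect_true(all(res0$consistent))
  # one cell differing by 0.1 across the two runs: sd = 0.1/sqrt(2) ~ 0.0707
  r2$ratios["S2", "CETP_T1"] <- 1.1
  res <- replicate_sd(list(r1, r2))
  expect_equal(unname(res$sd["S2", "CETP_T1"]), 0.1 / sqrt(2), tolerance = 1e-12)
  expect_false(res$consistent["S2", "CETP_T1"])
  expect_error(replicate_sd(list(r1)), "single run")
})

test_that("reproducible flagged ratios across replicate runs are consistent", {
  m <- rct_manifest()
  base_cfg <- list(n_samples = 60, loss_freq = 0, snp_artifact_freq = 0,
                   denat_fail_freq = 0)
  run_once <- function(seed) {
    cfg <- do.call(simulation_config, c(base_cfg, seed = seed))
    truth <- simulate_truth(cfg)
    truth$copies["S020", "CETP"] <- 1L
    normalize_cohort(simulate_mlpa_peaks(truth, m, cfg), m)
  }
  runs <- list(run_once(101), run_once(102))
  res <- replicate_sd(runs)
  # the genuine loss reproduces with small across-run sd
  expect_true(res$consistent["S020", "CETP_T1"])
  expect_lt(res$mean["S020", "CETP_T1"], 0.7)
})
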