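test_that("generators are deterministic under a fixed seed", {
  cfg <- simulation_config(n_samples = 20, seed = 42)
  m <- rct_manifest()
  t1 <- simulate_truth(cfg); t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)
  expect_identical(simulate_mlpa_peaks(t1, m, cfg)$values,
                   simulate_mlpa_peaks(t2, m, cfg)$values)
  expect_identical(simulate_count_table(t1, m, cfg)$values,
                   simulate_count_table(t2, m, cfg)$values)
  expect_identical(simulate_expression(t1, cfg), simulate_expression(t2, cfg))
  expect_identical(simulate_sample_sheet(cfg, t1), simulate_sample_sheet(cfg, t2))
  # a different seed changes the draw
  t3 <- simulate_truth(simulation_config(n_samples = 20, seed = 43))
  expect_false(identical(t1$amplification, t3$amplification))
})

test_that("zero-frequency config yields an all-diploid, flagless truth", {
  cfg <- noiseless_config(n_samples = 30, seed = 5)
  truth <- simulate_truth(cfg)
  expect_true(all(truth$copies == 2L))
  expect_equal(nrow(truth$snp_artifact), 0)
  expect_length(truth$denaturation_failure, 0)
})

test_that("non-diploid count falls in the Poisson band of its analytic mean", {
  cfg <- simulation_config(n_samples = 320, loss_freq = 0.003, seed = 11,
                           snp_artifact_freq = 0, denat_fail_freq = 0)
  truth <- simulate_truth(cfg)
  lambda <- 320 * 16 * 0.003  # n x genes x loss_freq = 15.36
  count <- sum(truth$copies != 2L)
  expect_gte(count, qpois(0.005, lambda))
  expect_lte(count, qpois(0.995, lambda))
})

test_that("noiseless peaks follow the copies/2 dosage law", {
  m <- rct_manifest()
  cfg <- noiseless_config(n_samples = 10, seed = 2)
  truth <- simulate_truth(cfg)
  truth$copies["S003", "CETP"] <- 1L
  peaks <- simulate_mlpa_peaks(truth, m, cfg)
  ref_level <- peaks$values["S001", "Ref_1"]
  # all-diploid sample: every target equals every reference peak
  expect_equal(unname(peaks$values["S001", m$probe_id[m$role == "target"]]),
               rep(ref_level, 16))
  # single-copy CETP: exactly half the reference level
  expect_equal(unname(peaks$values["S003", "CETP_T1"]), ref_level / 2)
  expect_equal(unname(peaks$values["S003", "Ref_5"]), ref_level)
  # denaturation controls are silent in normal samples
  expect_true(all(peaks$values[, c("Ref_17", "Ref_19")] == 0))
})

test_that("ligation-site heterozygotes halve the MLPA probe but not the count probe", {
  m <- rct_manifest()
  cfg <- noiseless_config(n_samples = 10, seed = 2)
  truth <- simulate_truth(cfg)
  truth$snp_artifact <- data.frame(sample_id = "S004", gene = "APOA4",
                                   stringsAsFactors = FALSE)
  peaks <- simulate_mlpa_peaks(truth, m, cfg)
  counts <- simulate_count_table(truth, m, cfg)
  expect_equal(unname(peaks$values["S004", "APOA4_T1"]),
               unname(peaks$values["S004", "Ref_1"]) / 2)
  expect_equal(unname(counts$values["S004", "APOA4_T1"]),
               unname(counts$values["S001", "APOA4_T1"]))
})

test_that("denaturation-failure samples fire the denaturation controls", {
  m <- rct_manifest()
  cfg <- noiseless_config(n_samples = 10, seed = 2)
  truth <- simulate_truth(cfg)
  truth$denaturation_failure <- "S007"
  peaks <- simulate_mlpa_peaks(truth, m, cfg)
  ref_level <- peaks$values["S007", "Ref_1"]
  expect_equal(unname(peaks$values["S007", "Ref_17"]), ref_level)
  # and their target signal is globally depressed
  expect_equal(unname(peaks$values["S007", "CETP_T1"]), ref_level / 2)
  expect_true(all(peaks$values["S002", c("Ref_17", "Ref_19")] == 0))
})

test_that("expression follows the configured dosage slope exactly when noiseless", {
  cfg0 <- noiseless_config(n_samples = 10, seed = 2, beta_expr = 0)
  truth <- simulate_truth(cfg0)
  truth$copies["S002", "LCAT"] <- 4L
  truth$copies["S003", "LCAT"] <- 1L
  x0 <- simulate_expression(truth, cfg0)
  # beta 0: expression independent of copies
  expect_equal(x0["S002", "LCAT"], x0["S001", "LCAT"])
  cfg1 <- noiseless_config(n_samples = 10, seed = 2, beta_expr = 1)
  x1 <- simulate_expression(truth, cfg1)
  mu <- x1["S001", "LCAT"]  # diploid baseline
  expect_equal(x1["S002", "LCAT"], mu + 1)
  expect_equal(x1["S003", "LCAT"], mu - 1)
  # homozygous deletion is floored, not -Inf
  truth$copies["S004", "LCAT"] <- 0L
  x2 <- simulate_expression(truth, cfg1)
  expect_equal(x2["S004", "LCAT"], mu - 5)
})

test_that("the sample sheet has plausible lipid and therapy structure", {
  cfg <- simulation_config(n_samples = 320, seed = 13)
  sheet <- simulate_sample_sheet(cfg)
  expect_equal(nrow(sheet), 320)
  expect_true(all(sheet$hdl > 0))
  expect_true(all(is.na(sheet$ldl) | sheet$ldl > 0))
  expect_true(all(sheet$trig > 0) && all(sheet$tchol > 0))
  # both extreme HDL strata are represented
  expect_gt(sum(sheet$hdl <= 40), 0)
  expect_gt(sum(sheet$hdl >= 60), 0)
  expect_gt(sum(is.na(sheet$ldl)), 0)
  # fraction of HIV+ on any therapy: binomial 99% band around 0.70
  pos <- sheet[sheet$hiv_positive, ]
  on_tx <- sum(pos$therapy %in% c("mono", "combination", "potent_art"))
  expect_gte(on_tx, qbinom(0.005, nrow(pos), 0.70))
  expect_lte(on_tx, qbinom(0.995, nrow(pos), 0.70))
})

test_that("the known-copy control panel obeys the dosage law and is recoverable", {
  m <- rct_manifest(multicopy = TRUE)
  cfg <- noiseless_config(n_samples = 10, seed = 4)
  ctl <- simulate_multicopy_controls(cfg, m)
  raw <- ctl$peaks$values[, "DEFB103A_T1"] / ctl$peaks$values[, "Ref_1"]
  expect_equal(unname(raw), c(1.0, 1.5, 2.0, 2.5, 3.0, 3.5))
  # a panel of a single diploid entry
  cfg1 <- noiseless_config(n_samples = 10, seed = 4, multicopy_panel = 2L)
  ctl1 <- simulate_multicopy_controls(cfg1, m)
  expect_equal(nrow(ctl1$peaks$values), 1)
  expect_equal(unname(ctl1$truth$copies[, "DEFB103A"]), 2L)
  # missing multicopy probe is an error
  expect_error(simulate_multicopy_controls(cfg, rct_manifest()), "multicopy")
})

test_that("log peak means match the generative model for diploid samples", {
  m <- rct_manifest()
  cfg <- simulation_config(n_samples = 200, seed = 21, loss_freq = 0,
                           snp_artifact_freq = 0, denat_fail_freq = 0,
                           amp_sd = 0, probe_eff_sd = 0, sigma_mlpa = 0.05)
  truth <- simulate_truth(cfg)
  peaks <- simulate_mlpa_peaks(truth, m, cfg)
  # with A_s = E_p = 1 the mean log peak per probe estimates log(base) with
  # standard error sigma/sqrt(n); check a 4-sigma envelope on a few probes
  logs <- log(peaks$values[, c("CETP_T1", "ABCA1_T1", "Ref_1", "Ref_9")])
  se <- 0.05 / sqrt(200)
  expect_true(all(abs(colMeans(logs) - log(1000)) < 4 * se))
  probe_sd <- apply(logs, 2, sd)
  expect_true(all(abs(probe_sd - 0.05) < 4 * 0.05 / sqrt(2 * 199)))
})
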