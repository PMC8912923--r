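make_ewas_stub <- function(q, amp, ids = sprintf("cpg%06d", seq_along(q)),
                           peak = NULL) {
  df <- data.frame(cpg_id = ids, q_value = q, amplitude_pct = amp,
                   peak_day = if (is.null(peak))
                     seq(0, 360, length.out = length(q)) else peak,
                   stringsAsFactors = FALSE)
  class(df) <- c("ewas_table", "data.frame")
  df
}

test_that("hit selection filters on FDR and amplitude jointly", {
  ew <- make_ewas_stub(q = c(0.04, 0.04, 0.06, 0.01),
                       amp = c(5.0, 3.9, 10, 4.0))
  hits <- select_soc_cpgs(ew)
  # q<0.05 & amp>=4: rows 1 and 4; amplitude 3.9 and q 0.06 are excluded
  expect_setequal(hits$cpg_ids, c("cpg000001", "cpg000004"))
  expect_equal(hits$provenance$fdr_threshold, 0.05)
  expect_equal(hits$provenance$min_amplitude_pct, 4)
  # pure filter: output is a subset of input rows
  expect_true(all(hits$cpg_ids %in% ew$cpg_id))
})

test_that("KS matching accepts identical and rejects disjoint distributions", {
  # identical distributions: KS p = 1, accepted
  mat <- make_beta_matrix(100, col_means = c(0.5, 0.5, 0.1, 0.9))
  mat$betas[, 2] <- mat$betas[, 1]  # identical vector
  tg <- cpg_set("soc_cpg", "cpg000001")
  mc <- select_matched_controls(tg, mat, seed = 1)
  expect_equal(length(mc), 1L)
  expect_false(mc$cpg_ids %in% tg$cpg_ids)
  # the accepted control satisfies KS p > 0.1 post hoc
  ksp <- suppressWarnings(
    ks.test(mat$betas[, tg$cpg_ids], mat$betas[, mc$cpg_ids]))$p.value
  expect_gt(ksp, 0.1)

  # all-divergent background: no admissible candidate
  mat2 <- make_beta_matrix(100, col_means = c(0.1, 0.9))
  expect_error(
    select_matched_controls(cpg_set("soc_cpg", "cpg000001"), mat2),
    "no admissible matched control")
})

test_that("KS statistic equals the brute-force max CDF gap", {
  set.seed(17)
  x <- runif(40); y <- runif(35, 0.2, 1)
  d_oracle <- max(vapply(sort(c(x, y)), function(t)
    abs(mean(x <= t) - mean(y <= t)), numeric(1)))
  ks <- suppressWarnings(ks.test(x, y))
  expect_equal(unname(ks$statistic), d_oracle, tolerance = 1e-12)
})

test_that("matched controls are disjoint from targets and exclusions", {
  set.seed(18)
  mat <- make_beta_matrix(80, col_means = rep(0.5, 40), noise_sd = 0.05)
  targets <- cpg_set("soc_cpg", sprintf("cpg%06d", 1:5))
  excl <- cpg_set("me", sprintf("cpg%06d", 6:10))
  mc <- select_matched_controls(targets, mat, exclusions = list(excl),
                                seed = 2)
  expect_equal(length(mc), 5L)
  expect_length(intersect(mc$cpg_ids, targets$cpg_ids), 0)
  expect_length(intersect(mc$cpg_ids, excl$cpg_ids), 0)
  # reproducible under seed
  mc2 <- select_matched_controls(targets, mat, exclusions = list(excl),
                                 seed = 2)
  expect_identical(mc$cpg_ids, mc2$cpg_ids)
  # every accepted match re-checks above the threshold
  prov <- mc$provenance$match
  expect_true(all(prov$ks_p > 0.1))
})

test_that("random controls sample uniformly without replacement", {
  bg <- sprintf("cpg%06d", 1:30)
  excl <- cpg_set("soc_cpg", bg[1:10])
  rc <- select_random_controls(20, bg, exclusions = list(excl), seed = 3)
  expect_equal(length(rc), 20L)
  expect_length(intersect(rc$cpg_ids, excl$cpg_ids), 0)
  # n = pool size returns the whole pool
  expect_setequal(rc$cpg_ids, bg[11:30])
  expect_identical(select_random_controls(20, bg, list(excl), seed = 3)$cpg_ids,
                   rc$cpg_ids)
  expect_error(select_random_controls(25, bg, list(excl)), "insufficient")
})

test_that("self-replication gives rho 1 and Wilcoxon p 1", {
  ew <- make_ewas_stub(q = runif(20, 0, 0.04), amp = runif(20, 4, 10))
  rep <- replication_stats(ew, ew, cpg_set("soc_cpg", ew$cpg_id))
  expect_equal(rep$phase_rho, 1)
  expect_equal(rep$wilcoxon_p, 1)
  expect_equal(rep$median_delta, 0)
  expect_equal(rep$n_replicated, 20)
  expect_error(replication_stats(ew, ew, ew$cpg_id[1:2]), "fewer than 3")
})

test_that("simulated attenuation is detected by the signed-rank test", {
  set.seed(19)
  amp_a <- runif(100, 4, 12)
  ew_a <- make_ewas_stub(q = runif(100, 0, 0.04), amp = amp_a)
  ew_b <- make_ewas_stub(q = runif(100, 0, 0.04), amp = amp_a / 2,
                         ids = ew_a$cpg_id, peak = ew_a$peak_day)
  rep <- replication_stats(ew_a, ew_b, ew_a$cpg_id)
  expect_lt(rep$wilcoxon_p, 1e-10)
  expect_equal(rep$median_delta / median(amp_a), -0.5, tolerance = 0.15)

  # noisy but correlated peak days replicate
  ew_c <- ew_a
  ew_c$peak_day <- pmin(pmax(ew_a$peak_day + runif(100, -30, 30), 0), 365)
  rep2 <- replication_stats(ew_a, ew_c, ew_a$cpg_id)
  expect_gt(rep2$phase_rho, 0.5)
  expect_lt(rep2$phase_p, 1e-4)
})

test_that("replication cohorts replicate phase and reveal attenuation", {
  cfg <- sim_config(n_samples = 200, n_cpgs = 400, n_hit_cpgs = 60,
                    amplitude_logit = 0.25, n_snps = 10, n_mqtl = 0,
                    seed = 91)
  coh_a <- simulate_cohort(cfg)
  coh_b <- simulate_replication_cohort(coh_a, seed = 92,
                                       amplitude_scale = 0.5)
  # shared truth: same loci, peaks; halved amplitudes
  expect_identical(coh_b$truth$cpgs$cpg_id, coh_a$truth$cpgs$cpg_id)
  expect_identical(coh_b$truth$cpgs$true_peak_day,
                   coh_a$truth$cpgs$true_peak_day)
  hits <- coh_a$truth$cpgs$is_hit
  expect_lt(max(coh_b$truth$cpgs$true_amplitude_pct[hits] /
                  coh_a$truth$cpgs$true_amplitude_pct[hits]), 0.52)

  ew_a <- run_ewas(coh_a$methylation, coh_a$metadata,
                   covariate_matrix(coh_a$metadata, c("sex", "age", "batch")))
  ew_b <- run_ewas(coh_b$methylation, coh_b$metadata,
                   covariate_matrix(coh_b$metadata, c("sex", "age", "batch")))
  rp <- replication_stats(ew_a, ew_b, coh_a$truth$cpgs$cpg_id[hits])
  expect_gt(rp$phase_rho, 0.5)
  expect_lt(rp$phase_p, 1e-4)
  expect_lt(rp$wilcoxon_p, 1e-6)
  expect_lt(rp$median_delta, 0)
})

test_that("Pratt signed-rank agrees with wilcox.test when zero-free", {
  set.seed(20)
  d <- rnorm(40, 0.3)
  ours <- socewas:::wilcoxon_pratt(d)
  ref <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  # zeros reduce the statistic but keep a valid p
  d0 <- c(d, rep(0, 10))
  ours0 <- socewas:::wilcoxon_pratt(d0)
  expect_true(ours0$p >= 0 && ours0$p <= 1)
})
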