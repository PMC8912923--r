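test_that("SNP filters drop low-MAF and low-homozygote variants", {
  set.seed(41)
  n <- 300
  d_keep <- rbinom(n, 2, 0.3)
  # exactly 10% MAF: excluded (threshold is exclusive)
  d_maf10 <- c(rep(1L, as.integer(0.2 * n)), rep(0L, n - as.integer(0.2 * n)))
  # common but only 9 minor homozygotes
  d_low_hom <- c(rep(2L, 9), rep(1L, 100), rep(0L, n - 109))
  g <- make_genotypes(cbind(keep = d_keep, maf10 = d_maf10,
                            lowhom = d_low_hom))
  suppressMessages(f <- filter_snps(g))
  expect_identical(f$snp_ids, "keep")
  expect_gt(f$maf, 0.10)
  expect_gte(f$n_hom, 10)
})

test_that("cis/trans labelling flips exactly at the 1 Mb boundary", {
  set.seed(43)
  n <- 120
  betas <- matrix(pmin(pmax(rnorm(n, 0.5, 0.05), 0.01), 0.99), n, 1,
                  dimnames = list(sprintf("S%03d", 1:n), "cpgA"))
  mat <- methylation_matrix(betas, "chr1", 2e6)
  dos <- cbind(near = rbinom(n, 2, 0.3), far = rbinom(n, 2, 0.3),
               other = rbinom(n, 2, 0.3))
  g <- make_genotypes(dos, chrom = c("chr1", "chr1", "chr2"),
                      pos = c(2e6 + 999999L, 2e6 + 1000001L, 5e5))
  res <- mqtl_scan(mat, g, keep_all = TRUE)
  expect_setequal(res$scope[res$snp_id == "near"], "cis")
  expect_setequal(res$scope[res$snp_id == "far"], "trans")
  expect_setequal(res$scope[res$snp_id == "other"], "trans")
})

test_that("per-SNP effects equal the lm oracle", {
  set.seed(47)
  n <- 150
  covs <- cbind(sex = sample(0:1, n, TRUE), pc1 = rnorm(n))
  g1 <- rbinom(n, 2, 0.35)
  g2 <- rbinom(n, 2, 0.2)
  m <- 0.5 + 0.25 * g1 + 0.1 * covs[, "sex"] + rnorm(n, 0, 0.4)
  a <- socewas:::.snp_assoc(m, cbind(g1, g2), covs)
  ref1 <- summary(lm(m ~ covs + g1))$coefficients["g1", ]
  ref2 <- summary(lm(m ~ covs + g2))$coefficients["g2", ]
  expect_equal(a$effect, unname(c(ref1[1], ref2[1])), tolerance = 1e-10)
  expect_equal(a$p, unname(c(ref1[4], ref2[4])), tolerance = 1e-10)
})

test_that("a spiked cis-SNP is discovered; null genotypes are not", {
  set.seed(53)
  n <- 284
  g_dos <- cbind(hit = rbinom(n, 2, 0.3),
                 null1 = rbinom(n, 2, 0.3),
                 null2 = rbinom(n, 2, 0.4))
  m <- 0 + 0.15 * g_dos[, "hit"] + rnorm(n, 0, 0.3)
  betas <- matrix(m_to_beta(m), n, 1,
                  dimnames = list(sprintf("S%03d", 1:n), "cpgA"))
  mat <- methylation_matrix(betas, "chr1", 5e6)
  g <- make_genotypes(g_dos, chrom = rep("chr1", 3),
                      pos = c(5e6 + 1e4, 5e6 + 2e4, 5e6 + 3e4))
  res <- mqtl_scan(mat, g)
  expect_true("hit" %in% res$snp_id[res$significant])
  expect_false(any(c("null1", "null2") %in%
                     res$snp_id[res$q < 0.05 & res$snp_id != "hit"]))
})

test_that("variance explained matches the adjusted-R2 formula and lm", {
  set.seed(59)
  n <- 200
  covs <- cbind(age = rnorm(n), sex = sample(0:1, n, TRUE))
  g <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4))
  m <- 0.2 * g[, 1] + 0.1 * covs[, "age"] + rnorm(n, 0, 0.4)
  ve <- variance_explained(m, g, covs)
  f_full <- summary(lm(m ~ covs + g))
  f_cov <- summary(lm(m ~ covs))
  expect_equal(ve$adj_r2_full, f_full$adj.r.squared, tolerance = 1e-12)
  expect_equal(ve$adj_r2_cov, f_cov$adj.r.squared, tolerance = 1e-12)
  expect_equal(ve$delta_adj_r2,
               f_full$adj.r.squared - f_cov$adj.r.squared)
  # direct formula on a small instance
  r2 <- f_full$r.squared
  p <- ncol(covs) + ncol(g)
  expect_equal(ve$adj_r2_full, 1 - (1 - r2) * (n - 1) / (n - p - 1))

  # zero-effect SNP at large n: delta ~ 0
  set.seed(61)
  n2 <- 1000
  m2 <- rnorm(n2)
  ve0 <- variance_explained(m2, cbind(rbinom(n2, 2, 0.3)), NULL)
  expect_lt(abs(ve0$delta_adj_r2), 0.01)

  expect_error(variance_explained(m2, matrix(numeric(0), n2, 0)),
               "at least one")
  expect_error(variance_explained(rnorm(5), matrix(rbinom(30, 2, .3), 5)),
               "degrees of freedom")
})

test_that("GxE scan picks the dominant Fourier term and finds interactions", {
  set.seed(67)
  n <- 300
  theta <- runif(n, 0, 2 * pi)
  g_dos <- cbind(gxe = rbinom(n, 2, 0.3), null = rbinom(n, 2, 0.3))
  # strong sin main effect plus G x sin interaction
  m <- 0.4 * sin(theta) + 0.3 * g_dos[, "gxe"] * sin(theta) +
    rnorm(n, 0, 0.3)
  main <- fit_cosinor(m, theta)
  expect_lt(main$term_pvalues["sin1theta"],
            main$term_pvalues["cos1theta"])
  g <- make_genotypes(g_dos)
  res <- gxe_scan(m, g, theta, main_fit = main)
  expect_equal(unique(res$term), "sin")
  expect_lt(res$q[res$snp_id == "gxe"], 0.05)
  expect_gt(res$p[res$snp_id == "null"], 0.001)

  # interaction estimate matches the lm oracle
  ref <- summary(lm(m ~ sin(theta) * g_dos[, "gxe"]))$coefficients
  expect_equal(res$interaction_effect[res$snp_id == "gxe"],
               ref["sin(theta):g_dos[, \"gxe\"]", 1], tolerance = 1e-10)

  # cos-dominant fit selects the cos variant
  m2 <- 0.4 * cos(theta) + rnorm(n, 0, 0.3)
  main2 <- fit_cosinor(m2, theta)
  res2 <- gxe_scan(m2, g, theta, main_fit = main2)
  expect_equal(unique(res2$term), "cos")
})

test_that("genotype-season association is calibrated and powered", {
  set.seed(71)
  n <- 284
  theta <- runif(n, 0, 2 * pi)
  md <- data.frame(sample_id = sprintf("S%03d", 1:n), theta = theta)

  # null: dosages independent of season
  g_null <- make_genotypes(matrix(rbinom(n * 40, 2, 0.3), n, 40))
  res_null <- soc_genotype_association(g_null, md)
  expect_lt(mean(res_null$p < 0.05), 0.15)

  # dosage correlated with sin(theta): detected
  liab <- 0.35 * scale(sin(theta))[, 1] + rnorm(n, 0, sqrt(1 - 0.35^2))
  d_cor <- as.integer(cut(liab, quantile(liab, c(0, 0.5, 0.85, 1)),
                          include.lowest = TRUE)) - 1L
  g_cor <- make_genotypes(matrix(d_cor, n, 1))
  res_cor <- soc_genotype_association(g_cor, md)
  expect_lt(res_cor$p, 0.001)

  # dichotomised mode reproduces the textbook chi-square on a 2x2 table
  day <- theta / (2 * pi) * 365.25
  rainy <- c(182, 304); dry <- c(335, 151)
  res_di <- soc_genotype_association(
    g_cor, md, mode = "dichotomised",
    season_windows = list(rainy, dry))
  in_w <- function(w) if (w[1] <= w[2]) day >= w[1] & day <= w[2] else
    day >= w[1] | day <= w[2]
  a <- sum(d_cor[in_w(rainy)]); b <- 2 * sum(in_w(rainy)) - a
  c_ <- sum(d_cor[in_w(dry)]); d_ <- 2 * sum(in_w(dry)) - c_
  tab <- rbind(c(a, b), c(c_, d_))
  N <- sum(tab)
  chi_hand <- N * (a * d_ - b * c_)^2 /
    ((a + b) * (c_ + d_) * (a + c_) * (b + d_))
  expect_equal(unname(res_di$stat), chi_hand, tolerance = 1e-10)

  expect_error(soc_genotype_association(g_cor, md, mode = "dichotomised",
                                        season_windows = list(c(400, 500),
                                                              dry)),
               "empty")
})
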