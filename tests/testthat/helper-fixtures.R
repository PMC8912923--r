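# Shared fixture builders. Everything is generated in code at test time.

# M-values following the single-pair cosinor model exactly
make_seasonal_m <- function(n = 200, beta1 = 1, gamma1 = 0, intercept = 0,
                            noise_sd = 0, seed = 1) {
  set.seed(seed)
  theta <- runif(n, 0, 2 * pi)
  m <- intercept + beta1 * sin(theta) + gamma1 * cos(theta) +
    rnorm(n, 0, noise_sd)
  list(m = m, theta = theta)
}

# genotype_matrix from an explicit dosage matrix
make_genotypes <- function(dosages, chrom = NULL, pos = NULL) {
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("snp%03d", seq_len(ncol(dosages)))
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("S%03d", seq_len(nrow(dosages)))
  }
  if (is.null(chrom)) chrom <- rep("chr1", ncol(dosages))
  if (is.null(pos)) pos <- seq_len(ncol(dosages)) * 1000L
  genotype_matrix(dosages, chrom, pos)
}

# small methylation_matrix with one intermediate CpG per column mean
make_beta_matrix <- function(n_samples, col_means, noise_sd = 0.02,
                             seed = 1) {
  set.seed(seed)
  betas <- vapply(col_means, function(mu)
    pmin(pmax(rnorm(n_samples, mu, noise_sd), 0.001), 0.999),
    numeric(n_samples))
  colnames(betas) <- sprintf("cpg%06d", seq_along(col_means))
  rownames(betas) <- sprintf("S%03d", seq_len(n_samples))
  methylation_matrix(betas, rep("chr1", length(col_means)),
                     seq_along(col_means) * 50000L)
}

# circular mean in day-of-year units
circular_mean_day <- function(dates, year_len = 365) {
  th <- 2 * pi * (as.numeric(strftime(dates, "%j")) - 1) / year_len
  (atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)) / (2 * pi) * year_len
}

# two-sided Fisher p by brute-force hypergeometric enumeration
hypergeom_p <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  lo <- max(0, k - n_); hi <- min(k, m)
  dens <- dhyper(lo:hi, m, n_, k)
  sum(dens[dens <= dhyper(a, m, n_, k) * (1 + 1e-7)])
}
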