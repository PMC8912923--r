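#' Configuration for a synthetic methylation cohort
#'
#' Bundles and validates all generator parameters. Defaults describe a
#' realistic single-site cohort: year-round conceptions, intermediate
#' methylation at seasonally responsive CpGs, a logit2-scale seasonal
#' half-amplitude of 0.173 (about a 6 percentage-point beta-scale
#' peak-to-nadir amplitude at baseline 0.5), residual M-value noise of
#' 0.3 SD, modest batch/sex/age/cell-composition structure, and common
#' SNPs with spiked cis effects on a subset of CpGs.
#'
#' @param n_samples Number of samples.
#' @param n_cpgs Number of CpGs.
#' @param n_hit_cpgs Number of truly seasonal CpGs.
#' @param amplitude_logit Seasonal half-amplitude on the logit2 (M-value)
#'   scale; the peak-to-nadir M difference is twice this.
#' @param peak_day Day of year (in \code{[0, 365)}) of the central
#'   methylation maximum of seasonal CpGs.
#' @param peak_day_sd Between-CpG spread (SD, days) of per-hit peak days
#'   around \code{peak_day}, reproducing the heterogeneous year-round
#'   phases seen at seasonally responsive loci; 0 gives a common phase.
#' @param baseline_beta Baseline methylation fraction of seasonal CpGs,
#'   strictly inside (0, 1).
#' @param noise_sd_logit Residual SD on the M-value scale.
#' @param covariate_effects Named numeric vector of logit2-scale
#'   coefficients for \code{sex}, \code{age}, \code{batch} and
#'   \code{intervention} effects (any subset).
#' @param n_batches Number of processing batches.
#' @param n_cell_factors Number of latent cell-composition factors.
#' @param cell_loading_sd SD of per-CpG loadings on each latent factor.
#' @param conception_concentration Von Mises concentration of conception
#'   dates around \code{peak_day}; 0 (default) gives uniform year-round
#'   conceptions.
#' @param n_snps Number of SNPs to simulate.
#' @param n_mqtl Number of CpGs given a dedicated cis-SNP effect.
#' @param maf_range Minor-allele-frequency sampling range; must lie within
#'   (0.10, 0.5] so every SNP can pass the MAF filter.
#' @param mqtl_effect_logit Per-dose effect of a spiked cis-SNP on its
#'   CpG's M-value.
#' @param cluster_gap_bp Maximum intra-cluster gap used when placing
#'   clustered CpGs.
#' @param enrichment_fold Target fold-enrichment of annotation tracks at
#'   seasonal CpGs relative to background.
#' @param year Calendar year in which conceptions are placed.
#' @param seed Integer seed making the whole cohort reproducible.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 250, n_cpgs = 2000, n_hit_cpgs = 50,
                       amplitude_logit = 0.173, peak_day = 240,
                       peak_day_sd = 45,
                       baseline_beta = 0.5, noise_sd_logit = 0.3,
                       covariate_effects = c(sex = 0.05, age = 0.02,
                                             batch = 0.1,
                                             intervention = 0),
                       n_batches = 2, n_cell_factors = 2,
                       cell_loading_sd = 0.1,
                       conception_concentration = 0,
                       n_snps = 100, n_mqtl = 20,
                       maf_range = c(0.15, 0.5),
                       mqtl_effect_logit = 0.15,
                       cluster_gap_bp = 5000, enrichment_fold = 10,
                       year = 2011, seed = 1L) {
  cfg <- list(n_samples = n_samples, n_cpgs = n_cpgs,
              n_hit_cpgs = n_hit_cpgs, amplitude_logit = amplitude_logit,
              peak_day = peak_day, peak_day_sd = peak_day_sd,
              baseline_beta = baseline_beta,
              noise_sd_logit = noise_sd_logit,
              covariate_effects = covariate_effects,
              n_batches = n_batches, n_cell_factors = n_cell_factors,
              cell_loading_sd = cell_loading_sd,
              conception_concentration = conception_concentration,
              n_snps = n_snps, n_mqtl = n_mqtl, maf_range = maf_range,
              mqtl_effect_logit = mqtl_effect_logit,
              cluster_gap_bp = cluster_gap_bp,
              enrichment_fold = enrichment_fold,
              year = year, seed = as.integer(seed))
  if (n_samples < 1 || n_cpgs < 1) stop("need at least one sample and CpG")
  if (n_hit_cpgs > n_cpgs) stop("n_hit_cpgs exceeds n_cpgs")
  if (baseline_beta <= 0 || baseline_beta >= 1) {
    stop("baseline_beta must lie strictly inside (0, 1)")
  }
  if (peak_day < 0 || peak_day >= 365) stop("peak_day must lie in [0, 365)")
  if (peak_day_sd < 0) stop("peak_day_sd must be >= 0")
  if (conception_concentration < 0) stop("concentration must be >= 0")
  if (noise_sd_logit < 0) stop("noise_sd_logit must be >= 0")
  if (maf_range[1] <= 0.10 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0.10, 0.5]")
  }
  class(cfg) <- "sim_config"
  cfg
}

# von Mises sampler (Best & Fisher rejection scheme); kappa = 0 is uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

#' Simulate conception dates around the year
#'
#' Draws conception days of year from a von Mises (circular normal)
#' density centred on \code{peak_day}; concentration 0 gives uniform
#' year-round conceptions, increasing values concentrate conceptions
#' around the peak.
#'
#' @param n Number of dates (>= 1).
#' @param concentration Von Mises concentration parameter, >= 0.
#' @param peak_day Day of year of the circular mean.
#' @param year Calendar year for the emitted dates. Default 2011.
#' @param seed Optional integer seed; \code{NULL} uses the current RNG
#'   stream.
#' @return \code{Date} vector of length \code{n}.
#' @export
simulate_conception_dates <- function(n, concentration = 0, peak_day = 240,
                                      year = 2011, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (concentration < 0) stop("concentration must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  year_len <- if (is_leap_year(year)) 366 else 365
  mu <- 2 * pi * peak_day / year_len
  theta <- rvonmises(n, mu, concentration)
  day <- floor(theta / (2 * pi) * year_len)
  as.Date(paste0(year, "-01-01")) + day
}

#' Simulate a seasonally varying CpG
#'
#' Builds M-values as \code{logit2(baseline) + amplitude *
#' cos(theta - theta_peak) + noise} and back-transforms to the beta scale,
#' the generative inverse of the single-pair cosinor model. With zero
#' amplitude and zero noise every value equals \code{baseline_beta}.
#'
#' @param dates \code{Date} vector of conception dates (non-empty).
#' @param baseline_beta Baseline methylation fraction in (0, 1).
#' @param amplitude_logit Seasonal half-amplitude on the M-value scale.
#' @param peak_day Day of year of the methylation maximum.
#' @param noise_sd_logit Residual M-value SD, >= 0.
#' @param year_days Days per year used to convert \code{peak_day} to an
#'   angle. Default 365.25.
#' @param seed Optional integer seed.
#' @return Numeric vector of beta values in (0, 1).
#' @export
simulate_seasonal_cpg <- function(dates, baseline_beta = 0.5,
                                  amplitude_logit = 0.173, peak_day = 240,
                                  noise_sd_logit = 0.3, year_days = 365.25,
                                  seed = NULL) {
  if (length(dates) == 0) stop("dates must be non-empty")
  if (baseline_beta <= 0 || baseline_beta >= 1) {
    stop("baseline_beta must lie strictly inside (0, 1)")
  }
  if (noise_sd_logit < 0) stop("noise_sd_logit must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  theta <- conception_theta(dates)
  theta_peak <- 2 * pi * peak_day / year_days
  m <- beta_to_m(baseline_beta) +
    amplitude_logit * cos(theta - theta_peak) +
    stats::rnorm(length(theta), 0, noise_sd_logit)
  m_to_beta(m)
}

#' Simulate a Hardy-Weinberg genotype dosage matrix
#'
#' Each SNP's minor-allele frequency is drawn from \code{maf_range} and
#' dosages are binomial(2, MAF) draws. Every emitted SNP is guaranteed to
#' pass the common-variant filters applied before mQTL mapping (empirical
#' MAF > 10% and at least 10 minor-allele homozygotes): SNPs failing them
#' by sampling chance are redrawn.
#'
#' @param n Number of samples.
#' @param n_snps Number of SNPs.
#' @param maf_range Length-2 range within (0.10, 0.5].
#' @param chrom,positions Optional per-SNP chromosome names and 1-based
#'   positions; defaults place SNPs uniformly along a single chromosome.
#' @param min_hom Minimum number of minor-allele homozygotes. Default 10.
#' @param seed Optional integer seed.
#' @return An object of class \code{genotype_matrix}: list with
#'   \code{dosages} (samples x SNPs, values 0/1/2), \code{snp_ids},
#'   \code{chrom}, \code{pos}, \code{maf} (empirical), \code{n_hom}.
#' @export
simulate_genotypes <- function(n, n_snps, maf_range = c(0.15, 0.5),
                               chrom = NULL, positions = NULL,
                               min_hom = 10, seed = NULL) {
  if (maf_range[1] <= 0.10 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0.10, 0.5]")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) {
    positions <- sort(sample.int(2.5e8, n_snps))
    chrom <- rep("chr1", n_snps)
  }
  dos <- matrix(0L, n, n_snps)
  maf_emp <- n_hom <- numeric(n_snps)
  for (s in seq_len(n_snps)) {
    for (try in seq_len(1000L)) {
      maf <- stats::runif(1, maf_range[1], maf_range[2])
      d <- stats::rbinom(n, 2L, maf)
      f <- mean(d) / 2
      f_min <- min(f, 1 - f)
      hom <- min(sum(d == 2L), sum(d == 0L))
      if (f_min > 0.10 && hom >= min_hom) break
      if (try == 1000L) stop("could not draw a SNP passing the filters; ",
                             "increase n or narrow maf_range")
    }
    dos[, s] <- d
    maf_emp[s] <- f_min
    n_hom[s] <- hom
  }
  snp_ids <- sprintf("snp%04d", seq_len(n_snps))
  colnames(dos) <- snp_ids
  rownames(dos) <- sprintf("S%03d", seq_len(n))
  structure(list(dosages = dos, snp_ids = snp_ids,
                 chrom = as.character(chrom), pos = as.integer(positions),
                 maf = maf_emp, n_hom = n_hom),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs, MAF %.2f-%.2f\n",
              nrow(x$dosages), ncol(x$dosages), min(x$maf), max(x$maf)))
  invisible(x)
}

#' Place CpG coordinates and enriched annotation tracks
#'
#' Assigns genomic coordinates to simulated CpGs such that a configurable
#' fraction of the designated hit CpGs fall in small clusters (pairs
#' within \code{cluster_gap_bp}) while all other CpGs are widely spaced
#' singletons, and builds annotation tracks whose overlap with hit CpGs
#' exceeds the background overlap rate by approximately
#' \code{enrichment_fold}.
#'
#' @param n_cpgs Total number of CpGs.
#' @param hit_ids Character vector of hit CpG ids; must be a subset of the
#'   generated ids \code{cpg000001..}.
#' @param cluster_gap_bp Maximum intra-cluster gap. Default 5000.
#' @param enrichment_fold Target fold-enrichment (>= 1) of track overlap
#'   at hits.
#' @param cluster_frac Fraction of hit CpGs to place in clusters.
#' @param bg_overlap_rate Background track overlap probability.
#' @param track_names Names of the tracks to generate.
#' @param seed Optional integer seed.
#' @return List with \code{coords} (data.frame \code{cpg_id},
#'   \code{chrom}, \code{pos}) and \code{tracks} (list of
#'   [annotation_track()]s).
#' @export
place_cpgs_and_tracks <- function(n_cpgs, hit_ids = character(0),
                                  cluster_gap_bp = 5000,
                                  enrichment_fold = 1,
                                  cluster_frac = 0.5,
                                  bg_overlap_rate = 0.05,
                                  track_names = "ME", seed = NULL) {
  if (enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cpg_ids <- sprintf("cpg%06d", seq_len(n_cpgs))
  if (!all(hit_ids %in% cpg_ids)) {
    stop("hit_ids must be a subset of the generated CpG ids")
  }
  n_chrom <- min(4L, n_cpgs)
  per_chrom <- ceiling(n_cpgs / n_chrom)
  slot <- seq_len(n_cpgs) - 1L
  chrom <- paste0("chr", 1L + slot %/% per_chrom)
  pos <- 50000L * (1L + slot %% per_chrom)

  # pull a fraction of hits into within-gap pairs (clusters)
  is_hit <- cpg_ids %in% hit_ids
  hit_idx <- which(is_hit)
  n_pairable <- floor(length(hit_idx) * cluster_frac / 2) * 2
  if (n_pairable >= 2) {
    paired <- sample(hit_idx, n_pairable)
    anchors <- paired[seq(1, n_pairable, by = 2)]
    partners <- paired[seq(2, n_pairable, by = 2)]
    gap <- pmin(cluster_gap_bp, 1000L)
    chrom[partners] <- chrom[anchors]
    pos[partners] <- pos[anchors] + as.integer(gap)
  }
  if (anyDuplicated(paste(chrom, pos))) stop("internal: duplicate positions")

  # the realised fold compares the hit rate to the rate over the WHOLE
  # background (hits included), so the hit overlap probability must be
  # inflated for the hits' own share w of the background:
  # fold = p_hit / (w * p_hit + (1 - w) * p_bg)
  w <- length(hit_ids) / n_cpgs
  p_hit <- if (enrichment_fold * w < 1) {
    min(1, enrichment_fold * (1 - w) * bg_overlap_rate /
          (1 - enrichment_fold * w))
  } else 1
  tracks <- lapply(track_names, function(nm) {
    overlap <- ifelse(is_hit, stats::runif(n_cpgs) < p_hit,
                      stats::runif(n_cpgs) < bg_overlap_rate)
    idx <- which(overlap)
    gr <- GenomicRanges::GRanges(
      seqnames = chrom[idx],
      ranges = IRanges::IRanges(start = pmax(1L, pos[idx] - 50L),
                                end = pos[idx] + 50L))
    annotation_track(nm, intervals = gr)
  })
  names(tracks) <- track_names
  list(coords = data.frame(cpg_id = cpg_ids, chrom = chrom, pos = pos,
                           stringsAsFactors = FALSE),
       tracks = tracks)
}

#' Simulate a complete cohort with known truth
#'
#' Composes [simulate_conception_dates()], [simulate_seasonal_cpg()]-style
#' seasonal signal injection, covariate/batch/cell-factor structure,
#' [simulate_genotypes()] with spiked cis-mQTL effects and
#' [place_cpgs_and_tracks()] into a cohort object carrying the full truth
#' table. All effects are additive on the logit2 (M-value) scale. Seasonal
#' CpGs are centred at \code{baseline_beta} (an intermediate-methylation
#' hotspot); background CpGs draw baselines from a bimodal
#' low/high/intermediate mixture typical of array methylomes. Latent
#' cell-composition factors load on all CpGs, producing correlated
#' structure recoverable by PCA. Deterministic given \code{config$seed}.
#'
#' @param config A [sim_config()].
#' @return An object of class \code{simulated_cohort}: list with
#'   \code{methylation} ([methylation_matrix()]), \code{metadata}
#'   (data.frame), \code{genotypes} (\code{genotype_matrix}),
#'   \code{tracks} (list of [annotation_track()]), \code{truth} (list with
#'   per-CpG \code{cpgs} data.frame and \code{mqtl} map), and
#'   \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  n_cpg <- config$n_cpgs

  dates <- simulate_conception_dates(
    n, concentration = config$conception_concentration,
    peak_day = config$peak_day, year = config$year)
  theta <- conception_theta(dates)

  sample_ids <- sprintf("S%03d", seq_len(n))
  sex <- sample(c(0L, 1L), n, replace = TRUE)
  age <- stats::rnorm(n, 2, 0.08)
  batch <- sample(seq_len(config$n_batches), n, replace = TRUE)
  intervention <- sample(c(0L, 1L), n, replace = TRUE)
  metadata <- data.frame(
    sample_id = sample_ids,
    conception_date = dates,
    theta = theta,
    sex = sex, age = age,
    batch = factor(batch),
    intervention = intervention,
    collection_date = dates + 280 + 730,
    stringsAsFactors = FALSE)

  # CpG identities, coordinates and enriched tracks
  cpg_ids <- sprintf("cpg%06d", seq_len(n_cpg))
  hit_ids <- if (config$n_hit_cpgs > 0)
    sort(sample(cpg_ids, config$n_hit_cpgs)) else character(0)
  placed <- place_cpgs_and_tracks(
    n_cpg, hit_ids = hit_ids, cluster_gap_bp = config$cluster_gap_bp,
    enrichment_fold = config$enrichment_fold)
  is_hit <- cpg_ids %in% hit_ids

  # per-CpG baselines: hits sit in an intermediate-methylation hotspot,
  # background follows the usual bimodal array profile
  base_beta <- numeric(n_cpg)
  mix <- sample(1:3, n_cpg, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  base_beta[mix == 1] <- stats::runif(sum(mix == 1), 0.03, 0.15)
  base_beta[mix == 2] <- stats::runif(sum(mix == 2), 0.85, 0.97)
  base_beta[mix == 3] <- stats::runif(sum(mix == 3), 0.30, 0.70)
  base_beta[is_hit] <- pmin(pmax(
    config$baseline_beta + stats::runif(sum(is_hit), -0.05, 0.05),
    0.05), 0.95)

  # covariate and latent cell-factor structure (additive on M scale)
  eff <- config$covariate_effects
  eff_of <- function(nm) if (nm %in% names(eff)) eff[[nm]] else 0
  cov_m <- eff_of("sex") * sex + eff_of("age") * (age - mean(age)) +
    eff_of("batch") * (batch - 1) + eff_of("intervention") * intervention
  z_cell <- matrix(stats::rnorm(n * config$n_cell_factors), n)
  loadings <- matrix(stats::rnorm(config$n_cell_factors * n_cpg,
                                  0, config$cell_loading_sd),
                     config$n_cell_factors, n_cpg)

  # genotypes: one dedicated cis-SNP per mQTL CpG, remainder unlinked
  n_mqtl <- min(config$n_mqtl, config$n_snps, n_cpg)
  mqtl_cpg <- if (n_mqtl > 0) sort(sample(cpg_ids, n_mqtl)) else character(0)
  mqtl_cpg_idx <- match(mqtl_cpg, placed$coords$cpg_id)
  snp_chrom <- character(config$n_snps)
  snp_pos <- integer(config$n_snps)
  if (n_mqtl > 0) {
    snp_chrom[seq_len(n_mqtl)] <- placed$coords$chrom[mqtl_cpg_idx]
    snp_pos[seq_len(n_mqtl)] <-
      placed$coords$pos[mqtl_cpg_idx] + 10000L
  }
  if (config$n_snps > n_mqtl) {
    rest <- (n_mqtl + 1):config$n_snps
    far_chrom <- sample(paste0("chr", 19:22), length(rest), replace = TRUE)
    snp_chrom[rest] <- far_chrom
    snp_pos[rest] <- sort(sample.int(5e7, length(rest)))
  }
  genotypes <- simulate_genotypes(
    n, config$n_snps, maf_range = config$maf_range,
    chrom = snp_chrom, positions = snp_pos)
  rownames(genotypes$dosages) <- sample_ids

  # per-hit peak days spread around the configured centre
  peak_days <- rep(NA_real_, n_cpg)
  peak_days[is_hit] <- (config$peak_day +
    stats::rnorm(sum(is_hit), 0, config$peak_day_sd)) %% 365.25
  theta_peaks <- 2 * pi * peak_days / 365.25

  M <- matrix(0, n, n_cpg, dimnames = list(sample_ids, cpg_ids))
  for (j in seq_len(n_cpg)) {
    mj <- beta_to_m(base_beta[j]) + cov_m + z_cell %*% loadings[, j]
    if (is_hit[j]) {
      mj <- mj + config$amplitude_logit * cos(theta - theta_peaks[j])
    }
    k <- match(cpg_ids[j], mqtl_cpg)
    if (!is.na(k)) {
      mj <- mj + config$mqtl_effect_logit * genotypes$dosages[, k]
    }
    M[, j] <- mj + stats::rnorm(n, 0, config$noise_sd_logit)
  }
  betas <- m_to_beta(M)

  true_amp <- ifelse(
    is_hit,
    (m_to_beta(beta_to_m(base_beta) + config$amplitude_logit) -
       m_to_beta(beta_to_m(base_beta) - config$amplitude_logit)) * 100,
    0)
  truth_cpgs <- data.frame(
    cpg_id = cpg_ids, is_hit = is_hit, baseline_beta = base_beta,
    true_amplitude_pct = true_amp,
    true_peak_day = peak_days,
    stringsAsFactors = FALSE)
  truth_mqtl <- if (n_mqtl > 0) data.frame(
    cpg_id = mqtl_cpg, snp_id = genotypes$snp_ids[seq_len(n_mqtl)],
    effect_logit = config$mqtl_effect_logit, stringsAsFactors = FALSE)
  else data.frame(cpg_id = character(0), snp_id = character(0),
                  effect_logit = numeric(0))

  structure(list(
    methylation = methylation_matrix(betas, placed$coords$chrom,
                                     placed$coords$pos),
    metadata = metadata,
    genotypes = genotypes,
    tracks = placed$tracks,
    truth = list(cpgs = truth_cpgs, mqtl = truth_mqtl),
    config = config
  ), class = "simulated_cohort")
}

#' Simulate a replication cohort sharing another cohort's truth
#'
#' Draws a fresh set of samples (conception dates, covariates, latent
#' cell factors, genotypes, residual noise) while keeping the original
#' cohort's per-CpG truth fixed: the same seasonal loci with the same
#' baselines and peak days, the same coordinates and annotation tracks,
#' and the same cis-mQTL map. This emulates measuring a second,
#' independent cohort (or the same children at a later age) drawn from
#' the same underlying biology, so cross-cohort replication and
#' attenuation statistics have a ground truth.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param seed Integer seed for the new sample draw.
#' @param n_samples Number of samples in the replication cohort; defaults
#'   to the original size.
#' @param amplitude_scale Multiplier applied to every true seasonal
#'   amplitude (on the M-value scale); values below 1 emulate attenuation
#'   of the seasonal effect, e.g. with age. Default 1.
#' @return A \code{simulated_cohort}; its truth table reflects the scaled
#'   amplitudes.
#' @export
simulate_replication_cohort <- function(cohort, seed,
                                        n_samples = NULL,
                                        amplitude_scale = 1) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (amplitude_scale < 0) stop("amplitude_scale must be >= 0")
  config <- cohort$config
  n <- if (is.null(n_samples)) config$n_samples else n_samples
  set.seed(as.integer(seed))

  truth <- cohort$truth$cpgs
  cpg_ids <- truth$cpg_id
  n_cpg <- length(cpg_ids)
  is_hit <- truth$is_hit
  base_beta <- truth$baseline_beta
  theta_peaks <- 2 * pi * truth$true_peak_day / 365.25
  amp <- config$amplitude_logit * amplitude_scale

  dates <- simulate_conception_dates(
    n, concentration = config$conception_concentration,
    peak_day = config$peak_day, year = config$year)
  theta <- conception_theta(dates)
  sample_ids <- sprintf("R%03d", seq_len(n))
  sex <- sample(c(0L, 1L), n, replace = TRUE)
  age <- stats::rnorm(n, 2, 0.08)
  batch <- sample(seq_len(config$n_batches), n, replace = TRUE)
  intervention <- sample(c(0L, 1L), n, replace = TRUE)
  metadata <- data.frame(
    sample_id = sample_ids, conception_date = dates, theta = theta,
    sex = sex, age = age, batch = factor(batch),
    intervention = intervention,
    collection_date = dates + 280 + 730, stringsAsFactors = FALSE)

  eff <- config$covariate_effects
  eff_of <- function(nm) if (nm %in% names(eff)) eff[[nm]] else 0
  cov_m <- eff_of("sex") * sex + eff_of("age") * (age - mean(age)) +
    eff_of("batch") * (batch - 1) + eff_of("intervention") * intervention
  z_cell <- matrix(stats::rnorm(n * config$n_cell_factors), n)
  loadings <- matrix(stats::rnorm(config$n_cell_factors * n_cpg,
                                  0, config$cell_loading_sd),
                     config$n_cell_factors, n_cpg)

  genotypes <- simulate_genotypes(
    n, config$n_snps, maf_range = config$maf_range,
    chrom = cohort$genotypes$chrom, positions = cohort$genotypes$pos)
  rownames(genotypes$dosages) <- sample_ids

  mqtl_cpg <- cohort$truth$mqtl$cpg_id
  M <- matrix(0, n, n_cpg, dimnames = list(sample_ids, cpg_ids))
  for (j in seq_len(n_cpg)) {
    mj <- beta_to_m(base_beta[j]) + cov_m + z_cell %*% loadings[, j]
    if (is_hit[j]) mj <- mj + amp * cos(theta - theta_peaks[j])
    k <- match(cpg_ids[j], mqtl_cpg)
    if (!is.na(k)) {
      mj <- mj + config$mqtl_effect_logit * genotypes$dosages[, k]
    }
    M[, j] <- mj + stats::rnorm(n, 0, config$noise_sd_logit)
  }

  truth_new <- truth
  truth_new$true_amplitude_pct <- ifelse(
    is_hit,
    (m_to_beta(beta_to_m(base_beta) + amp) -
       m_to_beta(beta_to_m(base_beta) - amp)) * 100, 0)

  structure(list(
    methylation = methylation_matrix(m_to_beta(M),
                                     cohort$methylation$chrom,
                                     cohort$methylation$pos),
    metadata = metadata,
    genotypes = genotypes,
    tracks = cohort$tracks,
    truth = list(cpgs = truth_new, mqtl = cohort$truth$mqtl),
    config = config
  ), class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "simulated_cohort: %d samples, %d CpGs (%d seasonal), %d SNPs ",
    "(%d cis-mQTL), seed %d\n"),
    x$config$n_samples, x$config$n_cpgs, x$config$n_hit_cpgs,
    x$config$n_snps, nrow(x$truth$mqtl), x$config$seed))
  invisible(x)
}
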