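#' Filter SNPs on MAF and homozygote count
#'
#' Retains common variants suitable for dosage-based linear modelling:
#' minor-allele frequency strictly above 10% and at least
#' \code{min_hom} minor-allele homozygous carriers (so the dosage-2 class
#' is not driven by a handful of individuals).
#'
#' @param genotypes A \code{genotype_matrix} (see
#'   [simulate_genotypes()] / [read_dosage_tsv()]).
#' @param maf_min MAF threshold (exclusive). Default 0.10.
#' @param min_hom Minimum minor-allele homozygote count. Default 10.
#' @return Filtered \code{genotype_matrix}; the number removed is
#'   reported via \code{message()}.
#' @export
filter_snps <- function(genotypes, maf_min = 0.10, min_hom = 10) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosages
  f <- colMeans(d) / 2
  maf <- pmin(f, 1 - f)
  hom_minor <- pmin(colSums(d == 0L), colSums(d == 2L))
  keep <- maf > maf_min & hom_minor >= min_hom
  message(sprintf("filter_snps: kept %d / %d SNPs (MAF > %.2f, >= %d hom)",
                  sum(keep), length(keep), maf_min, min_hom))
  structure(list(dosages = d[, keep, drop = FALSE],
                 snp_ids = genotypes$snp_ids[keep],
                 chrom = genotypes$chrom[keep],
                 pos = genotypes$pos[keep],
                 maf = maf[keep], n_hom = hom_minor[keep]),
            class = "genotype_matrix")
}

# residualise y (vector or columns of a matrix) on [1, X]
.residualise <- function(y, X) {
  Xi <- cbind(1, X)
  qr_x <- qr(Xi)
  as.matrix(stats::resid(stats::lm.fit(Xi, as.matrix(y))))
}

# per-SNP association of one CpG's M-values with dosages, adjusting for
# covariates via Frisch-Waugh residualisation; equivalent to the t-test
# on G in lm(M ~ covs + G)
.snp_assoc <- function(m, dosages, covariates) {
  ok <- !is.na(m)
  Xc <- cbind(rep(1, length(m)), covariates)[ok, , drop = FALSE]
  rm_ <- stats::resid(stats::lm.fit(Xc, m[ok]))
  rg <- apply(dosages[ok, , drop = FALSE], 2, function(g)
    stats::resid(stats::lm.fit(Xc, g)))
  rg <- as.matrix(rg)
  ssg <- colSums(rg^2)
  beta <- as.vector(crossprod(rg, rm_)) / ssg
  df <- sum(ok) - ncol(Xc) - 1
  rss <- sum(rm_^2) - beta^2 * ssg
  se <- sqrt(rss / df / ssg)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  data.frame(effect = beta, se = se, t = tval, p = p,
             stringsAsFactors = FALSE)
}

#' Two-step cis/trans mQTL scan
#'
#' For each query CpG, dosage effects on M-values are estimated by OLS
#' with the same adjustment covariates as the seasonal model
#' (\code{M ~ covariates + G}). Discovery is two-step to maximise power
#' for the predominant cis architecture: (i) only SNPs on the same
#' chromosome within \code{cis_window_bp} of the CpG are tested, with
#' Benjamini-Hochberg FDR within that family; (ii) all SNPs are tested,
#' with FDR within the full family. Records are labelled by scope; a cis
#' pair re-tested in step two carries the identical effect estimate.
#'
#' @param mat A [methylation_matrix()] restricted to the query CpGs (use
#'   [subset_cpgs()]), with outliers already handled as desired.
#' @param genotypes A filtered \code{genotype_matrix} aligned to the same
#'   samples.
#' @param covariates Numeric design matrix (samples x covariates).
#' @param cis_window_bp Window defining cis. Default 1e6.
#' @param fdr_threshold Significance threshold on q. Default 0.05.
#' @param keep_all Return all tested pairs rather than significant ones
#'   only. Default \code{FALSE}.
#' @return data.frame of mQTL records: \code{cpg_id}, \code{snp_id},
#'   \code{scope} ("cis"/"trans"), \code{effect} (per dose, M-value
#'   units), \code{p}, \code{q} (within-scope FDR), \code{significant}.
#' @export
mqtl_scan <- function(mat, genotypes, covariates = NULL,
                      cis_window_bp = 1e6, fdr_threshold = 0.05,
                      keep_all = FALSE) {
  stopifnot(inherits(mat, "methylation_matrix"),
            inherits(genotypes, "genotype_matrix"))
  if (!identical(rownames(mat$betas), rownames(genotypes$dosages))) {
    stop("methylation and genotype samples are misaligned")
  }
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  M <- beta_to_m(mat$betas)
  n_cpg <- ncol(M)

  run_step <- function(scope) {
    rows <- vector("list", n_cpg)
    for (j in seq_len(n_cpg)) {
      if (scope == "cis") {
        sel <- genotypes$chrom == mat$chrom[j] &
          abs(genotypes$pos - mat$pos[j]) <= cis_window_bp
      } else {
        sel <- rep(TRUE, length(genotypes$snp_ids))
      }
      if (!any(sel)) next
      a <- .snp_assoc(M[, j], genotypes$dosages[, sel, drop = FALSE],
                      covariates)
      rows[[j]] <- data.frame(
        cpg_id = mat$cpg_ids[j], snp_id = genotypes$snp_ids[sel],
        is_cis = genotypes$chrom[sel] == mat$chrom[j] &
          abs(genotypes$pos[sel] - mat$pos[j]) <= cis_window_bp,
        effect = a$effect, p = a$p, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  cis_tab <- run_step("cis")
  if (!is.null(cis_tab) && nrow(cis_tab)) {
    cis_tab$scope <- "cis"
    cis_tab$q <- fdr_adjust(cis_tab$p)
  }
  trans_tab <- run_step("trans")
  if (!is.null(trans_tab) && nrow(trans_tab)) {
    trans_tab$q <- fdr_adjust(trans_tab$p)
    trans_tab$scope <- ifelse(trans_tab$is_cis, "cis", "trans")
    # step two contributes the trans discoveries; cis pairs were already
    # adjudicated in step one
    trans_tab <- trans_tab[!trans_tab$is_cis, , drop = FALSE]
  }
  out <- rbind(cis_tab, trans_tab)
  if (is.null(out) || !nrow(out)) {
    out <- data.frame(cpg_id = character(0), snp_id = character(0),
                      scope = character(0), effect = numeric(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0))
    return(out)
  }
  out$significant <- out$q < fdr_threshold
  out <- out[, c("cpg_id", "snp_id", "scope", "effect", "p", "q",
                 "significant")]
  rownames(out) <- NULL
  if (!keep_all) out <- out[out$significant, , drop = FALSE]
  out
}

# adjusted R^2 of lm y ~ [1, X]
.adj_r2 <- function(y, X) {
  ok <- !is.na(y)
  Xi <- cbind(rep(1, length(y)), X)[ok, , drop = FALSE]
  yv <- y[ok]
  n <- length(yv)
  p <- ncol(Xi) - 1
  if (n - p - 1 <= 0) stop("more regressors than residual degrees of freedom")
  fit <- stats::lm.fit(Xi, yv)
  r2 <- 1 - sum(fit$residuals^2) / sum((yv - mean(yv))^2)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Methylation variance explained by a CpG's mQTL
#'
#' Adjusted-R-squared gain of the covariates-plus-mQTL model over the
#' covariates-only model, fitted on identical samples:
#' \code{delta_adj_r2 = adjR2(M ~ covs + G1 + ... + Gk) - adjR2(M ~
#' covs)}. Adjusted R-squared accounts for the differing number of mQTL
#' per CpG; the difference can be slightly negative for null SNPs.
#'
#' @param m_values Numeric vector of M-values for one CpG.
#' @param mqtl_dosages Matrix (samples x mQTL dosages); at least one
#'   column.
#' @param covariates Optional numeric design matrix.
#' @return List with \code{delta_adj_r2}, \code{adj_r2_full},
#'   \code{adj_r2_cov}, \code{n_mqtl}.
#' @export
variance_explained <- function(m_values, mqtl_dosages, covariates = NULL) {
  mqtl_dosages <- as.matrix(mqtl_dosages)
  if (ncol(mqtl_dosages) < 1) stop("at least one mQTL dosage is required")
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  full <- .adj_r2(m_values, cbind(covariates, mqtl_dosages))
  cov_only <- if (is.null(covariates)) 0 else .adj_r2(m_values, covariates)
  list(delta_adj_r2 = full - cov_only, adj_r2_full = full,
       adj_r2_cov = cov_only, n_mqtl = ncol(mqtl_dosages))
}

#' Gene-by-season interaction scan at one CpG
#'
#' Tests, for each SNP, the interaction between dosage and the dominant
#' Fourier term of the CpG's seasonal fit:
#' \code{M ~ covs + f(theta) + G + G:f(theta)} where \code{f} is
#' \code{sin} when the sin term had the smaller marginal p-value in the
#' main seasonal model and \code{cos} otherwise (ties choose sin). The
#' interaction coefficient's t-test p-values are BH-adjusted across SNPs.
#'
#' @param m_values Numeric vector of M-values for the CpG.
#' @param genotypes A \code{genotype_matrix}.
#' @param theta Conception angles in radians.
#' @param covariates Optional numeric design matrix.
#' @param main_fit The CpG's \code{cosinor_fit} from the main analysis
#'   (supplies the marginal sin/cos p-values).
#' @return data.frame with \code{snp_id}, \code{term} ("sin"/"cos"),
#'   \code{interaction_effect}, \code{p}, \code{q}.
#' @export
gxe_scan <- function(m_values, genotypes, theta, covariates = NULL,
                     main_fit = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(main_fit)) stop("main_fit is required to select the term")
  sin_p <- main_fit$term_pvalues["sin1theta"]
  cos_p <- main_fit$term_pvalues["cos1theta"]
  term <- if (!is.na(sin_p) && sin_p <= cos_p) "sin" else "cos"
  f <- if (term == "sin") sin(theta) else cos(theta)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  ok <- !is.na(m_values)
  n_snp <- ncol(genotypes$dosages)
  eff <- pv <- numeric(n_snp)
  for (s in seq_len(n_snp)) {
    g <- genotypes$dosages[, s]
    X <- cbind(rep(1, length(g)), covariates, f, g, g * f)[ok, , drop = FALSE]
    y <- m_values[ok]
    qr_x <- qr(X)
    cf <- qr.coef(qr_x, y)
    res <- y - X %*% cf
    df <- length(y) - ncol(X)
    sigma2 <- sum(res^2) / df
    xtx_inv <- chol2inv(qr.R(qr_x))
    k <- ncol(X)
    se <- sqrt(xtx_inv[k, k] * sigma2)
    eff[s] <- cf[k]
    pv[s] <- 2 * stats::pt(abs(cf[k] / se), df, lower.tail = FALSE)
  }
  data.frame(snp_id = genotypes$snp_ids, term = term,
             interaction_effect = eff, p = pv, q = fdr_adjust(pv),
             stringsAsFactors = FALSE)
}

#' Genotype-season association check
#'
#' Tests whether SNP dosages are themselves associated with season of
#' conception, which would confound mQTL-based interpretations. Two
#' modes: \code{"regression"} (default) regresses dosage on
#' \code{sin(theta) + cos(theta)} and reports the joint 2-df F-test;
#' \code{"dichotomised"} assigns samples to two season windows and
#' applies a Pearson chi-square test (no continuity correction) to the
#' 2x2 allele-count table.
#'
#' @param genotypes A \code{genotype_matrix}.
#' @param metadata data.frame with \code{conception_date} (or
#'   \code{theta}) aligned to the genotype rows.
#' @param mode \code{"regression"} or \code{"dichotomised"}.
#' @param season_windows For dichotomised mode: list of two elements,
#'   each \code{c(start_day, end_day)} (day-of-year, inclusive) defining
#'   the season groups, e.g. rainy \code{c(182, 304)} and dry
#'   \code{c(335, 151)} (windows may wrap past 31 December).
#' @param bonferroni_m Divisor for the reported Bonferroni threshold;
#'   defaults to the number of SNPs.
#' @return data.frame with \code{snp_id}, \code{stat}, \code{p},
#'   \code{q}, \code{significant_fdr}, \code{significant_bonf}; attribute
#'   \code{bonferroni_threshold}.
#' @export
soc_genotype_association <- function(genotypes, metadata,
                                     mode = c("regression",
                                              "dichotomised"),
                                     season_windows = NULL,
                                     bonferroni_m = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  theta <- if ("theta" %in% colnames(metadata)) metadata$theta else
    conception_theta(metadata$conception_date)
  n_snp <- ncol(genotypes$dosages)
  stat <- pv <- numeric(n_snp)
  if (mode == "regression") {
    X <- cbind(1, sin(theta), cos(theta))
    for (s in seq_len(n_snp)) {
      g <- genotypes$dosages[, s]
      fit <- stats::lm.fit(X, g)
      rss1 <- sum(fit$residuals^2)
      rss0 <- sum((g - mean(g))^2)
      df2 <- length(g) - 3
      Fstat <- ((rss0 - rss1) / 2) / (rss1 / df2)
      stat[s] <- Fstat
      pv[s] <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
    }
  } else {
    if (is.null(season_windows) || length(season_windows) != 2) {
      stop("dichotomised mode requires two season windows")
    }
    year_days <- 365.25
    day <- theta / (2 * pi) * year_days
    in_window <- function(w) {
      if (w[1] <= w[2]) day >= w[1] & day <= w[2]
      else day >= w[1] | day <= w[2]  # wraps past 31 December
    }
    g1 <- in_window(season_windows[[1]])
    g2 <- in_window(season_windows[[2]])
    if (!any(g1) || !any(g2)) stop("a season group is empty")
    for (s in seq_len(n_snp)) {
      d <- genotypes$dosages[, s]
      # allele counts: 2N chromosomes per group
      tab <- rbind(c(sum(d[g1]), 2 * sum(g1) - sum(d[g1])),
                   c(sum(d[g2]), 2 * sum(g2) - sum(d[g2])))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat[s] <- unname(ct$statistic)
      pv[s] <- ct$p.value
    }
  }
  m_bonf <- if (is.null(bonferroni_m)) n_snp else bonferroni_m
  out <- data.frame(snp_id = genotypes$snp_ids, stat = stat, p = pv,
                    q = fdr_adjust(pv),
                    stringsAsFactors = FALSE)
  out$significant_fdr <- out$q < 0.05
  out$significant_bonf <- out$p < 0.05 / m_bonf
  attr(out, "bonferroni_threshold") <- 0.05 / m_bonf
  out
}
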