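#' Run the per-CpG seasonal (cosinor) EWAS
#'
#' For every CpG: mask beta-scale outliers ([remove_outliers()]),
#' logit2-transform ([beta_to_m()]), fit the full cosinor model and the
#' covariate-only reduced model on the identical retained samples, test
#' the seasonal terms by a Gaussian likelihood-ratio test against
#' chi-square with 2 df per Fourier pair, adjust across CpGs by
#' Benjamini-Hochberg ([fdr_adjust()]) and summarise the modelled seasonal
#' effect as a beta-scale amplitude with peak/nadir days (the daily-grid
#' convention of [amplitude_phase()]).
#'
#' CpGs sharing an identical post-masking sample set are fitted together
#' through one QR decomposition, so genome-scale runs stay fast; results
#' are numerically identical to calling [fit_cosinor()] per CpG.
#'
#' @param mat A [methylation_matrix()].
#' @param metadata data.frame with a \code{sample_id} column matching the
#'   rownames of \code{mat$betas} and a \code{conception_date} column
#'   (\code{Date} or ISO-8601 string); alternatively a precomputed
#'   \code{theta} column in radians.
#' @param covariates Optional numeric design matrix (samples x covariates)
#'   from [covariate_matrix()], aligned to \code{metadata} row order.
#' @param fourier_pairs Number of Fourier pairs. Default 1.
#' @param fdr_m Number of tests assumed in the FDR correction; defaults to
#'   the number of CpGs analysed. Supply the array-background size to
#'   correct a subset against the full background.
#' @param outlier_k IQR multiplier for outlier masking (set \code{Inf} to
#'   disable). Default 3.
#' @return An \code{ewas_table}: data.frame with one row per CpG
#'   (\code{cpg_id}, \code{chrom}, \code{pos}, \code{intercept},
#'   \code{beta1}, \code{gamma1}, \code{lrt_stat}, \code{p_value},
#'   \code{q_value}, \code{amplitude_pct}, \code{peak_day},
#'   \code{nadir_day}, \code{sin_p}, \code{cos_p}, \code{n_used},
#'   \code{n_outliers}) and attributes \code{covariates} (column names),
#'   \code{n_samples}, \code{mean_outliers}, \code{total_outliers} and
#'   \code{lambda} (genomic inflation, when >= 100 CpGs).
#' @export
run_ewas <- function(mat, metadata, covariates = NULL, fourier_pairs = 1,
                     fdr_m = NULL, outlier_k = 3) {
  stopifnot(inherits(mat, "methylation_matrix"))
  ids_mat <- rownames(mat$betas)
  ids_meta <- as.character(metadata$sample_id)
  if (!identical(sort(ids_mat), sort(ids_meta))) {
    only_mat <- setdiff(ids_mat, ids_meta)
    only_meta <- setdiff(ids_meta, ids_mat)
    stop("sample ids are misaligned; only in methylation: ",
         paste(utils::head(only_mat, 5), collapse = ", "),
         "; only in metadata: ",
         paste(utils::head(only_meta, 5), collapse = ", "))
  }
  ord <- match(ids_mat, ids_meta)
  metadata <- metadata[ord, , drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[ord, , drop = FALSE]
  }
  theta <- if ("theta" %in% colnames(metadata)) metadata$theta else
    conception_theta(metadata$conception_date)

  n <- nrow(mat$betas)
  n_cpg <- ncol(mat$betas)
  betas <- mat$betas
  n_out <- integer(n_cpg)
  if (is.finite(outlier_k)) {
    for (j in seq_len(n_cpg)) {
      masked <- remove_outliers(betas[, j], k = outlier_k)
      betas[, j] <- masked$values
      n_out[j] <- masked$n_removed
    }
  }
  M <- beta_to_m(betas)

  Xr <- cbind(`(Intercept)` = rep(1, n), covariates)
  Xf <- Xr
  for (r in seq_len(fourier_pairs)) {
    fr <- cbind(sin(r * theta), cos(r * theta))
    colnames(fr) <- paste0(c("sin", "cos"), r, "theta")
    Xf <- cbind(Xf, fr)
  }
  p_full <- ncol(Xf)
  p_red <- ncol(Xr)
  cov_cols <- setdiff(colnames(Xr), "(Intercept)")

  # group CpGs by identical retained-sample pattern; one QR per group
  keys <- vapply(seq_len(n_cpg), function(j)
    paste(which(is.na(M[, j])), collapse = ","), character(1))
  groups <- split(seq_len(n_cpg), keys)

  out <- data.frame(
    cpg_id = mat$cpg_ids, chrom = mat$chrom, pos = mat$pos,
    intercept = NA_real_, beta1 = NA_real_, gamma1 = NA_real_,
    lrt_stat = NA_real_, p_value = NA_real_,
    amplitude_pct = NA_real_, peak_day = NA_real_, nadir_day = NA_real_,
    sin_p = NA_real_, cos_p = NA_real_,
    n_used = NA_integer_, n_outliers = n_out, stringsAsFactors = FALSE)

  grid_len <- 365
  theta_grid <- 2 * pi * (seq_len(grid_len) - 1) / grid_len
  sin_grid <- sin(theta_grid)
  cos_grid <- cos(theta_grid)
  day_grid <- 365.25 * theta_grid / (2 * pi)

  for (g in groups) {
    rows <- !is.na(M[, g[1]])
    n_used <- sum(rows)
    if (n_used <= p_full + 2) {
      stop("too few non-missing samples for the design at CpG ",
           mat$cpg_ids[g[1]])
    }
    Xfu <- Xf[rows, , drop = FALSE]
    Xru <- Xr[rows, , drop = FALSE]
    Y <- M[rows, g, drop = FALSE]

    qr_f <- qr(Xfu)
    if (qr_f$rank < p_full) {
      dropped <- colnames(Xfu)[qr_f$pivot[(qr_f$rank + 1):p_full]]
      stop("rank-deficient design; collinear column(s): ",
           paste(dropped, collapse = ", "))
    }
    cf <- qr.coef(qr_f, Y)
    rss_f <- colSums((Y - Xfu %*% cf)^2)
    qr_r <- qr(Xru)
    cr <- qr.coef(qr_r, Y)
    rss_r <- colSums((Y - Xru %*% cr)^2)

    stat <- pmax(n_used * log(rss_r / rss_f), 0)
    df_lrt <- 2 * fourier_pairs
    pval <- stats::pchisq(stat, df = df_lrt, lower.tail = FALSE)

    # marginal t-tests of the first Fourier pair
    df_res <- n_used - p_full
    sigma2 <- rss_f / df_res
    xtx_inv <- chol2inv(chol(crossprod(Xfu)))
    diag_idx <- match(c("sin1theta", "cos1theta"), colnames(Xfu))
    se_sin <- sqrt(xtx_inv[diag_idx[1], diag_idx[1]] * sigma2)
    se_cos <- sqrt(xtx_inv[diag_idx[2], diag_idx[2]] * sigma2)
    sin_p <- 2 * stats::pt(abs(cf["sin1theta", ] / se_sin), df_res,
                           lower.tail = FALSE)
    cos_p <- 2 * stats::pt(abs(cf["cos1theta", ] / se_cos), df_res,
                           lower.tail = FALSE)

    # amplitude and phase on the daily grid at the covariate reference
    # (means; indicator columns at their modal level)
    if (length(cov_cols)) {
      ref <- colMeans(Xfu[, cov_cols, drop = FALSE])
      binary <- vapply(cov_cols, function(nm)
        all(Xfu[, nm] %in% c(0, 1)), logical(1))
      ref[binary] <- round(ref[binary])
      base_m <- cf["(Intercept)", ] +
        as.vector(ref %*% cf[cov_cols, , drop = FALSE])
    } else {
      base_m <- cf["(Intercept)", ]
    }
    m_grid <- outer(sin_grid, cf["sin1theta", ]) +
      outer(cos_grid, cf["cos1theta", ])
    if (fourier_pairs > 1) {
      for (r in 2:fourier_pairs) {
        m_grid <- m_grid +
          outer(sin(r * theta_grid), cf[paste0("sin", r, "theta"), ]) +
          outer(cos(r * theta_grid), cf[paste0("cos", r, "theta"), ])
      }
    }
    beta_grid <- m_to_beta(sweep(m_grid, 2, base_m, "+"))
    i_max <- max.col(t(beta_grid), ties.method = "first")
    i_min <- max.col(-t(beta_grid), ties.method = "first")
    amp <- (beta_grid[cbind(i_max, seq_along(g))] -
              beta_grid[cbind(i_min, seq_along(g))]) * 100

    out$intercept[g] <- cf["(Intercept)", ]
    out$beta1[g] <- cf["sin1theta", ]
    out$gamma1[g] <- cf["cos1theta", ]
    out$lrt_stat[g] <- stat
    out$p_value[g] <- pval
    out$amplitude_pct[g] <- amp
    out$peak_day[g] <- day_grid[i_max]
    out$nadir_day[g] <- day_grid[i_min]
    out$sin_p[g] <- sin_p
    out$cos_p[g] <- cos_p
    out$n_used[g] <- n_used
  }

  zero <- out$beta1 == 0 & out$gamma1 == 0
  out$peak_day[zero] <- NA_real_
  out$nadir_day[zero] <- NA_real_

  m_tests <- if (is.null(fdr_m)) n_cpg else fdr_m
  out$q_value <- fdr_adjust(out$p_value, m = m_tests)
  out <- out[, c("cpg_id", "chrom", "pos", "intercept", "beta1", "gamma1",
                 "lrt_stat", "p_value", "q_value", "amplitude_pct",
                 "peak_day", "nadir_day", "sin_p", "cos_p", "n_used",
                 "n_outliers")]
  attr(out, "covariates") <- colnames(covariates)
  attr(out, "n_samples") <- n
  attr(out, "fdr_m") <- m_tests
  attr(out, "total_outliers") <- sum(out$n_outliers)
  attr(out, "mean_outliers") <- mean(out$n_outliers)
  attr(out, "lambda") <- if (n_cpg >= 100) inflation_lambda(out$p_value)
    else NA_real_
  class(out) <- c("ewas_table", "data.frame")
  out
}

#' @export
print.ewas_table <- function(x, ...) {
  cat(sprintf(
    "ewas_table: %d CpGs, %d samples; %.2f outliers/CpG removed; lambda = %s\n",
    nrow(x), attr(x, "n_samples"), attr(x, "mean_outliers"),
    formatC(attr(x, "lambda"), digits = 3, format = "fg")))
  NextMethod()
}
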