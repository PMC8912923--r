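#' Fit a per-CpG Fourier (cosinor) regression
#'
#' Ordinary least squares fit of M-values on an intercept, adjustment
#' covariates and \code{fourier_pairs} pairs of sin/cos terms of the
#' conception-date angle:
#' \deqn{M_i = \alpha_0 + \sum_k \alpha_k x_{ik} +
#'       \sum_{r=1}^{n}[\beta_r \sin(r\theta_i) + \gamma_r \cos(r\theta_i)]
#'       + \epsilon_i}
#' With a single pair (the default) the seasonal effect is a sinusoid with
#' free amplitude and phase whose maximum and minimum are half a year
#' apart.
#'
#' Samples with missing M-values are dropped; the retained sample set is
#' recorded so that nested models can be compared on identical data.
#'
#' @param m_values Numeric vector of M-values, one per sample (may contain
#'   \code{NA} from outlier masking).
#' @param theta Conception-date angles in radians, \code{[0, 2*pi)}; see
#'   [conception_theta()].
#' @param covariates Optional numeric design matrix (samples x covariates,
#'   no intercept column), e.g. from [covariate_matrix()].
#' @param fourier_pairs Number of Fourier pairs \code{n}; 0 fits the
#'   covariate-only (reduced) model. Default 1.
#' @return An object of class \code{cosinor_fit}: list with
#'   \code{coefficients} (full named vector), \code{beta1}/\code{gamma1}
#'   (first-pair sin/cos coefficients, \code{NA} when
#'   \code{fourier_pairs = 0}), \code{intercept}, \code{covariate_coefs},
#'   \code{rss}, \code{n_used}, \code{df_residual}, \code{used} (logical
#'   index of retained samples), \code{term_pvalues} (marginal t-test p for
#'   each Fourier term), and the model frame pieces needed for prediction.
#' @export
fit_cosinor <- function(m_values, theta, covariates = NULL,
                        fourier_pairs = 1) {
  n <- length(m_values)
  if (length(theta) != n) stop("m_values and theta lengths differ")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per sample")
  }
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (fourier_pairs > 0) {
    for (r in seq_len(fourier_pairs)) {
      fr <- cbind(sin(r * theta), cos(r * theta))
      colnames(fr) <- paste0(c("sin", "cos"), r, "theta")
      X <- cbind(X, fr)
    }
  }
  used <- !is.na(m_values)
  y <- m_values[used]
  Xu <- X[used, , drop = FALSE]
  p <- ncol(Xu)
  if (length(y) <= p + 2) stop("too few non-missing samples for the design")

  qr_x <- qr(Xu)
  if (qr_x$rank < p) {
    dropped <- colnames(Xu)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qr_x, y)
  resid <- y - Xu %*% coefs
  rss <- sum(resid^2)
  df_res <- length(y) - p
  sigma2 <- rss / df_res
  xtx_inv <- chol2inv(chol(crossprod(Xu)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  names(se) <- colnames(Xu)

  fourier_cols <- grep("^(sin|cos)[0-9]+theta$", colnames(Xu), value = TRUE)
  term_p <- if (length(fourier_cols)) {
    tval <- coefs[fourier_cols] / se[fourier_cols]
    stats::setNames(2 * stats::pt(abs(tval), df_res, lower.tail = FALSE),
                    fourier_cols)
  } else numeric(0)

  cov_cols <- setdiff(colnames(Xu), c("(Intercept)", fourier_cols))
  structure(list(
    coefficients = coefs,
    beta1 = if ("sin1theta" %in% names(coefs)) unname(coefs["sin1theta"]) else NA_real_,
    gamma1 = if ("cos1theta" %in% names(coefs)) unname(coefs["cos1theta"]) else NA_real_,
    intercept = unname(coefs["(Intercept)"]),
    covariate_coefs = coefs[cov_cols],
    term_pvalues = term_p,
    fourier_pairs = fourier_pairs,
    rss = rss, n_used = length(y), df_residual = df_res,
    used = used,
    design_colnames = colnames(Xu),
    covariate_means = if (length(cov_cols))
      colMeans(X[used, cov_cols, drop = FALSE]) else numeric(0),
    covariate_binary = if (length(cov_cols))
      apply(X[used, cov_cols, drop = FALSE], 2,
            function(v) all(v %in% c(0, 1))) else logical(0)
  ), class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "cosinor_fit: %d Fourier pair(s), n = %d, beta1 = %.4g, gamma1 = %.4g\n",
    x$fourier_pairs, x$n_used, x$beta1, x$gamma1))
  invisible(x)
}

#' Likelihood-ratio test between nested cosinor fits
#'
#' Gaussian likelihood-ratio statistic for the seasonal terms:
#' \code{stat = n * log(RSS_reduced / RSS_full)}, referred to a chi-square
#' distribution with 2 degrees of freedom per Fourier pair dropped. Both
#' fits must have been computed on the identical sample set.
#'
#' @param full_fit,reduced_fit \code{cosinor_fit} objects; the reduced fit
#'   is the same design minus the Fourier columns.
#' @return List with \code{stat} and \code{p}.
#' @export
lrt_pvalue <- function(full_fit, reduced_fit) {
  stopifnot(inherits(full_fit, "cosinor_fit"),
            inherits(reduced_fit, "cosinor_fit"))
  if (!identical(full_fit$used, reduced_fit$used)) {
    stop("full and reduced fits use different sample sets")
  }
  df <- 2 * (full_fit$fourier_pairs - reduced_fit$fourier_pairs)
  if (df <= 0) stop("full model must contain more Fourier pairs than reduced")
  n <- full_fit$n_used
  stat <- n * log(reduced_fit$rss / full_fit$rss)
  stat <- max(stat, 0)
  list(stat = stat, p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate q-values with an optional override of the
#' number of independent tests \code{m}, used when p-values for a subset of
#' loci are corrected against the full array background size.
#'
#' @param p_values Numeric vector of p-values in \code{[0, 1]}.
#' @param m Number of tests assumed for the correction; defaults to
#'   \code{length(p_values)}.
#' @return Numeric vector of q-values.
#' @export
fdr_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH", n = max(m, length(p_values)))
}

#' Seasonal amplitude and peak/nadir day of a cosinor fit
#'
#' Predicts M-values over a daily grid of the year at a covariate reference
#' point, back-transforms to the beta scale and reports the amplitude
#' (maximum minus minimum, in percentage points of methylation) together
#' with the days of year of the modelled maximum and minimum. The grid is
#' authoritative (it extends unchanged to multi-pair fits); for the
#' single-pair model the closed form — M-scale peak angle
#' \code{atan2(beta1, gamma1)} and M-scale amplitude
#' \code{2*sqrt(beta1^2 + gamma1^2)} — agrees within one grid step.
#'
#' The covariate reference defaults to the mean of each design column, with
#' binary (indicator) columns set to their modal value.
#'
#' @param fit A \code{cosinor_fit} with at least one Fourier pair.
#' @param covariate_reference Optional named numeric vector giving the
#'   covariate values at which to predict; defaults as described above.
#' @param grid_points Number of grid days across the year. Default 365.
#' @param year_days Days per year used to convert angles to days of year.
#'   Default 365.25.
#' @return List with \code{amplitude_pct}, \code{peak_day},
#'   \code{nadir_day} (days of year in \code{[0, year_days)}; \code{NA}
#'   when the seasonal coefficients are exactly zero).
#' @export
amplitude_phase <- function(fit, covariate_reference = NULL,
                            grid_points = 365, year_days = 365.25) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (fit$fourier_pairs < 1) stop("fit has no Fourier terms")
  ref <- fit$covariate_means
  if (!is.null(covariate_reference)) {
    ref[names(covariate_reference)] <- covariate_reference
  } else if (length(ref)) {
    # indicator columns go to their modal level, not the mean
    binary <- names(ref)[fit$covariate_binary[names(ref)]]
    ref[binary] <- round(ref[binary])
  }
  base_m <- fit$intercept +
    if (length(ref)) sum(fit$covariate_coefs[names(ref)] * ref) else 0

  theta_grid <- 2 * pi * (seq_len(grid_points) - 1) / grid_points
  m_grid <- rep(base_m, grid_points)
  for (r in seq_len(fit$fourier_pairs)) {
    b <- fit$coefficients[paste0("sin", r, "theta")]
    g <- fit$coefficients[paste0("cos", r, "theta")]
    m_grid <- m_grid + b * sin(r * theta_grid) + g * cos(r * theta_grid)
  }
  beta_grid <- m_to_beta(m_grid)
  amp <- (max(beta_grid) - min(beta_grid)) * 100
  seasonal_zero <- all(abs(fit$coefficients[grep("theta$",
    names(fit$coefficients))]) == 0)
  day_of <- function(i) year_days * theta_grid[i] / (2 * pi)
  if (seasonal_zero) {
    list(amplitude_pct = 0, peak_day = NA_real_, nadir_day = NA_real_)
  } else {
    list(amplitude_pct = amp,
         peak_day = day_of(which.max(beta_grid)),
         nadir_day = day_of(which.min(beta_grid)))
  }
}

#' Genomic inflation factor of a p-value vector
#'
#' Converts p-values to 1-df chi-square quantiles and divides their median
#' by the null median 0.4549 (\code{qchisq(0.5, 1)}). Values near 1
#' indicate well-calibrated tests; values well above 1 indicate inflation,
#' e.g. from a global exposure effect.
#'
#' @param p_values Numeric vector of at least 100 p-values.
#' @return The inflation factor lambda (scalar).
#' @export
inflation_lambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 100) stop("need at least 100 p-values")
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}
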