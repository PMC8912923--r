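#' Convert methylation beta values to M-values
#'
#' M-values are the log2 odds of methylation, \code{M = log2(beta/(1-beta))}.
#' Linear modelling of array methylation is performed on this scale because
#' beta values are bounded and heteroscedastic near 0 and 1.
#'
#' Values exactly at 0 or 1 (possible after aggressive normalisation) are
#' clamped to \code{[eps, 1-eps]} before the transform so the result is
#' always finite.
#'
#' @param beta Numeric vector (or matrix) of methylation fractions in
#'   \code{[0, 1]}. \code{NA}s pass through.
#' @param eps Clamping distance from the 0/1 boundary. Default \code{1e-6}.
#' @return Numeric object of the same shape, on the log2-odds scale.
#' @seealso [m_to_beta()]
#' @examples
#' beta_to_m(c(0.5, 2/3, 0.8))  # 0, 1, 2
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) {
    stop("beta values outside [0, 1]: e.g. ", beta[bad][1L])
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  ans <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(ans) <- dim(beta)
  ans
}

#' Convert M-values back to methylation beta values
#'
#' Inverse of [beta_to_m()]: \code{beta = 2^M / (1 + 2^M)}. Exact inverse on
#' \code{(0, 1)} up to floating-point precision.
#'
#' @param m Numeric vector or matrix of log2-odds methylation values.
#' @return Methylation fractions in \code{(0, 1)}.
#' @export
m_to_beta <- function(m) {
  # equivalent to 2^m/(1+2^m) but stable for large |m|
  stats::plogis(m * log(2))
}

#' Mask methylation outliers beyond 3 IQR from the quartiles
#'
#' Values outside \code{[Q25 - 3*IQR, Q75 + 3*IQR]} are set to \code{NA}.
#' Quartiles use type-7 linear interpolation (the R default) and are
#' computed once, on the input values; masking is not iterated. Applied per
#' CpG, on the beta scale, before model fitting.
#'
#' @param betas Numeric vector; may already contain \code{NA}s, which are
#'   ignored when computing quartiles and preserved in the output.
#' @param k Multiplier of the IQR defining the fence. Default 3.
#' @return List with \code{values} (input with outliers set to \code{NA})
#'   and \code{n_removed} (number of newly masked values).
#' @examples
#' remove_outliers(c(0.50, 0.51, 0.51, 0.52, 0.60))$n_removed  # 1
#' @export
remove_outliers <- function(betas, k = 3) {
  ok <- !is.na(betas)
  if (sum(ok) < 4L) stop("need at least 4 non-missing values")
  q <- stats::quantile(betas[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  out <- ok & (betas < q[1L] - k * iqr | betas > q[2L] + k * iqr)
  betas[out] <- NA_real_
  list(values = betas, n_removed = sum(out))
}

#' Principal component scores of an M-value matrix
#'
#' Unsupervised PCA of the sample-by-CpG M-value matrix, used to construct
#' adjustment covariates capturing technical structure (plate, slide) and
#' cell-composition variation. Columns are centred (not scaled) before the
#' decomposition. The sign of each component is fixed so that the loading
#' with the largest absolute value is positive.
#'
#' @param m_matrix Numeric matrix, samples in rows, CpGs in columns.
#' @param k Number of leading components to return.
#' @return Numeric matrix of PC scores (samples x k), columns named
#'   \code{PC1..PCk}, with attribute \code{var_explained} giving the
#'   fraction of total variance captured by each returned component.
#' @export
compute_pcs <- function(m_matrix, k) {
  if (!is.matrix(m_matrix)) m_matrix <- as.matrix(m_matrix)
  if (k <= 0) stop("k must be positive")
  if (k > min(dim(m_matrix))) stop("k exceeds min(n_samples, n_cpgs)")
  pr <- stats::prcomp(m_matrix, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load_j <- pr$rotation[, j]
    if (load_j[which.max(abs(load_j))] < 0) {
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  attr(scores, "var_explained") <- (pr$sdev[seq_len(k)]^2) / sum(pr$sdev^2)
  scores
}

#' Conception date as an angle around the year
#'
#' Maps a calendar date to radians in \code{[0, 2*pi)} with 1 January = 0,
#' so a full year sweeps the full circle: \code{theta = 2*pi * (days
#' elapsed since Jan 1) / (days in that year)}. Leap years use 366 days so
#' 31 December always falls just short of \code{2*pi}.
#'
#' @param date A \code{Date} vector (or anything \code{as.Date} accepts).
#' @return Numeric vector of angles in radians.
#' @examples
#' conception_theta(as.Date("2011-01-01"))  # 0
#' @export
conception_theta <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  jan1 <- as.Date(paste0(yr, "-01-01"))
  year_len <- ifelse(is_leap_year(yr), 366, 365)
  elapsed <- as.numeric(date - jan1)
  2 * pi * elapsed / year_len
}

is_leap_year <- function(y) {
  (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
}

#' Impute conception date from date of birth
#'
#' When gestational age is unknown, conception is taken as birth minus the
#' population-average gestation of 280 days.
#'
#' @param birth_date A \code{Date} vector.
#' @param gestation_days Assumed gestation length in days. Default 280.
#' @return \code{Date} vector of imputed conception dates.
#' @examples
#' conception_from_birth(as.Date("2008-01-01"))  # 2007-03-27
#' @export
conception_from_birth <- function(birth_date, gestation_days = 280) {
  as.Date(birth_date) - gestation_days
}

#' Regress a covariate out of an M-value matrix
#'
#' Per-CpG simple linear regression of M-values on a single covariate, with
#' the residuals returned after restoring each CpG's mean. Used in
#' sensitivity analyses where a covariate (e.g. infant sex) is removed
#' before the main seasonal model is fitted; refitting with the covariate
#' included afterwards yields a near-zero coefficient.
#'
#' @param m_matrix Numeric matrix, samples x CpGs.
#' @param covariate Numeric or factor vector, one value per sample; must
#'   vary across samples.
#' @return Residualised matrix of the same dimensions, column means
#'   preserved. Missing M-values are left missing.
#' @export
preadjust_covariate <- function(m_matrix, covariate) {
  if (!is.matrix(m_matrix)) m_matrix <- as.matrix(m_matrix)
  x <- if (is.numeric(covariate)) covariate else
    as.numeric(as.factor(covariate))
  if (length(x) != nrow(m_matrix)) {
    stop("covariate length must match number of samples (rows)")
  }
  if (stats::var(x, na.rm = TRUE) == 0) stop("covariate is constant")
  xc <- x - mean(x)
  ssx <- sum(xc^2)
  out <- m_matrix
  for (j in seq_len(ncol(m_matrix))) {
    y <- m_matrix[, j]
    ok <- !is.na(y)
    if (all(ok)) {
      b <- sum(xc * y) / ssx
      out[, j] <- y - b * xc
    } else {
      xo <- x[ok] - mean(x[ok])
      b <- sum(xo * y[ok]) / sum(xo^2)
      out[ok, j] <- y[ok] - b * xo
    }
  }
  out
}
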