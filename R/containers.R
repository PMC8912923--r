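#' Methylation matrix with CpG coordinates
#'
#' Light container pairing a samples-by-CpGs beta-value matrix with the
#' genomic coordinates of each CpG. Coordinates are 1-based base-pair
#' positions, the convention used throughout the package for point loci;
#' BED-style interval inputs (0-based half-open) are converted on read.
#'
#' @param betas Numeric matrix of methylation fractions in \code{[0, 1]}
#'   (missing values allowed), samples in rows (rownames = sample ids),
#'   CpGs in columns (colnames = CpG ids).
#' @param chrom Character vector of chromosome names, one per CpG.
#' @param pos Integer vector of 1-based positions, one per CpG.
#' @return An object of class \code{methylation_matrix}: a list with
#'   elements \code{betas}, \code{cpg_ids}, \code{chrom}, \code{pos}.
#' @export
methylation_matrix <- function(betas, chrom, pos) {
  if (!is.matrix(betas)) stop("betas must be a matrix (samples x CpGs)")
  if (is.null(colnames(betas))) stop("betas must have CpG ids as colnames")
  if (anyDuplicated(colnames(betas))) stop("CpG ids must be unique")
  rng <- range(betas, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("beta values must lie in [0, 1]")
  if (length(chrom) != ncol(betas) || length(pos) != ncol(betas)) {
    stop("chrom and pos must have one entry per CpG")
  }
  if (any(pos < 1)) stop("positions are 1-based and must be >= 1")
  structure(
    list(betas = betas, cpg_ids = colnames(betas),
         chrom = as.character(chrom), pos = as.integer(pos)),
    class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d samples x %d CpGs on %d chromosome(s)\n",
              nrow(x$betas), ncol(x$betas), length(unique(x$chrom))))
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$betas)

#' Subset a methylation matrix by CpG
#'
#' @param x A [methylation_matrix()].
#' @param cpgs Character vector of CpG ids (or logical/integer index).
#' @return A \code{methylation_matrix} restricted to the requested CpGs.
#' @export
subset_cpgs <- function(x, cpgs) {
  stopifnot(inherits(x, "methylation_matrix"))
  idx <- if (is.character(cpgs)) match(cpgs, x$cpg_ids) else
    seq_along(x$cpg_ids)[cpgs]
  if (anyNA(idx)) stop("unknown CpG ids: ",
                       paste(cpgs[is.na(idx)][1:min(3, sum(is.na(idx)))],
                             collapse = ", "))
  methylation_matrix(x$betas[, idx, drop = FALSE],
                     x$chrom[idx], x$pos[idx])
}

#' Labelled CpG set with provenance
#'
#' Records a selected set of CpGs (hits, matched controls, random
#' controls, ...) together with how it was constructed, so that
#' threshold-based selections can be audited and disjointness against
#' exclusion sets re-checked.
#'
#' @param label One of \code{"soc_cpg"}, \code{"matched_control"},
#'   \code{"random_control"} or a custom label.
#' @param cpg_ids Character vector of unique CpG ids.
#' @param provenance Named list of selection parameters (thresholds, seed,
#'   excluded set labels).
#' @return An object of class \code{cpg_set}.
#' @export
cpg_set <- function(label, cpg_ids, provenance = list()) {
  cpg_ids <- as.character(cpg_ids)
  if (anyDuplicated(cpg_ids)) stop("cpg_ids must be unique")
  structure(list(label = label, cpg_ids = cpg_ids, provenance = provenance),
            class = "cpg_set")
}

#' @export
print.cpg_set <- function(x, ...) {
  cat(sprintf("cpg_set '%s': %d CpGs\n", x$label, length(x$cpg_ids)))
  invisible(x)
}

#' @export
length.cpg_set <- function(x) length(x$cpg_ids)

#' Genotype dosage matrix with SNP coordinates
#'
#' Container for allelic dosages (0/1/2) with per-SNP chromosome,
#' position, empirical minor-allele frequency and minor-allele homozygote
#' count (the quantities the common-variant filters act on).
#'
#' @param dosages Integer matrix, samples x SNPs, values in 0/1/2, with
#'   sample ids as rownames and SNP ids as colnames.
#' @param chrom Character vector of SNP chromosomes.
#' @param pos Integer vector of 1-based SNP positions.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosages, chrom, pos) {
  if (!is.matrix(dosages)) stop("dosages must be a matrix (samples x SNPs)")
  if (!all(dosages %in% c(0L, 1L, 2L))) stop("dosages must be 0, 1 or 2")
  if (is.null(colnames(dosages))) stop("dosages must have SNP ids as colnames")
  if (length(chrom) != ncol(dosages) || length(pos) != ncol(dosages)) {
    stop("chrom and pos must have one entry per SNP")
  }
  storage.mode(dosages) <- "integer"
  f <- colMeans(dosages) / 2
  structure(list(dosages = dosages, snp_ids = colnames(dosages),
                 chrom = as.character(chrom), pos = as.integer(pos),
                 maf = pmin(f, 1 - f),
                 n_hom = pmin(colSums(dosages == 0L),
                              colSums(dosages == 2L))),
            class = "genotype_matrix")
}

#' Build a covariate design matrix from sample metadata
#'
#' Expands factors to treatment-coded indicator columns and keeps numeric
#' covariates as-is, producing the adjustment block shared by the seasonal,
#' mQTL and interaction models. An intercept is *not* included; model
#' fitting functions add it.
#'
#' @param metadata data.frame of per-sample covariates (rows in sample
#'   order).
#' @param covariates Character vector of column names to use; default all.
#' @param pcs Optional PC score matrix from [compute_pcs()] to append.
#' @return Numeric matrix with one row per sample.
#' @export
covariate_matrix <- function(metadata, covariates = colnames(metadata),
                             pcs = NULL) {
  if (length(covariates) == 0L && is.null(pcs)) {
    return(matrix(numeric(0), nrow = nrow(metadata), ncol = 0))
  }
  X <- NULL
  if (length(covariates) > 0L) {
    missing_cols <- setdiff(covariates, colnames(metadata))
    if (length(missing_cols)) {
      stop("covariates absent from metadata: ",
           paste(missing_cols, collapse = ", "))
    }
    df <- metadata[, covariates, drop = FALSE]
    X <- stats::model.matrix(~ ., data = df)[, -1L, drop = FALSE]
  }
  if (!is.null(pcs)) {
    X <- if (is.null(X)) as.matrix(pcs) else cbind(X, as.matrix(pcs))
  }
  if (anyNA(X)) stop("covariate matrix contains missing values")
  rownames(X) <- rownames(metadata)
  X
}
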