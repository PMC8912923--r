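#' Select seasonal hit CpGs by FDR and amplitude
#'
#' A pure filter on an EWAS table: CpGs with \code{q_value <
#' fdr_threshold} and a modelled seasonal amplitude of at least
#' \code{min_amplitude_pct} percentage points. The amplitude floor removes
#' statistically significant but biologically negligible effects.
#'
#' @param ewas An \code{ewas_table} from [run_ewas()].
#' @param fdr_threshold FDR cut-off. Default 0.05.
#' @param min_amplitude_pct Minimum beta-scale amplitude (percentage
#'   points); CpGs with amplitude strictly below this are excluded.
#'   Default 4.
#' @return A [cpg_set()] labelled \code{"soc_cpg"} with thresholds in its
#'   provenance.
#' @export
select_soc_cpgs <- function(ewas, fdr_threshold = 0.05,
                            min_amplitude_pct = 4) {
  stopifnot(all(c("q_value", "amplitude_pct") %in% colnames(ewas)))
  keep <- !is.na(ewas$q_value) & ewas$q_value < fdr_threshold &
    ewas$amplitude_pct >= min_amplitude_pct
  cpg_set("soc_cpg", ewas$cpg_id[keep],
          provenance = list(fdr_threshold = fdr_threshold,
                            min_amplitude_pct = min_amplitude_pct,
                            n_tested = nrow(ewas)))
}

#' Select distribution-matched control CpGs
#'
#' For each target CpG, finds a control CpG from the background whose
#' methylation beta distribution is statistically indistinguishable from
#' the target's by a two-sided Kolmogorov-Smirnov test (p above
#' \code{ks_p_threshold}). Matching is greedy and one-to-one: targets are
#' processed in shuffled order, candidates are drawn without replacement
#' from the shuffled background, and the first admissible candidate is
#' accepted. Controls are disjoint from the targets and from all exclusion
#' sets.
#'
#' @param targets A [cpg_set()] of CpGs to match.
#' @param background A [methylation_matrix()] containing both targets and
#'   candidate controls.
#' @param exclusions List of [cpg_set()]s to exclude from the candidate
#'   pool (e.g. all seasonal-associated CpGs and known metastable
#'   epialleles).
#' @param ks_p_threshold Minimum KS p-value for acceptance. Default 0.1.
#' @param seed Integer seed for the shuffles.
#' @return A [cpg_set()] labelled \code{"matched_control"}, with a
#'   \code{match} data.frame (target, control, KS statistic and p) in its
#'   provenance.
#' @export
select_matched_controls <- function(targets, background,
                                    exclusions = list(),
                                    ks_p_threshold = 0.1, seed = 1L) {
  stopifnot(inherits(targets, "cpg_set"),
            inherits(background, "methylation_matrix"))
  excl <- unique(c(targets$cpg_ids,
                   unlist(lapply(exclusions, function(s) s$cpg_ids))))
  pool <- setdiff(background$cpg_ids, excl)
  if (length(pool) < length(targets$cpg_ids)) {
    stop("background smaller than target set after exclusions")
  }
  set.seed(seed)
  target_order <- sample(targets$cpg_ids)
  pool <- sample(pool)
  chosen <- character(0)
  rows <- vector("list", length(target_order))
  for (i in seq_along(target_order)) {
    tg <- target_order[i]
    tv <- background$betas[, tg]
    tv <- tv[!is.na(tv)]
    found <- FALSE
    for (cand in pool) {
      cv <- background$betas[, cand]
      cv <- cv[!is.na(cv)]
      ks <- suppressWarnings(stats::ks.test(tv, cv))
      if (ks$p.value > ks_p_threshold) {
        chosen <- c(chosen, cand)
        pool <- setdiff(pool, cand)
        rows[[i]] <- data.frame(target = tg, control = cand,
                                ks_stat = unname(ks$statistic),
                                ks_p = ks$p.value,
                                stringsAsFactors = FALSE)
        found <- TRUE
        break
      }
    }
    if (!found) stop("no admissible matched control for target ", tg)
  }
  cpg_set("matched_control", chosen,
          provenance = list(ks_p_threshold = ks_p_threshold, seed = seed,
                            match = do.call(rbind, rows)))
}

#' Select random control CpGs
#'
#' Uniform sample without replacement from the background, excluding the
#' supplied sets.
#'
#' @param n Number of controls.
#' @param background A [methylation_matrix()] or character vector of
#'   background CpG ids.
#' @param exclusions List of [cpg_set()]s to exclude.
#' @param seed Integer seed.
#' @return A [cpg_set()] labelled \code{"random_control"}.
#' @export
select_random_controls <- function(n, background, exclusions = list(),
                                   seed = 1L) {
  ids <- if (inherits(background, "methylation_matrix"))
    background$cpg_ids else as.character(background)
  excl <- unique(unlist(lapply(exclusions, function(s) s$cpg_ids)))
  pool <- setdiff(ids, excl)
  if (length(pool) < n) stop("insufficient background after exclusions")
  set.seed(seed)
  cpg_set("random_control", sample(pool, n),
          provenance = list(seed = seed, n = n,
                            excluded = vapply(exclusions, function(s)
                              s$label, character(1))))
}

# Wilcoxon signed-rank test with the Pratt treatment of zero differences:
# zeros are kept in the ranking of |d| but contribute nothing to the
# statistic; normal approximation with zero/tie variance correction.
wilcoxon_pratt <- function(d) {
  n <- length(d)
  if (all(d == 0)) return(list(statistic = 0, p = 1))
  r <- rank(abs(d))
  nonzero <- d != 0
  v_plus <- sum(r[nonzero & d > 0])
  n0 <- sum(!nonzero)
  mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  ties <- table(r[nonzero])
  sigma2 <- (n * (n + 1) * (2 * n + 1) -
               n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  z <- (v_plus - mu) / sqrt(sigma2)
  z <- z - sign(z) * min(0.5 / sqrt(sigma2), abs(z))  # continuity corr.
  list(statistic = v_plus, p = 2 * stats::pnorm(-abs(z)))
}

#' Cross-dataset replication and attenuation statistics
#'
#' Compares seasonal fits of the same CpGs between two EWAS tables (e.g.
#' two cohorts, or the same cohort at two ages): Spearman correlation of
#' peak days (linear day-of-year values by default, matching the common
#' practice; a circular option avoids sensitivity to the 1 January cut),
#' paired amplitude differences with a two-sided Wilcoxon signed-rank test
#' (Pratt handling of zero differences; all-zero differences report
#' p = 1), and the count of CpGs replicating at \code{q < 0.05} in the
#' second table.
#'
#' @param ewas_a,ewas_b \code{ewas_table}s sharing the CpGs of interest;
#'   \code{a} is the discovery table, deltas are \code{b - a}.
#' @param cpgs A [cpg_set()] (or character vector) of CpGs to compare;
#'   at least 3 must be present in both tables.
#' @param circular_phase Use a circular rank correlation surrogate
#'   (correlation of sin/cos-embedded days) instead of linear Spearman.
#'   Default \code{FALSE}.
#' @return A list of class \code{replication_report}: \code{n_cpgs},
#'   \code{phase_rho}, \code{phase_p}, \code{amplitude_delta} (named
#'   vector, b - a), \code{median_delta}, \code{wilcoxon_stat},
#'   \code{wilcoxon_p}, \code{n_replicated}.
#' @export
replication_stats <- function(ewas_a, ewas_b, cpgs,
                              circular_phase = FALSE) {
  ids <- if (inherits(cpgs, "cpg_set")) cpgs$cpg_ids else as.character(cpgs)
  ids <- ids[ids %in% ewas_a$cpg_id & ids %in% ewas_b$cpg_id]
  if (length(ids) < 3) stop("fewer than 3 shared CpGs")
  a <- ewas_a[match(ids, ewas_a$cpg_id), ]
  b <- ewas_b[match(ids, ewas_b$cpg_id), ]

  if (circular_phase) {
    ang_a <- 2 * pi * a$peak_day / 365.25
    ang_b <- 2 * pi * b$peak_day / 365.25
    ct <- stats::cor.test(sin(ang_a) + cos(ang_a),
                          sin(ang_b) + cos(ang_b), method = "spearman",
                          exact = FALSE)
  } else {
    ct <- suppressWarnings(
      stats::cor.test(a$peak_day, b$peak_day, method = "spearman",
                      exact = FALSE))
  }
  delta <- stats::setNames(b$amplitude_pct - a$amplitude_pct, ids)
  wt <- wilcoxon_pratt(delta)
  structure(list(
    n_cpgs = length(ids),
    phase_rho = unname(ct$estimate), phase_p = ct$p.value,
    amplitude_delta = delta,
    median_delta = stats::median(delta),
    wilcoxon_stat = wt$statistic, wilcoxon_p = wt$p,
    n_replicated = sum(b$q_value < 0.05, na.rm = TRUE)
  ), class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf(paste0(
    "replication_report: %d CpGs; peak-day Spearman rho = %.3f ",
    "(p = %.3g); median amplitude delta = %.3f pct ",
    "(Wilcoxon p = %.3g); %d replicated at q < 0.05\n"),
    x$n_cpgs, x$phase_rho, x$phase_p, x$median_delta, x$wilcoxon_p,
    x$n_replicated))
  invisible(x)
}
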