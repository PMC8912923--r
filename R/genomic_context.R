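#' Annotation track: genomic intervals or a CpG id set
#'
#' Represents an external annotation (metastable epialleles,
#' parent-of-origin methylation, germline DMRs, retroviral elements,
#' transcription-factor binding sites, ...) either as genomic intervals
#' (a \code{GRanges}, 1-based closed; BED input is converted on read by
#' [read_bed_track()]) or as an explicit CpG id set.
#'
#' @param name Track name.
#' @param intervals A \code{GRanges} of intervals, or \code{NULL}.
#' @param cpg_ids Character vector of member CpG ids, or \code{NULL}.
#' @return An object of class \code{annotation_track}.
#' @export
annotation_track <- function(name, intervals = NULL, cpg_ids = NULL) {
  if (is.null(intervals) && is.null(cpg_ids)) {
    stop("provide intervals or cpg_ids")
  }
  if (!is.null(intervals)) {
    stopifnot(methods::is(intervals, "GRanges"))
    if (any(IRanges::width(intervals) < 1)) {
      stop("intervals must have positive width")
    }
  }
  structure(list(name = name, intervals = intervals, cpg_ids = cpg_ids),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  what <- if (!is.null(x$intervals))
    sprintf("%d intervals", length(x$intervals)) else
    sprintf("%d CpG ids", length(x$cpg_ids))
  cat(sprintf("annotation_track '%s': %s\n", x$name, what))
  invisible(x)
}

#' Cluster CpGs by genomic proximity
#'
#' Single-linkage chaining per chromosome: adjacent CpGs whose gap is at
#' most \code{max_gap_bp} (inclusive) join the same cluster; CpGs with no
#' neighbour within the gap are singletons. Every CpG belongs to exactly
#' one cluster, and the result is invariant to input order.
#'
#' @param coordinates data.frame with columns \code{cpg_id}, \code{chrom},
#'   \code{pos} (1-based).
#' @param max_gap_bp Maximum distance to the nearest neighbouring CpG
#'   within a cluster. Default 5000.
#' @return data.frame with one row per CpG: \code{cpg_id}, \code{chrom},
#'   \code{pos}, \code{cluster_id}, \code{cluster_size},
#'   \code{is_singleton}; plus attribute \code{n_clusters} (multi-CpG
#'   clusters only) and \code{n_singletons}.
#' @examples
#' co <- data.frame(cpg_id = c("a", "b", "c"), chrom = "chr1",
#'                  pos = c(100, 4000, 9500))
#' build_clusters(co)  # {a,b} cluster, c singleton
#' @export
build_clusters <- function(coordinates, max_gap_bp = 5000) {
  stopifnot(all(c("cpg_id", "chrom", "pos") %in% colnames(coordinates)))
  if (anyDuplicated(paste(coordinates$chrom, coordinates$pos))) {
    stop("duplicate (chrom, pos) coordinates")
  }
  ord <- order(coordinates$chrom, coordinates$pos)
  co <- coordinates[ord, , drop = FALSE]
  new_cluster <- c(TRUE, co$chrom[-1] != co$chrom[-nrow(co)] |
                     diff(co$pos) > max_gap_bp)
  cl <- cumsum(new_cluster)
  co$cluster_id <- sprintf("cl%05d", cl)
  size <- table(cl)
  co$cluster_size <- as.integer(size[as.character(cl)])
  co$is_singleton <- co$cluster_size == 1L
  out <- co[match(coordinates$cpg_id, co$cpg_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_clusters") <- sum(size > 1)
  attr(out, "n_singletons") <- sum(size == 1)
  out
}

#' De-cluster a CpG set
#'
#' Collapses genomic clusters to a single signal: one randomly sampled
#' member per multi-CpG cluster, while singleton CpGs are always kept.
#' Used so that runs of adjacent correlated CpGs contribute one unit to
#' enrichment analyses.
#'
#' @param set A [cpg_set()] (or character vector of CpG ids).
#' @param clusters Clustering of (at least) those CpGs from
#'   [build_clusters()]; clusters are recomputed on the subset of rows
#'   belonging to the set, so members of a cluster outside the set do not
#'   count.
#' @param seed Integer seed for the within-cluster sampling.
#' @return A [cpg_set()] with the de-clustered ids.
#' @export
decluster <- function(set, clusters, seed = 1L) {
  ids <- if (inherits(set, "cpg_set")) set$cpg_ids else as.character(set)
  label <- if (inherits(set, "cpg_set")) set$label else "custom"
  idx <- match(ids, clusters$cpg_id)
  if (anyNA(idx)) {
    stop("CpG(s) absent from clustering: ",
         paste(utils::head(ids[is.na(idx)], 3), collapse = ", "))
  }
  sub <- clusters[idx, , drop = FALSE]
  set.seed(seed)
  keep <- unlist(lapply(split(sub$cpg_id, sub$cluster_id), function(members) {
    if (length(members) == 1L) members else sample(members, 1L)
  }), use.names = FALSE)
  cpg_set(paste0(label, "_declustered"), keep,
          provenance = list(seed = seed, n_input = length(ids)))
}

# logical overlap of point CpGs with a track, within proximity_bp
.track_overlap <- function(cpg_ids, coordinates, track, proximity_bp = 0) {
  if (!is.null(track$cpg_ids)) {
    return(cpg_ids %in% track$cpg_ids)
  }
  idx <- match(cpg_ids, coordinates$cpg_id)
  if (anyNA(idx)) stop("CpG(s) missing coordinates")
  gr <- GenomicRanges::GRanges(
    seqnames = coordinates$chrom[idx],
    ranges = IRanges::IRanges(start = coordinates$pos[idx], width = 1L))
  hits <- GenomicRanges::countOverlaps(gr, track$intervals,
                                       maxgap = proximity_bp)
  hits > 0
}

#' Annotation enrichment of a CpG set over background
#'
#' Two-sided Fisher exact test of the 2x2 table (set vs background
#' excluding the set, by overlap with the track). A CpG overlaps the track
#' if its position is within \code{proximity_bp} of any interval (0 means
#' direct overlap); for id-set tracks, membership is used. The fold is
#' \code{(set_overlap/set_total) / (bg_overlap/bg_total)} with the
#' background taken as the full universe including the set. The
#' cluster-adjusted variant de-clusters both the set and the background,
#' repeats over \code{cluster_seeds} random draws and reports the median
#' fold and p.
#'
#' @param set A [cpg_set()]; must be a subset of \code{background}.
#' @param track An [annotation_track()].
#' @param background A [cpg_set()] or character vector: the CpG universe.
#' @param coordinates data.frame (\code{cpg_id}, \code{chrom}, \code{pos})
#'   covering the background (needed for interval tracks).
#' @param proximity_bp Overlap slack in bp. Default 0.
#' @param cluster_adjust De-cluster set and background first. Default
#'   \code{FALSE}.
#' @param max_gap_bp Cluster gap used when \code{cluster_adjust}.
#' @param cluster_seeds Seeds of the repeated de-clustered draws.
#' @return List of class \code{enrichment_result}: \code{set_label},
#'   \code{track_name}, \code{fold} (\code{NA} when the background rate is
#'   0), \code{p_value}, \code{counts} (set_overlap, set_total,
#'   bg_overlap, bg_total), \code{cluster_adjusted}.
#' @export
overlap_enrichment <- function(set, track, background, coordinates = NULL,
                               proximity_bp = 0, cluster_adjust = FALSE,
                               max_gap_bp = 5000, cluster_seeds = 1:100) {
  set_ids <- if (inherits(set, "cpg_set")) set$cpg_ids else
    as.character(set)
  bg_ids <- if (inherits(background, "cpg_set")) background$cpg_ids else
    as.character(background)
  if (!all(set_ids %in% bg_ids)) {
    stop("set must be a subset of the background")
  }
  set_label <- if (inherits(set, "cpg_set")) set$label else "custom"

  if (cluster_adjust) {
    if (is.null(coordinates)) stop("coordinates needed to de-cluster")
    cl <- build_clusters(coordinates[coordinates$cpg_id %in% bg_ids, ,
                                     drop = FALSE], max_gap_bp)
    draws <- lapply(cluster_seeds, function(s) {
      ds <- decluster(set_ids, cl, seed = s)$cpg_ids
      db <- decluster(bg_ids, cl, seed = s)$cpg_ids
      # keep the declustered set inside the declustered background
      db <- union(db, ds)
      one <- overlap_enrichment(cpg_set(set_label, ds), track, db,
                                coordinates, proximity_bp,
                                cluster_adjust = FALSE)
      c(fold = one$fold, p = one$p_value)
    })
    m <- do.call(rbind, draws)
    res <- overlap_enrichment(cpg_set(set_label, set_ids), track, bg_ids,
                              coordinates, proximity_bp,
                              cluster_adjust = FALSE)
    res$fold <- stats::median(m[, "fold"])
    res$p_value <- stats::median(m[, "p"])
    res$cluster_adjusted <- TRUE
    return(res)
  }

  ov <- .track_overlap(bg_ids, coordinates, track, proximity_bp)
  names(ov) <- bg_ids
  in_set <- bg_ids %in% set_ids
  set_overlap <- sum(ov[in_set])
  set_total <- sum(in_set)
  bg_overlap <- sum(ov)
  bg_total <- length(bg_ids)
  fold <- if (bg_overlap > 0)
    (set_overlap / set_total) / (bg_overlap / bg_total) else NA_real_
  tab <- matrix(c(set_overlap, set_total - set_overlap,
                  bg_overlap - set_overlap,
                  (bg_total - set_total) - (bg_overlap - set_overlap)),
                nrow = 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  structure(list(set_label = set_label, track_name = track$name,
                 fold = fold, p_value = p,
                 counts = c(set_overlap = set_overlap,
                            set_total = set_total,
                            bg_overlap = bg_overlap, bg_total = bg_total),
                 cluster_adjusted = FALSE),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: %s vs %s%s: fold = %s, p = %.3g (%d/%d vs %d/%d)\n",
    x$set_label, x$track_name,
    if (x$cluster_adjusted) " [cluster-adjusted]" else "",
    formatC(x$fold, digits = 3, format = "fg"), x$p_value,
    x$counts["set_overlap"], x$counts["set_total"],
    x$counts["bg_overlap"], x$counts["bg_total"]))
  invisible(x)
}

#' Proportion of a CpG set proximal to a track, with bootstrap CIs
#'
#' For each distance \code{d}, the proportion of the (de-clustered) set
#' lying within \code{d} bp of any track interval; a CpG inside an
#' interval has distance 0. Percentile 95% confidence intervals come from
#' bootstrap resampling of the de-clustered CpG set.
#'
#' @param set A [cpg_set()] or character vector (non-empty).
#' @param track An [annotation_track()] with intervals.
#' @param distances Positive, ascending distances in bp.
#' @param coordinates data.frame (\code{cpg_id}, \code{chrom},
#'   \code{pos}).
#' @param n_boot Number of bootstrap resamples. Default 1000.
#' @param declustered De-cluster the set first (one CpG per cluster).
#'   Default \code{TRUE}.
#' @param max_gap_bp Cluster gap. Default 5000.
#' @param seed Integer seed.
#' @return data.frame with \code{distance_bp}, \code{proportion},
#'   \code{ci_lo}, \code{ci_hi}, \code{n_cpgs}.
#' @export
proximity_curve <- function(set, track, distances, coordinates,
                            n_boot = 1000, declustered = TRUE,
                            max_gap_bp = 5000, seed = 1L) {
  ids <- if (inherits(set, "cpg_set")) set$cpg_ids else as.character(set)
  if (length(ids) == 0) stop("empty CpG set")
  if (any(distances <= 0) || is.unsorted(distances)) {
    stop("distances must be positive and ascending")
  }
  if (declustered) {
    cl <- build_clusters(coordinates[coordinates$cpg_id %in% ids, ,
                                     drop = FALSE], max_gap_bp)
    ids <- decluster(ids, cl, seed = seed)$cpg_ids
  }
  idx <- match(ids, coordinates$cpg_id)
  if (anyNA(idx)) stop("CpG(s) missing coordinates")
  gr <- GenomicRanges::GRanges(
    seqnames = coordinates$chrom[idx],
    ranges = IRanges::IRanges(start = coordinates$pos[idx], width = 1L))
  d_near <- GenomicRanges::distanceToNearest(gr, track$intervals)
  dist_bp <- rep(Inf, length(gr))
  dist_bp[S4Vectors::queryHits(d_near)] <-
    S4Vectors::mcols(d_near)$distance

  set.seed(seed)
  n <- length(ids)
  boot_idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  out <- lapply(distances, function(d) {
    within <- dist_bp <= d
    prop <- mean(within)
    boot_props <- colMeans(matrix(within[boot_idx], nrow = n))
    ci <- stats::quantile(boot_props, c(0.025, 0.975), names = FALSE)
    data.frame(distance_bp = d, proportion = prop,
               ci_lo = ci[1], ci_hi = ci[2], n_cpgs = n)
  })
  do.call(rbind, out)
}

#' Classify a CpG's gametic methylation status
#'
#' Applies the germline differential-methylation thresholds: an
#' oocyte-methylated germline DMR (\code{oo_gDMR}) has sperm methylation
#' below 25% and oocyte methylation above 75%; the symmetric
#' \code{sperm_gDMR} has oocyte below 25% and sperm above 75%;
#' \code{sperm_hypo_only} covers CpGs with sperm methylation at or below
#' 25% that do not qualify as oo-gDMRs; everything else is \code{none}.
#' Note the deliberate boundary asymmetry: sperm hypomethylation is
#' defined inclusively (<= 25%) while the oo-gDMR sperm threshold is
#' strict (< 25%), so a CpG at exactly 25% sperm methylation can be
#' \code{sperm_hypo_only} but never \code{oo_gDMR}.
#'
#' @param sperm_pct,oocyte_pct Methylation percentages in \code{[0, 100]}
#'   (vectorised).
#' @return Character vector of statuses.
#' @examples
#' classify_gamete_status(10, 90)  # "oo_gDMR"
#' @export
classify_gamete_status <- function(sperm_pct, oocyte_pct) {
  if (any(sperm_pct < 0 | sperm_pct > 100 |
          oocyte_pct < 0 | oocyte_pct > 100, na.rm = TRUE)) {
    stop("methylation percentages must lie in [0, 100]")
  }
  out <- rep("none", length(sperm_pct))
  out[sperm_pct <= 25] <- "sperm_hypo_only"
  out[sperm_pct < 25 & oocyte_pct > 75] <- "oo_gDMR"
  out[oocyte_pct < 25 & sperm_pct > 75] <- "sperm_gDMR"
  out
}
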