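#' Write / read a methylation matrix as TSV
#'
#' The on-disk layout is CpG rows by sample columns with a leading
#' \code{cpg_id} column plus \code{chrom} and \code{pos} columns. The
#' reader auto-orients: a file with a leading \code{sample_id} column
#' (samples in rows) is transposed on read; coordinates may then be
#' supplied separately.
#'
#' @param mat A [methylation_matrix()].
#' @param path Output file path.
#' @return \code{write_methylation_tsv}: the path, invisibly;
#'   \code{read_methylation_tsv}: a [methylation_matrix()].
#' @export
write_methylation_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "methylation_matrix"))
  dt <- data.table::data.table(cpg_id = mat$cpg_ids, chrom = mat$chrom,
                               pos = mat$pos)
  dt <- cbind(dt, data.table::as.data.table(t(mat$betas)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @param path File path to read.
#' @param chrom,pos Coordinates to attach when the file is sample-major
#'   and carries none.
#' @rdname write_methylation_tsv
#' @export
read_methylation_tsv <- function(path, chrom = NULL, pos = NULL) {
  dt <- data.table::fread(path, sep = "\t")
  first <- colnames(dt)[1]
  if (first == "cpg_id") {
    cpgs <- dt$cpg_id
    chrom <- if ("chrom" %in% colnames(dt)) dt$chrom else chrom
    pos <- if ("pos" %in% colnames(dt)) dt$pos else pos
    value_cols <- setdiff(colnames(dt), c("cpg_id", "chrom", "pos"))
    betas <- t(as.matrix(dt[, value_cols, with = FALSE]))
    colnames(betas) <- cpgs
    rownames(betas) <- value_cols
  } else if (first == "sample_id") {
    samples <- dt$sample_id
    betas <- as.matrix(dt[, -1])
    rownames(betas) <- samples
  } else {
    stop("cannot orient file: first column must be cpg_id or sample_id")
  }
  if (is.null(chrom)) chrom <- rep("chrUn", ncol(betas))
  if (is.null(pos)) pos <- seq_len(ncol(betas))
  methylation_matrix(betas, chrom, pos)
}

#' Write / read sample metadata CSV
#'
#' Dates are serialised as ISO-8601 strings and parsed back to
#' \code{Date}.
#'
#' @param metadata data.frame with at least \code{sample_id} and
#'   \code{conception_date}.
#' @param path File path.
#' @return The path (writer, invisibly) or the metadata data.frame
#'   (reader).
#' @export
write_metadata_csv <- function(metadata, path) {
  data.table::fwrite(metadata, path, dateTimeAs = "ISO")
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  for (col in intersect(c("conception_date", "collection_date"),
                        colnames(df))) {
    df[[col]] <- as.Date(df[[col]])
  }
  df
}

#' Write / read a genotype dosage TSV
#'
#' Layout: one row per SNP with \code{snp_id}, \code{chrom}, \code{pos},
#' then one dosage column per sample.
#'
#' @param genotypes A \code{genotype_matrix}.
#' @param path File path.
#' @return The path (writer, invisibly) or a \code{genotype_matrix}
#'   (reader).
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dt <- data.table::data.table(snp_id = genotypes$snp_ids,
                               chrom = genotypes$chrom,
                               pos = genotypes$pos)
  dt <- cbind(dt, data.table::as.data.table(t(genotypes$dosages)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  value_cols <- setdiff(colnames(dt), c("snp_id", "chrom", "pos"))
  dos <- t(as.matrix(dt[, value_cols, with = FALSE]))
  storage.mode(dos) <- "integer"
  colnames(dos) <- dt$snp_id
  rownames(dos) <- value_cols
  f <- colMeans(dos) / 2
  structure(list(dosages = dos, snp_ids = dt$snp_id,
                 chrom = as.character(dt$chrom), pos = as.integer(dt$pos),
                 maf = pmin(f, 1 - f),
                 n_hom = pmin(colSums(dos == 0L), colSums(dos == 2L))),
            class = "genotype_matrix")
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT genotypes reconstructed from dosages
#' (0 -> 0/0, 1 -> 0/1, 2 -> 1/1) and placeholder REF/ALT alleles, enough
#' for interchange with standard genotype tooling.
#'
#' @param genotypes A \code{genotype_matrix}.
#' @param path Output path (plain text).
#' @return The path, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  samples <- rownames(genotypes$dosages)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_along(genotypes$snp_ids), function(s) {
    paste(c(genotypes$chrom[s], genotypes$pos[s], genotypes$snp_ids[s],
            "A", "G", ".", "PASS", ".", "GT",
            gt_code[genotypes$dosages[, s] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read an annotation track as BED
#'
#' BED uses 0-based half-open intervals; the in-memory representation is
#' a 1-based closed \code{GRanges}, so coordinates are shifted on the
#' way in and out.
#'
#' @param track An [annotation_track()] with intervals.
#' @param path File path.
#' @return The path (writer, invisibly) or an [annotation_track()]
#'   (reader).
#' @export
write_bed_track <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  if (is.null(track$intervals)) stop("track has no intervals")
  gr <- track$intervals
  data.table::fwrite(
    data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
      end = GenomicRanges::end(gr),
      name = track$name),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @param name Track name to assign on read; defaults to the BED name
#'   column when present.
#' @rdname write_bed_track
#' @export
read_bed_track <- function(path, name = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3) stop("BED needs at least chrom, start, end")
  gr <- GenomicRanges::GRanges(
    seqnames = dt[[1]],
    ranges = IRanges::IRanges(start = dt[[2]] + 1L,  # from 0-based
                              end = dt[[3]]))
  if (is.null(name)) {
    name <- if (ncol(dt) >= 4) as.character(dt[[4]][1]) else "track"
  }
  annotation_track(name, intervals = gr)
}

#' Write an EWAS table (or any result data.frame) as TSV
#'
#' @param tab data.frame.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_results_tsv <- function(tab, path) {
  data.table::fwrite(as.data.frame(tab), path, sep = "\t")
  invisible(path)
}

#' Write a CpG set as a one-column TSV with a provenance side-car
#'
#' @param set A [cpg_set()].
#' @param path File path; the provenance is written next to it as
#'   \code{<path>.provenance.txt}.
#' @return The path, invisibly.
#' @export
write_cpg_set <- function(set, path) {
  stopifnot(inherits(set, "cpg_set"))
  writeLines(set$cpg_ids, path)
  prov <- set$provenance
  prov <- prov[!vapply(prov, is.data.frame, logical(1))]
  lines <- c(paste0("label: ", set$label),
             vapply(names(prov), function(nm)
               paste0(nm, ": ", paste(format(prov[[nm]]), collapse = ",")),
               character(1)))
  writeLines(lines, paste0(path, ".provenance.txt"))
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Emits the full text bundle: methylation TSV, metadata CSV, dosage TSV,
#' minimal VCF, one BED per annotation track and the truth tables.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_methylation_tsv(cohort$methylation,
                        file.path(dir, "methylation.tsv"))
  write_metadata_csv(cohort$metadata, file.path(dir, "metadata.csv"))
  write_dosage_tsv(cohort$genotypes, file.path(dir, "dosages.tsv"))
  write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  for (tr in cohort$tracks) {
    write_bed_track(tr, file.path(dir, paste0("track_", tr$name, ".bed")))
  }
  write_results_tsv(cohort$truth$cpgs, file.path(dir, "truth_cpgs.tsv"))
  write_results_tsv(cohort$truth$mqtl, file.path(dir, "truth_mqtl.tsv"))
  invisible(dir)
}
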