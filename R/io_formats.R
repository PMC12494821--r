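## On-disk contracts: VCF 4.x (GT only), BED4 interval tracks, result TSVs.
## Coordinates: VCF is 1-based inclusive, BED is 0-based half-open; window
## reports elsewhere in the package use 1-based inclusive spans.

#' Read a bi-allelic VCF into variant records and a genotype matrix
#'
#' Parses a VCF 4.x file (only the GT field is used) into a variant table and
#' a sparse samples-by-variants matrix of non-reference allele counts
#' (0/1/2). Multi-allelic records are an error: the pipeline expects
#' bi-allelic SNVs/indels. Missing genotypes (`./.`) are imputed as
#' homozygous reference for burden construction; the returned
#' `missing_rate` column records the per-variant missingness so that
#' single-variant tests can exclude them from MAC if desired.
#'
#' MAF/MAC are computed on the sample subset actually returned.
#'
#' @param path path to an uncompressed or bgzipped VCF file.
#' @param sample_subset optional character vector of sample IDs to keep (in
#'   the returned order).
#' @return list with `variants` (data.frame: chrom, pos, ref, alt, is_snv,
#'   ac, mac, maf, missing_rate) and `genotypes` (dgCMatrix, samples x
#'   variants, rownames = sample IDs).
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1]
    stopf("multi-allelic record at %s:%s (ALT=%s); split or drop it first",
          fix[i, "CHROM"], fix[i, "POS"], alt[i])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stopf("VCF has no GT field: %s", path)
  gt <- t(gt)  # samples x variants
  if (!is.null(sample_subset)) {
    missing_samples <- setdiff(sample_subset, rownames(gt))
    if (length(missing_samples) > 0)
      stopf("samples not in VCF: %s", paste(missing_samples, collapse = ", "))
    gt <- gt[sample_subset, , drop = FALSE]
  }
  codes <- gsub("|", "/", gt, fixed = TRUE)
  counts <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  counts[codes == "0/1" | codes == "1/0"] <- 1L
  counts[codes == "1/1"] <- 2L
  is_missing <- codes == "./." | is.na(codes)
  known <- c("0/0", "0/1", "1/0", "1/1", "./.")
  bad <- !(codes %in% known) & !is.na(codes)
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1, ]
    stopf("malformed GT '%s' for sample %s at %s:%s", gt[j[1], j[2]],
          rownames(gt)[j[1]], fix[j[2], "CHROM"], fix[j[2], "POS"])
  }
  counts[is_missing] <- 0L  # documented policy: impute missing as hom-ref
  g <- methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix")
  ac <- allele_counts(g)
  variants <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = alt,
    is_snv = nchar(fix[, "REF"]) == 1L & nchar(alt) == 1L,
    ac = ac$ac, mac = ac$mac, maf = ac$maf,
    missing_rate = colMeans(is_missing),
    stringsAsFactors = FALSE
  )
  rownames(variants) <- NULL
  list(variants = variants, genotypes = g)
}

#' Write variants and genotypes as a minimal VCF
#'
#' Inverse of [read_vcf()] for the fields this package uses; writing then
#' reading back reproduces genotypes and coordinates exactly.
#'
#' @param variants data.frame with chrom, pos, ref, alt.
#' @param genotypes samples x variants matrix of 0/1/2 counts.
#' @param path output path.
#' @export
write_vcf <- function(variants, genotypes, path) {
  stopifnot(nrow(variants) == ncol(genotypes))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  samples <- rownames(genotypes) %||% paste0("S", seq_len(nrow(genotypes)))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  g <- as.matrix(genotypes)
  ## write in blocks to bound the number of long strings held at once
  for (idx in chunk_indices(nrow(variants), 5000L)) {
    block <- vapply(idx, function(j) {
      paste(c(variants$chrom[j], variants$pos[j], ".", variants$ref[j],
              variants$alt[j], ".", "PASS", ".", "GT",
              gt_codes[g[, j] + 1L]), collapse = "\t")
    }, character(1))
    writeLines(block, con)
  }
  invisible(path)
}

#' Read a BED4 interval track
#'
#' BED intervals are 0-based half-open. Single-label tracks (e.g. a
#' chromatin-state partition of the genome) must not contain overlapping
#' intervals; multi-label tracks (e.g. repeat classes) may.
#'
#' @param path path to a 4+ column BED file (chrom, start, end, label).
#' @param name track name.
#' @param multi_label logical; whether overlapping intervals are allowed.
#' @return an `interval_track`: list(name, multi_label, intervals =
#'   data.frame(chrom, start, end, label)).
#' @export
read_bed_track <- function(path, name, multi_label = FALSE) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(interval_track(name, data.frame(chrom = character(), start = integer(),
                                           end = integer(), label = character()),
                          multi_label))
  }
  bed <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stopf("BED track '%s' needs >= 4 columns", name)
  intervals <- data.frame(chrom = as.character(bed[[1]]),
                          start = as.integer(bed[[2]]),
                          end = as.integer(bed[[3]]),
                          label = as.character(bed[[4]]),
                          stringsAsFactors = FALSE)
  bad <- which(intervals$start >= intervals$end)
  if (length(bad) > 0)
    stopf("BED track '%s': start >= end at line %d", name, bad[1])
  interval_track(name, intervals, multi_label)
}

#' Construct an interval track
#'
#' @param name track name.
#' @param intervals data.frame with chrom, start (0-based), end (exclusive),
#'   label.
#' @param multi_label whether intervals of different labels may overlap.
#' @export
interval_track <- function(name, intervals, multi_label = FALSE) {
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  if (!multi_label && nrow(intervals) > 1) {
    by_chrom <- split(intervals, intervals$chrom)
    for (ch in by_chrom) {
      if (nrow(ch) > 1 && any(ch$start[-1] < ch$end[-nrow(ch)]))
        stopf("track '%s' declared single-label but has overlapping intervals on %s",
              name, ch$chrom[1])
    }
  }
  structure(list(name = name, multi_label = multi_label, intervals = intervals),
            class = "interval_track")
}

#' Write an interval track as BED4
#' @param track an `interval_track`.
#' @param path output path.
#' @export
write_bed_track <- function(track, path) {
  write.table(track$intervals, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

track_to_granges <- function(track) {
  GenomicRanges::GRanges(
    seqnames = track$intervals$chrom,
    ranges = IRanges::IRanges(start = track$intervals$start + 1L,
                              end = track$intervals$end),
    label = track$intervals$label)
}

result_columns <- c("unit", "kind", "model", "estimate", "or", "se", "p",
                    "direction", "n_variants", "flag")

#' Write association results as TSV
#'
#' Fixed column order (unit, kind, model, estimate, or, se, p, direction,
#' n_variants, flag); p-values are written in scientific notation at full
#' double precision so a read-back round-trips.
#'
#' @param results data.frame of association results.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  out <- as.data.frame(results)[, result_columns, drop = FALSE]
  for (col in c("estimate", "or", "se", "p")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read association results written by [write_results()]
#' @param path TSV path.
#' @export
read_results <- function(path) {
  res <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(unit = "character", kind = "character",
                                   model = "character", flag = "character"))
  res
}

## Canonical empty AssocResult table.
assoc_result <- function(unit, kind, model, estimate, se, p, n_variants,
                         flag = "ok") {
  data.frame(unit = as.character(unit), kind = kind, model = model,
             estimate = estimate, or = exp(estimate), se = se, p = p,
             direction = sign(estimate), n_variants = n_variants,
             flag = flag, stringsAsFactors = FALSE)
}
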