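# VCF and popmap I/O. Reading goes through VariantAnnotation; writing is a
# plain-text formatter so exports stay greppable and bgzip-free.

#' Read a sample-to-population map
#'
#' @param path two-column headerless TSV: sample_id, population.
#' @return data.frame(sample_id, population).
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample_id", "population"),
                          colClasses = "character")
  if (anyDuplicated(pm$sample_id)) stop("duplicate sample ids in popmap")
  pm
}

#' Read genotypes from a VCF into a genotype matrix
#'
#' Loads biallelic single-nucleotide records only; multiallelic records,
#' indels and records with non-ACGT alleles are skipped and counted.
#' GT is decoded to ALT dosage; "./." and half-calls such as "0/." become
#' missing; phased separators are accepted as unphased. Per-genotype DP is
#' carried along when present.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @param popmap data.frame(sample_id, population) or path to a popmap TSV;
#'   must cover every sample in the VCF.
#' @param verbose report the number of skipped records.
#' @return a [genotype_matrix()]; the skip count is attached as
#'   `attr(, "skipped")` (named vector: multiallelic, indel, other).
#' @export
read_vcf <- function(path, popmap, verbose = TRUE) {
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  multi <- n_alt != 1
  alt <- rep(NA_character_, length(ref))
  alt[!multi] <- as.character(unlist(altl[!multi]))
  is_snv <- !multi & nchar(ref) == 1 & !is.na(alt) & nchar(alt) == 1
  acgt <- c("A", "C", "G", "T")
  good <- is_snv & ref %in% acgt & alt %in% acgt & ref != alt
  skipped <- c(multiallelic = sum(multi),
               indel = sum(!multi & (nchar(ref) != 1 | nchar(alt) != 1),
                           na.rm = TRUE),
               other = sum(!good) - sum(multi) -
                 sum(!multi & (nchar(ref) != 1 | nchar(alt) != 1),
                     na.rm = TRUE))
  if (verbose && sum(skipped) > 0)
    message(sum(skipped), " record(s) skipped (",
            paste(names(skipped), skipped, sep = "=", collapse = ", "), ")")
  if (!any(good)) stop("no biallelic SNV records in ", path)

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gt[good, , drop = FALSE]
  vcf_samples <- colnames(gt)
  absent <- setdiff(vcf_samples, popmap$sample_id)
  if (length(absent))
    stop("sample(s) missing from popmap: ", paste(absent, collapse = ", "))

  calls <- gt_to_dosage(gt)           # sites x samples
  depth <- VariantAnnotation::geno(vcf)$DP
  if (!is.null(depth)) {
    depth <- depth[good, , drop = FALSE]
    storage.mode(depth) <- "integer"
  }
  sites <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr))[good],
    pos = BiocGenerics::start(rr)[good],
    ref = ref[good], alt = alt[good], stringsAsFactors = FALSE)
  samples <- popmap[match(vcf_samples, popmap$sample_id), , drop = FALSE]
  gm <- genotype_matrix(t(calls), sites, samples,
                        depth = if (is.null(depth)) NULL else t(depth))
  attr(gm, "skipped") <- skipped
  gm
}

# Decode a GT character matrix to ALT dosage; any "." allele -> NA.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".") || is.na(g)) return(NA_integer_)
    sum(al == "1")
  }, integer(1))
  out <- matrix(map[match(gt, u)], nrow = nrow(gt))
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a genotype matrix as a VCF
#'
#' Emits a minimal VCF 4.2 with GT (and DP when available) plus a
#' provenance header line recording the writing package and version.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @param extra_header optional character vector of extra "##" lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, extra_header = character()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  has_dp <- !is.null(gm$depth)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=dmafpanel_%s", as.character(packageVersion("dmafpanel"))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp)
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t"))
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L], nrow = nrow(gm$calls))
  gt_chr[is.na(gm$calls)] <- "./."
  if (has_dp) {
    dp <- gm$depth
    dp[is.na(dp)] <- 0L
    gt_chr <- matrix(paste0(gt_chr, ":", dp), nrow = nrow(gt_chr))
  }
  fmt <- if (has_dp) "GT:DP" else "GT"
  body <- vapply(seq_len(nrow(gm$sites)), function(i) {
    paste(c(gm$sites$chrom[i], gm$sites$pos[i], gm$sites$id[i],
            gm$sites$ref[i], gm$sites$alt[i], ".", "PASS", ".",
            fmt, gt_chr[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a popmap TSV
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(gm, path) {
  utils::write.table(gm$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
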