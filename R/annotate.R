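# Gene-structure annotation, chromosome window density, MAF histogram.
#
# Categories follow the ANNOVAR-style precedence
#   exonic (CDS) > UTR5 > UTR3 > intronic > upstream/downstream > intergenic
# with "upstream;downstream" for sites simultaneously within 1 kb upstream
# of one gene and 1 kb downstream of another, and an optional combined
# "UTR5;UTR3" label for sites in the 5' UTR of one gene and the 3' UTR of
# another.

#' Read gene models from a GFF3 file
#'
#' Accepts the conventional gene -> mRNA/transcript -> exon/CDS/UTR
#' hierarchy and resolves every feature to its gene id.
#'
#' @param path GFF3 file.
#' @return object of class `gene_models`: list of GRanges (`genes`,
#'   `exons`, `cds`, `utr5`, `utr3`), each carrying a `gene_id` column.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID else rep(NA, length(gr))
  parent <- if ("Parent" %in% names(S4Vectors::mcols(gr)))
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  gene_ids <- id[is_gene]
  # feature -> gene: walk one or two Parent steps
  id_to_gene <- setNames(gene_ids, gene_ids)
  tx <- type %in% c("mRNA", "transcript")
  id_to_gene[id[tx]] <- parent[tx]
  resolve <- function(p) {
    g <- id_to_gene[p]
    unname(ifelse(is.na(g), p, g))
  }
  pick <- function(types) {
    sel <- type %in% types
    out <- gr[sel]
    S4Vectors::mcols(out) <- NULL
    out$gene_id <- resolve(parent[sel])
    out
  }
  genes <- gr[is_gene]
  S4Vectors::mcols(genes) <- NULL
  genes$gene_id <- gene_ids
  structure(list(genes = genes,
                 exons = pick("exon"),
                 cds = pick("CDS"),
                 utr5 = pick("five_prime_UTR"),
                 utr3 = pick("three_prime_UTR")),
            class = "gene_models")
}

#' Classify sites by gene structure
#'
#' @param sites data.frame with chrom, pos (and id; derived if absent).
#' @param models a [read_gene_models()] result.
#' @param flank upstream/downstream flank size in bp.
#' @param combine_utr if TRUE, a site in the 5' UTR of one gene and the
#'   3' UTR of another is labelled "UTR5;UTR3" instead of "UTR5".
#' @return data.frame(site_id, category, gene). Sites on chromosomes
#'   absent from the models are intergenic, with a warning.
#' @export
classify_sites <- function(sites, models, flank = 1000L,
                           combine_utr = FALSE) {
  stopifnot(inherits(models, "gene_models"))
  if (!"id" %in% names(sites))
    sites$id <- paste0(sites$chrom, ":", sites$pos)
  model_chroms <- unique(as.character(GenomeInfoDb::seqnames(models$genes)))
  off <- !(sites$chrom %in% model_chroms)
  if (any(off))
    warning(sum(off), " site(s) on chromosomes absent from the gene models; ",
            "classified intergenic")
  pts <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, width = 1))
  GenomeInfoDb::seqlevels(pts) <-
    union(GenomeInfoDb::seqlevels(pts), model_chroms)

  hit_genes <- function(subject) {
    ov <- GenomicRanges::findOverlaps(pts, subject, ignore.strand = TRUE)
    split(subject$gene_id[S4Vectors::subjectHits(ov)],
          factor(S4Vectors::queryHits(ov), levels = seq_along(pts)))
  }
  g_cds <- hit_genes(models$cds)
  g_u5 <- hit_genes(models$utr5)
  g_u3 <- hit_genes(models$utr3)
  g_tx <- hit_genes(models$genes)

  plus <- as.character(BiocGenerics::strand(models$genes)) != "-"
  gstart <- BiocGenerics::start(models$genes)
  gend <- BiocGenerics::end(models$genes)
  up <- models$genes
  IRanges::ranges(up) <- IRanges::IRanges(
    start = pmax(1L, ifelse(plus, gstart - flank, gend + 1L)),
    end = pmax(1L, ifelse(plus, gstart - 1L, gend + flank)))
  dn <- models$genes
  IRanges::ranges(dn) <- IRanges::IRanges(
    start = pmax(1L, ifelse(plus, gend + 1L, gstart - flank)),
    end = pmax(1L, ifelse(plus, gend + flank, gstart - 1L)))
  g_up <- hit_genes(up)
  g_dn <- hit_genes(dn)

  category <- character(nrow(sites))
  gene <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cds_g <- g_cds[[i]]; u5 <- g_u5[[i]]; u3 <- g_u3[[i]]
    txg <- g_tx[[i]]; upg <- g_up[[i]]; dng <- g_dn[[i]]
    if (length(cds_g)) {
      category[i] <- "exonic"; gene[i] <- paste(unique(cds_g), collapse = ";")
    } else if (length(u5) && length(u3) && combine_utr &&
               length(setdiff(u3, u5))) {
      category[i] <- "UTR5;UTR3"
      gene[i] <- paste(unique(c(u5, u3)), collapse = ";")
    } else if (length(u5)) {
      category[i] <- "UTR5"; gene[i] <- paste(unique(u5), collapse = ";")
    } else if (length(u3)) {
      category[i] <- "UTR3"; gene[i] <- paste(unique(u3), collapse = ";")
    } else if (length(txg)) {
      category[i] <- "intronic"; gene[i] <- paste(unique(txg), collapse = ";")
    } else if (length(upg) && length(setdiff(dng, upg))) {
      category[i] <- "upstream;downstream"
      gene[i] <- paste(unique(c(upg, dng)), collapse = ";")
    } else if (length(upg)) {
      category[i] <- "upstream"; gene[i] <- paste(unique(upg), collapse = ";")
    } else if (length(dng)) {
      category[i] <- "downstream"; gene[i] <- paste(unique(dng), collapse = ";")
    } else {
      category[i] <- "intergenic"; gene[i] <- NA_character_
    }
  }
  data.frame(site_id = sites$id, category = category, gene = gene,
             stringsAsFactors = FALSE)
}

#' Category counts and percentages
#'
#' @param annotations a [classify_sites()] result (or any data.frame with
#'   a `category` column).
#' @return data.frame(category, count, percent) with percent to 0.1 of
#'   the total; counts sum to the input size.
#' @export
annotation_summary <- function(annotations) {
  stopifnot(nrow(annotations) > 0)
  tab <- table(annotations$category)
  data.frame(category = names(tab), count = as.integer(tab),
             percent = round_half_up(100 * as.integer(tab) / nrow(annotations),
                                     1),
             stringsAsFactors = FALSE)
}

#' SNP density in fixed chromosome windows
#'
#' Tiles each chromosome into non-overlapping windows
#' \[k*W + 1, (k+1)*W\] and counts panel sites per window.
#'
#' @param panel table with chrom and pos.
#' @param chrom_lengths named vector (or data.frame(chrom, length)) of
#'   chromosome lengths covering every panel chromosome.
#' @param window window size in bp.
#' @return data.frame(chrom, window_start, window_end, count); counts sum
#'   to the panel size.
#' @export
window_density <- function(panel, chrom_lengths, window = 1e6) {
  if (is.data.frame(chrom_lengths))
    chrom_lengths <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  miss <- setdiff(unique(panel$chrom), names(chrom_lengths))
  if (length(miss)) stop("no length for chromosome(s): ",
                         paste(miss, collapse = ", "))
  res <- lapply(unique(panel$chrom)[site_order(unique(panel$chrom),
                                               seq_along(unique(panel$chrom)))],
                function(ch) {
    len <- chrom_lengths[[ch]]
    pos <- panel$pos[panel$chrom == ch]
    if (any(pos > len)) stop("site beyond declared length of ", ch)
    n_win <- ceiling(len / window)
    win <- floor((pos - 1) / window) + 1
    counts <- tabulate(win, nbins = n_win)
    data.frame(chrom = ch,
               window_start = (seq_len(n_win) - 1) * window + 1,
               window_end = pmin(seq_len(n_win) * window, len),
               count = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Folded pooled-MAF histogram
#'
#' Bins the folded pooled minor-allele frequency of panel sites over
#' \[0, 0.5\].
#'
#' @param pooled_freq numeric vector of pooled ALT-allele frequencies.
#' @param bin_width histogram bin width.
#' @return list(histogram = data.frame(bin_lo, bin_hi, count),
#'   frac_ge_0.2 = fraction of sites with folded MAF >= 0.2); counts sum
#'   to the number of sites.
#' @export
maf_histogram <- function(pooled_freq, bin_width = 0.05) {
  maf <- folded_maf(pooled_freq)
  stopifnot(all(maf >= 0 & maf <= 0.5 + 1e-12, na.rm = TRUE))
  breaks <- seq(0, 0.5, by = bin_width)
  if (max(breaks) < 0.5) breaks <- c(breaks, 0.5)
  idx <- findInterval(maf, breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[maf == 0] <- 1L   # [0, bw] closed on the left for the first bin
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  list(histogram = data.frame(bin_lo = utils::head(breaks, -1),
                              bin_hi = utils::tail(breaks, -1),
                              count = counts),
       frac_ge_0.2 = mean(maf >= 0.2, na.rm = TRUE))
}
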