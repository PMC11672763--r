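# In-code fixture builders shared across test files.

# Genotype matrix from a bare calls matrix; sites auto-placed on chr1.
make_gm <- function(calls, populations = NULL, chrom = NULL, pos = NULL,
                    depth = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(populations)) populations <- rep("P1", n)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = m)
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep(c("A", "C", "G", "T"), length.out = m),
                      alt = rep(c("G", "T", "A", "C"), length.out = m),
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("S", seq_len(n)),
                        population = populations,
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, sites, samples, depth = depth)
}

# Random genotype matrix with controllable missingness.
random_gm <- function(seed, n, m, n_pops = 1, missing = 0.05,
                      depth_mean = NULL) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  calls[matrix(runif(n * m) < missing, n, m)] <- NA
  depth <- if (!is.null(depth_mean)) matrix(rpois(n * m, depth_mean), n, m)
  make_gm(calls, populations = rep(paste0("P", seq_len(n_pops)),
                                   length.out = n),
          depth = depth)
}

# Crafted 5-record VCF: 3 clean biallelic SNVs + 1 multiallelic + 1 indel.
write_crafted_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/0:10\t0/1:12\t1/1:9",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:DP\t./.:0\t0/.:5\t1|1:8",
    "chr1\t300\t.\tG\tA,T\t.\tPASS\t.\tGT:DP\t0/1:10\t0/0:10\t0/0:10",
    "chr1\t400\t.\tAT\tA\t.\tPASS\t.\tGT:DP\t0/0:10\t0/0:10\t0/0:10",
    "chr2\t50\t.\tT\tC\t.\tPASS\t.\tGT:DP\t0/0:7\t0/1:7\t0/1:7"),
    path)
  path
}

crafted_popmap <- function() {
  data.frame(sample_id = c("S1", "S2", "S3"),
             population = c("A", "A", "B"), stringsAsFactors = FALSE)
}

# Tiny simulation used by several files (4 chromosomes incl. X).
tiny_sim <- function(seed = 11, n_sites = 400, n_per_pop = 8, ...) {
  sim_config(seed = seed, n_sites = n_sites, n_per_pop = n_per_pop,
             chrom_lengths = setNames(rep(5e4, 4),
                                      c("chr1", "chr2", "chr3", "chrX")),
             ...)
}

# Independent per-site QC oracle used against qc_filter_sites.
qc_oracle_keep <- function(gm, min_depth = 5, max_missing = 0.10,
                           max_het = 0.30) {
  vapply(seq_len(ncol(gm$calls)), function(j) {
    col <- gm$calls[, j]
    miss <- mean(is.na(col))
    het <- if (sum(!is.na(col)) > 0) mean(col[!is.na(col)] == 1) else NA
    dep <- if (is.null(gm$depth)) Inf else mean(gm$depth[, j])
    dep >= min_depth && miss < max_missing &&
      (is.na(het) || het < max_het) && !(miss == 1)
  }, logical(1))
}
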