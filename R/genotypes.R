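# GenotypeMatrix: the pipeline's universal currency.
#
# calls   : integer matrix, samples x sites; ALT-allele dosage 0/1/2, NA missing
# depth   : optional integer matrix, same shape; per-genotype read depth
# sites   : data.frame(chrom, pos, ref, alt, id); (chrom, pos)-sorted
# samples : data.frame(sample_id, population)

#' Construct a genotype matrix
#'
#' Bundles ALT-dosage calls with site metadata and sample population labels.
#' Sites are sorted by (chromosome, position) under a natural chromosome
#' ordering; calls (and depth) columns are reordered accordingly.
#'
#' @param calls integer matrix, samples in rows and sites in columns, values
#'   0, 1, 2 (ALT-allele count) or NA for a missing call.
#' @param sites data.frame with columns chrom, pos, ref, alt (single A/C/G/T
#'   letters, ref != alt). A site id "chrom:pos" is derived.
#' @param samples data.frame with columns sample_id and population.
#' @param depth optional integer matrix of per-genotype read depth, same
#'   shape as `calls`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, samples, depth = NULL) {
  calls <- as.matrix(calls)
  stopifnot(is.data.frame(sites), is.data.frame(samples))
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  stopifnot(all(c("sample_id", "population") %in% names(samples)))
  if (nrow(samples) != nrow(calls) || nrow(sites) != ncol(calls))
    stop("calls must be |samples| x |sites|")
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  bases <- c("A", "C", "G", "T")
  if (!all(sites$ref %in% bases) || !all(sites$alt %in% bases))
    stop("ref/alt must be single A/C/G/T bases")
  if (any(sites$ref == sites$alt)) stop("ref must differ from alt")
  sites$id <- paste0(sites$chrom, ":", sites$pos)
  if (anyDuplicated(sites$id)) stop("duplicate site ids")
  ok <- is.na(calls) | calls %in% 0:2
  if (!all(ok)) stop("calls must be 0, 1, 2 or NA")
  ord <- site_order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  calls <- calls[, ord, drop = FALSE]
  dimnames(calls) <- list(samples$sample_id, sites$id)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)[, ord, drop = FALSE]
    if (!identical(dim(depth), dim(calls))) stop("depth shape mismatch")
    if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
    dimnames(depth) <- dimnames(calls)
  }
  structure(
    list(calls = calls, depth = depth, sites = sites,
         samples = data.frame(sample_id = samples$sample_id,
                              population = samples$population,
                              stringsAsFactors = FALSE)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites, %d populations\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$samples$population))))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Per-site QC statistics
#'
#' Mean genotype depth, missing-call fraction and heterozygous fraction
#' (over non-missing calls) for every site.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame(id, mean_depth, missing_fraction, het_fraction);
#'   `mean_depth` is NA when the matrix carries no depth, `het_fraction`
#'   is NA for all-missing sites.
#' @export
site_qc_stats <- function(gm) {
  n <- nrow(gm$calls)
  miss <- colSums(is.na(gm$calls)) / n
  called <- n - colSums(is.na(gm$calls))
  het <- colSums(gm$calls == 1, na.rm = TRUE)
  het_frac <- ifelse(called > 0, het / called, NA_real_)
  md <- if (is.null(gm$depth)) rep(NA_real_, ncol(gm$calls))
        else colMeans(gm$depth, na.rm = TRUE)
  data.frame(id = gm$sites$id, mean_depth = md, missing_fraction = miss,
             het_fraction = het_frac, stringsAsFactors = FALSE)
}

#' Site-level quality filter
#'
#' Retains sites with mean depth >= `min_depth`, missing fraction strictly
#' below `max_missing` and heterozygous fraction strictly below `max_het`
#' (the depth bound is inclusive, the fraction bounds exclusive, matching
#' "depth >= 5X, missing rate < 10%, heterozygosity rate < 30%").
#' When the matrix has no depth information the depth criterion is skipped
#' with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param min_depth minimum per-site mean genotype depth (X units).
#' @param max_missing maximum missing-call fraction, exclusive.
#' @param max_het maximum heterozygous fraction of called genotypes,
#'   exclusive.
#' @return list(gm = filtered matrix, removed = data.frame(id, reason)); a
#'   site failing several criteria is reported once with the reasons
#'   joined by ";" in filter order (depth, missing, het).
#' @export
qc_filter_sites <- function(gm, min_depth = 5, max_missing = 0.10,
                            max_het = 0.30) {
  stopifnot(inherits(gm, "genotype_matrix"), ncol(gm$calls) > 0)
  if (max_missing < 0 || max_missing > 1 || max_het < 0 || max_het > 1)
    stop("fraction thresholds must lie in [0, 1]")
  if (min_depth < 0) stop("min_depth must be non-negative")
  qc <- site_qc_stats(gm)
  if (is.null(gm$depth)) {
    warning("no depth information; depth criterion skipped")
    fail_depth <- rep(FALSE, nrow(qc))
  } else {
    fail_depth <- !(qc$mean_depth >= min_depth)
  }
  fail_miss <- !(qc$missing_fraction < max_missing)
  # all-missing sites fail the missing filter first; treat their undefined
  # het fraction as passing so the reported reason is "missing"
  fail_het <- !is.na(qc$het_fraction) & !(qc$het_fraction < max_het)
  keep <- !(fail_depth | fail_miss | fail_het)
  reason <- mapply(function(d, m, h)
    paste(c("depth", "missing", "het")[c(d, m, h)], collapse = ";"),
    fail_depth, fail_miss, fail_het)
  removed <- data.frame(id = qc$id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(gm = subset_sites(gm, which(keep)), removed = removed)
}

# Subset a genotype_matrix by site index (order preserved).
subset_sites <- function(gm, idx) {
  gm$calls <- gm$calls[, idx, drop = FALSE]
  if (!is.null(gm$depth)) gm$depth <- gm$depth[, idx, drop = FALSE]
  gm$sites <- gm$sites[idx, , drop = FALSE]
  rownames(gm$sites) <- NULL
  gm
}

#' Remove named samples from a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param ids character vector of sample ids to drop (may be empty).
#' @return the matrix without those samples; the site list is unchanged.
#' @export
exclude_samples <- function(gm, ids) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(ids) == 0) return(gm)
  unknown <- setdiff(ids, gm$samples$sample_id)
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  keep <- !(gm$samples$sample_id %in% ids)
  gm$calls <- gm$calls[keep, , drop = FALSE]
  if (!is.null(gm$depth)) gm$depth <- gm$depth[keep, , drop = FALSE]
  gm$samples <- gm$samples[keep, , drop = FALSE]
  rownames(gm$samples) <- NULL
  gm
}

#' Restrict a genotype matrix to a set of site ids
#'
#' @param gm a [genotype_matrix()].
#' @param ids site ids ("chrom:pos") to keep; all must exist.
#' @return the restricted matrix, in the matrix's own site order.
#' @export
subset_to_sites <- function(gm, ids) {
  missing <- setdiff(ids, gm$sites$id)
  if (length(missing))
    stop("site id(s) absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  subset_sites(gm, which(gm$sites$id %in% ids))
}
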