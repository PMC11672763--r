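# Population-structure validation: GRM, PCA, IBS distances, NJ tree,
# cluster-vs-label concordance.

#' Genomic relationship matrix (GCTA estimator)
#'
#' A_jk = (1/m_jk) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i)),
#' with p_i the pooled ALT frequency over the analyzed cohort. Sites
#' monomorphic in the pooled sample are excluded; for each sample pair
#' only sites called in both contribute, and m_jk counts those sites.
#'
#' @param gm a [genotype_matrix()] with >= 2 samples.
#' @param allele_freq optional per-site ALT frequencies to standardize
#'   against (defaults to pooled frequencies from `gm` itself).
#' @return object of class `grm`: list(A = n x n matrix, m = per-pair
#'   marker counts, n_markers = usable marker count, sample_id).
#' @export
grm <- function(gm, allele_freq = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(gm$calls) >= 2)
  x <- gm$calls
  if (is.null(allele_freq)) {
    called <- colSums(!is.na(x))
    allele_freq <- ifelse(called > 0, colSums(x, na.rm = TRUE) / (2 * called),
                          NA_real_)
  }
  usable <- !is.na(allele_freq) & allele_freq > 0 & allele_freq < 1
  if (!any(usable)) stop("no polymorphic markers")
  x <- x[, usable, drop = FALSE]
  p <- allele_freq[usable]
  z <- sweep(x, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(x))
  called <- !is.na(z)
  z[!called] <- 0
  num <- tcrossprod(z)
  m <- tcrossprod(called * 1)
  if (any(m == 0)) {
    bad <- which(m == 0, arr.ind = TRUE)[1, ]
    stop("no shared usable markers for pair ",
         gm$samples$sample_id[bad[1]], " / ", gm$samples$sample_id[bad[2]])
  }
  A <- num / m
  dimnames(A) <- list(gm$samples$sample_id, gm$samples$sample_id)
  structure(list(A = A, m = m, n_markers = sum(usable),
                 sample_id = gm$samples$sample_id), class = "grm")
}

#' Principal components of a GRM
#'
#' Eigen-decomposes the double-centered relationship matrix and returns
#' the top k eigenpairs. Eigenvector signs are fixed by making the
#' largest-magnitude loading positive.
#'
#' @param g a [grm()] result (or a plain symmetric matrix).
#' @param k number of components.
#' @return object of class `grm_pca`: list(values = top-k eigenvalues
#'   descending, vectors = n x k orthonormal coordinates, sample_id).
#' @export
pca <- function(g, k = 3) {
  A <- if (inherits(g, "grm")) g$A else as.matrix(g)
  if (!isSymmetric(unname(A), tol = 1e-8)) stop("GRM must be symmetric")
  n <- nrow(A)
  if (k > n) stop("k exceeds the number of samples")
  # double centering: projects out the constant vector
  C <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vec[, j]))
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- rownames(A)
  colnames(vec) <- paste0("PC", seq_len(k))
  structure(list(values = e$values[seq_len(k)], vectors = vec,
                 trace_centered = sum(diag((C + t(C)) / 2)),
                 sample_id = rownames(A)),
            class = "grm_pca")
}

#' Pairwise identity-by-state distances
#'
#' d_jk = 1 - (1 / (2 m_jk)) * sum_i (2 - |x_ij - x_ik|) over sites
#' called in both samples (allele-sharing distance; 0 for identical
#' genotypes, 1 for opposite homozygotes everywhere).
#'
#' @param gm a [genotype_matrix()].
#' @return object of class `ibs_dist`: list(D = n x n distance matrix,
#'   m = per-pair co-called site counts, sample_id).
#' @export
ibs_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  x <- gm$calls
  ind <- lapply(0:2, function(v) (!is.na(x) & x == v) * 1)
  m <- tcrossprod(!is.na(x) * 1)
  if (any(m == 0)) {
    bad <- which(m == 0, arr.ind = TRUE)[1, ]
    stop("no co-called sites for pair ",
         gm$samples$sample_id[bad[1]], " / ", gm$samples$sample_id[bad[2]])
  }
  absdiff <- tcrossprod(ind[[1]], ind[[2]]) + tcrossprod(ind[[2]], ind[[1]]) +
    tcrossprod(ind[[2]], ind[[3]]) + tcrossprod(ind[[3]], ind[[2]]) +
    2 * (tcrossprod(ind[[1]], ind[[3]]) + tcrossprod(ind[[3]], ind[[1]]))
  D <- absdiff / (2 * m)
  dimnames(D) <- list(gm$samples$sample_id, gm$samples$sample_id)
  structure(list(D = D, m = m, sample_id = gm$samples$sample_id),
            class = "ibs_dist")
}

#' Mean between-population distances
#'
#' Averages an individual-level distance matrix within population blocks,
#' giving a population-level matrix suitable for a population tree.
#'
#' @param d an [ibs_distance()] result or plain distance matrix.
#' @param labels population label per sample.
#' @return symmetric matrix over populations (diagonal = mean
#'   within-population distance over distinct pairs).
#' @export
pop_mean_distance <- function(d, labels) {
  D <- if (inherits(d, "ibs_dist")) d$D else as.matrix(d)
  pops <- unique(labels)
  out <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i)) {
    ri <- which(labels == pops[i]); rj <- which(labels == pops[j])
    block <- D[ri, rj, drop = FALSE]
    out[i, j] <- out[j, i] <- if (i == j) {
      if (length(ri) < 2) 0 else mean(block[lower.tri(block)])
    } else mean(block)
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via ape); negative branch lengths
#' are clamped to zero with a message. The returned tree is unrooted.
#'
#' @param d an [ibs_distance()] result, distance matrix or `dist`.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  D <- if (inherits(d, "ibs_dist")) d$D
       else if (inherits(d, "dist")) as.matrix(d)
       else as.matrix(d)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (nrow(D) < 3) stop("need at least 3 leaves")
  tree <- ape::nj(stats::as.dist(D))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative NJ branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Concordance between clusters and declared populations
#'
#' Partitions samples by k-means on PCA coordinates (k = number of label
#' classes, deterministic seeding, multiple restarts) and scores the
#' partition against the labels with the adjusted Rand index and cluster
#' purity.
#'
#' @param coords numeric matrix of sample coordinates (e.g.
#'   `pca(...)$vectors`).
#' @param labels class label per sample (row).
#' @param seed RNG seed for k-means restarts.
#' @param nstart k-means restarts.
#' @return list(ari, purity, cluster = integer assignment).
#' @export
cluster_concordance <- function(coords, labels, seed = 1L, nstart = 25L) {
  coords <- as.matrix(coords)
  k <- length(unique(labels))
  if (nrow(coords) < k) stop("fewer samples than clusters")
  if (length(labels) != nrow(coords)) stop("labels/coords length mismatch")
  cl <- with_preserved_seed(seed,
    kmeans(coords, centers = k, nstart = nstart, iter.max = 100))
  list(ari = adjusted_rand_index(cl$cluster, labels),
       purity = cluster_purity(cl$cluster, labels),
       cluster = unname(cl$cluster))
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG
# stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Export a GRM as a plain TSV triplet
#'
#' Lower-triangle (including diagonal) rows: index1, index2, marker
#' count, relationship — the text analogue of the GCTA binary GRM.
#'
#' @param g a [grm()] result.
#' @param path output TSV path; a companion `<path>.id` file lists
#'   sample ids.
#' @return `path`, invisibly.
#' @export
write_grm_tsv <- function(g, path) {
  idx <- which(lower.tri(g$A, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   m = g$m[idx], a = g$A[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(g$sample_id, paste0(path, ".id"))
  invisible(path)
}

#' Export PCA coordinates as TSV
#' @param p a [pca()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eigenvec_tsv <- function(p, path) {
  df <- data.frame(sample_id = p$sample_id, p$vectors)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
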