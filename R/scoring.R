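# Per-population allele frequencies and delta-MAF differentiation scores.
#
# The selection score is the UNFOLDED allele-frequency differential
# |f_p - f_q| (the classic delta method).  Folding before differencing
# would send an ideally informative site (f = 0.9 vs 0.1) to delta = 0;
# the unfolded differential is invariant under a ref/alt swap, so nothing
# is lost.  Folded MAFs are still available for histograms and optional
# MAF floors.

#' Per-population ALT-allele frequencies
#'
#' Missing calls enter neither numerator nor denominator. Sites at which any
#' population has zero called alleles are flagged unscoreable and are
#' excluded from downstream selection.
#'
#' @param gm a [genotype_matrix()].
#' @return object of class `pop_freqs`: list with `freq` and `n_alleles`
#'   (sites x populations matrices), `pooled` (ALT frequency over all
#'   samples), `scoreable` (logical), `sites` (the site table) and
#'   `populations`.
#' @export
population_frequencies <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- unique(gm$samples$population)
  if (any(!nzchar(pops)) || length(pops) == 0)
    stop("empty population label")
  freq <- matrix(NA_real_, ncol(gm$calls), length(pops),
                 dimnames = list(gm$sites$id, pops))
  n_all <- matrix(0L, ncol(gm$calls), length(pops),
                  dimnames = list(gm$sites$id, pops))
  for (p in pops) {
    rows <- gm$samples$population == p
    if (!any(rows)) stop("population with no samples: ", p)
    sub <- gm$calls[rows, , drop = FALSE]
    called <- colSums(!is.na(sub))
    n_all[, p] <- 2L * called
    alt <- colSums(sub, na.rm = TRUE)
    freq[, p] <- ifelse(called > 0, alt / (2 * called), NA_real_)
  }
  pooled_called <- colSums(!is.na(gm$calls))
  pooled <- ifelse(pooled_called > 0,
                   colSums(gm$calls, na.rm = TRUE) / (2 * pooled_called),
                   NA_real_)
  structure(list(freq = freq, n_alleles = n_all, pooled = pooled,
                 scoreable = rowSums(n_all == 0) == 0,
                 sites = gm$sites, populations = pops),
            class = "pop_freqs")
}

#' Fold an allele frequency to a minor-allele frequency
#' @param f numeric vector of ALT-allele frequencies in [0, 1].
#' @return min(f, 1 - f).
#' @export
folded_maf <- function(f) pmin(f, 1 - f)

#' Pairwise allele-frequency differentials (delta-MAF)
#'
#' For every unordered population pair computes delta = |f_p - f_q| per
#' site, plus the per-site maximum and mean over pairs and the
#' per-population selection score s_p = max over q of delta[p, q].
#'
#' @param freqs a [population_frequencies()] result.
#' @return object of class `delta_scores`: list with `delta` (sites x
#'   pairs, columns named "p|q"), `max_delta`, `mean_delta`, `pop_score`
#'   (sites x populations), `scoreable`, `sites`, `populations`.
#'   Unscoreable sites carry NA scores.
#' @export
delta_scores <- function(freqs) {
  stopifnot(inherits(freqs, "pop_freqs"))
  pops <- freqs$populations
  if (length(pops) < 2) stop("need at least two populations")
  pairs <- utils::combn(pops, 2)
  delta <- matrix(NA_real_, nrow(freqs$freq), ncol(pairs),
                  dimnames = list(rownames(freqs$freq),
                                  apply(pairs, 2, paste, collapse = "|")))
  for (j in seq_len(ncol(pairs)))
    delta[, j] <- abs(freqs$freq[, pairs[1, j]] - freqs$freq[, pairs[2, j]])
  pop_score <- matrix(NA_real_, nrow(freqs$freq), length(pops),
                      dimnames = list(rownames(freqs$freq), pops))
  for (p in pops) {
    touch <- pairs[1, ] == p | pairs[2, ] == p
    pop_score[, p] <- apply(delta[, touch, drop = FALSE], 1, max)
  }
  sc <- freqs$scoreable
  delta[!sc, ] <- NA_real_
  pop_score[!sc, ] <- NA_real_
  structure(list(delta = delta,
                 max_delta = ifelse(sc, apply(delta, 1, max), NA_real_),
                 mean_delta = ifelse(sc, rowMeans(delta), NA_real_),
                 pop_score = pop_score,
                 scoreable = sc, sites = freqs$sites, populations = pops),
            class = "delta_scores")
}

#' Export frequencies and scores as one TSV-ready table
#'
#' @param freqs a [population_frequencies()] result.
#' @param scores the matching [delta_scores()] result.
#' @param path optional output TSV path.
#' @return data.frame with site id/chrom/pos, per-population frequencies,
#'   pairwise deltas, max/mean delta and per-population scores.
#' @export
score_table <- function(freqs, scores, path = NULL) {
  df <- cbind(freqs$sites[, c("id", "chrom", "pos")],
              setNames(as.data.frame(freqs$freq),
                       paste0("f_", colnames(freqs$freq))),
              setNames(as.data.frame(scores$delta),
                       paste0("delta_", gsub("\\|", "_", colnames(scores$delta)))),
              max_delta = scores$max_delta,
              mean_delta = scores$mean_delta,
              setNames(as.data.frame(scores$pop_score),
                       paste0("s_", colnames(scores$pop_score))))
  rownames(df) <- NULL
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
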