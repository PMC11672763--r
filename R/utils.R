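#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbeta rbinom rpois runif kmeans setNames na.omit
#' @importFrom utils write.table read.table packageVersion
NULL

# Natural chromosome ordering: numeric names (optionally "chr"-prefixed)
# first in numeric order, then X, then Y, then everything else
# alphabetically.  Returns an integer rank usable inside order().
chrom_rank <- function(chrom) {
  stripped <- sub("^[Cc]hr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(stripped))
  rank <- numeric(length(chrom))
  is_num <- !is.na(num)
  rank[is_num] <- num[is_num]
  rank[!is_num & stripped %in% c("X", "x")] <- 1e6
  rank[!is_num & stripped %in% c("Y", "y")] <- 1e6 + 1
  other <- !is_num & !(stripped %in% c("X", "x", "Y", "y"))
  # distinct ranks after Y, alphabetical
  if (any(other)) {
    lev <- sort(unique(stripped[other]))
    rank[other] <- 1e6 + 1 + match(stripped[other], lev)
  }
  rank
}

# Order of sites by (chrom, pos) under natural chromosome ranking.
site_order <- function(chrom, pos) order(chrom_rank(chrom), pos)

#' Classify chromosome names into autosome / X / Y / other
#'
#' @param chrom character vector of chromosome names ("chr" prefix optional).
#' @param sex_x,sex_y names (after prefix stripping) treated as X resp. Y.
#' @return character vector with values "autosome", "X", "Y" or "other".
#' @export
classify_chromosome <- function(chrom, sex_x = "X", sex_y = "Y") {
  stripped <- sub("^[Cc]hr", "", as.character(chrom))
  out <- rep("other", length(chrom))
  out[!is.na(suppressWarnings(as.numeric(stripped)))] <- "autosome"
  out[toupper(stripped) %in% toupper(sex_x)] <- "X"
  out[toupper(stripped) %in% toupper(sex_y)] <- "Y"
  out
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted-for-chance agreement between two labelings of the
#' same items; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b vectors of cluster/class labels of equal length.
#' @return a single number in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}

# Cluster purity: fraction of items whose cluster's majority class they share.
cluster_purity <- function(cluster, label) {
  tab <- table(cluster, label)
  sum(apply(tab, 1, max)) / length(cluster)
}

round_half_up <- function(x, digits = 0) {
  # Table-style rounding (.5 away from zero), unlike R's banker's rounding
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
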