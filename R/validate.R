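# Chip-validation statistics: per-sample call counts and rates, population
# summaries, failed-sample flagging.
#
# Rate denominators matter: the missing rate is taken over ALL panel
# sites, while het / hom-alt / reference-consistency rates are taken over
# CALLED sites only.  This is the only convention under which a row such
# as 12 missing + 1954 het + 968 hom-alt + 2068 hom-ref on a 5002-site
# panel yields het 1954/4990 = 39.16%.

#' Per-sample call statistics on the panel
#'
#' @param gm a [genotype_matrix()] restricted to panel sites.
#' @param sample_id one sample id, or NULL for all samples.
#' @return data.frame with one row per sample: sample_id, population,
#'   n_sites, n_missing, n_het, n_homalt, n_homref, missing_rate,
#'   call_rate, het_rate, homalt_rate, consistency_rate and a `failed`
#'   flag (TRUE when every call is missing, leaving called-site rates
#'   undefined).
#' @export
sample_stats <- function(gm, sample_id = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), ncol(gm$calls) > 0)
  if (!is.null(sample_id)) {
    if (!all(sample_id %in% gm$samples$sample_id))
      stop("unknown sample id")
    rows <- match(sample_id, gm$samples$sample_id)
  } else rows <- seq_len(nrow(gm$calls))
  calls <- gm$calls[rows, , drop = FALSE]
  n_sites <- ncol(calls)
  n_missing <- rowSums(is.na(calls))
  n_het <- rowSums(calls == 1, na.rm = TRUE)
  n_homalt <- rowSums(calls == 2, na.rm = TRUE)
  n_homref <- rowSums(calls == 0, na.rm = TRUE)
  called <- n_sites - n_missing
  data.frame(
    sample_id = gm$samples$sample_id[rows],
    population = gm$samples$population[rows],
    n_sites = n_sites, n_missing = n_missing, n_het = n_het,
    n_homalt = n_homalt, n_homref = n_homref,
    missing_rate = n_missing / n_sites,
    call_rate = 1 - n_missing / n_sites,
    het_rate = ifelse(called > 0, n_het / called, NA_real_),
    homalt_rate = ifelse(called > 0, n_homalt / called, NA_real_),
    consistency_rate = ifelse(called > 0, n_homref / called, NA_real_),
    failed = called == 0,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Population-level summary of sample statistics
#'
#' Unweighted per-population means of every count and rate, plus a grand
#' "Mean" row formed as the unweighted mean of the population means (the
#' usual summary-table convention).  The pooled per-sample grand mean is
#' also attached, since the two differ when populations have unequal
#' sizes: `attr(, "pooled_mean")`.
#'
#' @param stats a [sample_stats()] data.frame (all samples).
#' @param digits_rate decimals for percentage columns in the formatted
#'   table (counts are rounded to whole numbers).
#' @return data.frame, one row per population plus a final "Mean" row,
#'   with counts and percentage rates.
#' @export
population_summary <- function(stats, digits_rate = 2) {
  stopifnot(nrow(stats) > 0, all(nzchar(stats$population)))
  num_cols <- c("n_missing", "n_het", "n_homalt", "n_homref")
  rate_cols <- c("missing_rate", "het_rate", "homalt_rate",
                 "consistency_rate")
  pops <- unique(stats$population)
  per_pop <- do.call(rbind, lapply(pops, function(p) {
    s <- stats[stats$population == p, , drop = FALSE]
    if (nrow(s) == 0) stop("empty population: ", p)
    cbind(data.frame(population = p),
          as.data.frame(lapply(s[c(num_cols, rate_cols)], mean,
                               na.rm = TRUE)))
  }))
  grand <- cbind(data.frame(population = "Mean"),
                 as.data.frame(lapply(per_pop[c(num_cols, rate_cols)], mean)))
  out <- rbind(per_pop, grand)
  for (col in num_cols) out[[col]] <- round_half_up(out[[col]])
  for (col in rate_cols)
    out[[col]] <- round_half_up(100 * out[[col]], digits_rate)
  rownames(out) <- NULL
  pooled <- as.data.frame(lapply(stats[c(num_cols, rate_cols)], mean,
                                 na.rm = TRUE))
  pooled[rate_cols] <- 100 * pooled[rate_cols]
  attr(out, "pooled_mean") <- pooled
  out
}

#' Flag samples whose missing rate exceeds a threshold
#'
#' Flagged samples (library failures and the like) are dropped before any
#' population-structure analysis.
#'
#' @param stats a [sample_stats()] data.frame.
#' @param max_missing flagging threshold; flagged iff
#'   missing_rate > max_missing.
#' @return character vector of flagged sample ids.
#' @export
flag_failed_samples <- function(stats, max_missing = 0.90) {
  stats$sample_id[stats$missing_rate > max_missing]
}
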