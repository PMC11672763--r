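# Panel assembly: per-population top-K union -> capacity allocation
# favoring autosomes -> detection-rate pruning.
#
# All tie-breaks are by (chrom, pos) ascending so identical inputs give
# byte-identical panel exports.

#' Build the candidate table for panel selection
#'
#' Joins delta scores with probe pass flags and a chromosome class,
#' keeping only scoreable, probe-passing sites outside the chromosome
#' blacklist (Y by default: the chip deliberately carries no Y sites).
#'
#' @param scores a [delta_scores()] result.
#' @param probes a [probe_report()] result (site_id, pass), or NULL to
#'   treat every scoreable site as probe-feasible.
#' @param blacklist chromosome classes excluded outright.
#' @return data.frame of candidates: id, chrom, pos, chrom_class,
#'   max_delta, mean_delta and one s_<pop> column per population.
#' @export
panel_candidates <- function(scores, probes = NULL,
                             blacklist = "Y") {
  stopifnot(inherits(scores, "delta_scores"))
  df <- scores$sites[, c("id", "chrom", "pos")]
  df$chrom_class <- classify_chromosome(df$chrom)
  df$max_delta <- scores$max_delta
  df$mean_delta <- scores$mean_delta
  sc <- as.data.frame(scores$pop_score)
  names(sc) <- paste0("s_", names(sc))
  df <- cbind(df, sc)
  keep <- scores$scoreable & !(df$chrom_class %in% blacklist)
  if (!is.null(probes)) {
    m <- match(df$id, probes$site_id)
    keep <- keep & !is.na(m) & probes$pass[m]
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "populations") <- scores$populations
  out
}

#' Per-population top-K union
#'
#' For each population takes the K candidates with the largest selection
#' score s_p (ties broken by chromosome, position ascending), then unites
#' the lists, collapsing duplicates and recording which populations (and
#' at what rank) contributed each site.
#'
#' @param candidates a [panel_candidates()] table.
#' @param K sites taken per population.
#' @return data.frame: candidate columns + `provenance` ("pop:rank"
#'   entries joined by ","), sorted by (chrom, pos).
#' @export
top_k_union <- function(candidates, K = 1500L) {
  if (nrow(candidates) == 0) stop("no candidates")
  stopifnot(K >= 1)
  pops <- attr(candidates, "populations")
  if (is.null(pops))
    pops <- sub("^s_", "", grep("^s_", names(candidates), value = TRUE))
  prov <- setNames(vector("list", nrow(candidates)), candidates$id)
  chosen <- logical(nrow(candidates))
  for (p in pops) {
    s <- candidates[[paste0("s_", p)]]
    ord <- order(-s, chrom_rank(candidates$chrom), candidates$pos)
    take <- ord[seq_len(min(K, length(ord)))]
    chosen[take] <- TRUE
    for (r in seq_along(take))
      prov[[take[r]]] <- c(prov[[take[r]]], paste0(p, ":", r))
  }
  out <- candidates[chosen, , drop = FALSE]
  out$provenance <- vapply(prov[chosen], paste, character(1), collapse = ",")
  out$stage <- "topK"
  out <- out[site_order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "populations") <- pops
  out
}

#' Capacity allocation favoring autosomes
#'
#' Keeps every autosomal site; residual capacity is filled by
#' sex-chromosome sites in decreasing mean delta (ties by chromosome,
#' position). If the autosomal sites alone exceed capacity they are all
#' kept anyway, with a warning.
#'
#' @param union a [top_k_union()] result.
#' @param capacity total panel slots.
#' @return the allocated panel, (chrom, pos)-sorted, stage = "capacity".
#' @export
allocate_capacity <- function(union, capacity = 6000L) {
  if (capacity < 1) stop("capacity must be >= 1")
  auto <- union$chrom_class == "autosome"
  n_auto <- sum(auto)
  keep <- auto
  if (n_auto > capacity) {
    warning("autosomal sites (", n_auto, ") exceed capacity (", capacity,
            "); keeping all of them")
  } else {
    slots <- capacity - n_auto
    sex <- which(union$chrom_class %in% c("X", "Y"))
    if (slots > 0 && length(sex)) {
      ord <- sex[order(-union$mean_delta[sex],
                       chrom_rank(union$chrom[sex]), union$pos[sex])]
      keep[ord[seq_len(min(slots, length(ord)))]] <- TRUE
    }
  }
  out <- union[keep, , drop = FALSE]
  out$stage <- "capacity"
  out <- out[site_order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "populations") <- attr(union, "populations")
  out
}

#' Per-site detection rate in a test cohort
#'
#' Fraction of samples with a non-missing call at each site.
#'
#' @param gm a [genotype_matrix()] of the test cohort.
#' @return named numeric vector over the matrix's site ids.
#' @export
detection_rates <- function(gm) {
  setNames(colMeans(!is.na(gm$calls)), gm$sites$id)
}

#' Prune panel sites with low detection rates
#'
#' @param panel an [allocate_capacity()] (or earlier-stage) panel table.
#' @param detection named numeric vector of per-site call rates; must
#'   cover every panel site.
#' @param min_rate retention threshold (inclusive).
#' @return list(panel = surviving sites with stage = "survived_pruning",
#'   pruned = data.frame(id, detection_rate)).
#' @export
prune_by_detection <- function(panel, detection, min_rate = 0.95) {
  miss <- setdiff(panel$id, names(detection))
  if (length(miss))
    stop("no detection rate for site(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  rate <- detection[panel$id]
  keep <- rate >= min_rate
  out <- panel[keep, , drop = FALSE]
  out$stage <- "survived_pruning"
  rownames(out) <- NULL
  attr(out, "populations") <- attr(panel, "populations")
  list(panel = out,
       pruned = data.frame(id = panel$id[!keep],
                           detection_rate = unname(rate[!keep]),
                           stringsAsFactors = FALSE))
}

#' Export a panel as BED (0-based half-open)
#' @param panel a panel table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_panel_bed <- function(panel, path) {
  bed <- data.frame(panel$chrom, panel$pos - 1L, panel$pos, panel$id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a panel as TSV with provenance columns
#' @param panel a panel table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_panel_tsv <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
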