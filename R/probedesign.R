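# Probe feasibility: 110 bp flanking context, GC bounds, genome homology.
#
# "Homologous regions" is operationalized as exact genome occurrences of
# the probe's central 31-mer on both strands (the locus itself counts, so
# every probe scores >= 1).  k = 31 is a conventional uniqueness k-mer
# size and is configurable; this is a documented stand-in for whatever
# alignment heuristic a probe vendor applies.

PROBE_LENGTH <- 110L
HOMOLOGY_K <- 31L

# Offset of the variant base inside an even-length window: 55 left, 54
# right, i.e. 1-based offset 56 for L = 110.
probe_center_offset <- function(L) L %/% 2L + 1L

#' Extract the probe flanking context around sites
#'
#' Pulls the L-bp reference window covering positions
#' \[pos - L/2, pos + L/2 - 1\] around each site (site base at 1-based
#' offset L/2 + 1). Sites too close to a contig end are rejected with
#' reason "edge"; sites whose reference base disagrees with the declared
#' ref allele are rejected with reason "ref_mismatch".
#'
#' @param genome a [Biostrings::DNAStringSet] (named by chromosome) or a
#'   path to a FASTA file.
#' @param sites data.frame with chrom, pos, ref (and id; derived if absent).
#' @param L probe length in bp.
#' @return data.frame(site_id, sequence, ok, fail_reason); sequences are
#'   uppercase, NA when rejected.
#' @export
extract_context <- function(genome, sites, L = PROBE_LENGTH) {
  genome <- load_genome(genome)
  if (!"id" %in% names(sites))
    sites$id <- paste0(sites$chrom, ":", sites$pos)
  left <- L %/% 2L
  right <- L - left - 1L
  seqs <- rep(NA_character_, nrow(sites))
  reason <- rep(NA_character_, nrow(sites))
  lens <- setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    if (!chrom %in% names(genome)) stop("chromosome absent from FASTA: ", chrom)
    pos <- sites$pos[i]
    if (pos - left < 1 || pos + right > lens[[chrom]]) {
      reason[i] <- "edge"
      next
    }
    s <- toupper(as.character(Biostrings::subseq(genome[[chrom]],
                                                 pos - left, pos + right)))
    if (substr(s, left + 1L, left + 1L) != sites$ref[i]) {
      reason[i] <- "ref_mismatch"
      next
    }
    seqs[i] <- s
  }
  data.frame(site_id = sites$id, sequence = seqs, ok = is.na(reason),
             fail_reason = reason, stringsAsFactors = FALSE)
}

#' GC-content gate
#'
#' @param seq character vector of probe sequences.
#' @param lo,hi inclusive GC-fraction bounds.
#' @return data.frame(gc_fraction, pass, fail_reason); any sequence
#'   containing N fails with "ambiguous_base".
#' @export
gc_pass <- function(seq, lo = 0.30, hi = 0.70) {
  stopifnot(all(nchar(seq) > 0, na.rm = TRUE))
  if (any(grepl("[^ACGTNacgtn]", seq)))
    stop("non-IUPAC character in probe sequence")
  ss <- Biostrings::DNAStringSet(ifelse(is.na(seq), "A", seq))
  fr <- Biostrings::letterFrequency(ss, c("G", "C", "N"))
  gc <- (fr[, "G"] + fr[, "C"]) / nchar(seq)
  has_n <- fr[, "N"] > 0
  pass <- !has_n & gc >= lo & gc <= hi
  gc[is.na(seq)] <- NA_real_
  pass[is.na(seq)] <- FALSE
  data.frame(gc_fraction = gc, pass = pass,
             fail_reason = ifelse(is.na(seq), "no_sequence",
                           ifelse(has_n, "ambiguous_base",
                           ifelse(pass, NA_character_, "gc_out_of_range"))),
             stringsAsFactors = FALSE)
}

#' Count genomic homology hits for probe sequences
#'
#' Counts exact occurrences of each probe's central k-mer in the genome on
#' both strands, overlapping occurrences included. The probe's own locus
#' matches itself, so every count is >= 1.
#'
#' @param seq character vector of probe sequences (no N).
#' @param genome DNAStringSet or FASTA path.
#' @param max_hits pass threshold (pass iff count <= max_hits).
#' @param k central k-mer length (odd).
#' @return data.frame(homology_hits, pass).
#' @export
homology_hits <- function(seq, genome, max_hits = 5L, k = HOMOLOGY_K) {
  genome <- load_genome(genome)
  stopifnot(k %% 2 == 1)
  counts <- rep(NA_integer_, length(seq))
  for (i in seq_along(seq)) {
    if (is.na(seq[i])) next
    if (grepl("N", seq[i], fixed = TRUE)) stop("probe contains N")
    center <- probe_center_offset(nchar(seq[i]))
    half <- (k - 1L) %/% 2L
    if (center - half < 1 || center + half > nchar(seq[i]))
      stop("probe shorter than homology k-mer")
    kmer <- Biostrings::DNAString(substr(seq[i], center - half, center + half))
    fwd <- sum(Biostrings::vcountPattern(kmer, genome))
    rev <- sum(Biostrings::vcountPattern(Biostrings::reverseComplement(kmer),
                                         genome))
    counts[i] <- fwd + rev   # odd k cannot be its own reverse complement
  }
  data.frame(homology_hits = counts,
             pass = !is.na(counts) & counts <= max_hits)
}

#' Full probe-feasibility report for a set of sites
#'
#' Runs context extraction, the GC gate and the homology gate, producing
#' one row per site with a combined pass flag.
#'
#' @param genome DNAStringSet or FASTA path.
#' @param sites site table (chrom, pos, ref).
#' @param L probe length; `gc_lo`, `gc_hi` GC bounds; `max_hits`, `k` see
#'   [homology_hits()].
#' @param path optional TSV output path.
#' @return data.frame(site_id, sequence, gc_fraction, homology_hits,
#'   pass, fail_reason).
#' @export
probe_report <- function(genome, sites, L = PROBE_LENGTH, gc_lo = 0.30,
                         gc_hi = 0.70, max_hits = 5L, k = HOMOLOGY_K,
                         path = NULL) {
  genome <- load_genome(genome)
  ctx <- extract_context(genome, sites, L = L)
  gc <- gc_pass(ctx$sequence, gc_lo, gc_hi)
  hom <- data.frame(homology_hits = NA_integer_, pass = FALSE)[
    rep(1, nrow(ctx)), , drop = FALSE]
  eligible <- ctx$ok & gc$pass
  if (any(eligible))
    hom[eligible, ] <- homology_hits(ctx$sequence[eligible], genome,
                                     max_hits = max_hits, k = k)
  out <- data.frame(
    site_id = ctx$site_id, sequence = ctx$sequence,
    gc_fraction = gc$gc_fraction, homology_hits = hom$homology_hits,
    pass = ctx$ok & gc$pass & hom$pass,
    fail_reason = ifelse(!ctx$ok, ctx$fail_reason,
                  ifelse(!gc$pass, gc$fail_reason,
                  ifelse(!hom$pass, "homology", NA_character_))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

load_genome <- function(genome) {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("FASTA not found: ", genome)
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}
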