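# Hierarchical Balding-Nichols cohort simulator.
#
# The stated world: three breeds ("IM", "HS", "WZMQ") diverged at
# F_breed = 0.05 from a common ancestral frequency, with three weakly
# diverged types ("ARBS", "ELS", "ALS", F_type = 0.005) nested inside
# breed IM -- five populations in all, 60 samples each, 20,000 sites.
# Per-population frequencies follow the Balding-Nichols Beta law
#   f ~ Beta(p (1-F)/F, (1-p) (1-F)/F)
# around the parent frequency p; genotypes are Binomial(2, f) with
# independent per-call missingness and Poisson read depth.

#' Simulation configuration
#'
#' @param seed RNG seed (mandatory; all outputs are deterministic in it).
#' @param breeds breed names; the first carries the nested types.
#' @param types type names nested inside the first breed.
#' @param F_breed,F_type Balding-Nichols divergence of breeds from the
#'   ancestor and of types from their breed.
#' @param n_per_pop samples per population.
#' @param n_sites total SNP sites.
#' @param chrom_lengths named vector of chromosome lengths; default 29
#'   autosomes plus X, 1 Mb each.
#' @param ancestral_range range of the uniform ancestral-frequency law.
#' @param missing_rate per-call missingness probability.
#' @param depth_mean Poisson mean of per-genotype read depth.
#' @param n_failed_samples samples injected with `failed_missing_rate`
#'   missingness (library failures).
#' @param failed_missing_rate missingness of injected failed samples.
#' @param gene_fraction approximate fraction of each chromosome covered
#'   by toy gene models.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       breeds = c("IM", "HS", "WZMQ"),
                       types = c("ARBS", "ELS", "ALS"),
                       F_breed = 0.05, F_type = 0.005,
                       n_per_pop = 60L, n_sites = 20000L,
                       chrom_lengths = NULL,
                       ancestral_range = c(0.05, 0.95),
                       missing_rate = 0.002, depth_mean = 30,
                       n_failed_samples = 0L,
                       failed_missing_rate = 0.97,
                       gene_fraction = 0.3) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(F_breed > 0, F_breed < 1, F_type > 0, F_type < 1)
  if (is.null(chrom_lengths))
    chrom_lengths <- setNames(rep(1e6, 30),
                              c(paste0("chr", 1:29), "chrX"))
  if (any(chrom_lengths < 2 * 110))
    stop("chromosomes must be at least twice the probe length")
  first <- if (length(types)) types else breeds[1]
  pops <- c(first, breeds[-1])
  pop_breed <- setNames(c(rep(breeds[1], length(first)), breeds[-1]), pops)
  structure(list(seed = as.integer(seed), breeds = breeds, types = types,
                 populations = pops, pop_breed = pop_breed,
                 F_breed = F_breed, F_type = F_type,
                 n_per_pop = as.integer(n_per_pop),
                 n_sites = as.integer(n_sites),
                 chrom_lengths = chrom_lengths,
                 ancestral_range = ancestral_range,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 n_failed_samples = as.integer(n_failed_samples),
                 failed_missing_rate = failed_missing_rate,
                 gene_fraction = gene_fraction),
            class = "sim_config")
}

rbn <- function(parent, F) {
  a <- parent * (1 - F) / F
  b <- (1 - parent) * (1 - F) / F
  rbeta(length(parent), a, b)
}

#' Draw the simulation ground truth
#'
#' Samples site placement, ancestral frequencies, breed frequencies and
#' nested type frequencies under the hierarchical Balding-Nichols model.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_truth`: list(sites, ancestral,
#'   breed_freq, pop_freq, config).
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(config$seed, {
    margin <- 55L
    lens <- config$chrom_lengths
    # sites spread across chromosomes proportional to length
    n_per <- as.integer(round(config$n_sites * lens / sum(lens)))
    diff_n <- config$n_sites - sum(n_per)
    n_per[1] <- n_per[1] + diff_n
    sites <- do.call(rbind, lapply(seq_along(lens), function(i) {
      usable <- (margin + 1):(lens[i] - margin)
      pos <- sort(sample(usable, n_per[i]))
      data.frame(chrom = names(lens)[i], pos = pos,
                 stringsAsFactors = FALSE)
    }))
    bases <- c("A", "C", "G", "T")
    sites$ref <- sample(bases, nrow(sites), replace = TRUE)
    sites$alt <- vapply(sites$ref,
                        function(r) sample(setdiff(bases, r), 1),
                        character(1))
    sites$id <- paste0(sites$chrom, ":", sites$pos)

    p0 <- runif(config$n_sites, config$ancestral_range[1],
                config$ancestral_range[2])
    breed_freq <- vapply(config$breeds, function(b) rbn(p0, config$F_breed),
                         numeric(config$n_sites))
    pop_freq <- vapply(config$populations, function(pp) {
      b <- config$pop_breed[[pp]]
      if (pp %in% config$types) rbn(breed_freq[, b], config$F_type)
      else breed_freq[, b]
    }, numeric(config$n_sites))
    rownames(breed_freq) <- rownames(pop_freq) <- sites$id
    structure(list(sites = sites, ancestral = p0, breed_freq = breed_freq,
                   pop_freq = pop_freq, config = config),
              class = "sim_truth")
  })
}

#' Simulate a genotype cohort from the ground truth
#'
#' Genotypes are Binomial(2, f_pop) with independent per-call missingness
#' and Poisson depth; optional failed samples receive elevated
#' missingness. Deterministic given the config seed.
#'
#' @param truth a [simulate_frequencies()] result.
#' @param vcf_path optional path; when given the cohort is also written
#'   as a VCF (round-trippable through [read_vcf()]).
#' @return a [genotype_matrix()]; ids of injected failed samples are in
#'   `attr(, "failed_samples")`.
#' @export
simulate_genotypes <- function(truth, vcf_path = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  with_preserved_seed(config$seed + 1L, {
    n_pop <- length(config$populations)
    n <- n_pop * config$n_per_pop
    m <- config$n_sites
    samples <- data.frame(
      sample_id = paste0(rep(config$populations, each = config$n_per_pop),
                         "-", rep(seq_len(config$n_per_pop), n_pop)),
      population = rep(config$populations, each = config$n_per_pop),
      stringsAsFactors = FALSE)
    calls <- matrix(NA_integer_, n, m)
    for (k in seq_len(n_pop)) {
      rows <- ((k - 1) * config$n_per_pop + 1):(k * config$n_per_pop)
      f <- truth$pop_freq[, config$populations[k]]
      calls[rows, ] <- matrix(
        rbinom(length(rows) * m, 2, rep(f, each = length(rows))),
        nrow = length(rows))
    }
    if (config$missing_rate > 0)
      calls[matrix(runif(n * m) < config$missing_rate, n, m)] <- NA_integer_
    failed <- character(0)
    if (config$n_failed_samples > 0) {
      idx <- seq_len(config$n_failed_samples)
      failed <- samples$sample_id[idx]
      calls[idx, ][matrix(runif(length(idx) * m) < config$failed_missing_rate,
                          length(idx), m)] <- NA_integer_
    }
    depth <- matrix(rpois(n * m, config$depth_mean), n, m)
    depth[is.na(calls)] <- 0L
    gm <- genotype_matrix(calls, truth$sites, samples, depth = depth)
    attr(gm, "failed_samples") <- failed
    if (!is.null(vcf_path)) write_vcf(gm, vcf_path)
    gm
  })
}

#' Write a synthetic reference genome and toy gene models
#'
#' Emits a FASTA whose base at every simulated site equals that site's
#' ref allele, optionally plants extra copies of one site's probe window
#' (for homology testing), and writes a simple gene -> mRNA ->
#' exon/CDS/UTR GFF3 covering roughly `gene_fraction` of each
#' chromosome.
#'
#' @param truth a [simulate_frequencies()] result.
#' @param dir output directory (created if needed).
#' @param repeat_site_id optional site id whose 110-bp window is planted
#'   elsewhere in the genome.
#' @param repeat_copies total desired copy count of that window
#'   (including the original locus); one planted copy is
#'   reverse-complemented when more than two are requested.
#' @return list(fasta, gff3, repeats = data.frame of planted loci).
#' @export
write_reference <- function(truth, dir, repeat_site_id = NULL,
                            repeat_copies = 0L) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_preserved_seed(config$seed + 2L, {
    bases <- c("A", "C", "G", "T")
    seqs <- lapply(config$chrom_lengths, function(len)
      sample(bases, len, replace = TRUE))
    for (i in seq_len(nrow(truth$sites)))
      seqs[[truth$sites$chrom[i]]][truth$sites$pos[i]] <- truth$sites$ref[i]

    repeats <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0))
    if (!is.null(repeat_site_id) && repeat_copies > 1) {
      si <- match(repeat_site_id, truth$sites$id)
      if (is.na(si)) stop("unknown repeat site id")
      ch <- truth$sites$chrom[si]; pos <- truth$sites$pos[si]
      window <- seqs[[ch]][(pos - 55):(pos + 54)]
      targets <- names(config$chrom_lengths)
      placed <- 0L
      attempt <- 0L
      occupied <- list()
      while (placed < repeat_copies - 1 && attempt < 1000) {
        attempt <- attempt + 1L
        tc <- sample(targets, 1)
        start <- sample.int(config$chrom_lengths[[tc]] - 110L, 1)
        # avoid stamping over simulated sites or previous plants
        near_site <- any(truth$sites$chrom == tc &
                           abs(truth$sites$pos - (start + 55)) < 200)
        near_rep <- any(repeats$chrom == tc &
                          pmax(repeats$start, start) <=
                          pmin(repeats$end, start + 109))
        if (near_site || near_rep) next
        placed <- placed + 1L
        rc <- placed == 1L && repeat_copies > 2
        w <- if (rc) rev(chartr("ACGT", "TGCA", window)) else window
        seqs[[tc]][start:(start + 109L)] <- w
        repeats <- rbind(repeats, data.frame(
          chrom = tc, start = start, end = start + 109L,
          strand = if (rc) "-" else "+"))
      }
      if (placed < repeat_copies - 1) stop("could not place planted repeats")
    }

    fasta <- file.path(dir, "reference.fa")
    dss <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                           collapse = ""))
    names(dss) <- names(config$chrom_lengths)
    Biostrings::writeXStringSet(dss, fasta, width = 80)

    gff3 <- file.path(dir, "genes.gff3")
    write_toy_gff3(config, gff3)
    list(fasta = fasta, gff3 = gff3, repeats = repeats)
  })
}

# Toy gene models: 3 kb genes (UTR5 200 - CDS 200 | intron | CDS 400 |
# intron | CDS 200 - UTR3 200), alternating strands, spaced to cover
# about gene_fraction of each chromosome.
write_toy_gff3 <- function(config, path) {
  lines <- c("##gff-version 3")
  gid <- 0L
  for (ch in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[ch]]
    gene_len <- 3000L
    step <- max(gene_len + 200L, round(gene_len / config$gene_fraction))
    starts <- seq(1000L, len - gene_len - 1000L, by = step)
    for (s in starts) {
      gid <- gid + 1L
      strand <- if (gid %% 2 == 0) "-" else "+"
      g <- sprintf("G%05d", gid)
      e <- s + gene_len - 1L
      # plus-strand layout; for minus genes swap the UTR labels
      u5 <- c(s, s + 199L); c1 <- c(s + 200L, s + 399L)
      c2 <- c(s + 1400L, s + 1799L)
      c3 <- c(s + 2600L, s + 2799L); u3 <- c(s + 2800L, e)
      if (strand == "-") { tmp <- u5; u5 <- u3; u3 <- tmp }
      row <- function(type, lo, hi, id, parent)
        sprintf("%s\tdmafpanel\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                ch, type, lo, hi, strand, id, parent)
      lines <- c(lines,
        sprintf("%s\tdmafpanel\tgene\t%d\t%d\t.\t%s\t.\tID=%s", ch, s, e,
                strand, g),
        sprintf("%s\tdmafpanel\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                ch, s, e, strand, g, g),
        row("exon", s, s + 399L, paste0(g, ".e1"), paste0(g, ".t1")),
        row("exon", s + 1400L, s + 1799L, paste0(g, ".e2"), paste0(g, ".t1")),
        row("exon", s + 2600L, e, paste0(g, ".e3"), paste0(g, ".t1")),
        row("five_prime_UTR", u5[1], u5[2], paste0(g, ".u5"),
            paste0(g, ".t1")),
        row("CDS", c1[1], c1[2], paste0(g, ".c1"), paste0(g, ".t1")),
        row("CDS", c2[1], c2[2], paste0(g, ".c2"), paste0(g, ".t1")),
        row("CDS", c3[1], c3[2], paste0(g, ".c3"), paste0(g, ".t1")),
        row("three_prime_UTR", u3[1], u3[2], paste0(g, ".u3"),
            paste0(g, ".t1")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Hudson's FST estimator for two populations
#'
#' Ratio-of-averages estimator: per site
#' N = (p1 - p2)^2 - p1 (1 - p1)/(n1 - 1) - p2 (1 - p2)/(n2 - 1),
#' D = p1 (1 - p2) + p2 (1 - p1); FST = sum(N) / sum(D), with n the
#' called allele counts. Used as the independent oracle for recovering
#' the simulator's divergence parameter.
#'
#' @param gm a [genotype_matrix()].
#' @param pop1,pop2 population labels to compare.
#' @return a single FST estimate.
#' @export
hudson_fst <- function(gm, pop1, pop2) {
  fr <- population_frequencies(gm)
  p1 <- fr$freq[, pop1]; p2 <- fr$freq[, pop2]
  n1 <- fr$n_alleles[, pop1]; n2 <- fr$n_alleles[, pop2]
  ok <- n1 > 1 & n2 > 1
  p1 <- p1[ok]; p2 <- p2[ok]; n1 <- n1[ok]; n2 <- n2[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
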