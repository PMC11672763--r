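# Brute-force selection oracles, independent of the implementation.

oracle_topk <- function(cand, pops, K) {
  picked <- character(0)
  for (p in pops) {
    ord <- order(-cand[[paste0("s_", p)]], chrom_rank_oracle(cand$chrom),
                 cand$pos)
    picked <- union(picked, cand$id[ord][seq_len(min(K, nrow(cand)))])
  }
  picked
}

chrom_rank_oracle <- function(chrom) {
  # same documented convention: numeric, then X, then Y
  s <- sub("^chr", "", chrom)
  n <- suppressWarnings(as.numeric(s))
  ifelse(!is.na(n), n, ifelse(s == "X", 1e6, 1e6 + 1))
}

oracle_capacity <- function(union, capacity) {
  auto <- union$id[union$chrom_class == "autosome"]
  sex <- union[union$chrom_class %in% c("X", "Y"), ]
  slots <- max(0, capacity - length(auto))
  ord <- order(-sex$mean_delta, chrom_rank_oracle(sex$chrom), sex$pos)
  c(auto, sex$id[ord][seq_len(min(slots, nrow(sex)))])
}

random_candidates <- function(seed, n, pops = c("A", "B", "C"),
                              with_x = TRUE) {
  set.seed(seed)
  chrom <- sample(c("chr1", "chr2", if (with_x) "chrX"), n, replace = TRUE)
  cand <- data.frame(
    id = paste0("s", seq_len(n)), chrom = chrom,
    pos = sample(1e5, n), chrom_class = classify_chromosome(chrom),
    max_delta = NA, mean_delta = round(runif(n), 2),
    stringsAsFactors = FALSE)
  cand$id <- paste0(cand$chrom, ":", cand$pos)
  for (p in pops) cand[[paste0("s_", p)]] <- round(runif(n), 2)
  attr(cand, "populations") <- pops
  cand
}

test_that("top_k_union handles complete and zero overlap", {
  # identical rankings across populations -> union size exactly K
  cand <- random_candidates(1, 30)
  for (p in c("B", "C")) cand[[paste0("s_", p)]] <- cand$s_A
  expect_equal(nrow(top_k_union(cand, K = 7)), 7)

  # disjoint top-K lists -> union size #pops * K
  cand2 <- random_candidates(2, 30)
  cand2$s_A <- c(rep(1, 10), rep(0, 20))
  cand2$s_B <- c(rep(0, 10), rep(1, 10), rep(0, 10))
  cand2$s_C <- c(rep(0, 20), rep(1, 10))
  expect_equal(nrow(top_k_union(cand2, K = 10)), 30)

  expect_error(top_k_union(cand[0, ], K = 5), "no candidates")
})

site_order_oracle <- function(chrom, pos) order(chrom_rank_oracle(chrom), pos)

test_that("top_k_union equals the brute-force oracle with provenance", {
  for (seed in c(11, 12, 13)) {
    cand <- random_candidates(seed, 30)
    u <- top_k_union(cand, K = 4)
    expect_setequal(u$id, oracle_topk(cand, c("A", "B", "C"), 4))
    expect_true(all(nzchar(u$provenance)))
    expect_false(anyDuplicated(u$id) > 0)
    # sorted by (chrom, pos)
    expect_equal(u$id, u$id[site_order_oracle(u$chrom, u$pos)])
  }
})

test_that("allocate_capacity keeps autosomes and fills with sex sites", {
  # 40 autosomal + 10 X, capacity 45 -> all autosomes + top-5 X by mean delta
  cand <- random_candidates(3, 50, with_x = FALSE)
  cand$chrom[1:10] <- "chrX"
  cand$chrom_class <- classify_chromosome(cand$chrom)
  cand$id <- paste0(cand$chrom, ":", cand$pos)
  u <- top_k_union(cand, K = 50)
  pan <- allocate_capacity(u, capacity = 45)
  expect_setequal(pan$id, oracle_capacity(u, 45))
  expect_equal(sum(pan$chrom_class == "X"), 45 - sum(u$chrom_class == "autosome"))

  # no sex sites -> panel is all autosomal
  cand_a <- random_candidates(4, 20, with_x = FALSE)
  u_a <- top_k_union(cand_a, K = 20)
  expect_equal(nrow(allocate_capacity(u_a, capacity = 100)), nrow(u_a))

  # autosomes exceeding capacity are all kept, with a warning
  expect_warning(pan_all <- allocate_capacity(u_a, capacity = 5),
                 "exceed")
  expect_equal(nrow(pan_all), nrow(u_a))
  expect_error(allocate_capacity(u_a, capacity = 0), "capacity")
})

test_that("allocate_capacity breaks mean-delta ties by (chrom, pos)", {
  cand <- random_candidates(5, 20)
  cand$mean_delta <- 0.5   # all tied
  u <- top_k_union(cand, K = 20)
  pan <- allocate_capacity(u, capacity = sum(u$chrom_class == "autosome") + 3)
  xs <- u[u$chrom_class == "X", ]
  expected <- xs$id[order(chrom_rank_oracle(xs$chrom), xs$pos)][1:3]
  expect_setequal(pan$id[pan$chrom_class == "X"], expected)
})

test_that("prune_by_detection keeps sites at or above the threshold", {
  cand <- random_candidates(6, 20, with_x = FALSE)
  u <- top_k_union(cand, K = 20)

  all_one <- setNames(rep(1, nrow(u)), u$id)
  expect_equal(nrow(prune_by_detection(u, all_one)$panel), nrow(u))

  one_zero <- all_one
  one_zero[u$id[7]] <- 0
  res <- prune_by_detection(u, one_zero)
  expect_equal(res$pruned$id, u$id[7])
  expect_equal(nrow(res$panel), nrow(u) - 1)

  # uniform-random rates match a direct count oracle
  set.seed(8)
  rates <- setNames(runif(nrow(u)), u$id)
  res2 <- prune_by_detection(u, rates, min_rate = 0.4)
  expect_equal(nrow(res2$panel), sum(rates >= 0.4))

  expect_error(prune_by_detection(u, all_one[-1]), "no detection rate")
})

test_that("pipeline stages are monotone and exports are deterministic", {
  cand <- random_candidates(7, 50)
  u <- top_k_union(cand, K = 10)
  pan <- allocate_capacity(u, capacity = 25)
  expect_true(all(pan$id %in% u$id))
  set.seed(3)
  rates <- setNames(runif(nrow(pan), 0.8, 1), pan$id)
  final <- prune_by_detection(pan, rates, 0.9)$panel
  expect_true(all(final$id %in% pan$id))

  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_panel_tsv(final, f1)
  export_panel_tsv(final, f2)
  expect_identical(readLines(f1), readLines(f2))

  bed <- withr::local_tempfile(fileext = ".bed")
  export_panel_bed(final, bed)
  b <- read.table(bed, sep = "\t")
  expect_equal(b$V3 - b$V2, rep(1, nrow(final)))   # 0-based half-open
  expect_equal(b$V2, final$pos - 1)
})

test_that("panel_candidates drops unscoreable, probe-failing and Y sites", {
  gm <- random_gm(19, n = 12, m = 20, n_pops = 2, missing = 0)
  gm$sites$chrom[1:4] <- "chrY"
  gm2 <- genotype_matrix(gm$calls, gm$sites, gm$samples)
  ds <- delta_scores(population_frequencies(gm2))
  probes <- data.frame(site_id = gm2$sites$id,
                       pass = rep(c(TRUE, FALSE), 10))
  cand <- panel_candidates(ds, probes)
  expect_true(all(cand$chrom_class != "Y"))
  expect_true(all(cand$id %in% probes$site_id[probes$pass]))
})
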