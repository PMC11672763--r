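# Double-loop GRM oracle.
grm_oracle <- function(calls, p) {
  usable <- p > 0 & p < 1
  calls <- calls[, usable, drop = FALSE]
  p <- p[usable]
  n <- nrow(calls)
  A <- matrix(0, n, n)
  for (j in 1:n) for (k in 1:n) {
    acc <- 0; m <- 0
    for (i in seq_along(p)) {
      xj <- calls[j, i]; xk <- calls[k, i]
      if (is.na(xj) || is.na(xk)) next
      acc <- acc + (xj - 2 * p[i]) * (xk - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
      m <- m + 1
    }
    A[j, k] <- acc / m
  }
  A
}

test_that("grm matches closed forms and the brute-force oracle", {
  # single site, p = 0.5, x = 2 -> diagonal (2-1)^2/(2*0.5*0.5) = 2
  gm1 <- make_gm(matrix(c(2, 0), ncol = 1))
  g1 <- grm(gm1, allele_freq = 0.5)
  expect_equal(unname(g1$A[1, 1]), 2.0)

  # identical samples: off-diagonal equals diagonal
  gm2 <- make_gm(rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 1, 0, 0)))
  g2 <- grm(gm2)
  expect_equal(g2$A[1, 2], g2$A[1, 1])

  # 10 x 20 random matrix with missing: brute force to 1e-10
  gm3 <- random_gm(31, n = 10, m = 20, missing = 0.1)
  called <- colSums(!is.na(gm3$calls))
  p <- colSums(gm3$calls, na.rm = TRUE) / (2 * called)
  g3 <- grm(gm3)
  expect_equal(unname(g3$A), grm_oracle(gm3$calls, p), tolerance = 1e-10)
  expect_true(isSymmetric(g3$A))
})

test_that("grm permutes consistently with sample order", {
  gm <- random_gm(32, n = 8, m = 30, missing = 0.05)
  g <- grm(gm)
  set.seed(1)
  perm <- sample(8)
  gm_p <- genotype_matrix(gm$calls[perm, ], gm$sites, gm$samples[perm, ])
  g_p <- grm(gm_p)
  expect_equal(unname(g_p$A), unname(g$A[perm, perm]))
})

test_that("pca returns orthonormal top-k eigenpairs of the centered GRM", {
  # identity GRM: all eigenvalues of the centered matrix coincide
  ev <- pca(diag(6), k = 3)$values
  expect_equal(ev, rep(ev[1], 3))

  # rank-1 vv' with centered v: first eigenvalue |v|^2, rest ~ 0
  v <- c(2, -1, -1, 1, -1)
  v <- v - mean(v)
  p1 <- pca(tcrossprod(v), k = 3)
  expect_equal(p1$values[1], sum(v^2))
  expect_lt(abs(p1$values[2]), 1e-8)

  g <- grm(random_gm(33, n = 12, m = 50, missing = 0))
  p <- pca(g, k = 3)
  expect_equal(crossprod(p$vectors), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # eigenvalue sum over all components equals the centered trace
  p_all <- pca(g, k = 12)
  expect_equal(sum(p_all$values), p_all$trace_centered, tolerance = 1e-8)
  expect_error(pca(g, k = 13), "exceeds")
  expect_error(pca(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("PC1 separates two Balding-Nichols populations", {
  sc <- sim_config(seed = 91, breeds = c("P", "Q"), types = character(0),
                   F_breed = 0.05, F_type = 0.5, n_per_pop = 50,
                   n_sites = 5000,
                   chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                   missing_rate = 0)
  gm <- simulate_genotypes(simulate_frequencies(sc))
  p <- pca(grm(gm), k = 3)
  pc1 <- p$vectors[, 1]
  pop <- gm$samples$population
  expect_true(max(pc1[pop == "P"]) < min(pc1[pop == "Q"]) ||
                max(pc1[pop == "Q"]) < min(pc1[pop == "P"]))
})

test_that("ibs_distance matches hand computation and its axioms", {
  expect_equal(unname(ibs_distance(make_gm(rbind(c(0, 1, 2),
                                                 c(0, 1, 2))))$D[1, 2]), 0)
  expect_equal(unname(ibs_distance(make_gm(rbind(c(0, 2, 0),
                                                 c(2, 0, 2))))$D[1, 2]), 1)

  # 4-sample hand case with a missing cell
  calls <- rbind(c(0, 1, 2, NA),
                 c(0, 1, 1, 0),
                 c(2, 1, 0, 2),
                 c(1, NA, 2, 1))
  d <- ibs_distance(make_gm(calls))$D
  expect_equal(d[1, 2], (0 + 0 + 1) / (2 * 3))
  expect_equal(d[1, 3], (2 + 0 + 2) / (2 * 3))
  expect_equal(d[2, 4], (1 + 1 + 1) / (2 * 3))
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 4), rownames(d)))
  expect_true(all(d <= 1))
})

test_that("nj_tree reproduces closed forms and additive distances", {
  # 3 taxa: unique tree, closed-form branch lengths
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)

  # 4-taxon additive matrix from a known tree: exact recovery
  tree4 <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:3):1);")
  D4 <- ape::cophenetic.phylo(tree4)
  rec <- nj_tree(D4)
  expect_equal(phangorn::RF.dist(ape::unroot(tree4), rec), 0)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-9)

  # 8-taxon additivity property
  set.seed(55)
  tree8 <- ape::rtree(8)
  D8 <- ape::cophenetic.phylo(tree8)
  rec8 <- nj_tree(D8)
  expect_equal(ape::cophenetic.phylo(rec8)[rownames(D8), colnames(D8)], D8,
               tolerance = 1e-9)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("cluster_concordance scores partitions against labels", {
  set.seed(12)
  coords <- rbind(matrix(rnorm(40, 0), ncol = 2),
                  matrix(rnorm(40, 8), ncol = 2))
  labels <- rep(c("u", "v"), each = 20)
  cc <- cluster_concordance(coords, labels)
  expect_equal(cc$ari, 1.0)
  expect_equal(cc$purity, 1.0)

  # identical partitions score 1 by definition
  expect_equal(adjusted_rand_index(labels, labels), 1.0)
  # independent random labels: ARI near zero
  set.seed(13)
  r <- replicate(50, adjusted_rand_index(sample(1:3, 300, TRUE),
                                         sample(1:3, 300, TRUE)))
  expect_lt(abs(mean(r)), 0.01)
  expect_error(cluster_concordance(coords[1:1, , drop = FALSE], labels[1]),
               "fewer samples|length")
})

test_that("pop_mean_distance averages blocks of the sample matrix", {
  calls <- rbind(c(0, 0), c(0, 0), c(2, 2), c(2, 2))
  d <- ibs_distance(make_gm(calls, populations = c("A", "A", "B", "B")))
  pd <- pop_mean_distance(d, c("A", "A", "B", "B"))
  expect_equal(pd["A", "A"], 0)
  expect_equal(pd["A", "B"], 1)
})
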