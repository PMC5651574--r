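test_that("Nei distance matches its direct-formula oracle and limit cases", {
  expect_equal(nei_distance(c(0.5, 0.2), c(0.5, 0.2)), 0)
  expect_equal(nei_distance(c(1, 1, 0), c(0, 0, 1)), Inf)
  set.seed(3)
  for (i in 1:5) {
    x <- runif(5); y <- runif(5)
    expect_equal(nei_distance(x, y), max(0, oracle_nei(x, y)),
                 tolerance = 1e-12)
  }
  # individual-level matrix agrees with the scalar form on complete data
  g <- random_gm(8, 100, seed = 7)
  D <- nei_distance_matrix(g)
  for (pair in list(c(1, 2), c(3, 8))) {
    x <- g[pair[1], ] / 2; y <- g[pair[2], ] / 2
    expect_equal(D[pair[1], pair[2]], nei_distance(x, y), tolerance = 1e-12)
  }
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 8))
})

test_that("pairwise-complete Nei distances ignore loci missing in either individual", {
  g <- random_gm(5, 60, missing = 0.15, seed = 9)
  D <- nei_distance_matrix(g)
  ok <- !is.na(g[1, ]) & !is.na(g[2, ])
  expect_equal(D[1, 2], nei_distance(g[1, ok] / 2, g[2, ok] / 2),
               tolerance = 1e-12)
})

test_that("Reynolds distance: identity, fixed difference and oracle equivalence", {
  p <- runif(5, 0.1, 0.9)
  expect_equal(reynolds_distance(p, p, 24, 24), 0)        # floored negative
  expect_equal(reynolds_distance(rep(1, 4), rep(0, 4), 10, 12), 1)
  set.seed(19)
  for (i in 1:5) {
    p1 <- runif(5); p2 <- runif(5)
    expect_equal(reynolds_distance(p1, p2, 15, 22),
                 oracle_reynolds(p1, p2, 15, 22), tolerance = 1e-12)
  }
})

test_that("Manhattan distance is a per-locus mean and satisfies the triangle inequality", {
  expect_equal(manhattan_distance(c(0, 0), c(2, 2)), 2)
  expect_equal(manhattan_distance(c(0, 1, 2), c(0, 1, 2)), 0)
  g <- random_gm(9, 50, missing = 0.05, seed = 12)
  D <- manhattan_distance_matrix(g)
  expect_equal(D[2, 3], manhattan_distance(g[2, ], g[3, ]), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    trip <- sample(9, 3)
    expect_lte(D[trip[1], trip[3]],
               D[trip[1], trip[2]] + D[trip[2], trip[3]] + 1e-12)
  }
})

test_that("IBS kinship anchors and expected range for unrelated individuals", {
  g <- genotype_matrix(rbind(a = c(0L, 2L, 1L), b = c(2L, 0L, 1L)),
                       locus_ids = c("x", "y", "z"))
  K <- ibs_kinship(g)
  expect_equal(unname(diag(K)), c(1, 1))
  opp <- genotype_matrix(rbind(a = c(0L, 0L), b = c(2L, 2L)),
                         locus_ids = c("x", "y"))
  expect_equal(ibs_kinship(opp)["a", "b"], 0)
  sim <- simulate_genotypes(sim_config(n_pops = 1, n_per_pop = 30,
                                       n_loci = 4000, fst_per_pop = 1e-4,
                                       ancestral_maf = c(0.05, 0.5),
                                       pop_labels = "P"), seed = 14)
  Ks <- ibs_kinship(sim$genotypes)
  off <- mean(Ks[upper.tri(Ks)])
  expect_gt(off, 0.6); expect_lt(off, 0.75)
})

test_that("clustering merges the close pair first and matches a naive agglomeration", {
  d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchical_cluster(d)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))    # A,B merged first
  expect_equal(hc$height[1], 1)
  set.seed(6)
  for (i in 1:5) {
    m <- matrix(runif(36, 1, 10), 6); m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:6], letters[1:6])
    expect_equal(hierarchical_cluster(m)$height,
                 oracle_complete_linkage_heights(m), tolerance = 1e-12)
  }
  bad <- d; bad[1, 3] <- bad[3, 1] <- Inf
  expect_error(hierarchical_cluster(bad), "A-C")
})

test_that("a drifted population forms a pure subtree", {
  # best Jaccard agreement between any dendrogram node and the drifted set
  purity <- sapply(1:20, function(s) {
    cfg <- sim_config(n_pops = 4, n_per_pop = 12, n_loci = 4000,
                      fst_per_pop = c(0.01, 0.01, 0.08, 0.01))
    sim <- simulate_genotypes(cfg, seed = s)
    hc <- hierarchical_cluster(nei_distance_matrix(sim$genotypes))
    drift <- which(sim$sample_map$breed == "P3")
    best <- 0
    for (k in seq_along(hc$order)) {
      ct <- stats::cutree(hc, k = k)
      for (cl in unique(ct)) {
        mem <- which(ct == cl)
        j <- length(intersect(mem, drift)) / length(union(mem, drift))
        if (j > best) best <- j
      }
    }
    best
  })
  expect_true(all(purity >= 0.9))
})

test_that("AMOVA SS decomposition equals brute force and percentages sum to 100", {
  set.seed(8)
  m <- matrix(runif(36, 0, 4), 6); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(paste0("i", 1:6), paste0("i", 1:6))
  sm <- data.frame(sample_id = paste0("i", 1:6),
                   breed = rep(c("g1", "g2"), each = 3))
  res <- amova(m, sm, permutations = 0)
  ss <- oracle_amova_ss(m, sm$breed)
  expect_equal(res$ss_among, unname(ss["ss_among"]), tolerance = 1e-9)
  expect_equal(res$ss_within, unname(ss["ss_within"]), tolerance = 1e-9)
  expect_equal(res$pct_among + res$pct_within, 100, tolerance = 1e-9)
  expect_true(is.na(res$p_value))                  # permutations = 0 contract
  expect_error(amova(m, data.frame(sample_id = paste0("i", 1:6),
                                   breed = c("a", rep("b", 5))), 0), "size 1")
})

test_that("AMOVA is null under random labels and detects full divergence", {
  sim <- simulate_genotypes(sim_config(n_pops = 1, n_per_pop = 32,
                                       n_loci = 2000, fst_per_pop = 1e-4,
                                       pop_labels = "P"), seed = 51)
  D <- nei_distance_matrix(sim$genotypes)
  sm <- sim$sample_map
  set.seed(52)
  sm$breed <- sample(rep(c("a", "b", "c", "d"), 8))
  res <- amova(D, sm, permutations = 200, seed = 53)
  expect_lt(abs(res$pct_among), 2)
  expect_gt(res$p_value, 0.05)
  # two fully diverged populations: all loci fixed differences
  gfix <- genotype_matrix(rbind(matrix(0L, 6, 50), matrix(2L, 6, 50)),
                          paste0("i", 1:12), paste0("L", 1:50))
  Dfix <- manhattan_distance_matrix(gfix)
  res2 <- amova(Dfix, data.frame(sample_id = paste0("i", 1:12),
                                 breed = rep(c("x", "y"), each = 6)),
                permutations = 200, seed = 54)
  expect_gt(res2$pct_among, 90)
  expect_lt(res2$p_value, 0.05)
})

test_that("AMOVA among-population share rises with the drift parameter", {
  pct <- sapply(c(0.005, 0.02, 0.05), function(f) {
    sim <- simulate_genotypes(sim_config(n_pops = 3, n_per_pop = 12,
                                         n_loci = 2000, fst_per_pop = f),
                              seed = 61)
    amova(nei_distance_matrix(sim$genotypes), sim$sample_map,
          permutations = 0)$pct_among
  })
  expect_true(all(diff(pct) > 0))
})
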