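test_that("Weir-Cockerham components match an independent textbook oracle to 1e-12", {
  set.seed(17)
  for (rep in 1:10) {
    n_pop <- sample(2:4, 1)
    sizes <- sample(5:30, n_pop, replace = TRUE)
    pops <- rep(paste0("P", seq_len(n_pop)), sizes)
    L <- 10
    p <- runif(L, 0.05, 0.95)
    dos <- matrix(rbinom(sum(sizes) * L, 2, rep(p, each = sum(sizes))),
                  sum(sizes), L)
    g <- genotype_matrix(dos, paste0("i", seq_len(sum(sizes))),
                         paste0("L", 1:L))
    wc <- wc_theta(g, pops)
    for (l in which(wc$usable)) {
      o <- oracle_wc_locus(oracle_counts(dos[, l], pops))
      expect_equal(unname(wc$a[l]), unname(o["a"]), tolerance = 1e-12)
      expect_equal(unname(wc$b[l]), unname(o["b"]), tolerance = 1e-12)
      expect_equal(unname(wc$c[l]), unname(o["c"]), tolerance = 1e-12)
      expect_equal(unname(wc$theta[l]), unname(o["theta"]), tolerance = 1e-12)
    }
  }
})

test_that("theta closed forms: fixed difference gives 1; identical HWE counts give the small negative finite-sample value", {
  # p1 = 1, p2 = 0, all homozygous, n = 24 each
  g <- genotype_matrix(rbind(matrix(2L, 24, 1), matrix(0L, 24, 1)),
                       paste0("i", 1:48), "L1")
  expect_equal(wc_theta(g, rep(c("a", "b"), each = 24))$theta_multilocus, 1)
  # identical genotype counts (6/12/6 per pop): s2 = 0 makes a = -b and the
  # estimator slightly negative, a known property of the WC correction
  cnt <- c(rep(0L, 6), rep(1L, 12), rep(2L, 6))
  g2 <- genotype_matrix(matrix(c(cnt, cnt), ncol = 1), paste0("i", 1:48), "L1")
  wc <- wc_theta(g2, rep(c("a", "b"), each = 24))
  o <- oracle_wc_locus(list(c(6, 12, 6), c(6, 12, 6)))
  expect_equal(wc$theta_multilocus, unname(o["theta"]), tolerance = 1e-12)
  expect_lt(wc$theta_multilocus, 0)
  expect_equal(unname(wc$a[1]), unname(-wc$b[1]), tolerance = 1e-12)
  # the all-heterozygote identical configuration is the exact-zero case
  g3 <- genotype_matrix(matrix(1L, 20, 1), paste0("i", 1:20), "L1")
  expect_equal(unname(wc_theta(g3, rep(c("a", "b"), each = 10))$a[1]), 0,
               tolerance = 1e-15)
})

test_that("monomorphic loci are excluded and per-locus vector spans usable loci", {
  g <- genotype_matrix(cbind(L1 = rep(c(0L, 2L), 6), L2 = rep(0L, 12),
                             L3 = rep(c(0L, 1L), 6)),
                       sample_ids = paste0("i", 1:12))
  wc <- wc_theta(g, rep(c("a", "b"), 6))
  expect_false(wc$usable[2])
  expect_true(is.na(wc$theta[2]))
  expect_equal(sum(wc$usable), 2L)
  est <- fst_one_vs_rest(g, data.frame(sample_id = rownames(g),
                                       breed = rep(c("a", "b"), 6)),
                         target = "a", bootstrap_reps = 0)
  expect_equal(length(est$theta_per_locus), 3L)
  expect_equal(est$n_usable_loci, 2L)
})

test_that("multilocus theta is a ratio of sums, order-invariant and duplication-consistent", {
  g <- random_gm(30, 60, seed = 23)
  pops <- rep(c("a", "b"), 15)
  wc <- wc_theta(g, pops)
  perm <- sample(ncol(g))
  wc_perm <- wc_theta(g[, perm], pops)
  expect_equal(wc_perm$theta_multilocus, wc$theta_multilocus, tolerance = 1e-12)
  # duplicating every locus leaves the ratio-of-sums unchanged
  g2 <- genotype_matrix(cbind(unclass(g), unclass(g)),
                        rownames(g), c(colnames(g), paste0(colnames(g), "_d")))
  expect_equal(wc_theta(g2, pops)$theta_multilocus, wc$theta_multilocus,
               tolerance = 1e-12)
  expect_true(all(abs(wc$theta[wc$usable]) <= 1))
})

test_that("pairwise FST recovers the Balding-Nichols parameter", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 24, n_loci = 10000,
                    fst_per_pop = 0.02, pop_labels = c("A", "B"))
  sim <- simulate_genotypes(cfg, seed = 31)
  est <- fst_pairwise(sim$genotypes, sim$sample_map, bootstrap_reps = 0)
  expect_gt(est$table$theta, 0.015)
  expect_lt(est$table$theta, 0.025)
})

test_that("two halves of one population are not significantly differentiated", {
  cfg <- sim_config(n_pops = 1, n_per_pop = 48, n_loci = 4000,
                    fst_per_pop = 1e-4, pop_labels = "P")
  sim <- simulate_genotypes(cfg, seed = 37)
  sm <- sim$sample_map
  sm$breed <- rep(c("x", "y"), 24)                 # arbitrary split
  est <- fst_pairwise(sim$genotypes, sm, bootstrap_reps = 300, alpha = 0.005,
                      seed = 38)
  expect_false(est$table$significant)
  expect_true(est$table$ci_low <= 0 && est$table$ci_high >= 0)
})

test_that("only contrasts involving a drifted population are significant", {
  cfg <- sim_config(n_pops = 4, n_per_pop = 20, n_loci = 5000,
                    fst_per_pop = c(1e-4, 1e-4, 1e-4, 0.02),
                    pop_labels = c("A", "B", "C", "DRIFT"))
  sim <- simulate_genotypes(cfg, seed = 41)
  est <- fst_pairwise(sim$genotypes, sim$sample_map, bootstrap_reps = 300,
                      alpha = 0.005, seed = 42)
  drifted <- est$table$pop1 == "DRIFT" | est$table$pop2 == "DRIFT"
  expect_true(all(est$table$significant[drifted]))
  expect_false(any(est$table$significant[!drifted]))
})

test_that("one-vs-rest pools the remainder and flags planted outlier loci", {
  cfg <- sim_config(n_pops = 4, n_per_pop = 20, n_loci = 3000,
                    fst_per_pop = 0.02, n_outlier_loci = 20, outlier_pop = 2,
                    outlier_delta = 0.4)
  sim <- simulate_genotypes(cfg, seed = 43)
  est <- fst_one_vs_rest(sim$genotypes, sim$sample_map, target = "P2",
                         bootstrap_reps = 0)
  th <- est$theta_per_locus
  ok <- !is.na(th)
  cut <- mean(th[ok]) + 2 * sd(th[ok])
  planted <- sim$truth$outlier_loci
  expect_gt(mean(th[planted] > cut, na.rm = TRUE), 0.9)
  # shuffled labels within the pooled composition give theta ~ 0
  sm <- sim$sample_map
  set.seed(44)
  sm$breed <- sample(sm$breed)
  est0 <- fst_one_vs_rest(sim$genotypes, sm, target = "P2",
                          bootstrap_reps = 200, seed = 45)
  expect_lt(abs(est0$theta_multilocus), 0.005)
  expect_false(est0$significant)
  expect_error(fst_one_vs_rest(sim$genotypes, sim$sample_map, "nope", 0),
               "unknown breed")
})
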