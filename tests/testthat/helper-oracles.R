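# Independent brute-force oracles, deliberately written as plain scalar
# loops from the textbook formulas so they share no code with the package.

# Weir & Cockerham (1984) per-locus components for one biallelic locus.
# counts: list per population of c(n_aa, n_ab, n_bb)
oracle_wc_locus <- function(counts) {
  r <- length(counts)
  n <- sapply(counts, sum)
  p <- sapply(counts, function(x) (2 * x[3] + x[2]) / (2 * sum(x)))
  h <- sapply(counts, function(x) x[2] / sum(x))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# genotype counts per population at one locus from a dosage matrix column
oracle_counts <- function(dos_col, pops) {
  lapply(split(dos_col, pops), function(v) {
    v <- v[!is.na(v)]
    c(sum(v == 0), sum(v == 1), sum(v == 2))
  })
}

# Nei (1972) standard distance, direct evaluation for biallelic units
oracle_nei <- function(x, y) {
  jx <- jy <- jxy <- 0
  L <- length(x)
  for (l in seq_len(L)) {
    jx <- jx + x[l]^2 + (1 - x[l])^2
    jy <- jy + y[l]^2 + (1 - y[l])^2
    jxy <- jxy + x[l] * y[l] + (1 - x[l]) * (1 - y[l])
  }
  -log((jxy / L) / sqrt((jx / L) * (jy / L)))
}

# Reynolds (1983) least-squares coancestry, per-locus scalar loop
oracle_reynolds <- function(p1, p2, n1, n2) {
  num <- den <- 0
  for (l in seq_along(p1)) {
    s1 <- 2 * p1[l] * (1 - p1[l]); s2 <- 2 * p2[l] * (1 - p2[l])
    k <- (n1 * s1 + n2 * s2) / (4 * n1 * n2 * (n1 + n2 - 1))
    num <- num + (p1[l] - p2[l])^2 - (n1 + n2) * k
    den <- den + (p1[l] - p2[l])^2 + (4 * n1 * n2 - n1 - n2) * k
  }
  max(0, num / den)
}

# Excoffier (1992) sums of squares by explicit enumeration of pairs
oracle_amova_ss <- function(dm, groups) {
  N <- nrow(dm)
  ss_total <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    ss_total <- ss_total + dm[i, j]^2
  ss_total <- ss_total / N
  ss_within <- 0
  for (gname in unique(groups)) {
    idx <- which(groups == gname)
    s <- 0
    if (length(idx) > 1)
      for (a in seq_along(idx)[-length(idx)])
        for (b in (a + 1):length(idx)) s <- s + dm[idx[a], idx[b]]^2
    ss_within <- ss_within + s / length(idx)
  }
  c(ss_total = ss_total, ss_among = ss_total - ss_within,
    ss_within = ss_within)
}

# naive agglomerative clustering: returns merge heights in order, to
# compare against hclust on small matrices (complete linkage)
oracle_complete_linkage_heights <- function(dm) {
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1):length(clusters)) {
        d <- max(dm[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# brute-force O(S x G) window/gene overlap scan
oracle_window_genes <- function(windows, genes) {
  hits <- character(0)
  for (i in seq_len(nrow(windows))) for (j in seq_len(nrow(genes))) {
    if (sub("^chr", "", windows$chromosome[i]) ==
        sub("^chr", "", genes$chromosome[j]) &&
        genes$start_bp[j] <= windows$end_bp[i] &&
        genes$end_bp[j] >= windows$start_bp[i])
      hits <- c(hits, genes$gene_id[j])
  }
  sort(unique(hits))
}

# small random genotype matrix helper
random_gm <- function(n, L, maf_range = c(0.1, 0.5), missing = 0, seed = 1) {
  set.seed(seed)
  p <- runif(L, maf_range[1], maf_range[2])
  dos <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  if (missing > 0) dos[runif(n * L) < missing] <- NA
  genotype_matrix(dos, sprintf("ind%02d", 1:n), sprintf("L%03d", 1:L))
}
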