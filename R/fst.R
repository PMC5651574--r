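#' Weir-Cockerham variance components and theta per locus
#'
#' Implements the Weir & Cockerham (1984) variance-components estimator of
#' F_ST for diploid biallelic data with unequal sample sizes: per locus the
#' among-population (a), among-individual-within-population (b) and
#' within-individual (c) components, and theta = a / (a + b + c). Loci where
#' any population has zero calls, or that are monomorphic overall
#' (a + b + c = 0), are marked unusable and excluded from multilocus sums.
#' The multilocus estimate is the ratio of summed components
#' sum(a) / sum(a + b + c), never a mean of per-locus ratios. Negative
#' estimates are legitimate for this estimator and are preserved.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param pops factor or character vector of population labels, one per
#'   sample (row) of \code{g}.
#' @return list with per-locus vectors \code{a}, \code{b}, \code{c},
#'   \code{theta} (NA where unusable), logical \code{usable}, and
#'   \code{theta_multilocus}.
#' @references Weir BS, Cockerham CC (1984) Estimating F-statistics for the
#'   analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_theta <- function(g, pops) {
  pops <- factor(pops)
  if (length(pops) != nrow(g)) stop("'pops' must have one label per sample")
  r <- nlevels(pops)
  if (r < 2) stop("at least 2 populations required")
  sizes <- table(pops)
  if (any(sizes < 1)) stop("empty population level")

  nonmiss <- !is.na(g)
  gz <- g; gz[!nonmiss] <- 0L
  n <- rowsum(nonmiss + 0, pops)              # pops x loci, diploid counts
  ac <- rowsum(gz + 0, pops)                  # B allele counts x 2? no: dosage sums
  hs <- rowsum((g == 1L & nonmiss) + 0, pops) # het counts
  p <- ac / (2 * n)                           # B-allele freq per pop
  h <- hs / n                                 # het proportion per pop
  p[n == 0] <- 0; h[n == 0] <- 0

  nbar <- colSums(n) / r
  usable <- colSums(n > 0) == r & nbar > 1
  nC <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)

  a <- (nbar / nC) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  denom <- a + b + cc
  usable <- usable & is.finite(denom) & denom != 0
  theta <- ifelse(usable, a / denom, NA_real_)
  names(theta) <- colnames(g)
  list(a = a, b = b, c = cc, theta = theta, usable = usable,
       theta_multilocus = sum(a[usable]) / sum(denom[usable]))
}

# locus bootstrap of the multilocus ratio estimator
.boot_theta <- function(a, denom, reps) {
  L <- length(a)
  vapply(seq_len(reps), function(r) {
    idx <- sample.int(L, L, replace = TRUE)
    sum(a[idx]) / sum(denom[idx])
  }, numeric(1))
}

# single-contrast FST with bootstrap CI; returns an fst_estimate
.fst_contrast <- function(g, pops, label1, label2, bootstrap_reps, alpha,
                          alpha_suggestive) {
  wc <- wc_theta(g, pops)
  a <- wc$a[wc$usable]; denom <- (wc$a + wc$b + wc$c)[wc$usable]
  est <- wc$theta_multilocus
  ci <- ci_sugg <- c(NA_real_, NA_real_); signif <- signif_sugg <- NA
  if (bootstrap_reps > 0 && length(a) >= 2) {
    boot <- .boot_theta(a, denom, bootstrap_reps)
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
    ci_sugg <- unname(stats::quantile(boot,
      c(alpha_suggestive / 2, 1 - alpha_suggestive / 2)))
    signif <- ci[1] > 0 || ci[2] < 0
    signif_sugg <- ci_sugg[1] > 0 || ci_sugg[2] < 0
  }
  structure(list(contrast = c(label1, label2), theta_multilocus = est,
                 theta_per_locus = wc$theta, usable = wc$usable,
                 ci_low = ci[1], ci_high = ci[2], significant = signif,
                 suggestive = signif_sugg, alpha = alpha,
                 alpha_suggestive = alpha_suggestive,
                 n_usable_loci = sum(wc$usable),
                 bootstrap_reps = bootstrap_reps), class = "fst_estimate")
}

#' Pairwise F_ST between all breed pairs
#'
#' Weir-Cockerham multilocus theta for every pair of breeds, with a locus
#' bootstrap: resampling loci with replacement, the percentile interval at
#' level 1 - alpha (Bonferroni-style alpha, default 0.005 for six pairwise
#' tests) determines significance (interval excluding zero); a wider
#' interval at \code{alpha_suggestive} (default 0.01) flags suggestive
#' contrasts.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param sample_map data.frame with sample_id and breed.
#' @param bootstrap_reps locus bootstrap replicates (default 1000).
#' @param alpha significance level (CI level 1 - alpha).
#' @param alpha_suggestive suggestive significance level.
#' @param seed optional integer seed.
#' @return list with \code{table} (one row per pair: theta, CI,
#'   significance), \code{matrix} (symmetric theta matrix) and
#'   \code{estimates} (the full per-pair \code{fst_estimate} objects).
#' @export
fst_pairwise <- function(g, sample_map, bootstrap_reps = 1000, alpha = 0.005,
                         alpha_suggestive = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample_map <- sample_map[sample_map$sample_id %in% rownames(g), , drop = FALSE]
  breeds <- unique(sample_map$breed)
  if (length(breeds) < 2) stop("at least 2 breeds required")
  sz <- table(sample_map$breed)
  if (any(sz < 2)) stop("breed with fewer than 2 samples: ",
                        paste(names(sz)[sz < 2], collapse = ", "))
  pairs <- utils::combn(breeds, 2, simplify = FALSE)
  ests <- lapply(pairs, function(pr) {
    ids <- sample_map$sample_id[sample_map$breed %in% pr]
    pops <- sample_map$breed[match(ids, sample_map$sample_id)]
    .fst_contrast(g[ids, , drop = FALSE], pops, pr[1], pr[2],
                  bootstrap_reps, alpha, alpha_suggestive)
  })
  tab <- do.call(rbind, lapply(ests, function(e)
    data.frame(pop1 = e$contrast[1], pop2 = e$contrast[2],
               theta = e$theta_multilocus, ci_low = e$ci_low,
               ci_high = e$ci_high, significant = e$significant,
               suggestive = e$suggestive, n_usable_loci = e$n_usable_loci,
               stringsAsFactors = FALSE)))
  m <- matrix(0, length(breeds), length(breeds),
              dimnames = list(breeds, breeds))
  for (e in ests) {
    m[e$contrast[1], e$contrast[2]] <- e$theta_multilocus
    m[e$contrast[2], e$contrast[1]] <- e$theta_multilocus
  }
  list(table = tab, matrix = m, estimates = ests)
}

#' One-versus-rest F_ST for a target breed
#'
#' The remaining breeds are pooled into a single "rest" population and
#' Weir-Cockerham theta is estimated between the target breed and the pool,
#' keeping the per-locus theta vector for outlier thresholding.
#'
#' @inheritParams fst_pairwise
#' @param target breed label to contrast against the pooled remainder, or
#'   \code{"all"} to return one estimate per breed.
#' @return An \code{fst_estimate} (or a named list of them for
#'   \code{target = "all"}).
#' @export
fst_one_vs_rest <- function(g, sample_map, target, bootstrap_reps = 1000,
                            alpha = 0.005, alpha_suggestive = 0.01,
                            seed = NULL) {
  sample_map <- sample_map[sample_map$sample_id %in% rownames(g), , drop = FALSE]
  breeds <- unique(sample_map$breed)
  if (identical(target, "all")) {
    out <- lapply(breeds, function(b)
      fst_one_vs_rest(g, sample_map, b, bootstrap_reps, alpha,
                      alpha_suggestive, seed))
    names(out) <- breeds
    return(out)
  }
  if (!target %in% breeds) stop("unknown breed label: ", target)
  if (length(breeds) < 2) stop("no 'rest' population available")
  if (!is.null(seed)) set.seed(seed)
  ids <- sample_map$sample_id
  pops <- ifelse(sample_map$breed == target, target, "rest")
  .fst_contrast(g[ids, , drop = FALSE], pops, target, "rest",
                bootstrap_reps, alpha, alpha_suggestive)
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("F_ST (Weir-Cockerham) %s vs %s: theta = %.4f",
              x$contrast[1], x$contrast[2], x$theta_multilocus))
  if (!is.na(x$significant))
    cat(sprintf(" [%.4f, %.4f] %s", x$ci_low, x$ci_high,
                if (x$significant) "significant"
                else if (isTRUE(x$suggestive)) "suggestive" else "n.s."))
  cat("\n", x$n_usable_loci, " usable loci\n", sep = "")
  invisible(x)
}
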