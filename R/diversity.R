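#' Observed and expected heterozygosity
#'
#' \code{observed_heterozygosity} is the per-locus fraction of heterozygous
#' calls among non-missing calls. \code{expected_heterozygosity} is the
#' per-locus gene diversity 2p(1-p), optionally with Nei's (1978)
#' small-sample correction 2n/(2n-1) where n is the non-missing diploid
#' count at the locus. Both return the per-locus vector and its unweighted
#' mean over loci.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param samples optional sample subset (ids or indices).
#' @param unbiased apply the 2n/(2n-1) correction (default TRUE).
#' @return list with \code{per_locus} and \code{mean}.
#' @export
observed_heterozygosity <- function(g, samples = NULL) {
  i <- .resolve_samples(g, samples)
  if (length(i) == 0) stop("empty sample subset")
  m <- g[i, , drop = FALSE]
  n <- colSums(!is.na(m))
  if (any(n == 0)) stop("locus with no non-missing call in subset")
  ho <- colSums(m == 1L, na.rm = TRUE) / n
  list(per_locus = ho, mean = mean(ho))
}

#' @rdname observed_heterozygosity
#' @export
expected_heterozygosity <- function(g, samples = NULL, unbiased = TRUE) {
  i <- .resolve_samples(g, samples)
  if (length(i) == 0) stop("empty sample subset")
  m <- g[i, , drop = FALSE]
  n <- colSums(!is.na(m))
  if (any(n == 0)) stop("locus with no non-missing call in subset")
  p <- colSums(m, na.rm = TRUE) / (2 * n)
  he <- 2 * p * (1 - p)
  if (unbiased) he <- he * (2 * n) / (2 * n - 1)
  list(per_locus = he, mean = mean(he))
}

#' Wright's inbreeding coefficient with bootstrap confidence interval
#'
#' Multilocus F_IS = 1 - mean(Ho) / mean(He) (ratio of means over loci,
#' which avoids the instability of per-locus ratios at low-diversity loci).
#' The confidence interval resamples loci with replacement and applies the
#' bias-corrected (BC) percentile method; the estimate is flagged
#' significant when the interval excludes zero.
#'
#' @inheritParams observed_heterozygosity
#' @param bootstrap_reps number of locus-resampling replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed for the resampling.
#' @return list with \code{estimate}, \code{ci} (length-2), \code{significant},
#'   \code{bootstrap_reps}.
#' @export
fis <- function(g, samples = NULL, bootstrap_reps = 1000, conf = 0.95,
                unbiased = TRUE, seed = NULL) {
  i <- .resolve_samples(g, samples)
  if (length(i) < 2) stop("F_IS requires at least 2 samples")
  ho <- observed_heterozygosity(g, samples)$per_locus
  he <- expected_heterozygosity(g, samples, unbiased = unbiased)$per_locus
  if (mean(he) == 0) stop("mean expected heterozygosity is zero; F_IS undefined")
  est <- 1 - mean(ho) / mean(he)
  ci <- c(NA_real_, NA_real_); signif <- NA
  if (bootstrap_reps > 0) {
    if (length(ho) < 2) stop("bootstrap requires at least 2 loci")
    if (!is.null(seed)) set.seed(seed)
    L <- length(ho)
    boot <- vapply(seq_len(bootstrap_reps), function(r) {
      idx <- sample.int(L, L, replace = TRUE)
      1 - mean(ho[idx]) / mean(he[idx])
    }, numeric(1))
    ci <- .bc_percentile_ci(boot, est, conf)
    signif <- ci[1] > 0 || ci[2] < 0
  }
  list(estimate = est, ci = ci, significant = signif,
       bootstrap_reps = bootstrap_reps)
}

# bias-corrected (BC, no acceleration) percentile interval
.bc_percentile_ci <- function(boot, est, conf) {
  boot <- boot[is.finite(boot)]
  prop <- mean(boot < est)
  # guard the probit against degenerate bootstrap distributions
  prop <- min(max(prop, 1 / (2 * length(boot))), 1 - 1 / (2 * length(boot)))
  z0 <- stats::qnorm(prop)
  zq <- stats::qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2))
  probs <- stats::pnorm(2 * z0 + zq)
  unname(stats::quantile(boot, probs, type = 7))
}

#' Percentage of polymorphic loci in a sample subset
#'
#' 100 x (loci where both alleles are observed in the subset) / (loci with
#' at least one non-missing call in the subset).
#'
#' @inheritParams observed_heterozygosity
#' @return percentage in [0, 100].
#' @export
pct_polymorphic <- function(g, samples = NULL) {
  i <- .resolve_samples(g, samples)
  m <- g[i, , drop = FALSE]
  n <- colSums(!is.na(m))
  if (!any(n > 0)) stop("no loci with calls in subset")
  p <- colSums(m, na.rm = TRUE) / (2 * n)
  100 * sum(n > 0 & p > 0 & p < 1) / sum(n > 0)
}

#' Minor-allele-frequency class histogram
#'
#' Bins MAFs into the four conventional classes: rare [0, 0.05),
#' intermediate [0.05, 0.10), common [0.10, 0.30) and frequent [0.30, 0.50].
#' Intervals are half-open except the last, so every value in [0, 0.5] falls
#' in exactly one class and counts conserve the input size.
#'
#' @param mafs numeric vector of minor allele frequencies in [0, 0.5]
#'   (\code{NA} entries are dropped).
#' @return named integer vector (rare, intermediate, common, frequent).
#' @export
maf_class_histogram <- function(mafs) {
  mafs <- mafs[!is.na(mafs)]
  if (any(mafs < 0 | mafs > 0.5))
    stop("MAF values must lie in [0, 0.5]")
  out <- c(rare = sum(mafs < 0.05),
           intermediate = sum(mafs >= 0.05 & mafs < 0.10),
           common = sum(mafs >= 0.10 & mafs < 0.30),
           frequent = sum(mafs >= 0.30))
  stopifnot(sum(out) == length(mafs))
  out
}

#' Per-breed diversity summary table
#'
#' One row per breed plus a pooled "Total" row: sample size, mean expected
#' and observed heterozygosity, F_IS with its bias-corrected bootstrap
#' confidence interval, percent polymorphic loci, and the mean/SD and class
#' histogram of within-breed minor allele frequencies (computed over loci
#' polymorphic in the breed, mirroring a post-MAF-filter chip summary).
#'
#' @param g a \code{\link{genotype_matrix}} (typically post-QC).
#' @param sample_map data.frame with sample_id and breed.
#' @param bootstrap_reps bootstrap replicates for the F_IS interval.
#' @param conf confidence level for the F_IS interval.
#' @param seed integer seed for the bootstrap.
#' @return data.frame, one row per breed and one "Total" row.
#' @export
diversity_summary <- function(g, sample_map, bootstrap_reps = 1000,
                              conf = 0.95, seed = NULL) {
  sample_map <- sample_map[sample_map$sample_id %in% rownames(g), , drop = FALSE]
  breeds <- unique(sample_map$breed)
  groups <- c(stats::setNames(lapply(breeds, function(b)
    sample_map$sample_id[sample_map$breed == b]), breeds),
    list(Total = sample_map$sample_id))
  rows <- lapply(names(groups), function(nm) {
    ids <- groups[[nm]]
    ho <- observed_heterozygosity(g, ids)$mean
    he <- expected_heterozygosity(g, ids)$mean
    f <- if (nm == "Total") list(estimate = NA_real_, ci = c(NA, NA),
                                 significant = NA)
         else fis(g, ids, bootstrap_reps = bootstrap_reps, conf = conf,
                  seed = seed)
    maf <- compute_maf(g, samples = ids)
    maf_poly <- maf[maf > 0]
    cls <- maf_class_histogram(maf)
    data.frame(breed = nm, n = length(ids), H_E = he, H_O = ho,
               F_IS = f$estimate, F_IS_low = f$ci[1], F_IS_high = f$ci[2],
               F_IS_significant = f$significant,
               pct_polymorphic = pct_polymorphic(g, ids),
               maf_mean = mean(maf_poly), maf_sd = stats::sd(maf_poly),
               maf_rare = cls[["rare"]], maf_intermediate = cls[["intermediate"]],
               maf_common = cls[["common"]], maf_frequent = cls[["frequent"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
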