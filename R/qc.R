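#' Per-locus allele frequency and minor allele frequency
#'
#' \code{compute_b_freq} returns the B-allele frequency p per locus;
#' \code{compute_maf} folds it to min(p, 1 - p). Frequencies use non-missing
#' calls only. An all-missing locus yields \code{NA} with a warning.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param loci optional locus subset (names or indices).
#' @param samples optional sample subset (names or indices).
#' @return Named numeric vector, one entry per locus.
#' @export
compute_maf <- function(g, loci = NULL, samples = NULL) {
  p <- compute_b_freq(g, loci, samples)
  pmin(p, 1 - p)
}

#' @rdname compute_maf
#' @export
compute_b_freq <- function(g, loci = NULL, samples = NULL) {
  i <- .resolve_samples(g, samples)
  m <- if (is.null(loci)) g[i, , drop = FALSE] else g[i, loci, drop = FALSE]
  n <- colSums(!is.na(m))
  p <- colSums(m, na.rm = TRUE) / (2 * n)
  if (any(n == 0)) {
    warning(sum(n == 0), " locus/loci with no non-missing calls; NA returned")
    p[n == 0] <- NA_real_
  }
  p
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' One-degree-of-freedom goodness-of-fit test of the three genotype classes
#' against expectations from the observed allele frequency, without
#' continuity correction. Monomorphic input gives chi2 = 0, p = 1.
#' All arguments are vectorized over loci.
#'
#' @param n_aa,n_ab,n_bb counts of the three genotype classes (AA = zero
#'   copies of B).
#' @return data.frame with columns \code{chi2} and \code{p_value}.
#' @examples
#' hwe_chi2(25, 50, 25)  # exact HWE proportions: chi2 = 0
#' hwe_chi2(50, 0, 50)   # no heterozygotes: chi2 = 100
#' @export
hwe_chi2 <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (any(n < 1)) stop("at least one genotype call required per locus")
  p <- (2 * n_bb + n_ab) / (2 * n)
  q <- 1 - p
  exp_aa <- n * q^2; exp_ab <- n * 2 * p * q; exp_bb <- n * p^2
  chi2 <- rep(0, length(n))
  poly <- p > 0 & p < 1
  chi2[poly] <- (n_aa[poly] - exp_aa[poly])^2 / exp_aa[poly] +
    (n_ab[poly] - exp_ab[poly])^2 / exp_ab[poly] +
    (n_bb[poly] - exp_bb[poly])^2 / exp_bb[poly]
  data.frame(chi2 = chi2,
             p_value = ifelse(poly, stats::pchisq(chi2, 1, lower.tail = FALSE), 1))
}

#' QC configuration
#'
#' Thresholds of the five sequential marker filters. Defaults follow common
#' chip-QC practice for ~50K arrays: GenTrain >= 0.6, pooled MAF >= 0.05,
#' per-locus missingness <= 0.05, uniquely mapped probes only. HWE is
#' reported on the survivors, not filtered, unless \code{hwe_alpha} is set
#' to a numeric significance level.
#'
#' @param gentrain_min minimum Illumina GenTrain score (in [0,1]).
#' @param maf_min minimum pooled minor allele frequency.
#' @param missing_max maximum per-locus missing fraction.
#' @param hwe_alpha \code{"off"} (report only) or a numeric alpha for an
#'   additional HWE removal step.
#' @param require_unique_mapping drop probes with 0 or >1 genome hits.
#' @param sample_call_rate_min minimum per-sample call rate; samples below
#'   it are excluded before the marker filters.
#' @return A \code{qc_config} list.
#' @export
qc_config <- function(gentrain_min = 0.6, maf_min = 0.05, missing_max = 0.05,
                      hwe_alpha = "off", require_unique_mapping = TRUE,
                      sample_call_rate_min = 0.95) {
  num_ok <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  stopifnot(num_ok(gentrain_min), num_ok(maf_min), num_ok(missing_max),
            num_ok(sample_call_rate_min),
            identical(hwe_alpha, "off") || num_ok(hwe_alpha))
  structure(list(gentrain_min = gentrain_min, maf_min = maf_min,
                 missing_max = missing_max, hwe_alpha = hwe_alpha,
                 require_unique_mapping = require_unique_mapping,
                 sample_call_rate_min = sample_call_rate_min),
            class = "qc_config")
}

#' Apply sequential marker quality control
#'
#' Filters are applied in a fixed order -- GenTrain score, pooled MAF,
#' per-locus missingness, unmapped probes (0 hits), multi-hit probes (>1
#' hit) -- and each step's removal count refers to loci that survived all
#' previous steps, so the counts sum exactly:
#' initial = surviving + sum(removed). A Hardy-Weinberg chi-square test is
#' then run on the pooled sample across the survivors and the number of
#' failures reported (removal only if \code{hwe_alpha} is numeric).
#'
#' Samples whose call rate falls below \code{sample_call_rate_min} are
#' excluded first and listed in the report.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param snps data.frame of locus metadata with columns \code{locus_id} and,
#'   as needed by the enabled filters, \code{gentrain_score} and
#'   \code{mapping_hits}.
#' @param config a \code{\link{qc_config}}.
#' @return list with \code{genotypes} (filtered matrix) and \code{report}
#'   (a \code{qc_report}).
#' @export
apply_qc <- function(g, snps, config = qc_config()) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!all(colnames(g) %in% snps$locus_id))
    stop("SNP metadata does not cover all loci in the genotype matrix")
  snps <- snps[match(colnames(g), snps$locus_id), , drop = FALSE]

  call_rate <- rowMeans(!is.na(g))
  excluded_samples <- rownames(g)[call_rate < config$sample_call_rate_min]
  if (length(excluded_samples))
    g <- g[setdiff(rownames(g), excluded_samples), , drop = FALSE]

  initial <- ncol(g)
  alive <- rep(TRUE, initial)
  steps <- character(0); removed <- integer(0)
  drop_step <- function(name, bad) {
    bad <- bad & alive
    steps <<- c(steps, name); removed <<- c(removed, sum(bad))
    alive <<- alive & !bad
  }

  if (config$gentrain_min > 0) {
    if (is.null(snps$gentrain_score))
      stop("GenTrain filter enabled but 'gentrain_score' missing from metadata")
    drop_step("gentrain", !is.na(snps$gentrain_score) &
                snps$gentrain_score < config$gentrain_min)
  }
  maf <- suppressWarnings(compute_maf(g))
  drop_step("maf", is.na(maf) | maf < config$maf_min)
  drop_step("missingness", colMeans(is.na(g)) > config$missing_max)
  if (isTRUE(config$require_unique_mapping)) {
    if (is.null(snps$mapping_hits))
      stop("mapping filter enabled but 'mapping_hits' missing from metadata")
    drop_step("unmapped", !is.na(snps$mapping_hits) & snps$mapping_hits == 0L)
    drop_step("multi_hit", !is.na(snps$mapping_hits) & snps$mapping_hits > 1L)
  }

  surv <- g[, alive, drop = FALSE]
  cnt <- genotype_counts(surv)
  hwe <- hwe_chi2(cnt[, "n_aa"], cnt[, "n_ab"], cnt[, "n_bb"])
  hwe_test_alpha <- if (identical(config$hwe_alpha, "off")) 0.05 else config$hwe_alpha
  hwe_fail <- hwe$p_value < hwe_test_alpha
  if (!identical(config$hwe_alpha, "off")) {
    steps <- c(steps, "hwe"); removed <- c(removed, sum(hwe_fail))
    surv <- surv[, !hwe_fail, drop = FALSE]
  }

  report <- structure(list(
    initial = initial,
    steps = data.frame(step = steps, removed = removed,
                       stringsAsFactors = FALSE),
    surviving = colnames(surv),
    n_surviving = ncol(surv),
    hwe_fail = sum(hwe_fail),
    hwe_alpha = hwe_test_alpha,
    hwe_filtered = !identical(config$hwe_alpha, "off"),
    excluded_samples = excluded_samples,
    config = config), class = "qc_report")
  stopifnot(report$initial - sum(report$steps$removed) == report$n_surviving)
  list(genotypes = surv, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control\n")
  if (length(x$excluded_samples))
    cat("  samples excluded (call rate):",
        paste(x$excluded_samples, collapse = ", "), "\n")
  cat("  initial loci:", x$initial, "\n")
  for (i in seq_len(nrow(x$steps)))
    cat(sprintf("  removed by %-11s %6d\n", paste0(x$steps$step[i], ":"),
                x$steps$removed[i]))
  cat("  surviving:", x$n_surviving, "\n")
  cat(sprintf("  HWE failures at alpha %.3g: %d (%s)\n", x$hwe_alpha,
              x$hwe_fail, if (x$hwe_filtered) "removed" else "reported only"))
  invisible(x)
}

#' Genotype class counts per locus
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param samples optional sample subset.
#' @return matrix with columns n_aa, n_ab, n_bb (rows = loci).
#' @export
genotype_counts <- function(g, samples = NULL) {
  i <- .resolve_samples(g, samples)
  m <- g[i, , drop = FALSE]
  cbind(n_aa = colSums(m == 0L, na.rm = TRUE),
        n_ab = colSums(m == 1L, na.rm = TRUE),
        n_bb = colSums(m == 2L, na.rm = TRUE))
}

#' Survivor bookkeeping for a sequential filter cascade
#'
#' Conservation arithmetic of a sequential QC: starting from
#' \code{initial} markers and the per-step removal counts (each counted
#' among the survivors of the previous steps), the surviving number is
#' \code{initial - sum(removed)}.
#'
#' @param initial initial marker count.
#' @param removed integer vector of per-step removals.
#' @return integer survivor count.
#' @examples
#' qc_survivors(53347, c(1441, 2273, 150, 41, 937))  # 48505
#' @export
qc_survivors <- function(initial, removed) {
  stopifnot(initial >= 0, all(removed >= 0), sum(removed) <= initial)
  as.integer(initial - sum(removed))
}
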