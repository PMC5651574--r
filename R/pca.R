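#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are mean-imputed per locus, columns are centered, and the
#' decomposition runs through \code{stats::prcomp} (SVD). Variance scaling is
#' off by default, matching standard genotype-PCA practice; monomorphic loci
#' are then harmless (zero loading). For reproducibility each loading column
#' is oriented so that its largest-magnitude entry is positive (scores are
#' flipped consistently).
#'
#' @param g a \code{\link{genotype_matrix}} (post-QC; no all-missing loci).
#' @param scale divide each locus by its standard deviation (default FALSE;
#'   requires no zero-variance loci).
#' @return An object of class \code{snp_pca}: \code{scores} (individuals x
#'   components), \code{loadings} (loci x components, orthonormal columns),
#'   \code{sdev} (component standard deviations), \code{var_fraction}.
#' @export
run_pca <- function(g, scale = FALSE) {
  if (nrow(g) < 2 || ncol(g) < 2) stop("need at least 2 samples and 2 loci")
  x <- unclass(g) + 0
  nmiss <- colSums(is.na(x))
  if (any(nmiss == nrow(x))) stop("all-missing locus; run QC first")
  if (any(nmiss > 0)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  if (scale && any(apply(x, 2, stats::sd) == 0))
    stop("zero-variance locus with scale = TRUE")
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  # deterministic sign: largest-|loading| entry of each column positive
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    v <- pc$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  structure(list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
                 var_fraction = pc$sdev^2 / sum(pc$sdev^2),
                 scaled = scale, locus_ids = colnames(g),
                 sample_ids = rownames(g)), class = "snp_pca")
}

#' @export
print.snp_pca <- function(x, ...) {
  cat(sprintf("snp_pca: %d samples x %d loci; PC1 %.2f%%, PC2 %.2f%% of variance\n",
              length(x$sample_ids), length(x$locus_ids),
              100 * x$var_fraction[1], 100 * x$var_fraction[2]))
  invisible(x)
}

#' Per-SNP contribution to a principal component
#'
#' Follows the variable-correlation chain: r_j = loading_j * sd(component),
#' cos2_j = r_j^2, and contribution_j = 100 * cos2_j / sum_j cos2_j. With
#' unscaled PCA and unit-norm loading columns this is algebraically
#' identical to 100 * loading_j^2 (asserted internally), so the percentages
#' always sum to 100 per component.
#'
#' @param pca an \code{snp_pca}.
#' @param component component index (default 1).
#' @return data.frame: locus_id, loading, correlation, cos2,
#'   contribution_pct.
#' @export
snp_contributions <- function(pca, component = 1) {
  stopifnot(inherits(pca, "snp_pca"),
            component >= 1, component <= length(pca$sdev))
  v <- pca$loadings[, component]
  sdev <- pca$sdev[component]
  if (sdev == 0) {
    warning("component has zero variance; contributions set to 0")
    contrib <- rep(0, length(v))
  } else {
    r <- v * sdev
    cos2 <- r^2
    contrib <- 100 * cos2 / sum(cos2)
    stopifnot(max(abs(contrib - 100 * v^2 / sum(v^2))) < 1e-9)
  }
  data.frame(locus_id = pca$locus_ids, loading = v, correlation = v * sdev,
             cos2 = (v * sdev)^2, contribution_pct = contrib,
             stringsAsFactors = FALSE)
}

#' Expected per-SNP contribution under uniformity
#'
#' With M loci each contributing equally, every SNP carries 100 / M percent
#' of a component.
#'
#' @param n_loci number of loci M.
#' @return percentage.
#' @examples
#' signif(expected_contribution_pct(48505), 2)  # 0.0021
#' @export
expected_contribution_pct <- function(n_loci) {
  stopifnot(n_loci >= 1)
  100 / n_loci
}

#' Select SNPs exceeding a multiple of the expected contribution
#'
#' Selection threshold = factor x (100 / M) percent; SNPs whose
#' contribution is greater than or equal to the threshold are selected
#' (inclusive comparison).
#'
#' @param contribs output of \code{\link{snp_contributions}}.
#' @param factor multiple of the expected contribution (default 10).
#' @return list: \code{threshold_pct}, \code{expected_pct}, \code{factor},
#'   \code{selected} (data.frame of selected rows, contribution-sorted).
#' @export
select_high_contribution <- function(contribs, factor = 10) {
  m <- nrow(contribs)
  expected <- expected_contribution_pct(m)
  threshold <- factor * expected
  sel <- contribs[contribs$contribution_pct >= threshold, , drop = FALSE]
  sel <- sel[order(-sel$contribution_pct), , drop = FALSE]
  rownames(sel) <- NULL
  list(threshold_pct = threshold, expected_pct = expected, factor = factor,
       n_loci = m, selected = sel)
}

#' Per-individual contribution to components
#'
#' Contribution of individual i to component k = 100 * score_ik^2 /
#' sum_i score_ik^2; each component's column sums to 100.
#'
#' @param pca an \code{snp_pca}.
#' @param components component indices (default first 10 or all).
#' @return matrix individuals x components of percentages.
#' @export
individual_contributions <- function(pca,
                                     components = seq_len(min(10, length(pca$sdev)))) {
  s <- pca$scores[, components, drop = FALSE]
  out <- sweep(s^2, 2, colSums(s^2), `/`) * 100
  rownames(out) <- pca$sample_ids
  out
}

#' Validate selected SNPs against one-vs-rest F_ST outlier thresholds
#'
#' For each breed contrast the genome-wide per-locus theta mean and SD
#' define a threshold mean + k*SD (default k = 2); the validation counts
#' how many of the selected SNPs (and of all usable loci) lie strictly
#' above it. Loci with undefined theta are excluded from the mean/SD and
#' the counts.
#'
#' @param selected output of \code{\link{select_high_contribution}}, or a
#'   character vector of selected locus ids.
#' @param one_vs_rest named list of \code{fst_estimate} objects (one per
#'   breed, from \code{\link{fst_one_vs_rest}(target = "all")}).
#' @param k SD multiplier (default 2).
#' @return data.frame per contrast: breed, theta_mean, theta_sd, threshold,
#'   n_selected, n_selected_above, n_genomewide_above.
#' @export
validate_selected_by_fst <- function(selected, one_vs_rest, k = 2) {
  ids <- if (is.character(selected)) selected else selected$selected$locus_id
  rows <- lapply(names(one_vs_rest), function(b) {
    est <- one_vs_rest[[b]]
    th <- est$theta_per_locus
    miss <- setdiff(ids, names(th))
    if (length(miss))
      stop("selected loci absent from the F_ST locus set: ",
           paste(utils::head(miss, 5), collapse = ", "))
    ok <- !is.na(th)
    mu <- mean(th[ok]); sdv <- stats::sd(th[ok])
    cut <- mu + k * sdv
    sel_th <- th[ids]
    data.frame(breed = b, theta_mean = mu, theta_sd = sdv, threshold = cut,
               n_selected = length(ids),
               n_selected_above = sum(sel_th > cut, na.rm = TRUE),
               n_genomewide_above = sum(th[ok] > cut),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
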