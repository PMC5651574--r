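#' Two-level analysis of molecular variance (AMOVA)
#'
#' Decomposes squared inter-individual genetic distances into among- and
#' within-population variance components following Excoffier, Smouse &
#' Quattro (1992): SS_total = sum_{i<j} d_ij^2 / N, SS_within is the
#' analogous sum within each group divided by the group size, and the
#' expected mean squares give sigma2_within = MS_within and sigma2_among =
#' (MS_among - MS_within) / n0 with n0 = (N - sum(n_g^2)/N) / (G - 1).
#' Phi_ST = sigma2_among / (sigma2_among + sigma2_within). Significance is
#' assessed by permuting individuals among groups of fixed sizes; the
#' p-value is (1 + #\{Phi* >= Phi\}) / (1 + permutations).
#'
#' @param dm symmetric matrix of inter-individual distances (e.g. from
#'   \code{\link{nei_distance_matrix}}).
#' @param sample_map data.frame with sample_id and breed covering the
#'   matrix labels.
#' @param permutations number of label permutations (default 10000); 0
#'   skips the test and reports \code{p_value = NA}.
#' @param seed optional integer seed for the permutations.
#' @return An \code{amova_result} list: sums of squares, degrees of
#'   freedom, variance components, percentages (summing to 100), phi_st,
#'   permutations and p_value.
#' @references Excoffier L, Smouse PE, Quattro JM (1992) Analysis of
#'   molecular variance inferred from metric distances among DNA
#'   haplotypes. Genetics 131:479-491.
#' @export
amova <- function(dm, sample_map, permutations = 10000, seed = NULL) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  labs <- rownames(dm)
  sample_map <- sample_map[match(labs, sample_map$sample_id), , drop = FALSE]
  if (anyNA(sample_map$breed)) stop("sample map does not cover all labels")
  groups <- factor(sample_map$breed)
  sizes <- table(groups)
  if (nlevels(groups) < 2) stop("at least 2 groups required")
  if (any(sizes < 2)) stop("group of size 1: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  d2 <- dm^2
  N <- nrow(dm); G <- nlevels(groups)
  ind <- stats::model.matrix(~ groups - 1)      # N x G membership indicator

  decompose <- function(ind) {
    ngs <- colSums(ind)
    ss_within_g <- diag(t(ind) %*% d2 %*% ind) / (2 * ngs)
    ss_within <- sum(ss_within_g)
    ss_total <- sum(d2[upper.tri(d2)]) / N
    ss_among <- ss_total - ss_within
    df_among <- G - 1; df_within <- N - G
    ms_among <- ss_among / df_among
    ms_within <- ss_within / df_within
    n0 <- (N - sum(ngs^2) / N) / (G - 1)
    sigma2_within <- ms_within
    sigma2_among <- (ms_among - ms_within) / n0
    phi <- sigma2_among / (sigma2_among + sigma2_within)
    list(ss_among = ss_among, ss_within = ss_within, df_among = df_among,
         df_within = df_within, sigma2_among = sigma2_among,
         sigma2_within = sigma2_within, phi = phi)
  }

  obs <- decompose(ind)
  p_value <- NA_real_
  if (permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    ge <- vapply(seq_len(permutations), function(i) {
      decompose(ind[sample.int(N), , drop = FALSE])$phi >= obs$phi
    }, logical(1))
    p_value <- (1 + sum(ge)) / (1 + permutations)
  }
  tot <- obs$sigma2_among + obs$sigma2_within
  structure(list(
    ss_among = obs$ss_among, ss_within = obs$ss_within,
    df_among = obs$df_among, df_within = obs$df_within,
    sigma2_among = obs$sigma2_among, sigma2_within = obs$sigma2_within,
    pct_among = 100 * obs$sigma2_among / tot,
    pct_within = 100 * obs$sigma2_within / tot,
    phi_st = obs$phi, permutations = permutations, p_value = p_value),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (two-level)\n")
  cat(sprintf("  among populations:  SS = %.4f  df = %d  sigma2 = %.6f (%.2f%%)\n",
              x$ss_among, x$df_among, x$sigma2_among, x$pct_among))
  cat(sprintf("  within populations: SS = %.4f  df = %d  sigma2 = %.6f (%.2f%%)\n",
              x$ss_within, x$df_within, x$sigma2_within, x$pct_within))
  cat(sprintf("  Phi_ST = %.4f", x$phi_st))
  if (!is.na(x$p_value))
    cat(sprintf("  (p = %.3g, %d permutations)", x$p_value, x$permutations))
  cat("\n")
  invisible(x)
}
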