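#' Nei's (1972) standard genetic distance
#'
#' D = -ln( J_XY / sqrt(J_X * J_Y) ) where J_XY is the mean over loci of the
#' probability of allele identity between the two units and J_X, J_Y the
#' within-unit identities. A unit is either an individual (allele
#' frequencies 0, 0.5, 1 from its dosage) or a population frequency
#' profile. \code{nei_distance} is the scalar two-unit form;
#' \code{nei_distance_matrix} computes all pairwise individual distances
#' from a genotype matrix using, for each pair, only the loci called in
#' both individuals.
#'
#' Opposite fixation at every shared locus gives J_XY = 0; the distance is
#' then +Inf, which \code{nei_distance_matrix} can replace with a finite
#' sentinel for clustering (see \code{inf_replace}).
#'
#' @param x,y B-allele frequency vectors of the two units over shared loci.
#' @return Non-negative distance (possibly +Inf).
#' @references Nei M (1972) Genetic distance between populations.
#'   Am Nat 106:283-292.
#' @export
nei_distance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  jx <- mean(x^2 + (1 - x)^2)
  jy <- mean(y^2 + (1 - y)^2)
  jxy <- mean(x * y + (1 - x) * (1 - y))
  if (jx == 0 || jy == 0) stop("zero within-unit identity")
  if (jxy == 0) return(Inf)
  max(0, -log(jxy / sqrt(jx * jy)))
}

#' @rdname nei_distance
#' @param g a \code{\link{genotype_matrix}}.
#' @param inf_replace value substituted for infinite distances (default
#'   \code{NULL} keeps +Inf; pass e.g. a large finite sentinel before
#'   clustering).
#' @export
nei_distance_matrix <- function(g, inf_replace = NULL) {
  M <- (!is.na(g)) + 0
  X <- g / 2; X[is.na(X)] <- 0
  Y <- (1 - g / 2); Y[is.na(Y)] <- 0
  C <- M %*% t(M)                               # pairwise-complete locus counts
  if (any(C == 0)) stop("sample pair with no shared called loci")
  Sxy <- X %*% t(X) + Y %*% t(Y)                # sum over loci of identity
  A <- X^2 + Y^2                                # per-entry within identity
  Jx <- (A %*% t(M)) / C
  Jy <- t(Jx)
  Jxy <- Sxy / C
  D <- -log(Jxy / sqrt(Jx * Jy))
  D[Jxy == 0] <- Inf
  D[D < 0 & is.finite(D)] <- 0                  # numerical noise near identity
  diag(D) <- 0
  D <- (D + t(D)) / 2
  if (!is.null(inf_replace)) D[is.infinite(D)] <- inf_replace
  dimnames(D) <- list(rownames(g), rownames(g))
  D
}

#' Reynolds (1983) coancestry distance between two populations
#'
#' Weighted least-squares coancestry estimator for two populations with
#' sample sizes n1, n2 (diploid individuals): per locus with B-allele
#' frequencies p1, p2 and within-population heterozygosities
#' s_i = 2 p_i (1 - p_i),
#' \deqn{num = (p1-p2)^2 - (n1+n2)(n1 s1 + n2 s2) / (4 n1 n2 (n1+n2-1))}
#' \deqn{den = (p1-p2)^2 + (4 n1 n2 - n1 - n2)(n1 s1 + n2 s2) /
#'   (4 n1 n2 (n1+n2-1))}
#' and the distance is the ratio of the locus sums, floored at zero
#' (sampling noise can make the numerator negative). Identical profiles give
#' 0; a fixed difference gives exactly 1.
#'
#' @param p1,p2 B-allele frequency vectors over shared loci.
#' @param n1,n2 diploid sample sizes (scalars or per-locus vectors).
#' @return distance in [0, 1].
#' @references Reynolds J, Weir BS, Cockerham CC (1983) Estimation of the
#'   coancestry coefficient. Genetics 105:767-779.
#' @export
reynolds_distance <- function(p1, p2, n1, n2) {
  stopifnot(length(p1) == length(p2), all(n1 >= 1), all(n2 >= 1))
  s1 <- 2 * p1 * (1 - p1)
  s2 <- 2 * p2 * (1 - p2)
  corr <- (n1 * s1 + n2 * s2) / (4 * n1 * n2 * (n1 + n2 - 1))
  d2 <- (p1 - p2)^2
  num <- d2 - (n1 + n2) * corr
  den <- d2 + (4 * n1 * n2 - n1 - n2) * corr
  if (sum(den) == 0) stop("all loci monomorphic in both populations")
  max(0, sum(num) / sum(den))
}

#' Per-locus-normalized Manhattan distance between dosage vectors
#'
#' Mean absolute dosage difference over pairwise-complete loci, so that
#' missingness patterns do not scale the distance. Range [0, 2].
#'
#' @param g1,g2 dosage vectors (0/1/2 with NA).
#' @return non-negative distance.
#' @export
manhattan_distance <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) stop("no pairwise-complete loci")
  mean(abs(g1[ok] - g2[ok]))
}

#' @rdname manhattan_distance
#' @param g a \code{\link{genotype_matrix}}.
#' @export
manhattan_distance_matrix <- function(g) {
  M <- (!is.na(g)) + 0
  I0 <- (g == 0L) + 0; I0[is.na(g)] <- 0
  I1 <- (g == 1L) + 0; I1[is.na(g)] <- 0
  I2 <- (g == 2L) + 0; I2[is.na(g)] <- 0
  C <- M %*% t(M)
  if (any(C == 0)) stop("sample pair with no shared called loci")
  S <- I0 %*% t(I1) + I1 %*% t(I0) + I1 %*% t(I2) + I2 %*% t(I1) +
    2 * (I0 %*% t(I2) + I2 %*% t(I0))
  D <- S / C
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(rownames(g), rownames(g))
  D
}

#' Identity-by-state kinship matrix
#'
#' K_ij = 1 - sum(|g_i - g_j|) / (2 L_ij) over the L_ij pairwise-complete
#' loci: the average allele-sharing between two individuals. The diagonal is
#' exactly 1; two individuals homozygous for opposite alleles everywhere
#' score 0. For unrelated outbred individuals typed at common SNPs the
#' expected value sits well above 0.5.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @return symmetric matrix in [0, 1] with unit diagonal.
#' @export
ibs_kinship <- function(g) {
  K <- 1 - manhattan_distance_matrix(g) / 2
  dimnames(K) <- list(rownames(g), rownames(g))
  K
}

#' Agglomerative clustering of a distance matrix
#'
#' Thin wrapper over \code{stats::hclust} (default complete linkage) with an
#' explicit check for non-finite distances, which reports the offending
#' pairs instead of failing downstream.
#'
#' @param dm symmetric distance matrix with zero diagonal.
#' @param linkage linkage method passed to \code{hclust}.
#' @return an \code{hclust} tree.
#' @export
hierarchical_cluster <- function(dm, linkage = "complete") {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  bad <- which(!is.finite(dm) & upper.tri(dm), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    labs <- rownames(dm)
    stop("non-finite distances for pairs: ",
         paste(utils::head(paste(labs[bad[, 1]], labs[bad[, 2]], sep = "-"), 5),
               collapse = ", "))
  }
  stats::hclust(stats::as.dist(dm), method = linkage)
}

#' Convert an hclust tree to a Newick string
#'
#' Uses \code{\link[ape]{as.phylo}} so merge heights become branch lengths;
#' the returned string is semicolon-terminated.
#'
#' @param tree an \code{hclust} object.
#' @return Newick string.
#' @export
tree_to_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree))
}
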