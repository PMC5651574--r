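#' Simulation configuration for structured genotype data
#'
#' Parameters of a Balding-Nichols simulation: each locus draws an ancestral
#' B-allele frequency from the folded spectrum given by
#' \code{ancestral_maf}, and population k draws its frequency from
#' Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k), which has mean p and variance
#' F_k p(1-p) so that the per-population drift targets F_ST ~ F_k.
#' Genotypes are Binomial(2, p_k). A chosen set of outlier loci gets the
#' target population's frequency shifted by \code{outlier_delta} (clipped
#' to [0.01, 0.99]), planting loci with elevated one-vs-rest
#' differentiation. Missing calls are dropped uniformly at random.
#'
#' @param n_pops number of populations.
#' @param n_per_pop integer vector (recycled) of diploid sample sizes.
#' @param n_loci number of biallelic loci.
#' @param fst_per_pop per-population drift parameter F in (0, 1); recycled.
#' @param ancestral_maf either a length-2 range for a uniform MAF spectrum,
#'   or a function(n) returning n ancestral MAFs in (0, 0.5].
#' @param n_outlier_loci number of planted outlier loci.
#' @param outlier_pop index or label of the population carrying the shift.
#' @param outlier_delta absolute frequency shift at outlier loci.
#' @param missing_rate genotype missingness rate in [0, 1).
#' @param pop_labels population labels (default P1..Pk).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_pops = 4, n_per_pop = 24, n_loci = 10000,
                       fst_per_pop = 0.02, ancestral_maf = c(0.05, 0.5),
                       n_outlier_loci = 0, outlier_pop = 1,
                       outlier_delta = 0.35, missing_rate = 0,
                       pop_labels = paste0("P", seq_len(n_pops))) {
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pops)
  fst_per_pop <- rep_len(fst_per_pop, n_pops)
  stopifnot(n_pops >= 1, all(n_per_pop >= 1), n_loci >= 1,
            all(fst_per_pop > 0 & fst_per_pop < 1),
            n_outlier_loci >= 0, n_outlier_loci <= n_loci,
            outlier_delta >= 0, missing_rate >= 0, missing_rate < 1,
            length(pop_labels) == n_pops)
  if (is.numeric(ancestral_maf))
    stopifnot(length(ancestral_maf) == 2, ancestral_maf[1] > 0,
              ancestral_maf[2] <= 0.5, ancestral_maf[1] <= ancestral_maf[2])
  else stopifnot(is.function(ancestral_maf))
  if (is.character(outlier_pop)) outlier_pop <- match(outlier_pop, pop_labels)
  stopifnot(!is.na(outlier_pop), outlier_pop >= 1, outlier_pop <= n_pops)
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
                 fst_per_pop = fst_per_pop, ancestral_maf = ancestral_maf,
                 n_outlier_loci = n_outlier_loci, outlier_pop = outlier_pop,
                 outlier_delta = outlier_delta, missing_rate = missing_rate,
                 pop_labels = pop_labels), class = "sim_config")
}

# CHIR-style autosome count used for synthetic positions
.n_autosomes <- 29

#' Simulate a structured genotype dataset with known truth
#'
#' Draws a Balding-Nichols dataset under \code{config} (see
#' \code{\link{sim_config}}), returning the genotype matrix, SNP metadata
#' with synthetic positions on 29 autosomes (plus GenTrain-like scores and
#' mapping-hit counts so the QC stage is exercisable), the sample-to-breed
#' map, a synthetic gene annotation placing genes at known offsets from the
#' outlier loci (plus background genes), and the simulation truth
#' (ancestral and per-population frequencies, outlier locus ids).
#' Deterministic for a fixed \code{seed}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @return list: genotypes, snps, sample_map, genes, truth.
#' @export
simulate_genotypes <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  L <- config$n_loci; K <- config$n_pops
  maf <- if (is.function(config$ancestral_maf)) config$ancestral_maf(L)
         else stats::runif(L, config$ancestral_maf[1], config$ancestral_maf[2])
  stopifnot(all(maf > 0 & maf <= 0.5))
  # B allele is not systematically the minor one
  p_anc <- ifelse(stats::runif(L) < 0.5, maf, 1 - maf)

  p_pop <- matrix(NA_real_, K, L)
  for (k in seq_len(K)) {
    f <- config$fst_per_pop[k]
    p_pop[k, ] <- stats::rbeta(L, p_anc * (1 - f) / f,
                               (1 - p_anc) * (1 - f) / f)
  }
  # numerical guard: Beta draws can underflow to exactly 0/1 at extreme shapes
  p_pop <- pmin(pmax(p_pop, 0), 1)

  outliers <- integer(0)
  if (config$n_outlier_loci > 0) {
    outliers <- sort(sample.int(L, config$n_outlier_loci))
    k <- config$outlier_pop
    p0 <- p_pop[k, outliers]
    up <- p0 + config$outlier_delta <= 0.99
    shifted <- ifelse(up, p0 + config$outlier_delta,
                      p0 - config$outlier_delta)
    shifted <- pmin(pmax(shifted, 0.01), 0.99)
    if (all(abs(shifted - p0) < .Machine$double.eps))
      stop("outlier_delta produces no frequency shift at any locus")
    p_pop[k, outliers] <- shifted
  }

  N <- sum(config$n_per_pop)
  pop_of <- rep(seq_len(K), config$n_per_pop)
  dos <- matrix(stats::rbinom(N * L, 2, p_pop[pop_of, ]), N, L)
  if (config$missing_rate > 0)
    dos[stats::runif(N * L) < config$missing_rate] <- NA_integer_

  sample_ids <- unlist(lapply(seq_len(K), function(k)
    sprintf("%s_%02d", config$pop_labels[k], seq_len(config$n_per_pop[k]))))
  locus_ids <- sprintf("snp%05d", seq_len(L))
  g <- genotype_matrix(dos, sample_ids, locus_ids)

  chrom <- sort(sample.int(.n_autosomes, L, replace = TRUE))
  pos <- integer(L)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(1.2e8, length(idx)))
  }
  snps <- data.frame(locus_id = locus_ids, chromosome = as.character(chrom),
                     position_bp = pos,
                     allele_a = "A", allele_b = "B",
                     gentrain_score = round(0.4 + 0.6 * stats::rbeta(L, 3.3, 1), 4),
                     mapping_hits = sample(c(0L, 1L, 2L), L, replace = TRUE,
                                           prob = c(0.001, 0.979, 0.02)),
                     stringsAsFactors = FALSE)

  sample_map <- data.frame(sample_id = sample_ids,
                           breed = config$pop_labels[pop_of],
                           site = NA_character_, stringsAsFactors = FALSE)

  genes <- .synthetic_genes(snps, outliers, seed = seed)
  truth <- list(p_anc = p_anc, p_pop = p_pop,
                outlier_loci = locus_ids[outliers],
                pop_labels = config$pop_labels,
                outlier_pop = config$pop_labels[config$outlier_pop],
                config = config, seed = seed)
  list(genotypes = g, snps = snps, sample_map = sample_map, genes = genes,
       truth = truth)
}

# gene annotation fixture: one gene ~100 kb from each outlier locus (inside a
# 250 kb half-window) and one decoy ~400 kb away, plus random background genes
.synthetic_genes <- function(snps, outlier_idx, seed, n_background = 200) {
  near <- if (length(outlier_idx)) data.frame(
    gene_id = sprintf("NEAR_%s", snps$locus_id[outlier_idx]),
    chromosome = snps$chromosome[outlier_idx],
    start_bp = pmax(1L, snps$position_bp[outlier_idx] + 100000L),
    end_bp = snps$position_bp[outlier_idx] + 120000L,
    stringsAsFactors = FALSE) else NULL
  far <- if (length(outlier_idx)) data.frame(
    gene_id = sprintf("FAR_%s", snps$locus_id[outlier_idx]),
    chromosome = snps$chromosome[outlier_idx],
    start_bp = snps$position_bp[outlier_idx] + 400000L,
    end_bp = snps$position_bp[outlier_idx] + 420000L,
    stringsAsFactors = FALSE) else NULL
  bg_chrom <- as.character(sample.int(.n_autosomes, n_background, replace = TRUE))
  bg_start <- sample.int(1.2e8, n_background)
  bg <- data.frame(gene_id = sprintf("BG_%04d", seq_len(n_background)),
                   chromosome = bg_chrom, start_bp = bg_start,
                   end_bp = bg_start + sample(5000:200000, n_background,
                                              replace = TRUE),
                   stringsAsFactors = FALSE)
  out <- rbind(near, far, bg)
  rownames(out) <- NULL
  out
}

#' Study-shaped simulation preset
#'
#' A configuration emulating a four-breed, 50K-chip study design: breeds
#' NU (n = 23, matching one excluded sample), D, T, NI (n = 24 each);
#' 48,505 post-QC-scale loci; per-population drift F = (NU 0.005, D 0.006,
#' T 0.029, NI 0.009), the least-squares fit to pairwise F_ST magnitudes of
#' 0.005-0.023 with one strongly drifted population; an ancestral MAF
#' spectrum 0.05 + 0.45 Beta(2.22, 1.78) with mean MAF 0.30 and ancestral
#' heterozygosity 0.40; 49 outlier loci planted in the drifted T population
#' at delta = 0.35; 2\% missing calls.
#'
#' @param n_loci number of loci (default 48505; reduce for quick runs).
#' @return A \code{\link{sim_config}}.
#' @export
paper_shaped_preset <- function(n_loci = 48505) {
  sim_config(n_pops = 4, n_per_pop = c(23L, 24L, 24L, 24L), n_loci = n_loci,
             fst_per_pop = c(0.005, 0.006, 0.029, 0.009),
             ancestral_maf = function(n) 0.05 + 0.45 * stats::rbeta(n, 2.22, 1.78),
             n_outlier_loci = 49, outlier_pop = "T", outlier_delta = 0.35,
             missing_rate = 0.02, pop_labels = c("NU", "D", "T", "NI"))
}

#' Expected pairwise F_ST targets of a configuration
#'
#' Under independent Balding-Nichols drift from a common ancestor the
#' expected Weir-Cockerham theta between populations k and l is
#' approximately (F_k + F_l) / 2 for small F.
#'
#' @param config a \code{\link{sim_config}}.
#' @return symmetric matrix of expected pairwise F_ST.
#' @export
expected_pairwise_fst <- function(config) {
  f <- config$fst_per_pop
  m <- outer(f, f, function(a, b) (a + b) / 2)
  diag(m) <- 0
  dimnames(m) <- list(config$pop_labels, config$pop_labels)
  m
}
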