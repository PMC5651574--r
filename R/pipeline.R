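#' Run the full analysis pipeline
#'
#' Orchestrates the stages in dependency order: sample/marker QC ->
#' per-breed diversity -> pairwise and one-vs-rest Weir-Cockerham F_ST ->
#' inter-individual distances, hierarchical clustering with Newick export,
#' AMOVA and IBS kinship -> PCA, per-SNP contributions, high-contribution
#' selection and mean + k SD F_ST validation -> gene extraction in
#' cis-windows. Inputs are in-memory objects (as produced by
#' \code{\link{read_genotypes}} and friends, or by
#' \code{\link{simulate_genotypes}}). When \code{out_dir} is given, every
#' stage's table is written there along with a manifest JSON recording
#' parameters, seeds and output checksums. A stage failure is re-signalled
#' with the stage name prefixed.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param snps SNP metadata data.frame (locus_id, chromosome, position_bp,
#'   and QC columns gentrain_score / mapping_hits as required).
#' @param sample_map data.frame with sample_id, breed.
#' @param genes optional gene annotation data.frame; \code{NULL} skips the
#'   gene-window stage.
#' @param qc a \code{\link{qc_config}}.
#' @param bootstrap_reps bootstrap replicates for F_IS and F_ST intervals.
#' @param fst_alpha,fst_alpha_suggestive significance levels for the
#'   pairwise F_ST bootstrap.
#' @param amova_permutations permutations for the AMOVA test.
#' @param selection_factor multiple of the expected PC contribution used as
#'   selection threshold.
#' @param component principal component used for selection (default 1).
#' @param validation_k SD multiplier of the F_ST outlier threshold.
#' @param window_half_width_bp cis-window half-width in bp.
#' @param linkage linkage method for clustering.
#' @param seed master integer seed; stage seeds are derived from it.
#' @param out_dir optional output directory.
#' @return list of stage results: qc_report, diversity, fst_pairwise,
#'   fst_one_vs_rest, distances, tree, newick, amova_result, kinship, pca,
#'   contributions, selection, validation, gene_report, manifest.
#' @export
run_pipeline <- function(genotypes, snps, sample_map, genes = NULL,
                         qc = qc_config(), bootstrap_reps = 1000,
                         fst_alpha = 0.005, fst_alpha_suggestive = 0.01,
                         amova_permutations = 10000, selection_factor = 10,
                         component = 1, validation_k = 2,
                         window_half_width_bp = 250000,
                         linkage = "complete", seed = 42, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "': ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- list()

  qcd <- stage("qc", apply_qc(genotypes, snps, qc))
  res$qc_report <- qcd$report
  g <- qcd$genotypes
  sample_map <- sample_map[sample_map$sample_id %in% rownames(g), , drop = FALSE]

  res$diversity <- stage("diversity",
    diversity_summary(g, sample_map, bootstrap_reps = bootstrap_reps,
                      seed = seed + 1L))

  res$fst_pairwise <- stage("fst_pairwise",
    fst_pairwise(g, sample_map, bootstrap_reps = bootstrap_reps,
                 alpha = fst_alpha, alpha_suggestive = fst_alpha_suggestive,
                 seed = seed + 2L))
  res$fst_one_vs_rest <- stage("fst_one_vs_rest",
    fst_one_vs_rest(g, sample_map, target = "all",
                    bootstrap_reps = bootstrap_reps, alpha = fst_alpha,
                    alpha_suggestive = fst_alpha_suggestive,
                    seed = seed + 3L))

  res$distances <- stage("distances",
    nei_distance_matrix(g, inf_replace = NULL))
  dm_clust <- res$distances
  if (any(is.infinite(dm_clust)))
    dm_clust[is.infinite(dm_clust)] <- 2 * max(dm_clust[is.finite(dm_clust)])
  res$tree <- stage("clustering", hierarchical_cluster(dm_clust, linkage))
  res$newick <- stage("newick", tree_to_newick(res$tree))
  res$amova_result <- stage("amova",
    amova(dm_clust, sample_map, permutations = amova_permutations,
          seed = seed + 4L))
  res$kinship <- stage("kinship", ibs_kinship(g))

  res$pca <- stage("pca", run_pca(g))
  res$contributions <- stage("contributions",
    snp_contributions(res$pca, component = component))
  res$selection <- stage("selection",
    select_high_contribution(res$contributions, factor = selection_factor))
  res$validation <- stage("validation",
    validate_selected_by_fst(res$selection, res$fst_one_vs_rest,
                             k = validation_k))

  if (!is.null(genes)) {
    sel_snps <- snps[match(res$selection$selected$locus_id, snps$locus_id), ,
                     drop = FALSE]
    res$gene_report <- stage("gene_windows", {
      win <- build_windows(sel_snps, half_width_bp = window_half_width_bp)
      extract_genes(win, genes)
    })
  }

  params <- list(qc = unclass(qc), bootstrap_reps = bootstrap_reps,
                 fst_alpha = fst_alpha,
                 fst_alpha_suggestive = fst_alpha_suggestive,
                 amova_permutations = amova_permutations,
                 selection_factor = selection_factor, component = component,
                 validation_k = validation_k,
                 window_half_width_bp = window_half_width_bp,
                 linkage = linkage, seed = seed)
  if (!is.null(out_dir)) {
    wr <- function(x, f) {
      utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f
    }
    files <- c(
      wr(res$diversity, "diversity.tsv"),
      wr(res$fst_pairwise$table, "fst_pairwise.tsv"),
      wr(data.frame(breed = names(res$fst_one_vs_rest),
                    theta = vapply(res$fst_one_vs_rest,
                                   function(e) e$theta_multilocus, 0),
                    significant = vapply(res$fst_one_vs_rest,
                                         function(e) isTRUE(e$significant), TRUE)),
         "fst_one_vs_rest.tsv"),
      wr(data.frame(component = component,
                    t(c(pct_among = res$amova_result$pct_among,
                        pct_within = res$amova_result$pct_within,
                        phi_st = res$amova_result$phi_st,
                        p_value = res$amova_result$p_value))), "amova.tsv"),
      wr(res$selection$selected, "selected_snps.tsv"),
      wr(res$validation, "validation.tsv"))
    write_distance_matrix(res$distances, file.path(out_dir, "nei_distances.tsv"))
    writeLines(res$newick, file.path(out_dir, "tree.nwk"))
    files <- c(files, "nei_distances.tsv", "tree.nwk")
    if (!is.null(res$gene_report)) {
      files <- c(files, wr(res$gene_report$genes, "window_genes.tsv"))
    }
    manifest <- list(parameters = params,
                     files = as.list(stats::setNames(
                       unname(tools::md5sum(file.path(out_dir, files))), files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$manifest <- manifest
  } else {
    res$manifest <- list(parameters = params)
  }
  res
}
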