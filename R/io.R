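#' Read genotypes from PLINK ped/map or a TSV genotype matrix
#'
#' Two text dialects are supported. \code{ped_map}: whitespace-delimited
#' PLINK files where each .ped row is
#' \code{FID IID PAT MAT SEX PHENO A1 A2 A1 A2 ...} and the .map supplies
#' \code{chrom id cM pos} per locus. \code{tsv_matrix}: a tab-separated
#' matrix with a header of locus ids and one row per sample (first column =
#' sample id), cells coded \code{AA/AB/BB} (or two-letter genotypes such as
#' \code{AG}) with \code{NA}, \code{--}, \code{0 0}, \code{NC} or empty for
#' missing.
#'
#' Dosages count copies of the B allele. When no allele metadata is
#' available the lexicographically later observed allele at each locus is
#' taken as B, which is deterministic without a chip manifest. For a locus
#' where only one allele is observed that allele is necessarily designated
#' B (dosage 2): the A/B assignment of a monomorphic locus is not
#' recoverable from calls alone.
#'
#' @param path path to the .ped file or the TSV matrix.
#' @param format \code{"ped_map"} or \code{"tsv_matrix"}.
#' @param map_path path to the .map file; defaults to \code{path} with its
#'   extension replaced by \code{.map}.
#' @return A list with elements \code{genotypes} (a
#'   \code{\link{genotype_matrix}}) and \code{snps} (a data.frame of locus
#'   metadata: locus_id, chromosome, position_bp, allele_a, allele_b).
#' @export
read_genotypes <- function(path, format = c("ped_map", "tsv_matrix"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "ped_map") {
    if (is.null(map_path)) map_path <- sub("\\.[^.]*$", ".map", path)
    if (!file.exists(map_path)) stop("map file not found: ", map_path)
    .read_ped_map(path, map_path)
  } else {
    .read_tsv_matrix(path)
  }
}

.missing_codes <- c("NA", "--", "0 0", "00", "NC", "")

.read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) < 4)
    stop("malformed .map file: expected 4 columns, found ", ncol(map))
  snps <- data.frame(locus_id = map[[2]], chromosome = map[[1]],
                     position_bp = as.integer(map[[4]]),
                     stringsAsFactors = FALSE)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  L <- nrow(map)
  want <- 6 + 2 * L
  nf <- lengths(toks)
  if (any(nf != want))
    stop(sprintf(".ped line %d has %d fields, expected %d (%d loci in map)",
                 which(nf != want)[1], nf[nf != want][1], want, L))
  ids <- vapply(toks, `[[`, "", 2)
  a1 <- t(vapply(toks, function(x) x[seq(7, want, by = 2)], character(L)))
  a2 <- t(vapply(toks, function(x) x[seq(8, want, by = 2)], character(L)))
  if (L == 1) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA; a2[miss] <- NA
  dos <- matrix(NA_integer_, length(ids), L)
  allele_a <- allele_b <- rep(NA_character_, L)
  for (j in seq_len(L)) {
    obs <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(obs) > 2)
      stop("locus ", snps$locus_id[j], " has >2 alleles: ",
           paste(obs, collapse = "/"))
    if (length(obs) == 0) next
    b <- obs[length(obs)]                      # lexicographically later = B
    allele_b[j] <- b
    allele_a[j] <- if (length(obs) == 2) obs[1] else NA_character_
    dos[, j] <- (a1[, j] == b) + (a2[, j] == b)
  }
  snps$allele_a <- allele_a
  snps$allele_b <- allele_b
  list(genotypes = genotype_matrix(dos, ids, snps$locus_id), snps = snps)
}

.read_tsv_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  ids <- rownames(tab)
  loci <- colnames(tab)
  m <- as.matrix(tab)
  m[m %in% .missing_codes] <- NA
  ok <- !is.na(m) & nchar(m) == 2
  if (any(!is.na(m) & !ok))
    stop("unparseable genotype codes, e.g. ",
         paste(utils::head(unique(m[!is.na(m) & !ok]), 3), collapse = ", "))
  allele_a <- allele_b <- rep(NA_character_, length(loci))
  dos <- matrix(NA_integer_, length(ids), length(loci))
  c1 <- substr(m, 1, 1); c2 <- substr(m, 2, 2)
  for (j in seq_along(loci)) {
    obs <- sort(unique(stats::na.omit(c(c1[, j], c2[, j]))))
    if (length(obs) > 2)
      stop("locus ", loci[j], " has >2 alleles: ", paste(obs, collapse = "/"))
    if (length(obs) == 0) next
    b <- obs[length(obs)]
    allele_b[j] <- b
    allele_a[j] <- if (length(obs) == 2) obs[1] else NA_character_
    dos[, j] <- (c1[, j] == b) + (c2[, j] == b)
  }
  snps <- data.frame(locus_id = loci, chromosome = NA_character_,
                     position_bp = NA_integer_, allele_a = allele_a,
                     allele_b = allele_b, stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dos, ids, loci), snps = snps)
}

#' Write genotypes as a TSV matrix
#'
#' Inverse of \code{read_genotypes(format = "tsv_matrix")}: dosage 0/1/2 is
#' written as \code{AA/AB/BB} and missing as \code{NA}.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param path output path.
#' @export
write_genotypes <- function(g, path) {
  codes <- c("AA", "AB", "BB")
  m <- matrix(codes[g + 1L], nrow(g), ncol(g), dimnames = dimnames(g))
  m[is.na(m)] <- "NA"
  tab <- data.frame(sample_id = rownames(g), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-breed map
#'
#' TSV with header; columns \code{sample_id}, \code{breed} and optionally
#' \code{site}.
#'
#' @param path input path.
#' @return data.frame with sample_id, breed, site.
#' @export
read_sample_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "breed")
  if (!all(need %in% names(tab)))
    stop("sample map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in sample map")
  if (any(!nzchar(tab$breed))) stop("empty breed label in sample map")
  if (!"site" %in% names(tab)) tab$site <- NA_character_
  tab[, c("sample_id", "breed", "site")]
}

#' Read a gene annotation table
#'
#' TSV with header; columns \code{gene_id}, \code{chromosome},
#' \code{start_bp}, \code{end_bp} (1-based inclusive coordinates).
#'
#' @param path input path.
#' @return data.frame of gene records.
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chromosome", "start_bp", "end_bp")
  if (!all(need %in% names(tab)))
    stop("gene annotation must have columns: ", paste(need, collapse = ", "))
  tab$start_bp <- as.integer(tab$start_bp)
  tab$end_bp <- as.integer(tab$end_bp)
  bad <- which(is.na(tab$start_bp) | is.na(tab$end_bp) |
               tab$start_bp < 1L | tab$end_bp < tab$start_bp)
  if (length(bad))
    stop("invalid gene interval at line ", bad[1] + 1L,
         " (need 1 <= start_bp <= end_bp)")
  tab[, need]
}

#' Write and read a labelled square distance matrix
#'
#' TSV with a header row of labels and the label repeated in the first
#' column; values are written in full precision.
#'
#' @param dm symmetric numeric matrix with dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  tab <- data.frame(label = rownames(dm),
                    format(dm, digits = 17, trim = TRUE, scientific = TRUE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("label", colnames(dm))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @return \code{read_distance_matrix}: the matrix, validated for symmetry
#'   (within 1e-9) and a zero diagonal.
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  dm <- as.matrix(tab)
  if (nrow(dm) != ncol(dm))
    stop("distance matrix is not square: ", nrow(dm), "x", ncol(dm))
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-9, check.attributes = FALSE)))
    stop("distance matrix is not symmetric within 1e-9")
  if (any(abs(diag(dm)) > 0)) stop("distance matrix diagonal must be zero")
  dm
}

#' Write a tree in Newick format
#'
#' Accepts an \code{hclust} object (converted through
#' \code{\link[ape]{as.phylo}}) or a \code{phylo} tree and writes a
#' semicolon-terminated Newick string with branch lengths.
#'
#' @param tree \code{hclust} or \code{ape::phylo} object.
#' @param path output path.
#' @return The Newick string, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  if (!inherits(tree, "phylo")) stop("'tree' must be hclust or phylo")
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}
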