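#' Construct a genotype matrix
#'
#' The central container of the package: an integer matrix of B-allele
#' dosages (0, 1, 2; \code{NA} = missing call) with samples in rows and loci
#' in columns. Row and column names carry the sample and locus identifiers
#' and must be unique.
#'
#' @param dosage numeric/integer matrix with entries in \{0, 1, 2\} or
#'   \code{NA}.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to existing rownames.
#' @param locus_ids character vector of unique locus identifiers; defaults to
#'   existing colnames.
#' @return An object of class \code{genotype_matrix} (an integer matrix).
#' @examples
#' g <- genotype_matrix(rbind(a = c(0, 1, 2), b = c(2, NA, 0)),
#'                      locus_ids = c("s1", "s2", "s3"))
#' n_samples(g); n_loci(g)
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage),
                            locus_ids = colnames(dosage)) {
  if (!is.matrix(dosage)) stop("'dosage' must be a matrix")
  if (is.null(sample_ids) || is.null(locus_ids))
    stop("sample and locus identifiers are required")
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (length(sample_ids) != nrow(dosage) || length(locus_ids) != ncol(dosage))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ids: ",
         paste(utils::head(unique(locus_ids[duplicated(locus_ids)]), 5),
               collapse = ", "))
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad))
    stop("dosage entries must be 0, 1, 2 or NA; found ",
         paste(utils::head(unique(dosage[bad]), 5), collapse = ", "))
  m <- matrix(as.integer(dosage), nrow(dosage), ncol(dosage),
              dimnames = list(sample_ids, locus_ids))
  class(m) <- c("genotype_matrix", class(m))
  m
}

#' @rdname genotype_matrix
#' @param x a \code{genotype_matrix}.
#' @export
n_samples <- function(x) nrow(x)

#' @rdname genotype_matrix
#' @export
n_loci <- function(x) ncol(x)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

# subset while keeping the class and dimnames
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  class(out) <- c("genotype_matrix", "matrix", "array")
  out
}

# internal: coerce sample subset argument (NULL, logical, indices or names)
.resolve_samples <- function(g, samples) {
  if (is.null(samples)) return(seq_len(nrow(g)))
  if (is.character(samples)) {
    miss <- setdiff(samples, rownames(g))
    if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
    return(match(samples, rownames(g)))
  }
  samples
}
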