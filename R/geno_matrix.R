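#' SNP genotype matrix
#'
#' The package's core data object: an individuals x loci matrix of biallelic
#' genotype calls coded as the number of copies of the alternate allele
#' (0, 1, 2), with `NA` for missing calls, plus a locus table carrying
#' locus id, chromosome (possibly a synthetic contig), 1-based position
#' and the reference/alternate allele pair.
#'
#' @param calls integer matrix, individuals in rows, loci in columns;
#'   entries in `{0, 1, 2, NA}`. Row names are individual IDs (generated if
#'   absent); column names are locus IDs.
#' @param loci optional tibble with columns `locus_id`, `chrom`, `pos`,
#'   `ref`, `alt`, one row per column of `calls`. A minimal table is
#'   generated when omitted.
#' @return an object of class `geno_matrix`: a list with elements `calls`
#'   (integer matrix) and `loci` (tibble).
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 2))
#' n_loci(g)
#' @export
geno_matrix <- function(calls, loci = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix", call. = FALSE)
  storage.mode(calls) <- "integer"
  if (nrow(calls) < 1L || ncol(calls) < 1L)
    stop("genotype matrix needs at least one individual and one locus",
         call. = FALSE)
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("non-missing calls must be 0, 1 or 2 copies of the alternate allele",
         call. = FALSE)
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("ind_%d", seq_len(nrow(calls)))
  if (anyDuplicated(rownames(calls)))
    stop("individual IDs must be unique", call. = FALSE)
  if (is.null(loci)) {
    if (is.null(colnames(calls)))
      colnames(calls) <- sprintf("locus_%d", seq_len(ncol(calls)))
    loci <- tibble::tibble(
      locus_id = colnames(calls),
      chrom = "ctg1",
      pos = seq_len(ncol(calls)),
      ref = "A",
      alt = "C"
    )
  } else {
    loci <- tibble::as_tibble(loci)
    need <- c("locus_id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(loci)))
      stop("`loci` must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (nrow(loci) != ncol(calls))
      stop("`loci` must have one row per genotype column", call. = FALSE)
    colnames(calls) <- loci$locus_id
  }
  if (anyDuplicated(loci$locus_id))
    stop("locus IDs must be unique", call. = FALSE)
  if (any(loci$pos < 1L))
    stop("positions are 1-based and must be >= 1", call. = FALSE)
  if (any(loci$ref == loci$alt))
    stop("reference and alternate alleles must differ", call. = FALSE)
  structure(list(calls = calls, loci = loci), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Dimensions of a genotype matrix
#' @param g a [geno_matrix()]
#' @return integer count.
#' @export
n_individuals <- function(g) nrow(g$calls)

#' @rdname n_individuals
#' @export
n_loci <- function(g) ncol(g$calls)

#' Individual IDs of a genotype matrix
#' @param g a [geno_matrix()]
#' @return character vector.
#' @export
individuals <- function(g) rownames(g$calls)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()]
#' @param i individual index (logical, integer or ID)
#' @param j locus index (logical, integer or locus ID)
#' @param ... unused
#' @param drop ignored; dimensions are always kept
#' @return a [geno_matrix()]
#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  jj <- seq_len(ncol(x$calls))
  names(jj) <- colnames(x$calls)
  loci <- x$loci[jj[colnames(calls)], , drop = FALSE]
  geno_matrix(calls, loci)
}

#' Convert genotype calls to a long tibble
#'
#' One row per (individual, locus) cell, for dplyr/ggplot workflows.
#'
#' @param g a [geno_matrix()]
#' @return tibble with columns `individual_id`, `locus_id`, `dosage`.
#' @export
as_dosage_tibble <- function(g) {
  tibble::tibble(
    individual_id = rep(rownames(g$calls), times = ncol(g$calls)),
    locus_id = rep(colnames(g$calls), each = nrow(g$calls)),
    dosage = as.integer(g$calls)
  )
}

#' Random subset of loci
#'
#' Uniform sample of `n` loci without replacement, preserving the original
#' locus order; deterministic given `seed`. Mirrors drawing the random
#' 5,000- and 1,000-SNP panels used for computationally heavy analyses.
#'
#' @param g a [geno_matrix()]
#' @param n number of loci to keep, `1 <= n <= n_loci(g)`
#' @param seed integer seed
#' @return a [geno_matrix()] with `n` loci.
#' @export
subset_loci <- function(g, n, seed = 1L) {
  if (n < 1L || n > n_loci(g))
    stop("`n` must be between 1 and the number of loci", call. = FALSE)
  keep <- with_seed(seed, sort(sample.int(n_loci(g), n)))
  g[, keep]
}
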