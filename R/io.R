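#' Read a SNP genotype matrix from PLINK text PED/MAP or VCF
#'
#' Genotypes are coded as alternate-allele dosage exactly as written in the
#' file; phased and unphased genotypes are treated identically and missing
#' genotypes become `NA`. For VCF input only biallelic SNP records are used;
#' skipped records are counted and reported via the `skipped` attribute (and
#' a message). For PED/MAP input, where the file format does not name a
#' reference allele, the lexicographically smaller observed allele is taken
#' as reference and the larger as alternate; a locus monomorphic in the file
#' is coded as all-reference.
#'
#' @param path path to the `.ped` or `.vcf` file (for `ped_map`, the `.map`
#'   file is found by swapping the extension or via `map_path`)
#' @param format `"ped_map"` or `"vcf"`
#' @param map_path optional explicit path to the MAP file
#' @return a [geno_matrix()]; attribute `skipped` holds the number of
#'   non-biallelic/non-SNP VCF records dropped.
#' @export
read_genotypes <- function(path, format = c("ped_map", "vcf"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "ped_map") {
    read_ped_map(path, map_path)
  } else {
    read_vcf_genotypes(path)
  }
}

read_ped_map <- function(ped_path, map_path = NULL) {
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path,
                                   call. = FALSE)
  map_lines <- readLines(map_path)
  map_tok <- strsplit(trimws(map_lines), "\\s+")
  bad <- which(vapply(map_tok, length, 1L) < 4L)
  if (length(bad))
    stop(sprintf("malformed MAP line %d in %s", bad[1], map_path),
         call. = FALSE)
  loci <- tibble::tibble(
    locus_id = vapply(map_tok, `[`, "", 2L),
    chrom = vapply(map_tok, `[`, "", 1L),
    pos = as.integer(vapply(map_tok, `[`, "", 4L))
  )
  n_loc <- nrow(loci)
  if (n_loc == 0L) stop("empty MAP file: no usable loci", call. = FALSE)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  if (!length(ped_lines)) stop("empty PED file", call. = FALSE)
  tok <- strsplit(trimws(ped_lines), "\\s+")
  want <- 6L + 2L * n_loc
  lens <- vapply(tok, length, 1L)
  if (any(lens != want))
    stop(sprintf("malformed PED line %d: expected %d fields, found %d",
                 which(lens != want)[1], want, lens[lens != want][1]),
         call. = FALSE)
  ids <- vapply(tok, `[`, "", 2L)
  al <- matrix(unlist(lapply(tok, `[`, -(1:6))), nrow = length(tok),
               byrow = TRUE)
  a1 <- al[, seq(1, 2 * n_loc, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * n_loc, by = 2), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  calls <- matrix(NA_integer_, length(ids), n_loc)
  ref <- alt <- character(n_loc)
  for (j in seq_len(n_loc)) {
    obs <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(obs) > 2L)
      stop(sprintf("locus %s has more than two alleles in PED file",
                   loci$locus_id[j]), call. = FALSE)
    ref[j] <- if (length(obs)) obs[1] else "A"
    alt[j] <- if (length(obs) == 2L) obs[2] else "N"
    calls[, j] <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
  }
  calls <- matrix(as.integer(calls), nrow = length(ids),
                  dimnames = list(ids, loci$locus_id))
  loci$ref <- ref
  loci$alt <- alt
  geno_matrix(calls, loci[, c("locus_id", "chrom", "pos", "ref", "alt")])
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("empty VCF: no usable loci", call. = FALSE)
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT) & !is.na(fix$ALT)
  skipped <- sum(!is_snp)
  if (skipped > 0)
    message(skipped, " non-biallelic/non-SNP VCF record(s) skipped")
  if (!any(is_snp)) stop("no biallelic SNP records in VCF", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  dose <- function(s) {
    a <- strsplit(s, "[/|]")
    vapply(a, function(x) {
      if (any(is.na(x)) || any(x == ".")) return(NA_integer_)
      sum(as.integer(x))
    }, integer(1))
  }
  calls <- apply(gt, 2, dose)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1L)
  calls <- t(calls)  # individuals x loci
  dimnames(calls) <- list(colnames(gt), ids)
  loci <- tibble::tibble(locus_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT)
  out <- geno_matrix(calls, loci)
  attr(out, "skipped") <- skipped
  out
}

#' Write a genotype matrix as PLINK text PED/MAP
#'
#' @param g a [geno_matrix()]
#' @param ped_path,map_path output file paths
#' @return invisibly, `g`.
#' @export
write_ped_map <- function(g, ped_path, map_path = NULL) {
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", ped_path)
  loci <- g$loci
  writeLines(sprintf("%s\t%s\t0\t%d", loci$chrom, loci$locus_id, loci$pos),
             map_path)
  n <- n_individuals(g)
  lines <- character(n)
  for (i in seq_len(n)) {
    x <- g$calls[i, ]
    a1 <- ifelse(is.na(x), "0", ifelse(x >= 1L, loci$alt, loci$ref))
    a2 <- ifelse(is.na(x), "0", ifelse(x == 2L, loci$alt, loci$ref))
    lines[i] <- paste(c(individuals(g)[i], individuals(g)[i], 0, 0, 0, -9,
                        rbind(a1, a2)), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(g)
}

#' Write a genotype matrix as VCF (v4.2, biallelic SNP records)
#'
#' @param g a [geno_matrix()]
#' @param path output `.vcf` path
#' @return invisibly, `g`.
#' @export
write_vcf <- function(g, path) {
  loci <- g$loci
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fursealpop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individuals(g)), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(n_loci(g)), function(j) {
    x <- g$calls[, j]
    gt <- ifelse(is.na(x), "./.", gt_code[x + 1L])
    paste(c(loci$chrom[j], loci$pos[j], loci$locus_id[j], loci$ref[j],
            loci$alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(g)
}
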