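#' Quality-control configuration
#'
#' Thresholds for the five-step SNP filter chain: individual missingness,
#' locus missingness, minor allele frequency, per-population Hardy-Weinberg
#' exact tests, and within-population linkage-disequilibrium pruning. The
#' HWE and LD filters only remove a locus when it is flagged in at least
#' `min_populations_flagged` of the populations (six of eight by default).
#'
#' @param max_individual_missing_fraction drop individuals with more than
#'   this fraction of missing calls (default 0.90)
#' @param max_locus_missing_fraction drop loci with more than this fraction
#'   of missing calls (default 0.20)
#' @param min_maf minimum minor allele frequency, computed after the
#'   missingness filters (default 0.05)
#' @param hwe_alpha per-population exact-test significance level
#'   (default 0.01)
#' @param ld_r2_threshold within-population squared-correlation threshold
#'   for calling a pair of loci linked (default 0.8)
#' @param ld_window_loci sliding-window width, in loci, for LD pruning
#'   (default 50)
#' @param min_populations_flagged populations that must flag a locus before
#'   the HWE/LD filters remove it (default 6)
#' @param n_populations_expected expected number of populations (default 8)
#' @return list of class `qc_config`.
#' @export
qc_config <- function(max_individual_missing_fraction = 0.90,
                      max_locus_missing_fraction = 0.20,
                      min_maf = 0.05,
                      hwe_alpha = 0.01,
                      ld_r2_threshold = 0.8,
                      ld_window_loci = 50L,
                      min_populations_flagged = 6L,
                      n_populations_expected = 8L) {
  cfg <- list(
    max_individual_missing_fraction = max_individual_missing_fraction,
    max_locus_missing_fraction = max_locus_missing_fraction,
    min_maf = min_maf,
    hwe_alpha = hwe_alpha,
    ld_r2_threshold = ld_r2_threshold,
    ld_window_loci = as.integer(ld_window_loci),
    min_populations_flagged = as.integer(min_populations_flagged),
    n_populations_expected = as.integer(n_populations_expected)
  )
  fr <- c(cfg$max_individual_missing_fraction, cfg$max_locus_missing_fraction,
          cfg$min_maf, cfg$hwe_alpha, cfg$ld_r2_threshold)
  if (any(fr < 0) || any(fr > 1))
    stop("qc_config fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$min_populations_flagged > cfg$n_populations_expected)
    stop("min_populations_flagged cannot exceed n_populations_expected",
         call. = FALSE)
  structure(cfg, class = "qc_config")
}

#' Hardy-Weinberg exact test for one biallelic locus
#'
#' Two-sided exact test by full enumeration of all heterozygote counts
#' consistent with the observed allele counts; the p-value sums the
#' probabilities of all configurations no more probable than the observed
#' one. A monomorphic locus returns p = 1 (single configuration).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, sum >= 1)
#' @return exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(2, 4, 2)
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || n_AA + n_Aa + n_aa < 1)
    stop("genotype counts must be non-negative and sum to >= 1",
         call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  h_min <- if (nA %% 2 == 0) 0L else 1L
  h <- seq(h_min, min(nA, 2 * n - nA), by = 2L)
  logp <- -lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial(n - (nA + h) / 2) + h * log(2)
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  p_obs <- p[match(n_Aa, h)]
  sum(p[p <= p_obs * (1 + 1e-9)])
}

#' Linkage disequilibrium between two loci
#'
#' Squared Pearson correlation of alternate-allele dosages over
#' pairwise-complete individuals, optionally restricted to one colony.
#' A locus monomorphic within the subset makes the correlation undefined;
#' 0 is returned with attribute `undefined = TRUE`.
#'
#' @param g a [geno_matrix()]
#' @param locus_a,locus_b locus IDs or column indices
#' @param pops a [pop_map()] (required when `within` is a colony code)
#' @param within a colony code, or `"all"` for every individual
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g, locus_a, locus_b, pops = NULL, within = "all") {
  rows <- if (identical(within, "all")) seq_len(n_individuals(g))
          else which(group_labels(g, pops, "colony") == within)
  x <- g$calls[rows, locus_a]
  y <- g$calls[rows, locus_b]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2)
    stop("need at least 2 individuals with both calls non-missing",
         call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(0, undefined = TRUE))
  stats::cor(x, y)^2
}

# r^2 of column j against the following columns in a window (one pop's rows);
# NA where undefined
ld_r2_window <- function(calls, j, upto) {
  x <- calls[, j]
  sapply(seq((j + 1), upto), function(k) {
    y <- calls[, k]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return(NA_real_)
    sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
    if (sx == 0 || sy == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])^2
  })
}

#' Apply the SNP quality-control filter chain
#'
#' Filters in order: (1) individuals by missingness, (2) loci by
#' missingness, (3) loci by minor allele frequency (recomputed on the
#' post-missingness matrix), (4) loci out of Hardy-Weinberg equilibrium by
#' the exact test at `hwe_alpha` in at least `min_populations_flagged`
#' populations, (5) within-population sliding-window LD pruning with the
#' same at-least-k-populations rule, keeping the member of a linked pair
#' with the higher call rate (tie: lower locus index).
#'
#' @param g a [geno_matrix()]
#' @param pops a [pop_map()] covering all individuals
#' @param cfg a [qc_config()]
#' @return list with elements `genotypes` (filtered [geno_matrix()]) and
#'   `report` (tibble of class `filter_report`: one row per step with
#'   removal and surviving counts).
#' @export
apply_qc <- function(g, pops, cfg = qc_config()) {
  if (!inherits(cfg, "qc_config")) cfg <- do.call(qc_config, cfg)
  steps <- list()
  note <- function(step, ni_rm, nl_rm, gg) {
    steps[[length(steps) + 1L]] <<- tibble::tibble(
      step = step, n_individuals_removed = ni_rm, n_loci_removed = nl_rm,
      n_individuals = n_individuals(gg), n_loci = n_loci(gg))
  }

  # 1. individual missingness
  miss_i <- rowMeans(is.na(g$calls))
  keep_i <- miss_i <= cfg$max_individual_missing_fraction
  if (!any(keep_i))
    stop("all individuals removed by the missingness filter", call. = FALSE)
  g1 <- g[keep_i, ]
  note("individual_missingness", sum(!keep_i), 0L, g1)

  # 2. locus missingness
  miss_l <- colMeans(is.na(g1$calls))
  keep_l <- miss_l <= cfg$max_locus_missing_fraction
  if (!any(keep_l)) stop("all loci removed by the missingness filter",
                         call. = FALSE)
  g2 <- g1[, keep_l]
  note("locus_missingness", 0L, sum(!keep_l), g2)

  # 3. minor allele frequency (global, post-missingness)
  p <- colMeans(g2$calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_m <- !is.na(maf) & maf >= cfg$min_maf
  if (!any(keep_m)) stop("all loci removed by the MAF filter", call. = FALSE)
  g3 <- g2[, keep_m]
  note("maf", 0L, sum(!keep_m), g3)

  # 4. HWE exact test per population
  colony <- group_labels(g3, pops, "colony")
  flags <- rep(0L, n_loci(g3))
  for (pop in unique(colony)) {
    cc <- g3$calls[colony == pop, , drop = FALSE]
    pv <- apply(cc, 2, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(1)
      hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
    })
    flags <- flags + (pv < cfg$hwe_alpha)
  }
  keep_h <- flags < cfg$min_populations_flagged
  g4 <- g3[, keep_h]
  note("hwe", 0L, sum(!keep_h), g4)

  # 5. LD pruning
  call_rate <- colMeans(!is.na(g4$calls))
  colony <- group_labels(g4, pops, "colony")
  L <- n_loci(g4)
  flags <- rep(0L, L)
  w <- cfg$ld_window_loci
  for (pop in unique(colony)) {
    cc <- g4$calls[colony == pop, , drop = FALSE]
    pf <- rep(FALSE, L)
    for (j in seq_len(L - 1L)) {
      upto <- min(j + w - 1L, L)
      if (upto <= j) next
      r2 <- ld_r2_window(cc, j, upto)
      hit <- which(!is.na(r2) & r2 > cfg$ld_r2_threshold)
      for (k in j + hit) {
        # flag the worse-called member of the pair (tie: higher index)
        drop <- if (call_rate[j] < call_rate[k]) j
                else if (call_rate[k] < call_rate[j]) k
                else k
        pf[drop] <- TRUE
      }
    }
    flags <- flags + pf
  }
  keep_ld <- flags < cfg$min_populations_flagged
  g5 <- g4[, keep_ld]
  note("ld", 0L, sum(!keep_ld), g5)

  report <- dplyr::bind_rows(steps)
  class(report) <- c("filter_report", class(report))
  list(genotypes = g5, report = report)
}

#' Write a filter report as TSV and JSON
#'
#' @param report the `report` element of [apply_qc()]
#' @param tsv_path,json_path output paths (either may be `NULL`)
#' @return invisibly, `report`.
#' @export
write_filter_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(report, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(report)
}
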