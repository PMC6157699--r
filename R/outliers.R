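#' Simulate the neutral null table for the FST-outlier scan
#'
#' Island-model single-locus simulations with sample sizes matched to the
#' observed colonies; the migration rate is solved so that the expected
#' island-model FST matches the target (by the finite-island closed form),
#' optionally refined by simulation.
#'
#' @param sample_sizes observed diploid sample sizes per colony
#' @param target_fst the neutral FST the null should reproduce (typically
#'   a trimmed mean of observed per-locus values)
#' @param n_sims number of simulated loci
#' @param n_demes demes in the island model (default 8, the study design)
#' @param deme_size diploid deme size
#' @param min_maf pooled MAF ascertainment threshold
#' @param n_calib_iters extra calibration passes: after each, the
#'   migration rate is rescaled by the ratio of simulated to target mean
#'   FST (0 = closed form only)
#' @param seed integer seed
#' @return tibble with one row per simulated locus: `He` (pooled unbiased
#'   gene diversity), `theta` (multi-population Weir-Cockerham FST).
#' @export
fdist_null_table <- function(sample_sizes, target_fst, n_sims = 50000L,
                             n_demes = 8L, deme_size = 1000,
                             min_maf = 0.01, n_calib_iters = 1L,
                             seed = 1L) {
  m <- island_m_for_fst(target_fst, deme_size, n_demes)
  with_seed(seed, {
    for (it in seq_len(n_calib_iters)) {
      pilot <- .sim_island_genotypes(as.integer(n_demes),
                                     as.integer(sample_sizes), deme_size,
                                     m, 2000L, min_maf, 10000L)
      sim_mean <- mean(scan_locus_stats(pilot, sample_sizes)$theta,
                       na.rm = TRUE)
      if (sim_mean > 0 && target_fst > 0)
        m <- m * sim_mean / target_fst
    }
    sims <- .sim_island_genotypes(as.integer(n_demes),
                                  as.integer(sample_sizes), deme_size, m,
                                  as.integer(n_sims), min_maf, 10000L)
    out <- scan_locus_stats(sims, sample_sizes)
    attr(out, "migration_rate") <- m
    out
  })
}

# per-locus pooled He and multi-population WC theta for a complete dosage
# matrix whose rows are blocked by deme
scan_locus_stats <- function(calls, sample_sizes) {
  labels <- rep(sprintf("d%d", seq_along(sample_sizes)), sample_sizes)
  comp <- wc_components(calls, labels)
  den <- comp$a + comp$b + comp$c
  n <- nrow(calls)
  p <- colMeans(calls, na.rm = TRUE) / 2
  tibble::tibble(
    He = (2 * n) / (2 * n - 1) * 2 * p * (1 - p),
    theta = ifelse(!is.na(den) & den != 0, comp$a / den, NA_real_))
}

#' FDIST-style FST-outlier scan
#'
#' Per-locus multi-population Weir-Cockerham FST is compared with an
#' island-model null matched on heterozygosity: simulated (He, FST) pairs
#' are binned by pooled He (width `he_bin_width`, empty bins merged with
#' the nearest non-empty bin), and each observed locus gets a two-sided
#' rank-based tail probability within its bin, with (k+1)/(n+1) smoothing.
#' Benjamini-Hochberg q-values are attached, and the null envelope at the
#' requested confidence level is reported per bin.
#'
#' @param g a [geno_matrix()] (complete or missing calls allowed)
#' @param pops a [pop_map()]
#' @param n_sims island-model simulated loci for the null
#' @param ci envelope confidence level (default 0.99)
#' @param n_demes,deme_size island-model null settings
#' @param trim trimming fraction for the neutral-mean FST calibration
#' @param he_bin_width He bin width
#' @param null_table optional precomputed [fdist_null_table()] result
#' @param seed integer seed
#' @return object of class `outlier_scan`: `loci` (tibble: locus_id, He,
#'   theta, p, q, direction), `envelope` (tibble per He bin), `null_fst`
#'   (the calibration target), `ci`.
#' @export
fdist_scan <- function(g, pops, n_sims = 50000L, ci = 0.99, n_demes = 8L,
                       deme_size = 1000, trim = 0.25, he_bin_width = 0.02,
                       null_table = NULL, seed = 1L) {
  colony <- group_labels(g, pops, "colony")
  if (length(unique(colony)) < 2)
    stop("outlier scan needs >= 2 populations", call. = FALSE)
  sizes <- as.integer(table(colony)[unique(colony)])
  comp <- wc_components(g$calls, colony)
  den <- comp$a + comp$b + comp$c
  theta_obs <- ifelse(!is.na(den) & den != 0, comp$a / den, NA_real_)
  n_eff <- colSums(!is.na(g$calls))
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  he_obs <- (2 * n_eff) / pmax(2 * n_eff - 1, 1) * 2 * p * (1 - p)
  target <- mean(theta_obs, trim = trim, na.rm = TRUE)
  target <- max(target, 1e-4)
  if (is.null(null_table))
    null_table <- fdist_null_table(sizes, target, n_sims = n_sims,
                                   n_demes = n_demes, deme_size = deme_size,
                                   seed = seed)

  breaks <- seq(0, 1 + he_bin_width, by = he_bin_width)
  bin_of <- function(he) pmin(findInterval(he, breaks), length(breaks) - 1)
  sim_bin <- bin_of(null_table$He)
  occupied <- sort(unique(sim_bin))
  nearest_bin <- function(b) occupied[which.min(abs(occupied - b))]

  obs_bin <- bin_of(he_obs)
  merged <- !(obs_bin %in% occupied)
  if (any(merged))
    message(sum(merged), " locus/loci fell in empty He bins; ",
            "merged with the nearest non-empty bin")
  obs_bin <- vapply(obs_bin, nearest_bin, numeric(1))

  p_val <- rep(NA_real_, length(theta_obs))
  direction <- rep(NA_character_, length(theta_obs))
  for (b in unique(obs_bin)) {
    sims <- null_table$theta[sim_bin == b]
    sims <- sims[!is.na(sims)]
    idx <- which(obs_bin == b & !is.na(theta_obs))
    if (!length(idx)) next
    B <- length(sims)
    up <- (vapply(theta_obs[idx], function(t0) sum(sims >= t0),
                  numeric(1)) + 1) / (B + 1)
    lo <- (vapply(theta_obs[idx], function(t0) sum(sims <= t0),
                  numeric(1)) + 1) / (B + 1)
    p_val[idx] <- pmin(1, 2 * pmin(up, lo))
    direction[idx] <- ifelse(up < lo, "diversifying", "balancing")
  }
  alpha <- (1 - ci) / 2
  envelope <- dplyr::bind_rows(lapply(occupied, function(b) {
    sims <- null_table$theta[sim_bin == b]
    sims <- sims[!is.na(sims)]
    tibble::tibble(
      he_lower = breaks[b], he_upper = breaks[b + 1],
      n_sims = length(sims),
      theta_lower = stats::quantile(sims, alpha, names = FALSE),
      theta_upper = stats::quantile(sims, 1 - alpha, names = FALSE))
  }))
  loci <- tibble::tibble(
    locus_id = colnames(g$calls), He = he_obs, theta = theta_obs,
    p = p_val, q = bh_qvalues(p_val), direction = direction)
  structure(list(loci = loci, envelope = envelope, null_fst = target,
                 ci = ci),
            class = "outlier_scan")
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf(
    "<outlier_scan> %d loci against island null (mean FST %.4f); %d with q <= 0.05\n",
    nrow(x$loci), x$null_fst, sum(x$loci$q <= 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Tidy an outlier scan
#' @param x an `outlier_scan`
#' @param ... unused
#' @return the per-locus tibble.
#' @export
tidy.outlier_scan <- function(x, ...) x$loci

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR transform of a p-value vector (`NA`s preserved), via
#' [stats::p.adjust()].
#'
#' @param p p-values in `[0, 1]`
#' @return q-values, same length and order.
#' @export
bh_qvalues <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Call outlier loci at an FDR threshold
#'
#' @param scan an [fdist_scan()] result (or a tibble with `locus_id`, `q`,
#'   `direction`)
#' @param fdr q-value threshold
#' @return list with `diversifying` and `balancing` locus-id vectors.
#' @export
call_outliers <- function(scan, fdr = 0.05) {
  loci <- if (inherits(scan, "outlier_scan")) scan$loci else scan
  hit <- !is.na(loci$q) & loci$q <= fdr
  list(diversifying = loci$locus_id[hit & loci$direction == "diversifying"],
       balancing = loci$locus_id[hit & loci$direction == "balancing"])
}
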