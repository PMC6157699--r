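#' Assignment configuration
#'
#' @param zero_freq_substitute substitute for allele frequencies of exactly
#'   0 (and `1 - substitute` for 1), without renormalization
#' @param alpha significance level for the home-likelihood criterion
#' @param n_null_draws Monte-Carlo genotypes per individual for the home
#'   p-value
#' @param seed integer seed (governs missing-data imputation and the null
#'   draws)
#' @return list of class `assign_config`.
#' @export
assign_config <- function(zero_freq_substitute = 0.005, alpha = 0.05,
                          n_null_draws = 10000L, seed = 1L) {
  if (zero_freq_substitute <= 0 || zero_freq_substitute >= 1)
    stop("zero_freq_substitute must lie in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  structure(list(zero_freq_substitute = zero_freq_substitute, alpha = alpha,
                 n_null_draws = as.integer(n_null_draws),
                 seed = as.integer(seed)),
            class = "assign_config")
}

substitute_freq <- function(p, s) pmin(pmax(p, s), 1 - s)

#' Leave-one-out allele frequencies for one focal individual
#'
#' Per-population alternate-allele frequencies with the focal individual
#' excluded from its home population only; frequencies of exactly 0 or 1
#' are then replaced by `zero_freq_substitute` / `1 - zero_freq_substitute`
#' in every population (no renormalization).
#'
#' @param g a [geno_matrix()]
#' @param pops a [pop_map()]
#' @param focal individual ID
#' @param level `"colony"` or `"cluster"`
#' @param cfg an [assign_config()]
#' @return matrix populations x loci of substituted frequencies.
#' @export
loo_frequencies <- function(g, pops, focal, level = c("colony", "cluster"),
                            cfg = assign_config()) {
  level <- match.arg(level)
  lab <- group_labels(g, pops, level)
  i <- match(focal, individuals(g))
  if (is.na(i)) stop("unknown individual: ", focal, call. = FALSE)
  home <- lab[i]
  if (sum(lab == home) < 2)
    stop("home population of size 1; cannot leave one out", call. = FALSE)
  fm <- freq_by_group(g$calls, lab)
  counts <- fm$p * 2 * fm$n  # alt-allele counts
  genes <- 2 * fm$n
  x <- g$calls[i, ]
  ok <- !is.na(x)
  counts[home, ok] <- counts[home, ok] - x[ok]
  genes[home, ok] <- genes[home, ok] - 2
  p <- ifelse(genes > 0, counts / genes, NA_real_)
  substitute_freq(p, cfg$zero_freq_substitute)
}

#' Genotype log-likelihood under HWE given population frequencies
#'
#' Per locus, the genotype probability is `q^2`, `2pq` or `p^2` (with `p`
#' the alternate-allele frequency); log10 probabilities are summed over
#' loci. Missing calls must be imputed beforehand (see
#' [assign_individuals()]).
#'
#' @param calls integer dosage vector (no missing values)
#' @param freqs alternate-allele frequencies in (0, 1), same length
#' @return log10 likelihood.
#' @export
genotype_loglik <- function(calls, freqs) {
  if (anyNA(calls)) stop("impute missing calls before scoring",
                         call. = FALSE)
  if (any(freqs <= 0 | freqs >= 1))
    stop("frequencies must lie strictly in (0, 1) after substitution",
         call. = FALSE)
  lp <- log10(cbind((1 - freqs)^2, 2 * freqs * (1 - freqs), freqs^2))
  sum(lp[cbind(seq_along(calls), calls + 1L)])
}

#' Leave-one-out assignment of individuals to populations
#'
#' Every individual is scored against every population at the chosen
#' level: the home population's frequencies are recomputed without the
#' focal individual (leave-one-out), zero frequencies are replaced by
#' `zero_freq_substitute`, and genotype likelihoods assume HWE. Missing
#' calls are imputed once per analysis by drawing allele pairs from the
#' global allele pool (seeded). The best population is the argmax row
#' likelihood; the home p-value compares the observed home likelihood
#' with `n_null_draws` genotypes simulated from the home leave-one-out
#' frequencies.
#'
#' @param g a [geno_matrix()]
#' @param pops a [pop_map()]
#' @param level `"colony"` or `"cluster"`
#' @param cfg an [assign_config()]
#' @param exclude_from_average population labels excluded from the
#'   reported `accuracy_excluding` summary (e.g. known admixture-zone
#'   colonies)
#' @return object of class `assignment_result`: `individuals` (tibble:
#'   individual_id, home, best, correct, home_p), `loglik` (matrix
#'   individuals x populations, log10), `accuracy` (tibble per population
#'   plus overall rows), `level`, `cfg`.
#' @export
assign_individuals <- function(g, pops, level = c("colony", "cluster"),
                               cfg = assign_config(),
                               exclude_from_average = character()) {
  level <- match.arg(level)
  lab <- group_labels(g, pops, level)
  groups <- sort(unique(lab))
  if (any(table(lab) < 2))
    stop("every population at this level needs >= 2 individuals",
         call. = FALSE)
  n <- n_individuals(g)
  L <- n_loci(g)
  s <- cfg$zero_freq_substitute

  calls <- with_seed(cfg$seed, {
    x <- g$calls
    p_glob <- colMeans(x, na.rm = TRUE) / 2
    if (anyNA(x)) {
      for (j in seq_len(L)) {
        mi <- which(is.na(x[, j]))
        if (length(mi))
          x[mi, j] <- stats::rbinom(length(mi), 2, p_glob[j])
      }
    }
    x
  })

  fm <- freq_by_group(calls, lab)
  counts <- fm$p * 2 * fm$n
  genes <- 2 * fm$n

  # full-population likelihoods for all (individual, population) pairs
  p_full <- substitute_freq(counts / genes, s)
  ll <- matrix(0, n, length(groups), dimnames = list(individuals(g), groups))
  ind0 <- (calls == 0L) + 0
  ind1 <- (calls == 1L) + 0
  ind2 <- (calls == 2L) + 0
  for (k in seq_along(groups)) {
    p <- p_full[groups[k], ]
    ll[, k] <- ind0 %*% (2 * log10(1 - p)) +
      ind1 %*% log10(2 * p * (1 - p)) +
      ind2 %*% (2 * log10(p))
  }
  # overwrite home entries with leave-one-out likelihoods; home p-values
  home_p <- numeric(n)
  with_seed(cfg$seed + 1L, {
    for (i in seq_len(n)) {
      h <- lab[i]
      p_loo <- substitute_freq(
        (counts[h, ] - calls[i, ]) / (genes[h, ] - 2), s)
      ll[i, h] <- genotype_loglik(calls[i, ], p_loo)
      gp <- cbind((1 - p_loo)^2, 2 * p_loo * (1 - p_loo), p_loo^2)
      nulls <- .null_loglik_samples(gp, cfg$n_null_draws)
      home_p[i] <- perm_pvalue(sum(nulls <= ll[i, h]), cfg$n_null_draws)
    }
  })

  best <- groups[max.col(ll, ties.method = "first")]
  ind_tab <- tibble::tibble(
    individual_id = individuals(g), home = lab, best = best,
    correct = best == lab, home_p = home_p)
  per_pop <- dplyr::summarise(
    dplyr::group_by(ind_tab, population = .data$home),
    n = dplyr::n(), accuracy = mean(.data$correct), .groups = "drop")
  keep <- !(ind_tab$home %in% exclude_from_average)
  overall <- tibble::tibble(
    population = c("overall",
                   if (length(exclude_from_average)) "overall_excluding"),
    n = c(n, if (length(exclude_from_average)) sum(keep)),
    accuracy = c(mean(ind_tab$correct),
                 if (length(exclude_from_average))
                   mean(ind_tab$correct[keep])))
  structure(list(individuals = ind_tab, loglik = ll,
                 accuracy = dplyr::bind_rows(per_pop, overall),
                 level = level, cfg = cfg),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  ov <- x$accuracy$accuracy[x$accuracy$population == "overall"]
  cat(sprintf("<assignment_result> %s level: %.1f%% correctly assigned\n",
              x$level, 100 * ov))
  invisible(x)
}

#' Tidy per-individual assignments
#' @param x an `assignment_result`
#' @param ... unused
#' @return tibble with one row per individual.
#' @export
tidy.assignment_result <- function(x, ...) x$individuals

#' One-row assignment summary
#' @param x an `assignment_result`
#' @param ... unused
#' @return tibble with overall accuracy and the significant-home fraction.
#' @export
glance.assignment_result <- function(x, ...) {
  tibble::tibble(
    level = x$level,
    n = nrow(x$individuals),
    accuracy = mean(x$individuals$correct),
    prop_home_rejected = mean(x$individuals$home_p < x$cfg$alpha))
}

#' Assignment accuracy across locus panels
#'
#' Runs [assign_individuals()] on each locus subset and reports accuracy
#' per panel (e.g. all loci, a random subset, an outlier panel).
#'
#' @param g a [geno_matrix()]
#' @param pops a [pop_map()]
#' @param panels named list of locus-ID vectors
#' @param level `"colony"` or `"cluster"`
#' @param cfg an [assign_config()]
#' @return tibble with `panel`, `n_loci`, `accuracy`; attribute `results`
#'   holds the full per-panel `assignment_result`s.
#' @export
panel_assign <- function(g, pops, panels, level = c("colony", "cluster"),
                         cfg = assign_config()) {
  level <- match.arg(level)
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    stop("panels must be named", call. = FALSE)
  if (anyDuplicated(names(panels)))
    stop("duplicated panel names", call. = FALSE)
  results <- purrr::imap(panels, function(ids, nm) {
    if (!length(ids)) stop("empty panel: ", nm, call. = FALSE)
    missing_ids <- setdiff(ids, g$loci$locus_id)
    if (length(missing_ids))
      stop("panel ", nm, " names loci absent from the data", call. = FALSE)
    assign_individuals(g[, match(ids, g$loci$locus_id)], pops,
                       level = level, cfg = cfg)
  })
  out <- dplyr::bind_rows(purrr::imap(results, function(r, nm) {
    tibble::tibble(panel = nm, n_loci = length(panels[[nm]]),
                   accuracy = mean(r$individuals$correct))
  }))
  attr(out, "results") <- results
  out
}
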