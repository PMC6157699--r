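#' Alternate-allele frequencies per group
#'
#' Frequencies are computed from non-missing calls only. A group with no
#' non-missing call at a locus gets `NA` and `undefined = TRUE`.
#'
#' @param g a [geno_matrix()]
#' @param pops a [pop_map()]
#' @param level `"colony"`, `"cluster"` or `"global"`
#' @return tibble with columns `group`, `locus_id`, `n` (non-missing
#'   individuals), `freq`, `undefined`.
#' @export
allele_freqs <- function(g, pops, level = c("colony", "cluster", "global")) {
  level <- match.arg(level)
  lab <- group_labels(g, pops, level)
  fm <- freq_by_group(g$calls, lab)
  tibble::tibble(
    group = rep(rownames(fm$p), times = ncol(fm$p)),
    locus_id = rep(colnames(g$calls), each = nrow(fm$p)),
    n = as.integer(fm$n),
    freq = as.numeric(fm$p),
    undefined = as.integer(fm$n) == 0L
  )
}

# per-group count matrices: n (non-missing individuals), p (alt freq),
# h (observed het fraction); groups x loci
freq_by_group <- function(calls, labels) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  ok <- !is.na(calls)
  n <- rowsum(ok + 0, labels)               # groups x loci
  x <- calls; x[!ok] <- 0L
  s <- rowsum(x + 0, labels)
  het <- rowsum((ok & calls == 1L) + 0, labels)
  p <- ifelse(n > 0, s / (2 * n), NA_real_)
  h <- ifelse(n > 0, het / n, NA_real_)
  rownames(p) <- rownames(h) <- rownames(n) <- groups
  list(n = n, p = p, h = h, groups = groups)
}

#' Observed and expected heterozygosity per group
#'
#' Per locus, `Ho` is the fraction of heterozygous non-missing calls and
#' `He` the unbiased gene diversity `2n/(2n-1) * 2p(1-p)` with `n` the
#' non-missing individuals; group values are means across loci with at
#' least one non-missing call.
#'
#' @inheritParams allele_freqs
#' @return tibble with columns `group`, `n` (median individuals genotyped
#'   per locus), `Ho`, `He`.
#' @export
heterozygosity <- function(g, pops, level = c("colony", "cluster", "global")) {
  level <- match.arg(level)
  lab <- group_labels(g, pops, level)
  fm <- freq_by_group(g$calls, lab)
  he <- ifelse(fm$n >= 1, (2 * fm$n) / (2 * fm$n - 1) * 2 * fm$p * (1 - fm$p),
               NA_real_)
  he[fm$n == 1 & !is.na(fm$p)] <- 2 * fm$p[fm$n == 1 & !is.na(fm$p)] *
    (1 - fm$p[fm$n == 1 & !is.na(fm$p)])  # n = 1: no unbiased correction
  tibble::tibble(
    group = fm$groups,
    n = as.integer(vapply(fm$groups, function(gr) sum(lab == gr), 1L)),
    Ho = unname(rowMeans(fm$h, na.rm = TRUE)),
    He = unname(rowMeans(he, na.rm = TRUE))
  )
}

#' Inbreeding coefficient with a permutation test
#'
#' `FIS = 1 - Ho/He` on multilocus means. The null distribution re-pairs
#' gametes: within the group, the non-missing alleles of each locus are
#' permuted among individuals and re-paired, which leaves `He` unchanged
#' and resamples `Ho`. p is the fraction of permuted `|FIS|` at least as
#' large as observed, with (k+1)/(n+1) smoothing.
#'
#' @param g a [geno_matrix()]
#' @param pops a [pop_map()]
#' @param group group label at `level`
#' @param level `"colony"` or `"cluster"`
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return tibble with `group`, `FIS`, `p`, `n_perm`.
#' @export
fis_test <- function(g, pops, group, level = c("colony", "cluster"),
                     n_perm = 1000L, seed = 1L) {
  level <- match.arg(level)
  lab <- group_labels(g, pops, level)
  rows <- which(lab == group)
  if (length(rows) < 2) stop("group needs >= 2 individuals", call. = FALSE)
  cc <- g$calls[rows, , drop = FALSE]
  fm <- freq_by_group(cc, rep(group, length(rows)))
  n <- fm$n[1, ]; p <- fm$p[1, ]
  he <- ifelse(n >= 2, (2 * n) / (2 * n - 1) * 2 * p * (1 - p), NA_real_)
  ho_loc <- fm$h[1, ]
  mean_he <- mean(he, na.rm = TRUE)
  if (!is.finite(mean_he) || mean_he == 0)
    return(tibble::tibble(group = group, FIS = NA_real_, p = NA_real_,
                          n_perm = n_perm))
  fis_obs <- 1 - mean(ho_loc, na.rm = TRUE) / mean_he
  alleles <- lapply(seq_len(ncol(cc)), function(j) {
    x <- cc[!is.na(cc[, j]), j]
    if (!length(x)) return(NULL)
    c(rep(0L, sum(2L - x)), rep(1L, sum(x)))  # gene copies
  })
  perm_fis <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    ho_b <- vapply(alleles, function(al) {
      if (is.null(al)) return(NA_real_)
      al <- sample(al)
      m <- length(al) %/% 2
      mean(al[2 * seq_len(m) - 1] != al[2 * seq_len(m)])
    }, numeric(1))
    1 - mean(ho_b, na.rm = TRUE) / mean_he
  }, numeric(1)))
  p_val <- perm_pvalue(sum(abs(perm_fis) >= abs(fis_obs)), n_perm)
  tibble::tibble(group = group, FIS = fis_obs, p = p_val, n_perm = n_perm)
}

#' Diversity table per colony and cluster
#'
#' Sample sizes, mean observed and unbiased expected heterozygosity, and
#' FIS with its permutation p-value, for every colony and every cluster.
#'
#' @inheritParams fis_test
#' @return tibble with `level`, `group`, `n`, `Ho`, `He`, `FIS`, `FIS_p`.
#' @export
diversity_table <- function(g, pops, n_perm = 1000L, seed = 1L) {
  out <- lapply(c("cluster", "colony"), function(lv) {
    het <- heterozygosity(g, pops, lv)
    fis <- dplyr::bind_rows(lapply(seq_along(het$group), function(i) {
      fis_test(g, pops, het$group[i], lv, n_perm = n_perm, seed = seed + i)
    }))
    dplyr::mutate(
      dplyr::left_join(het,
                       dplyr::select(fis, "group", FIS = "FIS", FIS_p = "p"),
                       by = "group"),
      level = lv, .before = 1)
  })
  dplyr::bind_rows(out)
}

# Weir & Cockerham (1984) per-locus variance components a, b, c for r
# groups; rows with any empty group are NA.
wc_components <- function(calls, labels) {
  fm <- freq_by_group(calls, labels)
  r <- length(fm$groups)
  n <- fm$n; p <- fm$p; h <- fm$h
  ok <- colSums(n > 0) == r
  nbar <- colMeans(n)
  nc <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- !ok | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  list(a = a, b = b, c = cc)
}

# ratio-of-sums multilocus theta from components
theta_from_components <- function(comp) {
  den <- comp$a + comp$b + comp$c
  use <- !is.na(den)
  if (!any(use) || sum(den[use]) == 0) return(NA_real_)
  sum(comp$a[use]) / sum(den[use])
}

#' Weir-Cockerham FST between two colonies
#'
#' Multilocus theta combines per-locus variance components by ratio of
#' sums; negative estimates are not clamped. Significance by permuting
#' individuals between the two colonies; p is the smoothed fraction of
#' permuted theta at least as large as observed.
#'
#' @param g a [geno_matrix()]
#' @param pops a [pop_map()]
#' @param colony_a,colony_b colony codes (order does not matter)
#' @param n_perm permutations (0 skips the test)
#' @param seed integer seed
#' @return list with `theta` (multilocus), `per_locus` (tibble of locus,
#'   a, b, c, theta), `p`, `n_perm`.
#' @export
wc_fst <- function(g, pops, colony_a, colony_b, n_perm = 0L, seed = 1L) {
  pair <- sort(c(colony_a, colony_b))
  lab <- group_labels(g, pops, "colony")
  rows <- which(lab %in% pair)
  if (length(rows) < 4) stop("both colonies need >= 2 individuals",
                             call. = FALSE)
  cc <- g$calls[rows, , drop = FALSE]
  lab2 <- lab[rows]
  comp <- wc_components(cc, lab2)
  theta <- theta_from_components(comp)
  if (is.na(theta)) stop("no locus with a defined FST denominator",
                         call. = FALSE)
  den <- comp$a + comp$b + comp$c
  per_locus <- tibble::tibble(
    locus_id = colnames(cc), a = unname(comp$a), b = unname(comp$b),
    c = unname(comp$c),
    theta = unname(ifelse(!is.na(den) & den != 0, comp$a / den, NA_real_)))
  p_val <- NA_real_
  if (n_perm > 0) {
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      theta_from_components(wc_components(cc, sample(lab2)))
    }, numeric(1)))
    p_val <- perm_pvalue(sum(perm >= theta, na.rm = TRUE), n_perm)
  }
  list(theta = theta, per_locus = per_locus, p = p_val, n_perm = n_perm)
}

#' All pairwise colony FST values
#'
#' @inheritParams wc_fst
#' @return object of class `fst_matrix`: list with symmetric matrices
#'   `theta`, `linearized` (Slatkin `theta/(1-theta)`), `p`, and the tidy
#'   pair table `pairs`.
#' @export
pairwise_fst <- function(g, pops, n_perm = 0L, seed = 1L) {
  cols <- sort(unique(group_labels(g, pops, "colony")))
  k <- length(cols)
  th <- pv <- matrix(0, k, k, dimnames = list(cols, cols))
  diag(pv) <- NA_real_
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    f <- wc_fst(g, pops, cols[i], cols[j], n_perm = n_perm,
                seed = seed + 1000L * i + j)
    th[i, j] <- th[j, i] <- f$theta
    pv[i, j] <- pv[j, i] <- f$p
    pairs[[length(pairs) + 1L]] <- tibble::tibble(
      colony_a = cols[i], colony_b = cols[j], theta = f$theta,
      linearized = linearize_fst(f$theta), p = f$p)
  }
  structure(list(theta = th, linearized = linearize_fst(th), p = pv,
                 pairs = dplyr::bind_rows(pairs)),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("<fst_matrix> pairwise Weir-Cockerham theta\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pairwise FST matrix
#' @param x an `fst_matrix`
#' @param ... unused
#' @return tibble with one row per colony pair.
#' @export
tidy.fst_matrix <- function(x, ...) x$pairs

#' Slatkin's linearized FST
#'
#' `theta / (1 - theta)`, linear in divergence time under pure drift.
#' Negative inputs pass through with their sign; `theta = 1` maps to `Inf`.
#'
#' @param theta FST value(s), `theta <= 1`
#' @return transformed value(s).
#' @export
linearize_fst <- function(theta) {
  if (any(theta > 1, na.rm = TRUE))
    stop("FST cannot exceed 1", call. = FALSE)
  ifelse(theta == 1, Inf, theta / (1 - theta))
}

#' Mantel test between two distance matrices
#'
#' Pearson matrix correlation with a one-sided permutation test (joint
#' row/column relabelling of `B`), delegated to [vegan::mantel()]; the
#' reported p uses (k+1)/(n+1) smoothing.
#'
#' @param A,B symmetric matrices with zero diagonals and matching labels
#'   (when dimnames are present, `B` is reordered to match `A`)
#' @param n_perm permutations
#' @param seed integer seed
#' @return tibble of class `mantel_result` with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(A, B, n_perm = 999L, seed = 1L) {
  stopifnot(is.matrix(A), is.matrix(B), nrow(A) == ncol(A),
            nrow(B) == ncol(B), nrow(A) == nrow(B))
  if (max(abs(diag(A)), abs(diag(B))) > 1e-12)
    stop("distance matrices must have zero diagonals", call. = FALSE)
  if (!is.null(rownames(A)) && !is.null(rownames(B))) {
    if (!setequal(rownames(A), rownames(B)))
      stop("matrix labels do not match", call. = FALSE)
    B <- B[rownames(A), rownames(A)]
  }
  lo <- lower.tri(A)
  if (stats::sd(A[lo]) == 0 || stats::sd(B[lo]) == 0) {
    out <- tibble::tibble(r = NA_real_, p = NA_real_, n_perm = n_perm,
                          undefined = TRUE)
    class(out) <- c("mantel_result", class(out))
    return(out)
  }
  m <- with_seed(seed,
                 vegan::mantel(stats::as.dist(A), stats::as.dist(B),
                               method = "pearson", permutations = n_perm))
  out <- tibble::tibble(r = unname(m$statistic), p = m$signif,
                        n_perm = n_perm, undefined = FALSE)
  class(out) <- c("mantel_result", class(out))
  out
}

#' Isolation-by-distance test
#'
#' Mantel test of Slatkin-linearized pairwise FST against great-circle
#' geographic distance between colonies.
#'
#' @param fst an `fst_matrix` from [pairwise_fst()]
#' @param pops a [pop_map()] with colony coordinates
#' @inheritParams mantel_test
#' @return a `mantel_result` tibble.
#' @export
ibd_test <- function(fst, pops, n_perm = 999L, seed = 1L) {
  geo <- colony_distances(pops)
  mantel_test(fst$linearized, geo[rownames(fst$linearized),
                                  rownames(fst$linearized)],
              n_perm = n_perm, seed = seed)
}

#' Concordance between two marker sets
#'
#' Pearson correlation of per-colony expected heterozygosities and a
#' Mantel test of the two pairwise-FST matrices, as used to compare
#' microsatellite- and SNP-derived estimates.
#'
#' @param he_a,he_b named numeric vectors of per-colony He (matched labels)
#' @param fst_a,fst_b symmetric pairwise FST matrices (matched labels)
#' @param n_perm Mantel permutations
#' @param seed integer seed
#' @return tibble with `pearson_r`, `pearson_p`, `mantel_r`, `mantel_p`.
#' @export
marker_concordance <- function(he_a, he_b, fst_a, fst_b, n_perm = 999L,
                               seed = 1L) {
  if (!is.null(names(he_a)) && !is.null(names(he_b))) {
    if (!setequal(names(he_a), names(he_b)))
      stop("He vectors have mismatched colony labels", call. = FALSE)
    he_b <- he_b[names(he_a)]
  } else if (length(he_a) != length(he_b)) {
    stop("He vectors have mismatched lengths", call. = FALSE)
  }
  if (stats::sd(he_a) == 0 || stats::sd(he_b) == 0) {
    pr <- pp <- NA_real_
  } else {
    ct <- stats::cor.test(he_a, he_b)
    pr <- unname(ct$estimate); pp <- ct$p.value
  }
  mt <- mantel_test(fst_a, fst_b, n_perm = n_perm, seed = seed)
  tibble::tibble(pearson_r = pr, pearson_p = pp,
                 mantel_r = mt$r, mantel_p = mt$p)
}

#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are mean-imputed per locus, columns are centred at twice
#' the allele frequency, and the individual-by-individual covariance matrix
#' is eigendecomposed. Scores are deterministic up to sign.
#'
#' @param g a [geno_matrix()]
#' @param n_components number of components to return
#' @return object of class `geno_pca`: list with `scores` (tibble),
#'   `explained` (variance fractions) and `values` (eigenvalues).
#' @export
pca_genotypes <- function(g, n_components = 2L) {
  if (n_individuals(g) < 2) stop("PCA needs >= 2 individuals", call. = FALSE)
  x <- g$calls
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, mu)
  cv <- tcrossprod(x) / max(1, ncol(x) - 1)
  e <- eigen(cv, symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * 1e-10)
  if (n_components > rank) {
    warning("n_components exceeds rank; truncated to ", rank)
    n_components <- rank
  }
  vals <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(n_components)]), n_components)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(
    scores = dplyr::bind_cols(
      tibble::tibble(individual_id = individuals(g)),
      tibble::as_tibble(scores)),
    explained = vals[seq_len(n_components)] / sum(vals),
    values = vals
  ), class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d individuals; explained: %s\n",
              nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Tidy PCA scores
#' @param x a `geno_pca`
#' @param ... unused
#' @return tibble of individual scores.
#' @export
tidy.geno_pca <- function(x, ...) x$scores
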