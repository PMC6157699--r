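# Independent oracles used to check the package's estimators.

# Hardy-Weinberg exact test by direct factorial enumeration of every
# genotype configuration consistent with the observed allele counts.
oracle_hwe_exact <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  config_prob <- function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(na) -
          lfactorial(2 * n))
  }
  hs <- seq(if (nA %% 2 == 0) 0 else 1, min(nA, na), by = 2)
  probs <- vapply(hs, config_prob, numeric(1))
  p_obs <- probs[match(n_Aa, hs)]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# Weir & Cockerham (1984) a, b, c for one locus, scalar transliteration.
oracle_wc_abc <- function(dosages, labels) {
  keep <- !is.na(dosages)
  dosages <- dosages[keep]; labels <- labels[keep]
  pops <- unique(labels)
  r <- length(pops)
  n_i <- sapply(pops, function(g) sum(labels == g))
  if (any(n_i == 0)) return(c(a = NA, b = NA, c = NA))
  p_i <- sapply(pops, function(g) mean(dosages[labels == g]) / 2)
  h_i <- sapply(pops, function(g) mean(dosages[labels == g] == 1))
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

oracle_wc_theta <- function(calls, labels) {
  comps <- t(apply(calls, 2, oracle_wc_abc, labels = labels))
  ok <- stats::complete.cases(comps)
  sum(comps[ok, "a"]) / sum(comps[ok, ])
}

# Three-level AMOVA via centroid deviations (not pairwise distances):
# sums of squares about grand/group/colony centroids on mean-imputed
# dosage vectors.
oracle_amova <- function(calls, colony, group) {
  x <- calls
  for (j in seq_len(ncol(x))) {
    mu <- mean(x[, j], na.rm = TRUE)
    x[is.na(x[, j]), j] <- mu
  }
  N <- nrow(x)
  dev2 <- function(rows, center) {
    sum(sweep(x[rows, , drop = FALSE], 2, center)^2)
  }
  grand <- colMeans(x)
  ss_t <- dev2(seq_len(N), grand)
  pops_u <- unique(colony); groups_u <- unique(group)
  ss_wp <- sum(sapply(pops_u, function(p0) {
    rows <- which(colony == p0)
    dev2(rows, colMeans(x[rows, , drop = FALSE]))
  }))
  ss_wg <- sum(sapply(groups_u, function(g0) {
    rows <- which(group == g0)
    dev2(rows, colMeans(x[rows, , drop = FALSE]))
  }))
  ss_ag <- ss_t - ss_wg
  ss_ap <- ss_wg - ss_wp
  P <- length(pops_u); G <- length(groups_u)
  n_p <- sapply(pops_u, function(p0) sum(colony == p0))
  n_g <- sapply(groups_u, function(g0) sum(group == g0))
  grp_of <- sapply(pops_u, function(p0) group[colony == p0][1])
  sig_c <- ss_wp / (N - P)
  n_coef <- (N - sum(sapply(groups_u, function(g0)
    sum(n_p[grp_of == g0]^2) / n_g[groups_u == g0]))) / (P - G)
  sig_b <- (ss_ap / (P - G) - sig_c) / n_coef
  n1 <- (sum(sapply(groups_u, function(g0)
    sum(n_p[grp_of == g0]^2) / n_g[groups_u == g0])) - sum(n_p^2) / N) /
    (G - 1)
  n2 <- (N - sum(n_g^2) / N) / (G - 1)
  sig_a <- (ss_ag / (G - 1) - sig_c - n1 * sig_b) / n2
  list(ss = c(ss_ag, ss_ap, ss_wp, ss_t),
       variance = c(sig_a, sig_b, sig_c))
}

# Benjamini-Hochberg step-up by the textbook formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
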