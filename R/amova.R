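#' Hierarchical analysis of molecular variance
#'
#' Three-level AMOVA (among groups of colonies, among colonies within
#' groups, within colonies) on squared alternate-allele-dosage differences
#' summed over loci, using the standard nested sums-of-squares
#' decomposition. Missing dosages are mean-imputed per locus before
#' distances are formed. Phi statistics and permutation p-values are
#' reported: individuals are permuted among colonies (within groups for
#' Phi_SC, across the whole data for Phi_ST) and whole colonies among
#' groups for Phi_CT.
#'
#' @param g a [geno_matrix()]
#' @param pops a [pop_map()]
#' @param grouping named character vector mapping colony code to group
#'   label; defaults to the cluster assignment in `pops`
#' @param n_perm permutations (0 skips the tests)
#' @param seed integer seed
#' @return object of class `amova_result`: list with `components` (tibble:
#'   source, df, sum_sq, variance, percent), `phi` (tibble: statistic,
#'   value, p).
#' @export
amova <- function(g, pops, grouping = NULL, n_perm = 0L, seed = 1L) {
  colony <- group_labels(g, pops, "colony")
  if (is.null(grouping)) {
    grouping <- stats::setNames(pops$colonies$cluster, pops$colonies$colony)
  }
  if (!all(colony %in% names(grouping)))
    stop("grouping must cover every colony", call. = FALSE)
  group <- unname(grouping[colony])
  if (length(unique(group)) < 2)
    stop("AMOVA needs >= 2 groups", call. = FALSE)

  x <- g$calls
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  d2 <- as.matrix(stats::dist(x))^2

  obs <- amova_decompose(d2, colony, group)

  phi_p <- c(Phi_CT = NA_real_, Phi_SC = NA_real_, Phi_ST = NA_real_)
  if (n_perm > 0) {
    perms <- with_seed(seed, {
      st <- sc <- ct <- numeric(n_perm)
      colonies_of_group <- split(unique(colony),
                                 grouping[unique(colony)])
      for (b in seq_len(n_perm)) {
        # Phi_ST: individuals among colonies, whole data
        cs <- sample(colony)
        st[b] <- amova_decompose(d2, cs, unname(grouping[cs]))$phi["Phi_ST"]
        # Phi_SC: individuals among colonies within groups
        cs2 <- colony
        for (grp in names(colonies_of_group)) {
          idx <- which(group == grp)
          cs2[idx] <- sample(colony[idx])
        }
        sc[b] <- amova_decompose(d2, cs2, group)$phi["Phi_SC"]
        # Phi_CT: colonies among groups
        ucol <- unique(colony)
        perm_map <- stats::setNames(
          sample(unname(grouping[ucol])), ucol)
        ct[b] <- amova_decompose(d2, colony,
                                 unname(perm_map[colony]))$phi["Phi_CT"]
      }
      list(st = st, sc = sc, ct = ct)
    })
    phi_p <- c(
      Phi_CT = perm_pvalue(sum(perms$ct >= obs$phi["Phi_CT"], na.rm = TRUE),
                           n_perm),
      Phi_SC = perm_pvalue(sum(perms$sc >= obs$phi["Phi_SC"], na.rm = TRUE),
                           n_perm),
      Phi_ST = perm_pvalue(sum(perms$st >= obs$phi["Phi_ST"], na.rm = TRUE),
                           n_perm))
  }

  structure(list(
    components = obs$components,
    phi = tibble::tibble(
      statistic = c("Phi_CT", "Phi_SC", "Phi_ST"),
      value = unname(obs$phi[c("Phi_CT", "Phi_SC", "Phi_ST")]),
      p = unname(phi_p[c("Phi_CT", "Phi_SC", "Phi_ST")])),
    n_perm = n_perm
  ), class = "amova_result")
}

# nested sums-of-squares decomposition on a squared-distance matrix
amova_decompose <- function(d2, colony, group) {
  N <- nrow(d2)
  pops_u <- unique(colony)
  P <- length(pops_u)
  groups_u <- unique(group)
  G <- length(groups_u)
  ss_of <- function(idx) if (length(idx) < 2) 0 else
    sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  ss_t <- ss_of(seq_len(N))
  ss_wp <- sum(vapply(pops_u, function(p0) ss_of(which(colony == p0)),
                      numeric(1)))
  ss_wg <- sum(vapply(groups_u, function(g0) ss_of(which(group == g0)),
                      numeric(1)))
  ss_ag <- ss_t - ss_wg
  ss_ap <- ss_wg - ss_wp
  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- N - P
  n_p <- vapply(pops_u, function(p0) sum(colony == p0), numeric(1))
  grp_of_pop <- vapply(pops_u, function(p0) group[colony == p0][1],
                       character(1))
  n_g <- vapply(groups_u, function(g0) sum(group == g0), numeric(1))
  names(n_g) <- groups_u
  # expected-mean-square coefficients (Excoffier's n, n', n'')
  n_coef <- if (df_ap > 0)
    (N - sum(vapply(groups_u, function(g0)
      sum(n_p[grp_of_pop == g0]^2) / n_g[g0], numeric(1)))) / df_ap
  else NA_real_
  n1 <- (sum(vapply(groups_u, function(g0)
    sum(n_p[grp_of_pop == g0]^2) / n_g[g0], numeric(1))) -
      sum(n_p^2) / N) / df_ag
  n2 <- (N - sum(n_g^2) / N) / df_ag
  ms_wp <- ss_wp / df_wp
  sig_c <- ms_wp
  sig_b <- if (df_ap > 0) (ss_ap / df_ap - sig_c) / n_coef else 0
  sig_a <- (ss_ag / df_ag - sig_c - n1 * sig_b) / n2
  tot <- sig_a + sig_b + sig_c
  phi <- c(Phi_CT = sig_a / tot,
           Phi_SC = if (df_ap > 0) sig_b / (sig_b + sig_c) else NA_real_,
           Phi_ST = (sig_a + sig_b) / tot)
  if (tot == 0) phi[] <- c(0, if (df_ap > 0) 0 else NA_real_, 0)
  list(
    components = tibble::tibble(
      source = c("among_groups", "among_colonies_within_groups",
                 "within_colonies", "total"),
      df = c(df_ag, df_ap, df_wp, N - 1),
      sum_sq = c(ss_ag, ss_ap, ss_wp, ss_t),
      variance = c(sig_a, sig_b, sig_c, tot),
      percent = if (tot == 0) c(0, 0, 0, 100)
                else 100 * c(sig_a, sig_b, sig_c, tot) / tot),
    phi = phi)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  print(as.data.frame(x$components))
  print(as.data.frame(x$phi))
  invisible(x)
}

#' Tidy AMOVA variance components
#' @param x an `amova_result`
#' @param ... unused
#' @return tibble of variance components.
#' @export
tidy.amova_result <- function(x, ...) x$components

#' One-row AMOVA summary
#' @param x an `amova_result`
#' @param ... unused
#' @return tibble with the three Phi statistics and their p-values.
#' @export
glance.amova_result <- function(x, ...) {
  tidyr::pivot_wider(x$phi, names_from = "statistic",
                     values_from = c("value", "p"))
}
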