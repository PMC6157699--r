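# Small in-code fixtures shared across test files.

toy_geno <- function(calls, colonies, clusters = NULL, lat = NULL,
                     lon = NULL) {
  g <- geno_matrix(calls)
  ucol <- unique(colonies)
  if (is.null(clusters)) clusters <- stats::setNames(ucol, ucol)
  col_tab <- tibble::tibble(colony = ucol,
                            cluster = unname(clusters[ucol]))
  if (!is.null(lat)) { col_tab$lat <- lat; col_tab$lon <- lon }
  pops <- pop_map(
    tibble::tibble(individual_id = individuals(g), colony = colonies),
    col_tab)
  list(g = g, pops = pops)
}

# two colonies fixed for opposite alleles
fixed_pair_fixture <- function(n_per = 10, n_loci = 20) {
  calls <- rbind(matrix(0L, n_per, n_loci), matrix(2L, n_per, n_loci))
  rownames(calls) <- sprintf("i%02d", seq_len(2 * n_per))
  toy_geno(calls, rep(c("A", "B"), each = n_per))
}

# Balding-Nichols two-cluster fixture with a given drift F
two_cluster_fixture <- function(f, n_per = 20, n_loci = 300, seed = 1) {
  cols <- tibble::tibble(
    colony = c("N1", "N2", "S1", "S2"),
    cluster = rep(c("North", "South"), each = 2),
    n = n_per, lat = c(-41, -42, -46, -45.5),
    lon = c(172, 173, 169, 170),
    f_colony = 1e-4, admix_weight = NA_real_)
  generate_study(synth_config(
    colonies = cols, n_loci = n_loci, f_cluster = f,
    admix_between = c("North", "South"), missing_rate = 0, seed = seed))
}
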