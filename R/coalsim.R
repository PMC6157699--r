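#' Demographic scenario parameters for the two-bottleneck history
#'
#' Parameter set for the recolonization history of the New Zealand fur
#' seal: a very large pre-human population, a decline to a historical size
#' after Polynesian hunting, a collapse into a single small refugium after
#' European sealing, and post-sealing recolonization with divergence into a
#' northern and a southern population. Sizes are diploid effective sizes;
#' times are generations before present.
#'
#' Required orderings: `t_Polynesian > t_Europeans > t_post_seal`, and the
#' pre-human size must exceed both contemporary sizes.
#'
#' @param Ne_NZ_S,Ne_NZ_N contemporary effective sizes of the southern and
#'   northern populations
#' @param Ne_refugium effective size of the post-sealing refugium
#' @param Ne_historical_NZ effective size between the two declines
#' @param Ne_pre_historical pre-human effective size
#' @param t_Polynesian,t_Europeans,t_post_seal event times (generations)
#' @return list of class `scenario_params`.
#' @export
scenario_params <- function(Ne_NZ_S, Ne_NZ_N, Ne_refugium, Ne_historical_NZ,
                            Ne_pre_historical, t_Polynesian, t_Europeans,
                            t_post_seal) {
  p <- list(Ne_NZ_S = Ne_NZ_S, Ne_NZ_N = Ne_NZ_N, Ne_refugium = Ne_refugium,
            Ne_historical_NZ = Ne_historical_NZ,
            Ne_pre_historical = Ne_pre_historical,
            t_Polynesian = t_Polynesian, t_Europeans = t_Europeans,
            t_post_seal = t_post_seal)
  if (any(unlist(p[1:5]) <= 0)) stop("effective sizes must be positive",
                                     call. = FALSE)
  if (!(p$t_Europeans > p$t_post_seal))
    stop("condition violated: t_Europeans > t_post_seal", call. = FALSE)
  if (!(p$t_Polynesian > p$t_Europeans))
    stop("condition violated: t_Polynesian > t_Europeans", call. = FALSE)
  if (!(p$Ne_pre_historical > p$Ne_NZ_N))
    stop("condition violated: Ne_pre_historical > Ne_NZ_N", call. = FALSE)
  if (!(p$Ne_pre_historical > p$Ne_NZ_S))
    stop("condition violated: Ne_pre_historical > Ne_NZ_S", call. = FALSE)
  structure(p, class = "scenario_params")
}

#' Build the two-decline demographic scenario
#'
#' Backward in time: two isolated demes (north, south) of sizes
#' `Ne_NZ_N`, `Ne_NZ_S` until `t_post_seal`, where they merge into the
#' refugium deme of size `Ne_refugium`; at `t_Europeans` the ancestral size
#' becomes `Ne_historical_NZ`, and at `t_Polynesian` it becomes
#' `Ne_pre_historical` (extending to infinity).
#'
#' @param p a [scenario_params()] (or plain list with the same fields)
#' @param n_N,n_S diploid sample sizes of the north and south demes
#' @param generation_time_years used only to annotate reports in years
#' @return object of class `demographic_scenario`.
#' @export
build_two_decline_scenario <- function(p, n_N, n_S,
                                       generation_time_years = 7) {
  if (!inherits(p, "scenario_params")) p <- do.call(scenario_params, p)
  new_scenario(
    name = "two_decline",
    n_N = n_N, n_S = n_S,
    N_N = p$Ne_NZ_N, N_S = p$Ne_NZ_S,
    epoch_t = c(p$t_post_seal, p$t_Europeans, p$t_Polynesian),
    epoch_N = c(p$Ne_refugium, p$Ne_historical_NZ, p$Ne_pre_historical),
    generation_time_years = generation_time_years)
}

#' Build the constant-size null scenario
#'
#' The same population divergence at `t_post_seal`, but a single ancestral
#' deme of constant size `Ne_constant` with no earlier size changes.
#'
#' @param Ne_constant constant ancestral effective size
#' @param Ne_NZ_N,Ne_NZ_S contemporary deme sizes
#' @param t_post_seal divergence time (generations)
#' @inheritParams build_two_decline_scenario
#' @return object of class `demographic_scenario`.
#' @export
build_null_scenario <- function(Ne_constant, Ne_NZ_N, Ne_NZ_S, t_post_seal,
                                n_N, n_S, generation_time_years = 7) {
  new_scenario(
    name = "null",
    n_N = n_N, n_S = n_S, N_N = Ne_NZ_N, N_S = Ne_NZ_S,
    epoch_t = t_post_seal, epoch_N = Ne_constant,
    generation_time_years = generation_time_years)
}

new_scenario <- function(name, n_N, n_S, N_N, N_S, epoch_t, epoch_N,
                         generation_time_years) {
  if (any(c(N_N, N_S, epoch_N) <= 0))
    stop("effective sizes must be positive", call. = FALSE)
  if (any(diff(epoch_t) <= 0))
    stop("event times must be strictly increasing backward in time",
         call. = FALSE)
  if (epoch_t[1] <= 0) stop("divergence time must be positive", call. = FALSE)
  structure(list(name = name, n_N = n_N, n_S = n_S, N_N = N_N, N_S = N_S,
                 epoch_t = as.numeric(epoch_t), epoch_N = as.numeric(epoch_N),
                 generation_time_years = generation_time_years),
            class = "demographic_scenario")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat(sprintf("<demographic_scenario> %s: samples %d + %d diploids\n",
              x$name, x$n_N, x$n_S))
  cat(sprintf("  [0, %.4g) gens: demes N_N = %.4g, N_S = %.4g\n",
              x$epoch_t[1], x$N_N, x$N_S))
  for (e in seq_along(x$epoch_t)) {
    to <- if (e < length(x$epoch_t)) sprintf("%.4g", x$epoch_t[e + 1])
          else "Inf"
    cat(sprintf("  [%.4g, %s) gens (%.0f yr): ancestral N = %.4g\n",
                x$epoch_t[e], to,
                x$epoch_t[e] * x$generation_time_years, x$epoch_N[e]))
  }
  invisible(x)
}

#' Coalescent simulation configuration
#'
#' @param n_loci number of unlinked SNP loci
#' @param min_maf_pooled pooled-sample minor-allele-frequency ascertainment
#'   threshold (Hudson-style SNP selection); in `[0, 0.5)`
#' @param max_redraws_per_locus cap on whole-locus rejection redraws
#' @param seed integer seed (`NULL` to use the current RNG stream)
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 1000L, min_maf_pooled = 0.05,
                       max_redraws_per_locus = 10000L, seed = NULL) {
  if (min_maf_pooled < 0 || min_maf_pooled >= 0.5)
    stop("min_maf_pooled must lie in [0, 0.5)", call. = FALSE)
  structure(list(n_loci = as.integer(n_loci),
                 min_maf_pooled = min_maf_pooled,
                 max_redraws_per_locus = as.integer(max_redraws_per_locus),
                 seed = seed),
            class = "sim_config")
}

# raw dosage matrix (individuals x loci), deme-1 rows first
sim_scenario_matrix <- function(s, cfg) {
  .sim_two_deme_genotypes(s$n_N, s$n_S, s$N_N, s$N_S, s$epoch_t, s$epoch_N,
                          cfg$n_loci, cfg$min_maf_pooled,
                          cfg$max_redraws_per_locus)
}

#' Simulate one SNP locus under a demographic scenario
#'
#' A single Kingman coalescent tree with one mutation placed proportional
#' to branch length, redrawn until the pooled minor allele frequency
#' reaches `min_maf_pooled`.
#'
#' @param s a `demographic_scenario`
#' @param min_maf_pooled,max_redraws ascertainment settings
#' @param seed integer seed or `NULL`
#' @return tibble with one row per diploid individual: `deme`, `dosage`.
#' @export
simulate_locus <- function(s, min_maf_pooled = 0.05, max_redraws = 10000L,
                           seed = NULL) {
  m <- with_seed(seed, .sim_two_deme_genotypes(
    s$n_N, s$n_S, s$N_N, s$N_S, s$epoch_t, s$epoch_N, 1L,
    min_maf_pooled, max_redraws))
  tibble::tibble(
    deme = rep(c("NZ-N", "NZ-S"), c(s$n_N, s$n_S)),
    dosage = as.integer(m[, 1]))
}

#' Simulate a SNP dataset under a demographic scenario
#'
#' `n_loci` independent loci; gene copies are paired at random into
#' diploids within demes. Deterministic given `cfg$seed`.
#'
#' @param s a `demographic_scenario`
#' @param cfg a [sim_config()]
#' @return list with `genotypes` (a [geno_matrix()]) and `pops` (a
#'   [pop_map()] with the two demes as colonies/clusters).
#' @export
simulate_dataset <- function(s, cfg = sim_config()) {
  m <- with_seed(cfg$seed, sim_scenario_matrix(s, cfg))
  rownames(m) <- sprintf("sim_%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("locus_%d", seq_len(ncol(m)))
  g <- geno_matrix(m)
  pops <- pop_map(
    tibble::tibble(individual_id = rownames(m),
                   colony = rep(c("NZ-N", "NZ-S"), c(s$n_N, s$n_S))),
    tibble::tibble(colony = c("NZ-N", "NZ-S"),
                   cluster = c("NZ-N", "NZ-S")))
  list(genotypes = g, pops = pops)
}

#' Simulate a SNP dataset under a finite-island model
#'
#' Within-deme pair-coalescence rate `1/(2N)` per generation and
#' per-lineage migration at rate `m` to a uniformly chosen other deme;
#' single-mutation SNP loci with pooled-MAF ascertainment. Used as the
#' neutral null for the FST-outlier scan.
#'
#' @param n_demes demes in the island model
#' @param deme_size diploid size `N` of every deme
#' @param migration_rate per-lineage migration rate `m` (> 0)
#' @param sample_sizes diploid sample sizes of the sampled demes (the
#'   first `length(sample_sizes)` demes)
#' @param cfg a [sim_config()]
#' @return list with `genotypes` and `pops` (sampled demes as colonies).
#' @export
island_model_dataset <- function(n_demes, deme_size, migration_rate,
                                 sample_sizes, cfg = sim_config()) {
  if (migration_rate <= 0) stop("migration_rate must be > 0", call. = FALSE)
  m <- with_seed(cfg$seed, .sim_island_genotypes(
    as.integer(n_demes), as.integer(sample_sizes), deme_size,
    migration_rate, cfg$n_loci, cfg$min_maf_pooled,
    cfg$max_redraws_per_locus))
  rownames(m) <- sprintf("sim_%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("locus_%d", seq_len(ncol(m)))
  demes <- sprintf("deme%d", seq_along(sample_sizes))
  pops <- pop_map(
    tibble::tibble(individual_id = rownames(m),
                   colony = rep(demes, sample_sizes)),
    tibble::tibble(colony = demes, cluster = demes))
  list(genotypes = geno_matrix(m), pops = pops)
}

#' Expected island-model FST
#'
#' Exact low-mutation closed form for the simulated model (per-lineage
#' backward migration at rate `m` to a uniformly chosen *other* deme):
#' pairwise within-deme coalescence time is `2Nd` and between-deme
#' `2Nd + (d-1)/(2m)`, giving `FST = 1 / (1 + 4Nm d/(d-1))`. Used to
#' calibrate outlier-scan null simulations and to cross-check the
#' simulator.
#'
#' @param N diploid deme size
#' @param m per-lineage migration rate
#' @param d number of demes
#' @return expected FST.
#' @export
island_fst_expected <- function(N, m, d) {
  1 / (1 + 4 * N * m * d / (d - 1))
}

#' Migration rate matching a target island-model FST
#'
#' Inverts [island_fst_expected()] for `m`.
#'
#' @param fst target FST in (0, 1)
#' @param N diploid deme size
#' @param d number of demes
#' @return migration rate `m`.
#' @export
island_m_for_fst <- function(fst, N, d) {
  if (fst <= 0 || fst >= 1) stop("target FST must lie in (0,1)",
                                 call. = FALSE)
  (1 / fst - 1) / (4 * N * d / (d - 1))
}
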