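#' Default synthetic colony design
#'
#' Eight breeding colonies in three groups — a north-western and a
#' southern cluster plus two admixture-zone colonies — with the study's
#' pup sample sizes (167 in total), plausible New Zealand coastal
#' coordinates, a per-colony drift parameter `f_colony`, and, for the
#' admixed colonies, a mixture weight `admix_weight` on the first cluster
#' of `admix_between` (see [synth_config()]).
#'
#' @return tibble with columns `colony`, `cluster`, `n`, `lat`, `lon`,
#'   `f_colony`, `admix_weight`.
#' @export
default_synth_colonies <- function() {
  tibble::tibble(
    colony = c("OBI", "CF", "WP", "CP", "OP", "HB", "VB", "NP"),
    cluster = c(rep("NZ-North-West", 3), rep("NZ-North-East", 2),
                rep("NZ-South", 3)),
    n = c(28L, 23L, 21L, 14L, 15L, 22L, 22L, 22L),
    lat = c(-43.86, -41.75, -40.95, -41.61, -42.25, -46.90, -45.90, -46.45),
    lon = c(168.88, 171.47, 172.10, 175.29, 173.82, 168.13, 170.74, 169.82),
    f_colony = 0.003,
    admix_weight = c(NA, NA, NA, 0.6, 0.5, NA, NA, NA))
}

#' Synthetic-study configuration
#'
#' The generator draws an ancestral alternate-allele frequency per locus
#' uniformly on `ancestral_bounds`, builds one Balding-Nichols frequency
#' pool per cluster named in `admix_between` (beta with mean equal to the
#' ancestral frequency and drift parameter `f_cluster`), gives admixed
#' colonies the weighted mixture of the two pools, draws colony
#' frequencies Balding-Nichols around their pool with drift `f_colony`,
#' and samples genotypes binomially under HWE, masking calls at
#' `missing_rate`.
#'
#' @param colonies colony design tibble (see [default_synth_colonies()])
#' @param n_loci number of unlinked loci
#' @param ancestral_bounds uniform bounds of the ancestral frequency; the
#'   defaults imply a mean expected heterozygosity near 0.26
#' @param f_cluster drift parameter separating the two cluster pools
#' @param admix_between the two cluster labels whose pools admixed
#'   colonies mix; other clusters at these labels draw from their own pool
#' @param missing_rate missing-call rate
#' @param seed integer seed
#' @return list of class `synth_config`.
#' @export
synth_config <- function(colonies = default_synth_colonies(),
                         n_loci = 2000L,
                         ancestral_bounds = c(0.03, 0.30),
                         f_cluster = 0.015,
                         admix_between = c("NZ-North-West", "NZ-South"),
                         missing_rate = 0.02,
                         seed = 1L) {
  colonies <- tibble::as_tibble(colonies)
  need <- c("colony", "cluster", "n", "lat", "lon", "f_colony",
            "admix_weight")
  if (!all(need %in% names(colonies)))
    stop("colony design needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(colonies$n < 2)) stop("every colony needs n >= 2", call. = FALSE)
  if (any(colonies$f_colony < 0 | colonies$f_colony >= 1))
    stop("f_colony must lie in [0, 1)", call. = FALSE)
  w <- colonies$admix_weight
  if (any(!is.na(w) & (w < 0 | w > 1)))
    stop("admixture weights must lie in [0, 1]", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  structure(list(colonies = colonies, n_loci = as.integer(n_loci),
                 ancestral_bounds = ancestral_bounds,
                 f_cluster = f_cluster, admix_between = admix_between,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synth_config")
}

# Balding-Nichols draw: beta with mean p and drift F (F = 0 returns p)
rbn <- function(p, f) {
  if (f <= 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Generate a synthetic multi-colony SNP study
#'
#' @param cfg a [synth_config()]
#' @return list with `genotypes` (a [geno_matrix()]), `pops` (a
#'   [pop_map()] with coordinates) and `truth` (generator record: seed,
#'   drift schedule, ancestral bounds, per-colony expected-divergence
#'   scores).
#' @export
generate_study <- function(cfg = synth_config()) {
  col <- cfg$colonies
  L <- cfg$n_loci
  with_seed(cfg$seed, {
    p_anc <- stats::runif(L, cfg$ancestral_bounds[1], cfg$ancestral_bounds[2])
    flip <- stats::runif(L) < 0.5  # random minor-allele orientation
    p_anc[flip] <- 1 - p_anc[flip]
    pools <- list()
    for (cl in unique(col$cluster)) {
      pools[[cl]] <- rbn(p_anc, cfg$f_cluster)
    }
    calls <- matrix(NA_integer_, sum(col$n), L)
    ids <- character(sum(col$n))
    row0 <- 0L
    for (i in seq_len(nrow(col))) {
      w <- col$admix_weight[i]
      pool <- if (!is.na(w)) {
        w * pools[[cfg$admix_between[1]]] +
          (1 - w) * pools[[cfg$admix_between[2]]]
      } else pools[[col$cluster[i]]]
      p_col <- rbn(pool, col$f_colony[i])
      n_i <- col$n[i]
      block <- matrix(stats::rbinom(n_i * L, 2, rep(p_col, each = n_i)),
                      nrow = n_i)
      calls[row0 + seq_len(n_i), ] <- block
      ids[row0 + seq_len(n_i)] <- sprintf("%s_%02d", col$colony[i],
                                          seq_len(n_i))
      row0 <- row0 + n_i
    }
    if (cfg$missing_rate > 0)
      calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
    rownames(calls) <- ids
    colnames(calls) <- sprintf("snp_%05d", seq_len(L))
    g <- geno_matrix(calls)
    pops <- pop_map(
      tibble::tibble(individual_id = ids,
                     colony = rep(col$colony, col$n)),
      col[, c("colony", "cluster", "lat", "lon")])
    list(genotypes = g, pops = pops,
         truth = list(seed = cfg$seed, f_cluster = cfg$f_cluster,
                      f_colony = stats::setNames(col$f_colony, col$colony),
                      admix_weight = stats::setNames(col$admix_weight,
                                                     col$colony),
                      ancestral_bounds = cfg$ancestral_bounds,
                      missing_rate = cfg$missing_rate))
  })
}

#' Write a synthetic study to disk as portable fixtures
#'
#' Emits PED/MAP, VCF, the two population-map TSVs, and a truth JSON that
#' records the generator settings; re-reading the PED/MAP or VCF
#' reproduces the genotype matrix exactly.
#'
#' @param study a [generate_study()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of written paths.
#' @export
write_fixture <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("study.ped", "study.map", "study.vcf",
                            "individuals.tsv", "colonies.tsv",
                            "truth.json"))
  write_ped_map(study$genotypes, paths[1], paths[2])
  write_vcf(study$genotypes, paths[3])
  write_pop_map(study$pops, paths[4], paths[5])
  jsonlite::write_json(study$truth, paths[6], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
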