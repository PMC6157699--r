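test_that("leave-one-out frequencies follow the substitution contract", {
  # home pop of two heterozygotes: LOO frequency for the focal is 0.5
  calls <- rbind(c(1L), c(1L), c(0L), c(2L))
  rownames(calls) <- c("a", "b", "c", "d")
  fx <- toy_geno(calls, c("P", "P", "Q", "Q"))
  f <- loo_frequencies(fx$g, fx$pops, "a")
  expect_equal(unname(f["P", 1]), 0.5)

  # home monomorphic for the reference allele, focal carries the alternate:
  # the leave-one-out zero frequency becomes 0.005
  calls2 <- rbind(c(1L), c(0L), c(0L), c(2L), c(0L))
  rownames(calls2) <- c("foc", "h1", "h2", "q1", "q2")
  fx2 <- toy_geno(calls2, c("P", "P", "P", "Q", "Q"))
  f2 <- loo_frequencies(fx2$g, fx2$pops, "foc",
                        cfg = assign_config(zero_freq_substitute = 0.005))
  expect_equal(unname(f2["P", 1]), 0.005)
  # non-home population frequencies are untouched by the leave-one-out
  full_q <- mean(calls2[c("q1", "q2"), 1]) / 2
  expect_equal(unname(f2["Q", 1]), full_q)
  expect_error(loo_frequencies(fx2$g, fx2$pops, "nope"), "unknown")
})

test_that("genotype log-likelihood matches the closed form", {
  expect_equal(genotype_loglik(c(1L, 1L), c(0.5, 0.5)),
               2 * log10(0.5), tolerance = 1e-12)
  p <- c(0.2, 0.7, 0.4)
  x <- c(0L, 2L, 1L)
  manual <- log10((1 - 0.2)^2) + log10(0.7^2) + log10(2 * 0.4 * 0.6)
  expect_equal(genotype_loglik(x, p), manual, tolerance = 1e-12)
  # likelihood falls as the genotype diverges from the frequencies
  p2 <- rep(0.9, 5)
  expect_gt(genotype_loglik(rep(2L, 5), p2),
            genotype_loglik(rep(0L, 5), p2))
  expect_error(genotype_loglik(c(NA, 1L), c(0.5, 0.5)), "impute")
  expect_error(genotype_loglik(c(1L), 1), "strictly")
})

test_that("fixed populations are perfectly assignable; single pop trivially", {
  fp <- fixed_pair_fixture(10, 100)
  res <- assign_individuals(fp$g, fp$pops,
                            cfg = assign_config(n_null_draws = 200))
  expect_equal(mean(res$individuals$correct), 1)
  expect_equal(res$individuals$best, res$individuals$home)

  # genotypes drawn from the very frequencies being fitted: home p-values
  # approximately uniform (large pop keeps the leave-one-out shift small)
  set.seed(2)
  freqs <- runif(40, 0.2, 0.8)
  calls <- sapply(freqs, function(p) rbinom(150, 2, p))
  rownames(calls) <- sprintf("i%d", 1:150)
  single <- toy_geno(calls, rep("only", 150))
  res1 <- assign_individuals(single$g, single$pops,
                             cfg = assign_config(n_null_draws = 400))
  expect_equal(mean(res1$individuals$correct), 1)
  expect_gt(suppressWarnings(
    stats::ks.test(res1$individuals$home_p, "punif")$p.value), 0.01)
})

test_that("panmictic colonies assign at chance level", {
  set.seed(4)
  calls <- matrix(rbinom(96 * 120, 2, rep(runif(120, 0.2, 0.8),
                                          each = 96)), 96, 120)
  rownames(calls) <- sprintf("i%d", 1:96)
  fx <- toy_geno(calls, rep(sprintf("C%d", 1:8), each = 12))
  res <- assign_individuals(fx$g, fx$pops,
                            cfg = assign_config(n_null_draws = 50))
  acc <- mean(res$individuals$correct)
  se <- sqrt(0.125 * 0.875 / 96)
  expect_lt(abs(acc - 1 / 8), 4 * se)
})

test_that("accuracy is invariant to individual and locus permutations", {
  st <- two_cluster_fixture(0.1, n_per = 12, n_loci = 80, seed = 19)
  g <- st$genotypes; pops <- st$pops
  cfg <- assign_config(n_null_draws = 50, seed = 3)
  base <- assign_individuals(g, pops, "cluster", cfg)
  perm_i <- with_seed(7, sample(n_individuals(g)))
  perm_l <- with_seed(8, sample(n_loci(g)))
  g2 <- g[perm_i, perm_l]
  res2 <- assign_individuals(g2, pops, "cluster", cfg)
  expect_equal(mean(res2$individuals$correct),
               mean(base$individuals$correct))
})

test_that("cluster-level accuracy grows with divergence", {
  accs <- sapply(c(0.005, 0.02, 0.05, 0.2), function(f) {
    st <- two_cluster_fixture(f, n_per = 12, n_loci = 200, seed = 23)
    res <- assign_individuals(st$genotypes, st$pops, "cluster",
                              assign_config(n_null_draws = 20, seed = 5))
    mean(res$individuals$correct)
  })
  expect_true(all(diff(accs) >= 0))
  expect_gte(accs[4], 0.95)
})

test_that("panel assignment validates panels and matches the full run", {
  st <- two_cluster_fixture(0.1, n_per = 8, n_loci = 60, seed = 29)
  g <- st$genotypes; pops <- st$pops
  cfg <- assign_config(n_null_draws = 20, seed = 2)
  full <- assign_individuals(g, pops, "cluster", cfg)
  pa <- panel_assign(g, pops, list(full = g$loci$locus_id), "cluster", cfg)
  expect_equal(pa$accuracy, mean(full$individuals$correct))
  expect_error(panel_assign(g, pops, list(a = character(0)), "cluster",
                            cfg), "empty panel")
  expect_error(panel_assign(g, pops,
                            list(a = g$loci$locus_id[1:2],
                                 a = g$loci$locus_id[3:4]),
                            "cluster", cfg), "duplicated")
})

test_that("an informative panel beats a random panel of the same size", {
  st <- two_cluster_fixture(0.08, n_per = 15, n_loci = 250, seed = 37)
  g <- st$genotypes; pops <- st$pops
  lab <- group_labels(g, pops, "cluster")
  comp <- fursealpop:::wc_components(g$calls, lab)
  den <- comp$a + comp$b + comp$c
  per_locus <- ifelse(!is.na(den) & den != 0, comp$a / den, -Inf)
  top <- g$loci$locus_id[order(per_locus, decreasing = TRUE)[1:25]]
  rnd <- with_seed(5, sample(g$loci$locus_id, 25))
  cfg <- assign_config(n_null_draws = 20, seed = 4)
  pa <- panel_assign(g, pops, list(informative = top, random = rnd),
                     "cluster", cfg)
  expect_gte(pa$accuracy[pa$panel == "informative"],
             pa$accuracy[pa$panel == "random"])
})
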