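test_that("prior draws respect bounds, conditions and the seed", {
  spec <- fur_seal_priors()
  d1 <- sample_priors(spec, 500, seed = 3)
  d2 <- sample_priors(spec, 500, seed = 3)
  expect_identical(d1, d2)
  expect_true(all(d1$t_Europeans > d1$t_post_seal))
  expect_true(all(d1$Ne_pre_historical > d1$Ne_NZ_N))
  for (i in seq_len(nrow(spec$params)))
    expect_true(all(d1[[spec$params$param[i]]] >= spec$params$lower[i] &
                      d1[[spec$params$param[i]]] <= spec$params$upper[i]))
  # t_post_seal marginal stays ~ U[1,25]: the condition rarely binds
  ks <- suppressWarnings(
    stats::ks.test(d1$t_post_seal, "punif", 1, 25))
  expect_gt(ks$p.value, 0.01)
})

test_that("summary statistics follow their closed-form conventions", {
  # identical allele frequencies in both samples: Nei D = 0, FST ~ 0
  calls <- rbind(matrix(rep(c(0L, 1L, 2L, 1L), 5), 4, 5),
                 matrix(rep(c(0L, 1L, 2L, 1L), 5), 4, 5))
  rownames(calls) <- sprintf("i%d", 1:8)
  fx <- toy_geno(calls, rep(c("N", "S"), each = 4))
  ss <- summary_stats(fx$g, fx$pops, c("N", "S"))
  expect_equal(ss[["nei_all"]], 0, tolerance = 1e-12)
  expect_lt(abs(ss[["fst_all"]]), 0.2)

  # monomorphic sample: all-loci diversity 0, polymorphic-loci flagged 0
  calls2 <- rbind(matrix(0L, 3, 4), matrix(c(0L, 1L, 2L), 3, 4))
  rownames(calls2) <- sprintf("i%d", 1:6)
  fx2 <- toy_geno(calls2, rep(c("N", "S"), each = 3))
  ss2 <- summary_stats(fx2$g, fx2$pops, c("N", "S"))
  expect_equal(ss2[["div_all_N"]], 0)
  expect_equal(ss2[["div_poly_N"]], 0)

  # hand-computed Nei distance from listed frequencies
  # sample N: p = 0.25 (n=2: dosages 0,1); sample S: p = 0.75
  calls3 <- matrix(c(0L, 1L, 2L, 1L), 4, 1)
  rownames(calls3) <- sprintf("i%d", 1:4)
  fx3 <- toy_geno(calls3, rep(c("N", "S"), each = 2))
  ss3 <- summary_stats(fx3$g, fx3$pops, c("N", "S"))
  jx <- 0.25^2 + 0.75^2; jy <- jx; jxy <- 2 * 0.25 * 0.75
  expect_equal(ss3[["nei_all"]], -log(jxy / sqrt(jx * jy)),
               tolerance = 1e-12)
})

test_that("matrix fast path and missing-data path agree on complete data", {
  st <- two_cluster_fixture(0.05, n_per = 12, n_loci = 60, seed = 8)
  lab <- group_labels(st$genotypes, st$pops, "cluster")
  ss_matrix <- fursealpop:::summary_stats_matrix(
    st$genotypes$calls, which(lab == "North"), which(lab == "South"))
  ss_general <- summary_stats(st$genotypes, st$pops,
                              c("North", "South"), "cluster")
  expect_equal(ss_matrix, ss_general, tolerance = 1e-12)
})

test_that("reference tables have the promised layout and finite stats", {
  scen <- fur_seal_scenarios()
  tab <- build_reference_table(scen, 12, 8, sim_config(n_loci = 60),
                               n_per_scenario = 15, seed = 21)
  expect_equal(nrow(tab), 30)
  expect_setequal(unique(tab$scenario), c("two_decline", "null"))
  sn <- fursealpop:::stat_names()
  expect_true(all(sn %in% names(tab)))
  expect_true(all(is.finite(as.matrix(tab[, sn]))))
})

test_that("bottleneck and null scenarios separate in summary-stat space", {
  scen <- fur_seal_scenarios()
  deep <- abc_scenario("deep", prior_spec(tibble::tibble(
    param = "dummy", lower = 0, upper = 1)),
    function(draw, n_N, n_S)
      build_two_decline_scenario(
        scenario_params(1000, 1000, 100, 5e5, 5e6, 106, 49.2, 20.3),
        n_N, n_S))
  shallow <- abc_scenario("flat", prior_spec(tibble::tibble(
    param = "dummy", lower = 0, upper = 1)),
    function(draw, n_N, n_S)
      build_null_scenario(5e5, 1000, 1000, 20.3, n_N, n_S))
  tab <- build_reference_table(list(deep = deep, flat = shallow), 20, 15,
                               sim_config(n_loci = 150),
                               n_per_scenario = 25, seed = 5)
  wt <- stats::wilcox.test(div_all_N ~ scenario, data = tab)
  expect_lt(wt$p.value, 1e-4)
})

test_that("rejection retains the nearest rows with standardized distance", {
  scen <- fur_seal_scenarios()
  tab <- build_reference_table(scen, 10, 8, sim_config(n_loci = 40),
                               n_per_scenario = 25, seed = 31)
  obs <- unlist(tab[7, fursealpop:::stat_names()])
  rej_all <- abc_reject(tab, obs, tolerance = 1)
  expect_equal(nrow(rej_all$retained), nrow(tab))
  rej <- abc_reject(tab, obs, tolerance = 0.1)
  expect_equal(nrow(rej$retained), ceiling(0.1 * nrow(tab)))
  expect_equal(rej$retained$distance[1], 0, tolerance = 1e-12)
  expect_equal(unlist(rej$retained[1, fursealpop:::stat_names()]), obs)
  expect_error(abc_reject(tab, obs, tolerance = 0), "tolerance")
})

test_that("direct model choice equals counted frequencies; symmetric case", {
  # hand-built rejection object: 6 retained rows, 4 vs 2
  ret <- tibble::tibble(scenario = rep(c("A", "B"), c(4, 2)),
                        distance = 1:6 / 10)
  rej <- structure(list(retained = ret, observed = c(x = 0),
                        stat_sd = c(x = 1), stats_used = "x",
                        tolerance = 1),
                   class = "abc_rejection")
  mc <- model_choice(rej, method = "direct")
  expect_equal(mc$direct[mc$scenario == "A"], 4 / 6, tolerance = 1e-6)

  # two identical scenarios: probabilities near 1/2
  same <- fur_seal_scenarios()["two_decline"]
  scen2 <- list(s1 = same$two_decline, s2 = same$two_decline)
  scen2$s2$name <- "s2"
  tab <- build_reference_table(scen2, 15, 10, sim_config(n_loci = 80),
                               n_per_scenario = 60, seed = 41)
  obs <- colMeans(tab[, fursealpop:::stat_names()])
  mc2 <- model_choice(abc_reject(tab, unlist(obs), tolerance = 0.5))
  expect_lt(abs(mc2$direct[1] - 0.5), 0.25)
  expect_lt(abs(mc2$logistic[1] - 0.5), 0.3)
  expect_equal(sum(mc2$direct), 1)
  expect_equal(sum(mc2$logistic), 1)
})

test_that("local-linear adjustment recovers a linear toy relation", {
  # one informative stat linearly tied to a size-like parameter
  set.seed(6)
  n <- 300
  stat <- runif(n, 0.2, 0.4)
  par_true <- exp(2 + 3 * stat + rnorm(n, 0, 0.01))
  tab <- tibble::tibble(scenario = "s",
                        Ne_toy = par_true,
                        div_poly_N = stat, div_all_N = stat,
                        div_poly_S = stat, div_all_S = stat,
                        fst_nonnull = 0.5, fst_all = 0.5,
                        nei_nonnull = 0.5, nei_all = 0.5)
  obs <- c(div_poly_N = 0.3, div_all_N = 0.3, div_poly_S = 0.3,
           div_all_S = 0.3, fst_nonnull = 0.5, fst_all = 0.5,
           nei_nonnull = 0.5, nei_all = 0.5)
  pr <- prior_spec(tibble::tibble(param = "Ne_toy", lower = 1,
                                  upper = 1e4))
  rej <- suppressWarnings(abc_reject(tab, obs, tolerance = 0.5))
  post <- adjust_posterior(rej, pr)
  s <- posterior_summary(post)
  expect_equal(s$mode, exp(2 + 3 * 0.3), tolerance = 0.05)
  # and the posterior respects the prior bounds on a time-like parameter
  tab$t_toy <- runif(n, 5, 25)
  pr2 <- prior_spec(tibble::tibble(param = "t_toy", lower = 5, upper = 25))
  post2 <- adjust_posterior(suppressWarnings(
    abc_reject(tab, obs, tolerance = 0.5)), pr2)
  expect_true(all(post2$draws$t_toy >= 5 & post2$draws$t_toy <= 25))
})

test_that("posterior summaries handle point masses and uniform samples", {
  pm <- structure(list(
    draws = tibble::tibble(Ne_x = rep(110, 60)),
    weights = rep(1 / 60, 60),
    prior = prior_spec(tibble::tibble(param = "Ne_x", lower = 1,
                                      upper = 1000))),
    class = "abc_posterior")
  s <- posterior_summary(pm)
  expect_equal(s$mode, 110)
  expect_equal(s$q05, 110)
  expect_equal(s$q95, 110)

  set.seed(9)
  u <- runif(4000)
  pu <- structure(list(
    draws = tibble::tibble(Ne_u = u),
    weights = rep(1 / 4000, 4000),
    prior = prior_spec(tibble::tibble(param = "Ne_u", lower = 0,
                                      upper = 1))),
    class = "abc_posterior")
  su <- posterior_summary(pu)
  expect_equal(su$q05, 0.05, tolerance = 0.02)
  expect_equal(su$q95, 0.95, tolerance = 0.02)
})

test_that("rejection posterior converges to the prior as tolerance -> 1", {
  scen <- fur_seal_scenarios()["two_decline"]
  tab <- build_reference_table(scen, 10, 8, sim_config(n_loci = 50),
                               n_per_scenario = 400, seed = 51)
  obs <- unlist(tab[1, fursealpop:::stat_names()])
  rej <- abc_reject(tab, obs, tolerance = 1)
  ks <- suppressWarnings(stats::ks.test(rej$retained$t_post_seal,
                                        "punif", 1, 25))
  expect_gt(ks$p.value, 0.05)
  expect_lt(max(abs(sort(rej$retained$t_post_seal) -
                      qunif(ppoints(nrow(rej$retained)), 1, 25))) / 24,
            0.05)
})

test_that("scenario confidence separates well-separated scenarios", {
  deep <- abc_scenario("deep", prior_spec(tibble::tibble(
    param = "dummy", lower = 0, upper = 1)),
    function(draw, n_N, n_S)
      build_two_decline_scenario(
        scenario_params(1000, 1000, 100, 5e5, 5e6, 106, 49.2, 20.3),
        n_N, n_S))
  flat <- abc_scenario("flat", prior_spec(tibble::tibble(
    param = "dummy", lower = 0, upper = 1)),
    function(draw, n_N, n_S)
      build_null_scenario(5e5, 1000, 1000, 20.3, n_N, n_S))
  scen <- list(deep = deep, flat = flat)
  tab <- build_reference_table(scen, 20, 15, sim_config(n_loci = 120),
                               n_per_scenario = 80, seed = 61)
  conf <- scenario_confidence(tab, scen, focal = "deep", n_pods = 12,
                              n_N = 20, n_S = 15,
                              sim_cfg = sim_config(n_loci = 120),
                              tolerance = 0.1, seed = 62)
  expect_lte(conf$type_I, 0.25)
  expect_lte(conf$type_II, 0.25)

  # direct and logistic estimates agree for well-separated scenarios
  # (averaged over datasets; single draws can straddle the boundary)
  tab2 <- build_reference_table(scen, 20, 15, sim_config(n_loci = 400),
                                n_per_scenario = 300, seed = 61)
  diffs <- sapply(63:70, function(sd0) {
    d_obs <- simulate_dataset(deep$build(NULL, 20, 15),
                              sim_config(n_loci = 400, seed = sd0))
    obs <- summary_stats(d_obs$genotypes, d_obs$pops, c("NZ-N", "NZ-S"))
    mc <- suppressWarnings(model_choice(abc_reject(tab2, obs, 0.1)))
    if (!"logistic" %in% names(mc)) return(0)  # degenerate: both saturate
    max(abs(mc$direct - mc$logistic))
  })
  expect_lte(mean(diffs), 0.15)
})
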