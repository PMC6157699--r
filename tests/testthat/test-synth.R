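test_that("the default design reproduces the study layout", {
  st <- generate_study(synth_config(n_loci = 100, seed = 2))
  expect_equal(n_individuals(st$genotypes), 167)
  sizes <- table(st$pops$individuals$colony)
  expect_equal(unname(sizes[c("OBI", "CF", "WP", "CP", "OP",
                              "HB", "VB", "NP")]),
               table(rep(1:8, c(28, 23, 21, 14, 15, 22, 22, 22)))[1:8],
               ignore_attr = TRUE)
  expect_equal(length(unique(st$pops$colonies$cluster)), 3)
  st2 <- generate_study(synth_config(n_loci = 100, seed = 2))
  expect_identical(st$genotypes$calls, st2$genotypes$calls)
})

test_that("zero drift and no admixture gives panmixia", {
  cols <- default_synth_colonies()
  cols$f_colony <- 0
  cols$admix_weight <- NA_real_
  st <- generate_study(synth_config(colonies = cols, n_loci = 300,
                                    f_cluster = 0, missing_rate = 0,
                                    seed = 3))
  lab <- group_labels(st$genotypes, st$pops, "colony")
  comp <- fursealpop:::wc_components(st$genotypes$calls, lab)
  theta <- sum(comp$a, na.rm = TRUE) /
    sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  expect_lt(abs(theta), 0.01)
})

test_that("realized diversity tracks the ancestral-frequency bounds", {
  st <- generate_study(synth_config(n_loci = 2000, seed = 5))
  het <- heterozygosity(st$genotypes, st$pops, "global")
  a <- 0.03; b <- 0.30
  implied <- 2 * ((a + b) / 2 - (a^2 + a * b + b^2) / 3)
  expect_lt(abs(het$He - implied), 0.05)
})

test_that("realized FST tracks the configured drift schedule", {
  # distance-driven per-colony F: realized pairwise theta should rank with
  # the configured F sums
  cols <- tibble::tibble(
    colony = sprintf("C%d", 1:6),
    cluster = "one",
    n = 15L,
    lat = seq(-41, -46, length.out = 6),
    lon = seq(173, 168, length.out = 6),
    f_colony = c(0.002, 0.006, 0.012, 0.02, 0.03, 0.045),
    admix_weight = NA_real_)
  st <- generate_study(synth_config(colonies = cols, n_loci = 600,
                                    f_cluster = 0, admix_between =
                                      c("one", "one"), missing_rate = 0,
                                    seed = 7))
  fst <- pairwise_fst(st$genotypes, st$pops)
  pairs <- tidy(fst)
  fmap <- stats::setNames(cols$f_colony, cols$colony)
  expected <- fmap[pairs$colony_a] + fmap[pairs$colony_b]
  expect_gt(cor(pairs$theta, expected, method = "spearman"), 0.8)
})

test_that("admixed colonies sit between the two cluster pools", {
  st <- generate_study(synth_config(n_loci = 1500, missing_rate = 0,
                                    seed = 9))
  g <- st$genotypes; pops <- st$pops
  theta_between <- wc_fst_cluster <- function(a, b) {
    lab <- group_labels(g, pops, "cluster")
    rows <- lab %in% c(a, b)
    comp <- fursealpop:::wc_components(g$calls[rows, ], lab[rows])
    sum(comp$a, na.rm = TRUE) / sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  }
  t_nw_s <- theta_between("NZ-North-West", "NZ-South")
  t_ne_nw <- theta_between("NZ-North-East", "NZ-North-West")
  t_ne_s <- theta_between("NZ-North-East", "NZ-South")
  expect_lt(t_ne_nw, t_nw_s)
  expect_lt(t_ne_s, t_nw_s)
})

test_that("fixtures round-trip through disk and pass permissive QC", {
  st <- generate_study(synth_config(n_loci = 40, seed = 13))
  dir <- withr::local_tempdir()
  paths <- write_fixture(st, dir)
  expect_true(all(file.exists(paths)))
  g_ped <- read_genotypes(file.path(dir, "study.ped"), "ped_map")
  expect_identical(unname(g_ped$calls), unname(st$genotypes$calls))
  g_vcf <- read_genotypes(file.path(dir, "study.vcf"), "vcf")
  expect_identical(unname(g_vcf$calls), unname(st$genotypes$calls))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 13)
  expect_equal(truth$f_cluster, 0.015)
  pops <- read_pop_map(file.path(dir, "individuals.tsv"),
                       file.path(dir, "colonies.tsv"))
  res <- apply_qc(g_vcf, pops,
                  qc_config(max_locus_missing_fraction = 1, min_maf = 0,
                            hwe_alpha = 1e-12, ld_r2_threshold = 1))
  expect_equal(sum(res$report$n_loci_removed), 0)
  expect_equal(sum(res$report$n_individuals_removed), 0)
})
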