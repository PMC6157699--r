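test_that("allele frequencies come from non-missing calls only", {
  calls <- rbind(c(0L, NA), c(1L, NA), c(2L, NA), c(0L, 0L))
  rownames(calls) <- c("a", "b", "c", "d")
  fx <- toy_geno(calls, c("P", "P", "P", "Q"))
  af <- allele_freqs(fx$g, fx$pops, "colony")
  expect_equal(af$freq[af$group == "P" & af$locus_id == "locus_1"], 0.5)
  expect_true(af$undefined[af$group == "P" & af$locus_id == "locus_2"])
  expect_equal(af$freq[af$group == "Q" & af$locus_id == "locus_2"], 0)
})

test_that("heterozygosity uses the unbiased He formula", {
  # 4 individuals at p = 0.5: He = (8/7) * 0.5
  calls <- matrix(c(0L, 1L, 1L, 2L), 4, 3)
  rownames(calls) <- sprintf("i%d", 1:4)
  fx <- toy_geno(calls, rep("A", 4))
  het <- heterozygosity(fx$g, fx$pops, "colony")
  expect_equal(het$He, (8 / 7) * 0.5, tolerance = 1e-12)
  expect_equal(het$Ho, 0.5)

  all_het <- toy_geno(matrix(1L, 4, 5,
                             dimnames = list(sprintf("i%d", 1:4), NULL)),
                      rep("A", 4))
  expect_equal(heterozygosity(all_het$g, all_het$pops, "colony")$Ho, 1)

  mono <- toy_geno(matrix(2L, 3, 4,
                          dimnames = list(sprintf("i%d", 1:3), NULL)),
                   rep("A", 3))
  h <- heterozygosity(mono$g, mono$pops, "colony")
  expect_equal(h$Ho, 0)
  expect_equal(h$He, 0)
})

test_that("FIS matches 1 - Ho/He and the permutation test behaves", {
  set.seed(2)
  # heterozygote excess: all individuals heterozygous
  calls <- matrix(1L, 10, 8, dimnames = list(sprintf("i%d", 1:10), NULL))
  fx <- toy_geno(calls, rep("A", 10))
  f <- fis_test(fx$g, fx$pops, "A", n_perm = 200, seed = 1)
  expect_lt(f$FIS, 0)

  # toy group: direct formula
  calls2 <- matrix(c(0L, 0L, 1L, 2L, 2L,
                     1L, 1L, 0L, 2L, 1L), 5, 2)
  rownames(calls2) <- sprintf("i%d", 1:5)
  fx2 <- toy_geno(calls2, rep("A", 5))
  het <- heterozygosity(fx2$g, fx2$pops, "colony")
  f2 <- fis_test(fx2$g, fx2$pops, "A", n_perm = 50, seed = 1)
  expect_equal(f2$FIS, 1 - het$Ho / het$He, tolerance = 1e-12)

  # near Hardy-Weinberg proportions: FIS ~ 0, non-significant
  set.seed(5)
  calls3 <- matrix(rbinom(40 * 50, 2, 0.5), 40, 50)
  rownames(calls3) <- sprintf("i%d", 1:40)
  fx3 <- toy_geno(calls3, rep("A", 40))
  f3 <- fis_test(fx3$g, fx3$pops, "A", n_perm = 500, seed = 2)
  expect_lt(abs(f3$FIS), 0.1)
  expect_gt(f3$p, 0.05)
})

test_that("Weir-Cockerham FST equals the variance-component oracle", {
  set.seed(3)
  calls <- rbind(matrix(rbinom(4 * 6, 2, 0.3), 4, 6),
                 matrix(rbinom(4 * 6, 2, 0.7), 4, 6))
  rownames(calls) <- sprintf("i%d", 1:8)
  fx <- toy_geno(calls, rep(c("A", "B"), each = 4))
  f <- wc_fst(fx$g, fx$pops, "A", "B")
  expect_equal(f$theta, oracle_wc_theta(calls, rep(c("A", "B"), each = 4)),
               tolerance = 1e-12)
  per <- f$per_locus
  oc <- t(apply(calls, 2, oracle_wc_abc,
                labels = rep(c("A", "B"), each = 4)))
  expect_equal(per$a, unname(oc[, "a"]), tolerance = 1e-12)
})

test_that("FST limits: identical colonies near 0, fixed colonies near 1", {
  set.seed(4)
  block <- matrix(rbinom(12 * 40, 2, 0.4), 12, 40)
  calls <- rbind(block[1:6, ], block[1:6, ])
  rownames(calls) <- sprintf("i%d", 1:12)
  fx <- toy_geno(calls, rep(c("A", "B"), each = 6))
  th0 <- wc_fst(fx$g, fx$pops, "A", "B")$theta
  expect_lte(th0, 0)          # duplicated compositions: no between-group
  expect_lt(abs(th0), 0.15)   # variance, small-sample estimator noise only

  fp <- fixed_pair_fixture(12, 30)
  expect_gt(wc_fst(fp$g, fp$pops, "A", "B")$theta, 0.95)
})

test_that("wc_fst is symmetric in its colony arguments", {
  set.seed(6)
  calls <- matrix(rbinom(10 * 15, 2, 0.3), 10, 15)
  rownames(calls) <- sprintf("i%d", 1:10)
  fx <- toy_geno(calls, rep(c("A", "B"), each = 5))
  f1 <- wc_fst(fx$g, fx$pops, "A", "B", n_perm = 99, seed = 7)
  f2 <- wc_fst(fx$g, fx$pops, "B", "A", n_perm = 99, seed = 7)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$p, f2$p)
})

test_that("Slatkin linearization is the exact transform", {
  expect_equal(linearize_fst(0), 0)
  expect_equal(linearize_fst(0.5), 1)
  expect_equal(linearize_fst(0.02), 0.02 / 0.98)
  expect_equal(linearize_fst(-0.01), -0.01 / 1.01)
  expect_equal(linearize_fst(1), Inf)
  expect_error(linearize_fst(1.2), "exceed")
  th <- c(0.01, 0.1, 0.5)
  expect_true(all(linearize_fst(th) > th))
})

test_that("Mantel test recovers perfect and hand-computed correlations", {
  set.seed(8)
  A <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(A) <- list(letters[1:6], letters[1:6])
  m <- mantel_test(A, A, n_perm = 199, seed = 1)
  expect_equal(m$r, 1)
  expect_lte(m$p, 0.05)

  B4 <- matrix(c(0, 1, 2, 3,
                 1, 0, 1.5, 2.5,
                 2, 1.5, 0, 1,
                 3, 2.5, 1, 0), 4, 4)
  A4 <- matrix(c(0, 2, 1, 4,
                 2, 0, 3, 1,
                 1, 3, 0, 2,
                 4, 1, 2, 0), 4, 4)
  m4 <- mantel_test(A4, B4, n_perm = 99, seed = 1)
  lo <- lower.tri(A4)
  expect_equal(m4$r, cor(A4[lo], B4[lo]), tolerance = 1e-12)

  const <- matrix(1, 4, 4); diag(const) <- 0
  expect_true(mantel_test(const * 0, B4, n_perm = 9, seed = 1)$undefined)
})

test_that("marker concordance combines Pearson and Mantel checks", {
  he <- c(A = 0.2, B = 0.25, C = 0.3, D = 0.28)
  fstm <- matrix(c(0, .01, .02, .03,
                   .01, 0, .015, .02,
                   .02, .015, 0, .01,
                   .03, .02, .01, 0), 4, 4,
                 dimnames = list(names(he), names(he)))
  mc <- marker_concordance(he, he, fstm, fstm, n_perm = 99, seed = 1)
  expect_equal(mc$pearson_r, 1)
  expect_equal(mc$mantel_r, 1)
  mc2 <- marker_concordance(he, c(A = .2, B = .2, C = .2, D = .2),
                            fstm, fstm, n_perm = 99, seed = 1)
  expect_true(is.na(mc2$pearson_r))
})

test_that("PCA separates duplicated blocks and matches the eigen oracle", {
  set.seed(12)
  calls <- rbind(matrix(rbinom(8 * 25, 2, 0.15), 8),
                 matrix(rbinom(8 * 25, 2, 0.85), 8))
  rownames(calls) <- sprintf("i%d", 1:16)
  pc <- pca_genotypes(geno_matrix(calls), 2)
  grp <- rep(c(1, 2), each = 8)
  expect_true(all(sign(pc$scores$PC1[grp == 1]) !=
                    sign(pc$scores$PC1[grp == 2])))
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_true(all(pc$explained >= 0) && sum(pc$explained) <= 1 + 1e-12)

  set.seed(9)
  calls <- matrix(rbinom(10 * 20, 2, 0.4), 10, 20)
  rownames(calls) <- sprintf("i%d", 1:10)
  g <- geno_matrix(calls)
  pc2 <- pca_genotypes(g, 3)
  x <- sweep(calls, 2, colMeans(calls))
  ev <- eigen(tcrossprod(x) / (ncol(calls) - 1), symmetric = TRUE)$values
  expect_equal(pc2$values[1:3], ev[1:3], tolerance = 1e-8)
})

test_that("multilocus theta rises with the generating divergence F", {
  thetas <- sapply(c(0.001, 0.01, 0.05, 0.2), function(f) {
    st <- two_cluster_fixture(f, n_per = 15, n_loci = 250, seed = 31)
    lab <- group_labels(st$genotypes, st$pops, "cluster")
    comp <- fursealpop:::wc_components(st$genotypes$calls, lab)
    sum(comp$a, na.rm = TRUE) /
      sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  })
  expect_true(all(diff(thetas) > 0))
})

test_that("permutation p-values respect the smoothing floor", {
  fp <- fixed_pair_fixture(6, 10)
  f <- wc_fst(fp$g, fp$pops, "A", "B", n_perm = 49, seed = 2)
  expect_gte(f$p, 1 / 50)
})
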