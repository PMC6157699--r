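test_that("BH q-values match the step-up formula and edge cases", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_qvalues(p), rep(0.04, 4))
  expect_equal(bh_qvalues(p), oracle_bh(p))
  set.seed(3)
  pr <- runif(50)
  expect_equal(bh_qvalues(pr), oracle_bh(pr))
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(bh_qvalues(0.2), 0.2)
  expect_equal(bh_qvalues(numeric(0)), numeric(0))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  # ordering invariant: q non-decreasing in p
  q <- bh_qvalues(pr)
  expect_true(all(diff(q[order(pr)]) >= -1e-12))
})

null_scan_fixture <- function(n_loci, seed, n_per = 15, fst = 0.05) {
  m <- island_m_for_fst(fst, 1000, 8)
  island_model_dataset(8, 1000, m, rep(n_per, 8),
                       sim_config(n_loci = n_loci, min_maf_pooled = 0.05,
                                  seed = seed))
}

shared_null_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab))
      tab <<- fdist_null_table(rep(15, 8), 0.05, n_sims = 30000,
                               seed = 99)
    tab
  }
})

test_that("p-values are calibrated on island-null data", {
  d <- null_scan_fixture(400, seed = 71)
  scan <- fdist_scan(d$genotypes, d$pops, null_table = shared_null_table(),
                     seed = 72)
  ks <- suppressWarnings(stats::ks.test(scan$loci$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(nrow(scan$loci), 400)
  # bin-tail probability equals a direct counting oracle
  nt <- shared_null_table()
  loc <- scan$loci[which.max(scan$loci$theta), ]
  bin_lo <- floor(loc$He / 0.02) * 0.02
  sims <- nt$theta[nt$He >= bin_lo & nt$He < bin_lo + 0.02 &
                     !is.na(nt$theta)]
  if (length(sims) > 50) {  # occupied bin: exact counting check
    up <- (sum(sims >= loc$theta) + 1) / (length(sims) + 1)
    lo <- (sum(sims <= loc$theta) + 1) / (length(sims) + 1)
    expect_equal(loc$p, min(1, 2 * min(up, lo)), tolerance = 1e-12)
  }
})

test_that("no outliers are called on null data; fdr = 1 returns all", {
  d <- null_scan_fixture(300, seed = 73)
  scan <- fdist_scan(d$genotypes, d$pops, null_table = shared_null_table(),
                     seed = 74)
  called <- call_outliers(scan, fdr = 0.05)
  expect_lte(length(called$diversifying) + length(called$balancing),
             0.02 * 300)
  all_called <- call_outliers(scan, fdr = 1)
  expect_equal(sort(c(all_called$diversifying, all_called$balancing)),
               sort(scan$loci$locus_id[!is.na(scan$loci$q)]))
})

test_that("an extreme planted locus breaches the diversifying envelope", {
  d <- null_scan_fixture(150, seed = 75)
  # plant one near-fixed locus (far beyond the null divergence)
  m20 <- island_m_for_fst(0.8, 1000, 8)
  planted <- island_model_dataset(8, 1000, m20, rep(15, 8),
                                  sim_config(n_loci = 1, seed = 76))
  calls <- cbind(d$genotypes$calls, planted = planted$genotypes$calls[, 1])
  colnames(calls)[ncol(calls)] <- "planted"
  g <- geno_matrix(calls)
  scan <- fdist_scan(g, d$pops, null_table = shared_null_table(),
                     seed = 77)
  loc <- scan$loci[scan$loci$locus_id == "planted", ]
  expect_equal(loc$p, min(scan$loci$p, na.rm = TRUE))
  expect_equal(loc$direction, "diversifying")
  env <- scan$envelope
  row <- which(env$he_lower - 1e-9 <= loc$He & loc$He < env$he_upper + 1e-9)
  if (length(row) == 1) expect_gt(loc$theta, env$theta_upper[row])
})

test_that("the null envelope brackets the null loci at the stated level", {
  d <- null_scan_fixture(400, seed = 78)
  scan <- fdist_scan(d$genotypes, d$pops, ci = 0.99,
                     null_table = shared_null_table(), seed = 79)
  env <- scan$envelope
  outside <- 0
  for (i in seq_len(nrow(scan$loci))) {
    He <- scan$loci$He[i]; th <- scan$loci$theta[i]
    row <- which(env$he_lower - 1e-9 <= He & He < env$he_upper + 1e-9)
    if (length(row) == 1 && !is.na(th))
      outside <- outside + (th < env$theta_lower[row] ||
                              th > env$theta_upper[row])
  }
  expect_lte(outside / nrow(scan$loci), 0.05)
})
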