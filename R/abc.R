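#' Uniform prior specification with ordering conditions
#'
#' @param params tibble with columns `param`, `lower`, `upper`
#' @param conditions character vector of predicates over the parameter
#'   names (e.g. `"t_Europeans > t_post_seal"`), each evaluated per draw
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(params, conditions = character()) {
  params <- tibble::as_tibble(params)
  stopifnot(all(c("param", "lower", "upper") %in% names(params)))
  if (any(params$lower >= params$upper))
    stop("prior lower bounds must be below upper bounds", call. = FALSE)
  structure(list(params = params, conditions = conditions),
            class = "prior_spec")
}

#' Default fur-seal priors for the two-decline scenario
#'
#' Uniform priors on the five effective sizes and three event times of the
#' two-bottleneck recolonization history, with the ordering condition that
#' the European-era decline predates the post-sealing divergence and that
#' the pre-human size exceeds both contemporary sizes. The prior supports
#' already order the Polynesian decline before the European one.
#'
#' @return a [prior_spec()].
#' @export
fur_seal_priors <- function() {
  prior_spec(
    tibble::tibble(
      param = c("Ne_NZ_S", "Ne_NZ_N", "Ne_refugium", "Ne_historical_NZ",
                "Ne_pre_historical", "t_Polynesian", "t_Europeans",
                "t_post_seal"),
      lower = c(1e2, 1e2, 1e2, 1e3, 1e3, 100, 25, 1),
      upper = c(1e4, 1e4, 2.5e3, 5e6, 5e6, 200, 50, 25)),
    conditions = c("t_Europeans > t_post_seal",
                   "Ne_pre_historical > Ne_NZ_N",
                   "Ne_pre_historical > Ne_NZ_S"))
}

#' Default priors for the constant-size null scenario
#'
#' Same divergence structure and contemporary-size priors as the
#' two-decline scenario; the single ancestral size gets the same prior as
#' the deep historical sizes.
#'
#' @return a [prior_spec()].
#' @export
null_scenario_priors <- function() {
  prior_spec(
    tibble::tibble(
      param = c("Ne_NZ_S", "Ne_NZ_N", "Ne_constant", "t_post_seal"),
      lower = c(1e2, 1e2, 1e3, 1),
      upper = c(1e4, 1e4, 5e6, 25)))
}

#' Published posterior modes of the two-decline fur-seal fit
#'
#' Point estimates (posterior modes) of the demographic parameters for the
#' New Zealand fur seal: contemporary sizes near 1,120 (south) and 652
#' (north), a post-sealing refugium of ~110, historical and pre-human
#' sizes of ~572,000 and ~4,900,000, and event times of ~106, ~49.2 and
#' ~20.3 generations.
#'
#' @return named list usable with [scenario_params()].
#' @export
fur_seal_posterior_modes <- function() {
  list(Ne_NZ_S = 1120, Ne_NZ_N = 652, Ne_refugium = 110,
       Ne_historical_NZ = 572000, Ne_pre_historical = 4900000,
       t_Polynesian = 106, t_Europeans = 49.2, t_post_seal = 20.3)
}

#' Published posterior 5-95% ranges of the two-decline fur-seal fit
#'
#' Central credible ranges matching [fur_seal_posterior_modes()], as a
#' [prior_spec()] suitable for drawing pseudo-observed dataset parameters.
#'
#' @return a [prior_spec()].
#' @export
fur_seal_posterior_ranges <- function() {
  prior_spec(
    tibble::tibble(
      param = c("Ne_NZ_S", "Ne_NZ_N", "Ne_refugium", "Ne_historical_NZ",
                "Ne_pre_historical", "t_Polynesian", "t_Europeans",
                "t_post_seal"),
      lower = c(483, 336, 102, 228000, 356000, 105, 30.2, 5.89),
      upper = c(7940, 6600, 161, 4750000, 4810000, 194, 49, 24.2)),
    conditions = c("t_Europeans > t_post_seal",
                   "Ne_pre_historical > Ne_NZ_N",
                   "Ne_pre_historical > Ne_NZ_S"))
}

#' Sample parameter draws from a prior specification
#'
#' Independent uniforms; draws violating any ordering condition are
#' rejected and redrawn. Deterministic given `seed`.
#'
#' @param spec a [prior_spec()]
#' @param n number of accepted draws
#' @param seed integer seed or `NULL`
#' @return tibble of `n` rows, one column per parameter.
#' @export
sample_priors <- function(spec, n, seed = NULL) {
  with_seed(seed, {
    out <- NULL
    tried <- 0
    while (is.null(out) || nrow(out) < n) {
      m <- max(n, 100L)
      draws <- purrr::pmap(
        list(spec$params$param, spec$params$lower, spec$params$upper),
        function(pm, lo, hi) stats::runif(m, lo, hi))
      names(draws) <- spec$params$param
      draws <- tibble::as_tibble(draws)
      keep <- rep(TRUE, m)
      for (cond in spec$conditions)
        keep <- keep & rlang::eval_tidy(rlang::parse_expr(cond), draws)
      tried <- tried + m
      out <- dplyr::bind_rows(out, draws[keep, ])
      if (tried >= 1e4 && nrow(out) / tried < 1e-4)
        stop("prior condition acceptance rate below 1e-4", call. = FALSE)
    }
    out[seq_len(n), ]
  })
}

# summary statistics from a dosage matrix with no missing calls,
# rows split into two samples by idx list; returns named numeric(8)
summary_stats_matrix <- function(calls, idx_N, idx_S) {
  stat_block <- function(idx) {
    n <- length(idx)
    cc <- calls[idx, , drop = FALSE]
    p <- colMeans(cc) / 2
    he <- (2 * n) / (2 * n - 1) * 2 * p * (1 - p)
    het <- colMeans(cc == 1L)
    poly <- p > 0 & p < 1
    list(p = p, he = he, het = het, n = n, poly = poly)
  }
  a <- stat_block(idx_N)
  b <- stat_block(idx_S)
  div_poly <- function(s) if (any(s$poly)) mean(s$he[s$poly]) else 0
  # Weir-Cockerham components for two samples, vectorized over loci
  r <- 2
  nbar <- (a$n + b$n) / 2
  nc <- (r * nbar - (a$n^2 + b$n^2) / (r * nbar)) / (r - 1)
  pbar <- (a$n * a$p + b$n * b$p) / (r * nbar)
  s2 <- (a$n * (a$p - pbar)^2 + b$n * (b$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (a$n * a$het + b$n * b$het) / (r * nbar)
  aa <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  bb <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc2 <- hbar / 2
  den <- aa + bb + cc2
  fst <- ifelse(den != 0, aa / den, NA_real_)
  # Nei (1972) standard distance from the biallelic frequency pair
  jx <- a$p^2 + (1 - a$p)^2
  jy <- b$p^2 + (1 - b$p)^2
  jxy <- a$p * b$p + (1 - a$p) * (1 - b$p)
  nei <- -log(jxy / sqrt(jx * jy))
  mean_nonnull <- function(x) {
    ok <- is.finite(x) & x != 0
    if (any(ok)) mean(x[ok]) else 0
  }
  mean_all <- function(x) mean(ifelse(is.finite(x), x, 0))
  c(div_poly_N = div_poly(a), div_all_N = mean(a$he),
    div_poly_S = div_poly(b), div_all_S = mean(b$he),
    fst_nonnull = mean_nonnull(fst), fst_all = mean_all(fst),
    nei_nonnull = mean_nonnull(nei), nei_all = mean_all(nei))
}

#' DIYABC-style summary statistics for two samples
#'
#' Eight statistics: per sample, mean unbiased gene diversity across
#' polymorphic loci and across all loci; for the pair, mean per-locus
#' Weir-Cockerham FST and mean Nei (1972) standard distance, each over the
#' "nonnull" loci (statistic defined and nonzero) and over all loci
#' (undefined or monomorphic contributions counted as 0).
#'
#' Missing calls are dropped per locus within each sample before
#' frequencies are formed.
#'
#' @param g a [geno_matrix()]
#' @param pops a [pop_map()]
#' @param samples character pair of colony (or cluster) labels
#' @param level label level of `samples`
#' @return named numeric vector of 8 statistics.
#' @export
summary_stats <- function(g, pops, samples, level = c("colony", "cluster")) {
  level <- match.arg(level)
  if (length(samples) != 2) stop("`samples` must name two groups",
                                 call. = FALSE)
  lab <- group_labels(g, pops, level)
  idx_N <- which(lab == samples[1])
  idx_S <- which(lab == samples[2])
  if (!length(idx_N) || !length(idx_S))
    stop("both samples must be non-empty", call. = FALSE)
  if (n_loci(g) == 0) stop("zero loci", call. = FALSE)
  if (!anyNA(g$calls))
    return(summary_stats_matrix(g$calls, idx_N, idx_S))
  # missing-data path: per-locus complete calls within each sample
  stat_block <- function(idx) {
    cc <- g$calls[idx, , drop = FALSE]
    n <- colSums(!is.na(cc))
    p <- ifelse(n > 0, colSums(cc, na.rm = TRUE) / (2 * n), NA_real_)
    he <- ifelse(n >= 1, (2 * n) / pmax(2 * n - 1, 1) * 2 * p * (1 - p), 0)
    het <- ifelse(n > 0, colSums(cc == 1L, na.rm = TRUE) / n, NA_real_)
    list(p = p, he = ifelse(is.na(he), 0, he), het = het, n = n,
         poly = !is.na(p) & p > 0 & p < 1)
  }
  a <- stat_block(idx_N)
  b <- stat_block(idx_S)
  comp <- wc_components(g$calls[c(idx_N, idx_S), , drop = FALSE],
                        rep(c("A", "B"), c(length(idx_N), length(idx_S))))
  den <- comp$a + comp$b + comp$c
  fst <- ifelse(!is.na(den) & den != 0, comp$a / den, NA_real_)
  jx <- a$p^2 + (1 - a$p)^2
  jy <- b$p^2 + (1 - b$p)^2
  jxy <- a$p * b$p + (1 - a$p) * (1 - b$p)
  nei <- -log(jxy / sqrt(jx * jy))
  mean_nonnull <- function(x) {
    ok <- is.finite(x) & x != 0
    if (any(ok)) mean(x[ok]) else 0
  }
  mean_all <- function(x) mean(ifelse(is.finite(x), x, 0))
  div_poly <- function(s) if (any(s$poly)) mean(s$he[s$poly]) else 0
  c(div_poly_N = div_poly(a), div_all_N = mean(a$he),
    div_poly_S = div_poly(b), div_all_S = mean(b$he),
    fst_nonnull = mean_nonnull(fst), fst_all = mean_all(fst),
    nei_nonnull = mean_nonnull(nei), nei_all = mean_all(nei))
}

stat_names <- function() c("div_poly_N", "div_all_N", "div_poly_S",
                           "div_all_S", "fst_nonnull", "fst_all",
                           "nei_nonnull", "nei_all")

#' Scenario definition for reference-table simulation
#'
#' Bundles a scenario name, its prior, and a builder mapping one prior
#' draw to a [build_two_decline_scenario()]-style demographic scenario.
#'
#' @param name scenario label
#' @param prior a [prior_spec()]
#' @param build `function(draw, n_N, n_S)` returning a
#'   `demographic_scenario`
#' @return list of class `abc_scenario`.
#' @export
abc_scenario <- function(name, prior, build) {
  structure(list(name = name, prior = prior, build = build),
            class = "abc_scenario")
}

#' The two competing fur-seal scenarios
#'
#' Two-decline (bottlenecked) versus constant-ancestral-size null, with
#' their default priors.
#'
#' @return named list of two [abc_scenario()] objects.
#' @export
fur_seal_scenarios <- function() {
  list(
    two_decline = abc_scenario(
      "two_decline", fur_seal_priors(),
      function(draw, n_N, n_S)
        build_two_decline_scenario(do.call(scenario_params, as.list(draw)),
                                   n_N, n_S)),
    null = abc_scenario(
      "null", null_scenario_priors(),
      function(draw, n_N, n_S)
        build_null_scenario(draw$Ne_constant, draw$Ne_NZ_N, draw$Ne_NZ_S,
                            draw$t_post_seal, n_N, n_S)))
}

#' Build an ABC reference table
#'
#' For each scenario: draw parameters from its prior, simulate a SNP
#' dataset, and record the eight summary statistics. Reproducible given
#' `seed`.
#'
#' @param scenarios named list of [abc_scenario()] objects
#' @param n_N,n_S diploid sample sizes
#' @param sim_cfg a [sim_config()] (its `seed` is ignored; `seed` below
#'   governs the whole table)
#' @param n_per_scenario simulations per scenario
#' @param seed integer seed
#' @return tibble of class `abc_reftable`: `scenario`, parameter columns,
#'   eight statistic columns.
#' @export
build_reference_table <- function(scenarios, n_N, n_S, sim_cfg,
                                  n_per_scenario, seed = 1L) {
  stopifnot(length(scenarios) >= 1)
  out <- with_seed(seed, {
    purrr::imap(scenarios, function(sc, nm) {
      draws <- sample_priors(sc$prior, n_per_scenario)
      stats_m <- matrix(NA_real_, n_per_scenario, 8,
                        dimnames = list(NULL, stat_names()))
      for (i in seq_len(n_per_scenario)) {
        s <- sc$build(draws[i, ], n_N, n_S)
        m <- sim_scenario_matrix(s, sim_cfg)
        stats_m[i, ] <- summary_stats_matrix(m, seq_len(n_N),
                                             n_N + seq_len(n_S))
      }
      dplyr::bind_cols(tibble::tibble(scenario = nm), draws,
                       tibble::as_tibble(stats_m))
    })
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("abc_reftable", class(out))
  out
}

#' ABC rejection step
#'
#' Statistics are standardized by their standard deviation across the
#' table (zero-variance statistics are excluded with a warning), distances
#' are Euclidean, and the `ceiling(tolerance * n)` closest rows are
#' retained (ties broken by row order).
#'
#' @param table an `abc_reftable` (or any tibble with the statistic
#'   columns)
#' @param observed named statistic vector from [summary_stats()]
#' @param tolerance retained fraction in (0, 1]
#' @return list of class `abc_rejection`: `retained` (tibble with
#'   `distance`), `observed`, `stat_sd`, `stats_used`, `tolerance`.
#' @export
abc_reject <- function(table, observed, tolerance = 0.01) {
  if (tolerance <= 0 || tolerance > 1)
    stop("tolerance must lie in (0, 1]", call. = FALSE)
  sn <- intersect(stat_names(), names(table))
  X <- as.matrix(table[, sn])
  sds <- apply(X, 2, stats::sd)
  use <- sds > 0
  if (!all(use))
    warning("zero-variance statistic(s) excluded from distance: ",
            paste(sn[!use], collapse = ", "))
  Z <- sweep(X[, use, drop = FALSE], 2, sds[use], "/")
  z0 <- observed[sn][use] / sds[use]
  d <- sqrt(rowSums(sweep(Z, 2, z0)^2))
  keep <- order(d)[seq_len(ceiling(tolerance * nrow(table)))]
  retained <- table[keep, ]
  retained$distance <- d[keep]
  structure(list(retained = retained, observed = observed[sn],
                 stat_sd = sds, stats_used = sn[use],
                 tolerance = tolerance),
            class = "abc_rejection")
}

#' Scenario posterior probabilities (model choice)
#'
#' Direct estimate: scenario frequencies among the retained simulations.
#' Logistic estimate: multinomial logistic regression of the scenario
#' label on the standardized statistics over the retained rows, evaluated
#' at the observed vector. Probabilities are clipped to `[eps, 1 - eps]`
#' and renormalized.
#'
#' @param rejection an [abc_reject()] result built from a multi-scenario
#'   table
#' @param method `"direct"`, `"logistic"` or `"both"`
#' @param eps clipping constant
#' @return tibble of class `model_choice`: `scenario`, `direct` and/or
#'   `logistic` columns.
#' @export
model_choice <- function(rejection, method = c("both", "direct", "logistic"),
                         eps = 1e-6) {
  method <- match.arg(method)
  ret <- rejection$retained
  scen_all <- sort(unique(ret$scenario))
  if (length(scen_all) < 1) stop("no retained rows", call. = FALSE)
  clip_norm <- function(p) {
    p <- pmin(pmax(p, eps), 1 - eps)
    p / sum(p)
  }
  out <- tibble::tibble(scenario = scen_all)
  if (method %in% c("both", "direct")) {
    freq <- vapply(scen_all, function(s) mean(ret$scenario == s), numeric(1))
    out$direct <- unname(clip_norm(freq))
  }
  if (method %in% c("both", "logistic")) {
    if (length(scen_all) == 1) {
      warning("single scenario among retained rows; degenerate model choice")
      out$logistic <- 1
    } else {
      Z <- sweep(as.matrix(ret[, rejection$stats_used]), 2,
                 rejection$stat_sd[rejection$stats_used], "/")
      # drop duplicated (near-perfectly collinear) statistics: they carry
      # no extra information and destabilize the regression
      cc <- suppressWarnings(stats::cor(Z))
      keep <- rep(TRUE, ncol(Z))
      for (i in seq_len(ncol(Z))[-1])
        if (any(abs(cc[i, seq_len(i - 1)][keep[seq_len(i - 1)]]) > 0.999,
                na.rm = TRUE)) keep[i] <- FALSE
      Z <- Z[, keep, drop = FALSE]
      df <- data.frame(scenario = factor(ret$scenario, levels = scen_all), Z)
      z0 <- as.data.frame(t((rejection$observed[rejection$stats_used] /
                               rejection$stat_sd[rejection$stats_used])[keep]))
      names(z0) <- colnames(Z)
      # Epanechnikov weights on rejection distance, as in the local
      # regression step
      dmax <- max(ret$distance %||% rep(1, nrow(ret)))
      w <- if (is.null(ret$distance) || dmax == 0) rep(1, nrow(ret))
           else 1 - (ret$distance / dmax)^2
      w[w <= 0] <- min(w[w > 0]) * 1e-3
      fit <- nnet::multinom(scenario ~ ., data = df, weights = w,
                            trace = FALSE, maxit = 500)
      pr <- stats::predict(fit, newdata = z0, type = "probs")
      if (is.null(dim(pr))) {
        if (length(pr) == 1) pr <- c(1 - pr, pr)  # binomial case
        names(pr) <- scen_all
      }
      out$logistic <- unname(clip_norm(as.numeric(pr[scen_all])))
    }
  }
  class(out) <- c("model_choice", class(out))
  out
}

#' Local-linear (Beaumont) posterior adjustment
#'
#' Parameters are transformed (log for sizes, scaled logit for times,
#' using the prior bounds), regressed on the standardized statistics with
#' Epanechnikov weights on rejection distance, and the regression
#' prediction at the observed statistics replaces the fitted part; the
#' adjusted draws are back-transformed and so respect the prior bounds.
#' A singular regression falls back to the unadjusted rejection sample
#' with a warning.
#'
#' @param rejection an [abc_reject()] result (single-scenario rows; use
#'   `scenario` to filter a multi-scenario table)
#' @param prior the scenario's [prior_spec()] (provides bounds and the
#'   parameter list)
#' @param scenario optional scenario name to filter the retained rows
#' @return object of class `abc_posterior`: `draws` (tibble of adjusted
#'   parameters), `weights`, `prior`, `unadjusted` (tibble).
#' @export
adjust_posterior <- function(rejection, prior, scenario = NULL) {
  ret <- rejection$retained
  if (!is.null(scenario)) ret <- ret[ret$scenario == scenario, ]
  if (nrow(ret) < 50)
    stop("need >= 50 retained draws for posterior adjustment", call. = FALSE)
  pars <- prior$params$param
  lo <- stats::setNames(prior$params$lower, pars)
  hi <- stats::setNames(prior$params$upper, pars)
  fwd <- function(x, pm) {
    if (startsWith(pm, "t_")) {
      u <- (x - lo[pm]) / (hi[pm] - lo[pm])
      u <- pmin(pmax(u, 1e-8), 1 - 1e-8)
      stats::qlogis(u)
    } else log(x)
  }
  bwd <- function(z, pm) {
    if (startsWith(pm, "t_"))
      lo[pm] + (hi[pm] - lo[pm]) * stats::plogis(z)
    else exp(z)
  }
  Z <- sweep(as.matrix(ret[, rejection$stats_used]), 2,
             rejection$stat_sd[rejection$stats_used], "/")
  z0 <- rejection$observed[rejection$stats_used] /
    rejection$stat_sd[rejection$stats_used]
  dmax <- max(ret$distance)
  w <- if (dmax == 0) rep(1, nrow(ret)) else 1 - (ret$distance / dmax)^2
  w[w <= 0] <- min(w[w > 0]) * 1e-3  # keep boundary rows, tiny weight
  draws <- ret[, pars]
  adjusted <- draws
  for (pm in pars) {
    tp <- fwd(draws[[pm]], pm)
    fit <- tryCatch(
      stats::lm.wfit(cbind(1, Z), tp, w),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("singular local-linear regression for ", pm,
              "; returning unadjusted draws")
      adjusted[[pm]] <- draws[[pm]]
    } else {
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0  # aliased columns: pivoted fit used 0
      pred0 <- sum(c(1, z0) * coefs)
      adjusted[[pm]] <- bwd(pred0 + fit$residuals, pm)
    }
  }
  structure(list(draws = adjusted, weights = w / sum(w), prior = prior,
                 unadjusted = draws),
            class = "abc_posterior")
}

#' Posterior mode and central 90% interval per parameter
#'
#' Mode from a weighted Gaussian kernel density (Silverman bandwidth) on
#' the untransformed scale; quantiles are weighted 5% and 95%.
#'
#' @param posterior an [adjust_posterior()] result
#' @return tibble with `param`, `mode`, `q05`, `q95` in prior row order.
#' @export
posterior_summary <- function(posterior) {
  pars <- posterior$prior$params$param
  w <- posterior$weights
  dplyr::bind_rows(lapply(pars, function(pm) {
    x <- posterior$draws[[pm]]
    q <- weighted_quantile(x, w, c(0.05, 0.95))
    tibble::tibble(param = pm, mode = weighted_mode(x, w),
                   q05 = q[1], q95 = q[2])
  }))
}

#' Tidy an adjusted ABC posterior
#' @param x an `abc_posterior`
#' @param ... unused
#' @return long tibble of weighted draws: `param`, `value`, `weight`.
#' @export
tidy.abc_posterior <- function(x, ...) {
  dplyr::mutate(
    tidyr::pivot_longer(
      dplyr::bind_cols(x$draws, .weight = x$weights),
      -".weight", names_to = "param", values_to = "value"),
    weight = .data$.weight, .weight = NULL)
}

#' One-row summary of an ABC posterior
#' @param x an `abc_posterior`
#' @param ... unused
#' @return wide tibble of posterior modes.
#' @export
glance.abc_posterior <- function(x, ...) {
  s <- posterior_summary(x)
  tidyr::pivot_wider(s[, c("param", "mode")], names_from = "param",
                     values_from = "mode")
}

#' Confidence in scenario choice: type I and II error rates
#'
#' Simulates pseudo-observed datasets (PODs) under each scenario with
#' parameters drawn from `pod_priors`, classifies each by rejection plus
#' model choice against the full reference table, and reports: type I, the
#' fraction of focal-scenario PODs not assigned to the focal scenario;
#' type II, the fraction of alternative-scenario PODs assigned to the
#' focal scenario.
#'
#' @param table a multi-scenario `abc_reftable`
#' @param scenarios the named list of [abc_scenario()] objects used to
#'   build the table
#' @param focal name of the focal scenario
#' @param pod_priors named list of [prior_spec()] objects to draw POD
#'   parameters from (defaults to each scenario's own prior)
#' @param n_pods PODs per scenario
#' @param n_N,n_S diploid sample sizes
#' @param sim_cfg a [sim_config()]
#' @param tolerance rejection tolerance
#' @param method `"logistic"` or `"direct"` classification probabilities
#' @param seed integer seed
#' @return tibble of class `scenario_confidence`: `type_I`, `type_II`,
#'   `n_pods`; attribute `assignments` holds the per-POD table.
#' @export
scenario_confidence <- function(table, scenarios, focal = names(scenarios)[1],
                                pod_priors = NULL, n_pods = 100L,
                                n_N, n_S, sim_cfg = sim_config(),
                                tolerance = 0.01,
                                method = c("logistic", "direct"),
                                seed = 1L) {
  method <- match.arg(method)
  if (n_pods < 1) stop("n_pods must be >= 1", call. = FALSE)
  if (is.null(pod_priors))
    pod_priors <- purrr::map(scenarios, "prior")
  rows <- with_seed(seed, {
    purrr::imap(scenarios, function(sc, nm) {
      draws <- sample_priors(pod_priors[[nm]], n_pods)
      assigned <- character(n_pods)
      for (i in seq_len(n_pods)) {
        s <- sc$build(draws[i, ], n_N, n_S)
        m <- sim_scenario_matrix(s, sim_cfg)
        obs <- summary_stats_matrix(m, seq_len(n_N), n_N + seq_len(n_S))
        mc <- model_choice(abc_reject(table, obs, tolerance),
                           method = method)
        assigned[i] <- mc$scenario[which.max(mc[[method]])]
      }
      tibble::tibble(generating = nm, assigned = assigned)
    })
  })
  assignments <- dplyr::bind_rows(rows)
  foc <- assignments$generating == focal
  out <- tibble::tibble(
    focal = focal,
    type_I = mean(assignments$assigned[foc] != focal),
    type_II = mean(assignments$assigned[!foc] == focal),
    n_pods = n_pods)
  class(out) <- c("scenario_confidence", class(out))
  attr(out, "assignments") <- assignments
  out
}
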