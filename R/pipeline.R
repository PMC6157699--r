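#' Run the full analysis pipeline
#'
#' Executes the study's analysis order on a fixture or user dataset:
#' quality control, diversity/differentiation statistics,
#' isolation-by-distance, AMOVA, ABC model choice, the FST-outlier scan,
#' and leave-one-out assignment, writing TSV/JSON reports and a run
#' manifest. Any stage failure halts with the stage name.
#'
#' The configuration is a nested list (or path to an equivalent YAML
#' file) with elements:
#' \describe{
#'   \item{input}{either `list(ped = ..., individuals = ..., colonies
#'     = ...)` / `list(vcf = ...)`, or `list(synth = TRUE, n_loci = ...,
#'     seed = ...)` to generate a synthetic study}
#'   \item{out_dir}{output directory}
#'   \item{stages}{named logical toggles: `stats`, `ibd`, `amova`, `abc`,
#'     `outliers`, `assign` (QC always runs)}
#'   \item{qc}{arguments for [qc_config()]}
#'   \item{perm}{permutations for the statistics stages}
#'   \item{abc}{`n_per_scenario`, `n_loci`, `tolerance`, `samples` (two
#'     cluster labels)}
#'   \item{outliers}{`n_sims`, `ci`, `fdr`}
#'   \item{assign}{arguments for [assign_config()]}
#'   \item{seeds}{named integer seeds per stage: `qc`, `stats`, `ibd`,
#'     `amova`, `abc`, `outliers`, `assign`}
#' }
#'
#' @param config nested list or YAML path
#' @return invisibly, a list with every stage's result plus the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- utils::modifyList(
    list(stats = TRUE, ibd = TRUE, amova = TRUE, abc = TRUE,
         outliers = TRUE, assign = TRUE),
    config$stages %||% list())
  seeds <- utils::modifyList(
    list(qc = 1L, stats = 2L, ibd = 3L, amova = 4L, abc = 5L,
         outliers = 6L, assign = 7L),
    config$seeds %||% list())
  perm <- config$perm %||% 199L
  results <- list()
  ran <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # input
  inp <- config$input %||% list(synth = TRUE)
  if (isTRUE(inp$synth)) {
    study <- stage("input", generate_study(synth_config(
      n_loci = inp$n_loci %||% 2000L, seed = inp$seed %||% 1L)))
    g <- study$genotypes; pops <- study$pops
  } else if (!is.null(inp$ped) || !is.null(inp$vcf)) {
    g <- stage("input", if (!is.null(inp$ped))
      read_genotypes(inp$ped, "ped_map") else
      read_genotypes(inp$vcf, "vcf"))
    pops <- stage("input", read_pop_map(inp$individuals, inp$colonies))
  } else stop("pipeline config: no input specified", call. = FALSE)

  # qc (always)
  qc_res <- stage("qc", apply_qc(g, pops,
                                 do.call(qc_config, config$qc %||% list())))
  g <- qc_res$genotypes
  write_filter_report(qc_res$report,
                      file.path(out_dir, "filter_report.tsv"),
                      file.path(out_dir, "filter_report.json"))
  results$qc <- qc_res
  ran <- c(ran, "qc")

  fst <- NULL
  if (stages$stats) {
    results$diversity <- stage("stats",
      diversity_table(g, pops, n_perm = perm, seed = seeds$stats))
    utils::write.table(results$diversity,
                       file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fst <- stage("stats", pairwise_fst(g, pops, n_perm = perm,
                                       seed = seeds$stats))
    results$fst <- fst
    utils::write.table(tidy(fst), file.path(out_dir, "fst_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ran <- c(ran, "stats")
  }
  if (stages$ibd) {
    if (is.null(fst)) fst <- stage("ibd", pairwise_fst(g, pops))
    results$ibd <- stage("ibd", ibd_test(fst, pops, n_perm = perm,
                                         seed = seeds$ibd))
    utils::write.table(results$ibd, file.path(out_dir, "ibd.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ran <- c(ran, "ibd")
  }
  if (stages$amova) {
    results$amova <- stage("amova", amova(g, pops, n_perm = perm,
                                          seed = seeds$amova))
    utils::write.table(tidy(results$amova),
                       file.path(out_dir, "amova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ran <- c(ran, "amova")
  }
  if (stages$abc) {
    acfg <- config$abc %||% list()
    samples <- acfg$samples %||% c("NZ-North-West", "NZ-South")
    n_use <- min(acfg$n_loci %||% 1000L, n_loci(g))
    g_abc <- subset_loci(g, n_use, seed = seeds$abc)
    lab <- group_labels(g_abc, pops, "cluster")
    n_N <- sum(lab == samples[1]); n_S <- sum(lab == samples[2])
    scen <- fur_seal_scenarios()
    tab <- stage("abc", build_reference_table(
      scen, n_N, n_S, sim_config(n_loci = n_use),
      n_per_scenario = acfg$n_per_scenario %||% 500L, seed = seeds$abc))
    obs <- stage("abc", summary_stats(g_abc, pops, samples, "cluster"))
    rej <- stage("abc", abc_reject(tab, obs,
                                   tolerance = acfg$tolerance %||% 0.05))
    results$model_choice <- stage("abc", model_choice(rej))
    utils::write.table(results$model_choice,
                       file.path(out_dir, "model_choice.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    best <- results$model_choice$scenario[
      which.max(results$model_choice$logistic)]
    post <- tryCatch(
      adjust_posterior(rej, scen[[best]]$prior, scenario = best),
      error = function(e) NULL)
    if (!is.null(post)) {
      results$posterior <- posterior_summary(post)
      utils::write.table(results$posterior,
                         file.path(out_dir, "posterior.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ran <- c(ran, "abc")
  }
  if (stages$outliers) {
    ocfg <- config$outliers %||% list()
    results$outliers <- stage("outliers", fdist_scan(
      g, pops, n_sims = ocfg$n_sims %||% 50000L, ci = ocfg$ci %||% 0.99,
      seed = seeds$outliers))
    utils::write.table(results$outliers$loci,
                       file.path(out_dir, "outlier_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(results$outliers$envelope,
                       file.path(out_dir, "outlier_envelope.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ran <- c(ran, "outliers")
  }
  if (stages$assign) {
    results$assign <- stage("assign", assign_individuals(
      g, pops, level = "colony",
      cfg = do.call(assign_config,
                    utils::modifyList(list(seed = seeds$assign),
                                      config$assign %||% list()))))
    utils::write.table(results$assign$accuracy,
                       file.path(out_dir, "assignment_accuracy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ran <- c(ran, "assign")
  }

  manifest <- list(
    package = "fursealpop",
    version = as.character(utils::packageVersion("fursealpop")),
    stages = ran,
    seeds = seeds,
    n_individuals = n_individuals(g),
    n_loci = n_loci(g),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
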