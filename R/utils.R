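#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream
#' @param expr expression to evaluate
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# (k+1)/(n+1)-smoothed permutation p-value
perm_pvalue <- function(n_as_extreme, n_perm) {
  (n_as_extreme + 1) / (n_perm + 1)
}

# weighted quantile (type-4-style, linear on the weighted ECDF)
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p)[1]
    if (is.na(i)) x[length(x)] else x[i]
  }, numeric(1))
}

# mode of a weighted Gaussian KDE (Silverman bandwidth)
weighted_mode <- function(x, w) {
  if (length(unique(x)) == 1L) return(x[1])
  w <- w / sum(w)
  # Silverman bandwidth from the raw draws; weights enter the KDE only
  d <- suppressWarnings(stats::density(x, weights = w, bw = "nrd0"))
  d$x[which.max(d$y)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
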