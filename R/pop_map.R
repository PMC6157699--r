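#' Population (colony) map
#'
#' Maps every individual to a breeding colony, every colony to a genetic
#' cluster, and optionally every colony to geographic coordinates (decimal
#' degrees, required for isolation-by-distance tests).
#'
#' @param individuals tibble with columns `individual_id`, `colony`
#' @param colonies tibble with columns `colony`, `cluster` and optionally
#'   `lat`, `lon`
#' @return an object of class `pop_map`: list of the two validated tibbles.
#' @examples
#' pm <- pop_map(
#'   tibble::tibble(individual_id = c("a", "b"), colony = c("OBI", "HB")),
#'   tibble::tibble(colony = c("OBI", "HB"),
#'                  cluster = c("NZ-North-West", "NZ-South"))
#' )
#' @export
pop_map <- function(individuals, colonies) {
  individuals <- tibble::as_tibble(individuals)
  colonies <- tibble::as_tibble(colonies)
  if (!all(c("individual_id", "colony") %in% names(individuals)))
    stop("`individuals` needs columns individual_id, colony", call. = FALSE)
  if (!all(c("colony", "cluster") %in% names(colonies)))
    stop("`colonies` needs columns colony, cluster", call. = FALSE)
  if (anyDuplicated(individuals$individual_id))
    stop("duplicated individual IDs in population map", call. = FALSE)
  if (anyDuplicated(colonies$colony))
    stop("duplicated colony codes", call. = FALSE)
  missing_col <- setdiff(individuals$colony, colonies$colony)
  if (length(missing_col))
    stop("colonies without a cluster assignment: ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  structure(list(individuals = individuals, colonies = colonies),
            class = "pop_map")
}

#' @export
print.pop_map <- function(x, ...) {
  cat(sprintf("<pop_map> %d individuals, %d colonies, %d clusters\n",
              nrow(x$individuals), nrow(x$colonies),
              length(unique(x$colonies$cluster))))
  invisible(x)
}

#' Group labels for the individuals of a genotype matrix
#'
#' @param g a [geno_matrix()]
#' @param pops a [pop_map()] covering all individuals of `g`
#' @param level `"colony"`, `"cluster"` or `"global"`
#' @return character vector of group labels, one per individual of `g`.
#' @export
group_labels <- function(g, pops, level = c("colony", "cluster", "global")) {
  level <- match.arg(level)
  ids <- individuals(g)
  idx <- match(ids, pops$individuals$individual_id)
  if (anyNA(idx))
    stop("individuals missing from the population map: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  colony <- pops$individuals$colony[idx]
  switch(level,
    colony = colony,
    cluster = pops$colonies$cluster[match(colony, pops$colonies$colony)],
    global = rep("global", length(ids))
  )
}

#' Great-circle distances between colonies
#'
#' Pairwise geographic distance matrix (kilometres) from colony coordinates,
#' used as the predictor side of the isolation-by-distance Mantel test.
#'
#' @param pops a [pop_map()] whose `colonies` table has `lat`, `lon`
#' @return symmetric matrix of great-circle distances in km, colony codes as
#'   dimnames.
#' @export
colony_distances <- function(pops) {
  cc <- pops$colonies
  if (!all(c("lat", "lon") %in% names(cc)) || anyNA(cc$lat) || anyNA(cc$lon))
    stop("colony coordinates (lat, lon) are required for geographic distances",
         call. = FALSE)
  n <- nrow(cc)
  d <- matrix(0, n, n, dimnames = list(cc$colony, cc$colony))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      d[i, j] <- d[j, i] <-
        geosphere::distGeo(c(cc$lon[i], cc$lat[i]),
                           c(cc$lon[j], cc$lat[j])) / 1000
    }
  }
  d
}

#' Read a population map from TSV
#'
#' Expects an individuals file with columns `individual_id`, `colony` and a
#' colonies file with `colony`, `cluster` and optional `lat`, `lon`.
#'
#' @param individuals_path,colonies_path TSV paths
#' @return a [pop_map()].
#' @export
read_pop_map <- function(individuals_path, colonies_path) {
  ind <- utils::read.delim(individuals_path, stringsAsFactors = FALSE)
  col <- utils::read.delim(colonies_path, stringsAsFactors = FALSE)
  pop_map(ind, col)
}

#' Write a population map as TSV
#' @param pops a [pop_map()]
#' @param individuals_path,colonies_path output TSV paths
#' @return invisibly, `pops`.
#' @export
write_pop_map <- function(pops, individuals_path, colonies_path) {
  utils::write.table(pops$individuals, individuals_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pops$colonies, colonies_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(pops)
}
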