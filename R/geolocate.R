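#' Re-georeference displaced rural clusters to the nearest populated cell
#'
#' DHS displaces rural cluster coordinates by up to 10 km, enough to land a
#' cluster far from any settlement. This correction moves each rural cluster
#' to the centre of the nearest cell whose population exceeds a threshold,
#' an automatic surrogate for the manual satellite-imagery re-georeferencing
#' used with real survey data. Urban clusters are never adjusted (their
#' displacement is at most 2 km).
#'
#' Ties at equal distance break to the smaller distance first (exact ties to
#' the smaller row-major cell index). A rural cluster with no populated cell
#' within \code{max_search} stays in place and is flagged in the report.
#'
#' @param clusters Cluster data frame with \code{x}, \code{y},
#'   \code{urban_rural}.
#' @param population A [set_raster()] of per-cell population.
#' @param max_search Search radius in metres; must cover the rural
#'   displacement bound (default 10 km).
#' @param pop_threshold A cell counts as populated when its population is
#'   strictly greater than this (default 0).
#' @return List with \code{clusters} (coordinates updated for snapped rural
#'   clusters) and \code{report} (per-cluster data frame: \code{cluster_id},
#'   \code{snapped}, \code{shift_distance}, \code{matched}).
#' @export
snap_rural_clusters <- function(clusters, population, max_search = 10000,
                                pop_threshold = 0) {
  stopifnot(inherits(population, "set_raster"))
  if (max_search < 0) stop("max_search must be non-negative")
  clusters <- as.data.frame(clusters)
  stopifnot(all(c("x", "y", "urban_rural") %in% names(clusters)))
  grid <- population$grid
  pop_cells <- which(population$values > pop_threshold)
  cc <- cell_centers(grid)[pop_cells, , drop = FALSE]
  n <- nrow(clusters)
  shift <- numeric(n); matched <- rep(TRUE, n); snapped <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (clusters$urban_rural[i] != "rural") next
    if (length(pop_cells) == 0) { matched[i] <- FALSE; next }
    d <- sqrt((cc[, 1] - clusters$x[i])^2 + (cc[, 2] - clusters$y[i])^2)
    best <- which(d == min(d))[1]  # pop_cells is ascending, so first = smallest index
    if (d[best] > max_search) { matched[i] <- FALSE; next }
    shift[i] <- d[best]
    snapped[i] <- TRUE
    clusters$x[i] <- cc[best, 1]
    clusters$y[i] <- cc[best, 2]
  }
  report <- data.frame(cluster_id = clusters$cluster_id, snapped = snapped,
                       shift_distance = shift, matched = matched,
                       stringsAsFactors = FALSE)
  list(clusters = clusters, report = report)
}
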