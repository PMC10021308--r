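#' Catalog of wall and roof materials appropriate for SET
#'
#' Screening + Eave Tubes (SET) needs walls robust enough to hold eave tubes
#' and a roof/eave line that can be closed: the defaults list exactly the
#' finished materials that qualify. Any code not in the appropriate set —
#' including unknown or missing codes — is treated as unsuitable, which is the
#' conservative choice for an intervention-feasibility screen.
#'
#' @param wall_appropriate Character vector of appropriate wall materials.
#' @param roof_appropriate Character vector of appropriate roof materials.
#' @return An object of class \code{material_catalog}.
#' @export
material_catalog <- function(
    wall_appropriate = c("cement", "bricks", "cement blocks", "stone with lime/cement"),
    roof_appropriate = c("metal", "cement", "ceramic tiles", "roofing shingles")) {
  if (length(wall_appropriate) == 0 || length(roof_appropriate) == 0)
    stop("appropriate material sets must be non-empty")
  structure(list(wall_appropriate = unique(as.character(wall_appropriate)),
                 roof_appropriate = unique(as.character(roof_appropriate))),
            class = "material_catalog")
}

# inappropriate labels used by the synthetic generator (standard DHS-style
# inventory; anything outside the catalog's appropriate set classifies as
# unsuitable, these are just realistic draws)
wall_inappropriate_labels <- function() {
  c("no walls", "cane/palm/trunks", "dirt", "bamboo with mud", "stone with mud",
    "uncovered adobe", "plywood", "cardboard", "reused wood", "covered adobe",
    "wood planks/shingles", "mud", "other")
}

roof_inappropriate_labels <- function() {
  c("no roof", "thatch/palm leaf", "sod", "rustic mat", "palm/bamboo",
    "wood planks", "cardboard", "wood", "calamine/cement fiber", "other")
}

#' Lookup table from DHS numeric material codes to labels
#'
#' Ships the standard DHS wall (hv214) and roof (hv215) code inventories with
#' the labels used by [material_catalog()]. Users working from raw DHS
#' recodes can join on \code{component} + \code{code}; the table is an
#' ordinary data frame and can be edited to match country-specific recodes.
#'
#' @return Data frame with columns \code{component} ("wall"/"roof"),
#'   \code{code} (integer DHS code) and \code{label}.
#' @export
dhs_material_lookup <- function() {
  path <- system.file("extdata", "dhs_material_codes.csv", package = "setprior")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Classify a household as suitable for SET
#'
#' A household is suitable when BOTH its wall and its roof material are in
#' the appropriate sets of the catalog. Codes absent from the appropriate
#' sets — including unknown codes — classify as unsuitable; unknown codes
#' (not in either the appropriate set or the shipped inappropriate
#' inventory) additionally raise a warning so data problems surface.
#'
#' @param records Data frame with columns \code{cluster_id},
#'   \code{wall_code}, \code{roof_code} (one row per household).
#' @param catalog A [material_catalog()].
#' @return Logical vector, one flag per record.
#' @examples
#' classify_household(data.frame(cluster_id = 1,
#'                               wall_code = "cement", roof_code = "metal"))
#' @export
classify_household <- function(records, catalog = material_catalog()) {
  records <- as_household_records(records)
  known <- c(catalog$wall_appropriate, catalog$roof_appropriate,
             wall_inappropriate_labels(), roof_inappropriate_labels())
  unk <- unique(c(records$wall_code, records$roof_code))
  unk <- setdiff(unk, known)
  if (length(unk))
    warning("unknown material code(s) classified unsuitable: ",
            paste(unk, collapse = ", "))
  (records$wall_code %in% catalog$wall_appropriate) &
    (records$roof_code %in% catalog$roof_appropriate)
}

as_household_records <- function(records) {
  records <- as.data.frame(records)
  need <- c("cluster_id", "wall_code", "roof_code")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("household records lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) > 0 && (any(!nzchar(as.character(records$wall_code))) ||
                            any(!nzchar(as.character(records$roof_code)))))
    stop("material codes must be non-empty strings")
  records$wall_code <- as.character(records$wall_code)
  records$roof_code <- as.character(records$roof_code)
  records
}

#' Aggregate household classifications into cluster counts
#'
#' Collapses household records to one row per survey cluster: the number of
#' households, the number classified suitable, and the suitability
#' proportion, joined to the cluster coordinate table.
#'
#' @param records Household data frame (\code{cluster_id}, \code{wall_code},
#'   \code{roof_code}).
#' @param coords Cluster table with at least \code{cluster_id}, \code{x},
#'   \code{y}; an optional \code{urban_rural} column ("urban"/"rural") is
#'   carried through.
#' @param catalog A [material_catalog()].
#' @return Data frame with one row per cluster holding \code{cluster_id},
#'   coordinates, \code{n_households}, \code{n_suitable}, \code{proportion}.
#'   Clusters present in \code{coords} but without records are omitted with
#'   a warning; records whose cluster id is missing from \code{coords} are an
#'   error.
#' @export
aggregate_clusters <- function(records, coords, catalog = material_catalog()) {
  records <- as_household_records(records)
  coords <- as.data.frame(coords)
  stopifnot(all(c("cluster_id", "x", "y") %in% names(coords)))
  if (nrow(records) == 0) {
    warning("no household records; returning empty cluster table")
    out <- coords[0, , drop = FALSE]
    out$n_households <- integer(0); out$n_suitable <- integer(0)
    out$proportion <- numeric(0)
    return(out)
  }
  orphan <- setdiff(unique(records$cluster_id), coords$cluster_id)
  if (length(orphan))
    stop("records reference cluster id(s) absent from the coordinate table: ",
         paste(orphan, collapse = ", "))
  suit <- classify_household(records, catalog)
  n <- tapply(suit, records$cluster_id, length)
  k <- tapply(suit, records$cluster_id, sum)
  tab <- data.frame(cluster_id = names(n),
                    n_households = as.integer(n),
                    n_suitable = as.integer(k),
                    stringsAsFactors = FALSE)
  empty <- setdiff(as.character(coords$cluster_id), tab$cluster_id)
  if (length(empty))
    warning(length(empty), " cluster(s) without household records omitted")
  out <- merge(coords, tab, by.x = "cluster_id", by.y = "cluster_id")
  out$cluster_id <- if (is.numeric(coords$cluster_id)) as.numeric(out$cluster_id) else out$cluster_id
  out <- out[order(match(out$cluster_id, coords$cluster_id)), , drop = FALSE]
  out$proportion <- out$n_suitable / out$n_households
  rownames(out) <- NULL
  out
}

#' Summarise cluster suitability by administrative unit
#'
#' Computes, per department and urban/rural class, the five-number summary of
#' cluster suitability proportions (the quantities a suitability boxplot
#' draws). Quartiles use the linear-interpolation convention
#' (\code{quantile type = 7}).
#'
#' @param clusters Cluster table from [aggregate_clusters()] (needs
#'   \code{x}, \code{y}, \code{proportion}; \code{urban_rural} optional).
#' @param departments A [set_raster()] of integer department labels
#'   tessellating the grid.
#' @return Data frame with one row per department x stratum: \code{n_clusters},
#'   \code{min}, \code{q1}, \code{median}, \code{q3}, \code{max}. Clusters
#'   falling outside every department are reported in an
#'   \code{"outside"} row.
#' @export
cluster_suitability_summary <- function(clusters, departments) {
  stopifnot(inherits(departments, "set_raster"))
  clusters <- as.data.frame(clusters)
  stopifnot(all(c("x", "y", "proportion") %in% names(clusters)))
  idx <- cell_index_at(departments$grid, clusters$x, clusters$y)
  dept <- ifelse(is.na(idx), NA, departments$values[idx])
  dept <- ifelse(is.na(dept), "outside", as.character(dept))
  strat <- if ("urban_rural" %in% names(clusters)) as.character(clusters$urban_rural)
           else rep("all", nrow(clusters))
  groups <- split(clusters$proportion, list(department = dept, stratum = strat),
                  drop = TRUE)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    p <- groups[[g]]
    q <- stats::quantile(p, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(department = parts[1], stratum = parts[2], n_clusters = length(p),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$department, out$stratum), , drop = FALSE]
}
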