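#' Extract buffered covariate means at point locations
#'
#' For each point and layer, averages the layer over all cells whose centres
#' lie within the closed disk of the given radius around the point — the
#' raster analogue of a 2-km buffer mean around a survey cluster. If no cell
#' centre falls inside the disk, the value of the cell containing the point
#' is used (and noted via a message). Points outside the grid's bounding box
#' yield \code{NA} with a warning.
#'
#' The inclusion rule is centre-in-disk, not area-weighted intersection;
#' with 5-km cells and a 2-km buffer the fallback path (no centre in disk)
#' is the common one, matching single-cell extraction.
#'
#' @param stack A [covariate_stack()].
#' @param points Two-column matrix or data frame of x, y coordinates.
#' @param radius Buffer radius in metres (> 0). Default 2000.
#' @return Data frame with one row per point and one column per layer.
#' @export
buffer_extract <- function(stack, points, radius = 2000) {
  stopifnot(inherits(stack, "covariate_stack"))
  if (length(stack$layers) == 0) stop("covariate stack has no layers")
  if (radius <= 0) stop("radius must be > 0")
  points <- as.matrix(as.data.frame(points)[, 1:2])
  grid <- stack$grid
  cc <- cell_centers(grid)
  n <- nrow(points)
  out <- matrix(NA_real_, n, length(stack$layers),
                dimnames = list(NULL, names(stack$layers)))
  xmax <- grid$origin_x + grid$n_cols * grid$cell_size
  ymax <- grid$origin_y + grid$n_rows * grid$cell_size
  n_fallback <- 0L
  for (i in seq_len(n)) {
    px <- points[i, 1]; py <- points[i, 2]
    if (is.na(px) || is.na(py) || px < grid$origin_x || px > xmax ||
        py < grid$origin_y || py > ymax) {
      warning(sprintf("point %d lies outside the grid; returning NA", i))
      next
    }
    d2 <- (cc[, 1] - px)^2 + (cc[, 2] - py)^2
    inside <- which(d2 <= radius^2)
    if (length(inside) == 0) {
      inside <- cell_index_at(grid, px, py)
      n_fallback <- n_fallback + 1L
    }
    for (l in seq_along(stack$layers))
      out[i, l] <- mean(stack$layers[[l]][inside])
  }
  if (n_fallback > 0)
    message(n_fallback, " point(s) had no cell centre within the buffer; ",
            "used the containing cell's value")
  as.data.frame(out)
}

#' Assemble the model design matrix from cluster covariate means
#'
#' Builds an intercept-plus-covariates design matrix from a table of
#' per-cluster covariate values, optionally centring and scaling each
#' covariate column. The standardization parameters are recorded so the same
#' affine transform can be replayed on grid-cell covariates at prediction
#' time (an unstandardised prediction grid would silently shift every
#' coefficient).
#'
#' @param cluster_table Data frame of per-cluster covariate means (columns =
#'   covariates). Rows with missing values are dropped with a warning naming
#'   them.
#' @param standardize Centre/scale covariate columns (default TRUE).
#' @param reuse Optional standardization record from a previous call, to
#'   replay the fit-time transform on new data.
#' @return List with \code{X} (matrix, first column the intercept),
#'   \code{standardization} (data frame: \code{layer}, \code{center},
#'   \code{scale}) and \code{kept} (row indices retained).
#' @export
build_design <- function(cluster_table, standardize = TRUE, reuse = NULL) {
  tab <- as.data.frame(cluster_table)
  if (ncol(tab) == 0) {
    X <- matrix(1, nrow(tab), 1, dimnames = list(NULL, "(Intercept)"))
    return(list(X = X, standardization = NULL, kept = seq_len(nrow(tab))))
  }
  bad <- which(!stats::complete.cases(tab))
  if (length(bad)) {
    warning("dropping row(s) with missing covariates: ", paste(bad, collapse = ", "))
    tab <- tab[-bad, , drop = FALSE]
  }
  kept <- setdiff(seq_len(nrow(cluster_table)), bad)
  M <- as.matrix(tab)
  std <- NULL
  if (standardize) {
    if (is.null(reuse)) {
      ctr <- colMeans(M)
      scl <- apply(M, 2, stats::sd)
      zero <- which(scl == 0 | !is.finite(scl))
      if (length(zero))
        stop("zero-variance covariate under standardization: ",
             paste(colnames(M)[zero], collapse = ", "))
      std <- data.frame(layer = colnames(M), center = ctr, scale = scl,
                        row.names = NULL, stringsAsFactors = FALSE)
    } else {
      std <- reuse
      if (!all(colnames(M) %in% std$layer))
        stop("standardization record lacks layer(s): ",
             paste(setdiff(colnames(M), std$layer), collapse = ", "))
      std <- std[match(colnames(M), std$layer), , drop = FALSE]
      ctr <- std$center; scl <- std$scale
    }
    M <- sweep(sweep(M, 2, ctr, "-"), 2, scl, "/")
  }
  X <- cbind("(Intercept)" = 1, M)
  list(X = X, standardization = std, kept = kept)
}
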