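#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (\code{ncols},
#' \code{nrows}, \code{xllcorner}, \code{yllcorner}, \code{cellsize},
#' \code{NODATA_value}) followed by rows of values, top row first, as GIS
#' tools expect.
#'
#' @param x A [set_raster()].
#' @param path File path (conventionally \code{.asc}).
#' @return \code{write_ascii_grid} returns \code{path} invisibly;
#'   \code{read_ascii_grid} returns a [set_raster()].
#' @export
write_ascii_grid <- function(x, path) {
  stopifnot(inherits(x, "set_raster"))
  g <- x$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", g$n_cols), paste("nrows", g$n_rows),
               paste("xllcorner", g$origin_x), paste("yllcorner", g$origin_y),
               paste("cellsize", g$cell_size), "NODATA_value -9999"), con)
  M <- as.matrix(x)                      # row 1 = bottom row of the grid
  M[is.na(M)] <- -9999
  for (i in rev(seq_len(nrow(M))))       # ASCII grids store the top row first
    writeLines(paste(format(M[i, ], trim = TRUE, digits = 10), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param name Layer name for the raster read back.
#' @export
read_ascii_grid <- function(path, name = NULL) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1); val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- tolower(key)
  g <- grid_spec(val[["nrows"]], val[["ncols"]], val[["cellsize"]],
                 val[["xllcorner"]], val[["yllcorner"]])
  rows <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  M <- do.call(rbind, rev(rows))         # back to bottom-row-first
  M[M == -9999] <- NA
  set_raster(g, as.numeric(t(M)), name = name)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Produces \code{households.csv}, \code{clusters.csv}, one \code{.asc} grid
#' per covariate plus \code{prevalence.asc}, \code{population.asc},
#' \code{travel.asc}, \code{departments.asc}, and \code{truth.json} with the
#' generative parameters.
#'
#' @param sim A \code{set_sim_data}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_set_data <- function(sim, dir) {
  stopifnot(inherits(sim, "set_sim_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$households, file.path(dir, "households.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$clusters, file.path(dir, "clusters.csv"), row.names = FALSE)
  if (!is.null(sim$covariates))
    for (nm in names(sim$covariates$layers))
      write_ascii_grid(set_raster(sim$grid, sim$covariates$layers[[nm]], nm),
                       file.path(dir, paste0(nm, ".asc")))
  for (nm in c("prevalence", "population", "travel", "departments"))
    write_ascii_grid(sim[[nm]], file.path(dir, paste0(nm, ".asc")))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- sim$truth
    jsonlite::write_json(list(beta0 = tr$beta0, beta_j = tr$beta_j,
                              gp_sigma = tr$gp_sigma, gp_range = tr$gp_range,
                              phi = tr$phi, nu = tr$nu),
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' Read a dataset written by [write_set_data()]
#'
#' @param dir Directory path.
#' @return A list shaped like a \code{set_sim_data} (without the latent
#'   truth fields), usable by [run_set_pipeline()].
#' @export
read_set_data <- function(dir) {
  households <- utils::read.csv(file.path(dir, "households.csv"),
                                stringsAsFactors = FALSE)
  clusters <- utils::read.csv(file.path(dir, "clusters.csv"),
                              stringsAsFactors = FALSE)
  ctx <- lapply(c("prevalence", "population", "travel", "departments"),
                function(nm) read_ascii_grid(file.path(dir, paste0(nm, ".asc")), nm))
  names(ctx) <- c("prevalence", "population", "travel", "departments")
  grid <- ctx$prevalence$grid
  cov_files <- setdiff(list.files(dir, pattern = "\\.asc$"),
                       paste0(names(ctx), ".asc"))
  covariates <- NULL
  if (length(cov_files)) {
    layers <- lapply(cov_files, function(f)
      read_ascii_grid(file.path(dir, f))$values)
    names(layers) <- sub("\\.asc$", "", cov_files)
    covariates <- covariate_stack(grid, layers)
  }
  structure(c(list(grid = grid, households = households, clusters = clusters,
                   covariates = covariates), ctx),
            class = "set_sim_data")
}
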