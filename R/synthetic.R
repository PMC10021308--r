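#' Ground-truth parameters for the synthetic world
#'
#' Bundles the generative parameters of the simulated suitability surface:
#' a logit-linear predictor over standardized covariates plus a zero-mean
#' Matern Gaussian process, with beta-binomial sampling at cluster level.
#'
#' @param beta0 Intercept on the logit scale.
#' @param beta_j Numeric vector of covariate coefficients (logit scale); its
#'   length sets the number of covariate layers used.
#' @param gp_sigma Marginal standard deviation of the latent field.
#' @param gp_range Matern scale parameter (metres).
#' @param phi Beta-binomial precision (> 0); smaller means more
#'   cluster-level overdispersion.
#' @param nu Matern smoothness.
#' @return An object of class \code{synthetic_truth}; fields
#'   \code{latent_field} and \code{true_p} are filled in by
#'   [simulate_set_data()].
#' @export
synthetic_truth <- function(beta0 = -0.5, beta_j = c(1.5, -0.8),
                            gp_sigma = 1, gp_range = 25000, phi = 15, nu = 1) {
  if (gp_sigma < 0 || gp_range <= 0 || phi <= 0 || nu <= 0)
    stop("gp_sigma must be >= 0 and gp_range, phi, nu > 0")
  structure(list(beta0 = beta0, beta_j = as.numeric(beta_j), gp_sigma = gp_sigma,
                 gp_range = gp_range, phi = phi, nu = nu,
                 latent_field = NULL, true_p = NULL),
            class = "synthetic_truth")
}

#' Generate smooth standardized covariate rasters
#'
#' Draws \code{n_layers} independent smooth Gaussian fields over the grid
#' (Matern, nu = 1) and standardizes each to cell mean 0, sd 1. These stand
#' in for the housing-development covariates of the real analysis (aridity,
#' travel time to the nearest city, degree of urbanisation, crop production
#' value); they carry the right spatial statistics, not the semantics.
#'
#' @param grid A [grid_spec()].
#' @param n_layers Number of layers (>= 1).
#' @param smoothness_range Matern scale of the fields, metres. As it tends
#'   to 0 the layers approach independent cell noise.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A [covariate_stack()] with layers named \code{cov1}, \code{cov2}, ...
#' @export
generate_covariate_rasters <- function(grid, n_layers, smoothness_range = 30000,
                                       seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  if (n_layers < 1) stop("n_layers must be >= 1")
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    f <- simulate_latent_field(grid, gp_sigma = 1, gp_range = smoothness_range,
                               nu = 1, seed = seed + 7919L * l)
    layers[[l]] <- (f - mean(f)) / stats::sd(f)
  }
  names(layers) <- paste0("cov", seq_len(n_layers))
  covariate_stack(grid, layers)
}

#' Simulate one draw of the latent Matern Gaussian field
#'
#' Draws a zero-mean Gaussian process with Matern covariance over the grid's
#' cell centres by Cholesky factorisation of the exact covariance matrix
#' (practical up to a few thousand cells).
#'
#' @param grid A [grid_spec()].
#' @param gp_sigma Marginal sd (>= 0; 0 returns the zero field).
#' @param gp_range Matern scale parameter (metres, > 0).
#' @param nu Smoothness (> 0).
#' @param seed Integer seed.
#' @return Numeric vector of per-cell field values (row-major).
#' @export
simulate_latent_field <- function(grid, gp_sigma, gp_range, nu = 1, seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  if (gp_sigma < 0 || gp_range <= 0 || nu <= 0)
    stop("gp_sigma must be >= 0 and gp_range, nu > 0")
  m <- n_cells(grid)
  if (gp_sigma == 0) return(numeric(m))
  K <- matern_cov_matrix(cell_centers(grid), sigma = gp_sigma,
                         range_param = gp_range, nu = nu, jitter = 1e-8)
  L <- tryCatch(chol(K), error = function(e)
    stop("latent-field covariance not positive definite after jitter: ",
         conditionMessage(e)))
  with_seed(seed, as.numeric(crossprod(L, stats::rnorm(m))))
}

# run code under a temporary RNG state so generators are deterministic by
# seed without clobbering the caller's stream
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Sample survey clusters and household records from the synthetic truth
#'
#' Places clusters on distinct random grid cells, draws each cluster's size
#' uniformly on 15..32 households (the range of the motivating survey),
#' draws its suitable count from the beta-binomial law with mean equal to
#' the true per-cell suitability and precision \code{phi}, and emits one
#' household record per house with material codes consistent with the count:
#' suitable houses get appropriate wall and roof codes, unsuitable houses
#' get at least one inappropriate component.
#'
#' @param grid A [grid_spec()].
#' @param n_clusters Number of clusters (must not exceed the cell count).
#' @param urban_fraction Proportion of clusters flagged urban (rounded to a
#'   whole number of clusters, assigned at random).
#' @param truth A [synthetic_truth()] whose \code{true_p} has been filled in
#'   (see [simulate_set_data()]), or a numeric per-cell \code{true_p} vector.
#' @param seed Integer seed.
#' @return List with \code{clusters} (data frame: \code{cluster_id}, true
#'   cell-centre coordinates \code{x}, \code{y}, \code{urban_rural},
#'   \code{cell}, \code{n_households}, \code{n_suitable}) and
#'   \code{households} (data frame: \code{cluster_id}, \code{wall_code},
#'   \code{roof_code}).
#' @export
sample_clusters <- function(grid, n_clusters, urban_fraction, truth, seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  if (urban_fraction < 0 || urban_fraction > 1)
    stop("urban_fraction must lie in [0, 1]")
  true_p <- if (inherits(truth, "synthetic_truth")) truth$true_p else as.numeric(truth)
  if (is.null(true_p)) stop("truth$true_p is empty; run simulate_set_data() first")
  phi <- if (inherits(truth, "synthetic_truth")) truth$phi else Inf
  m <- n_cells(grid)
  if (n_clusters > m)
    stop("n_clusters exceeds the number of grid cells; unique placement impossible")
  with_seed(seed, {
    cells <- sample.int(m, n_clusters)
    n <- sample(15:32, n_clusters, replace = TRUE)
    mu <- true_p[cells]
    p <- if (is.infinite(phi)) mu else stats::rbeta(n_clusters, mu * phi, (1 - mu) * phi)
    p[mu >= 1] <- 1; p[mu <= 0] <- 0   # degenerate Beta endpoints
    k <- stats::rbinom(n_clusters, n, p)
    n_urban <- round(n_clusters * urban_fraction)
    urban <- rep("rural", n_clusters)
    urban[sample.int(n_clusters, n_urban)] <- "urban"
    cc <- cell_centers(grid)
    clusters <- data.frame(cluster_id = seq_len(n_clusters),
                           x = cc[cells, 1], y = cc[cells, 2],
                           urban_rural = urban, cell = cells,
                           n_households = n, n_suitable = k,
                           stringsAsFactors = FALSE)
    households <- emit_household_records(clusters)
    list(clusters = clusters, households = households)
  })
}

# material codes consistent with each cluster's (n, k); unsuitable houses get
# at least one inappropriate component
emit_household_records <- function(clusters) {
  cat_ <- material_catalog()
  wa <- cat_$wall_appropriate; ra <- cat_$roof_appropriate
  wi <- wall_inappropriate_labels(); ri <- roof_inappropriate_labels()
  recs <- lapply(seq_len(nrow(clusters)), function(i) {
    n <- clusters$n_households[i]; k <- clusters$n_suitable[i]
    wall <- character(n); roof <- character(n)
    if (k > 0) {
      wall[seq_len(k)] <- sample(wa, k, replace = TRUE)
      roof[seq_len(k)] <- sample(ra, k, replace = TRUE)
    }
    if (k < n) {
      idx <- (k + 1):n
      # which component(s) fail: 1 wall, 2 roof, 3 both
      fail <- sample(1:3, length(idx), replace = TRUE)
      wall[idx] <- ifelse(fail != 2, sample(wi, length(idx), replace = TRUE),
                          sample(wa, length(idx), replace = TRUE))
      roof[idx] <- ifelse(fail != 1, sample(ri, length(idx), replace = TRUE),
                          sample(ra, length(idx), replace = TRUE))
    }
    data.frame(cluster_id = clusters$cluster_id[i], wall_code = wall,
               roof_code = roof, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Displace cluster coordinates the way DHS does
#'
#' Moves each cluster by a uniformly random angle and a distance uniform on
#' [0, 2 km] for urban clusters and [0, 10 km] for rural clusters, emulating
#' the positional masking DHS applies for privacy. True coordinates are
#' retained in \code{true_x}, \code{true_y} so downstream corrections can be
#' scored against them.
#'
#' @param clusters Cluster data frame with \code{x}, \code{y},
#'   \code{urban_rural}.
#' @param seed Integer seed.
#' @param urban_max,rural_max Maximum displacement distances in metres.
#' @return The cluster data frame with displaced \code{x}, \code{y} and new
#'   \code{true_x}, \code{true_y} columns.
#' @export
displace_coordinates <- function(clusters, seed = 1, urban_max = 2000,
                                 rural_max = 10000) {
  clusters <- as.data.frame(clusters)
  stopifnot(all(c("x", "y", "urban_rural") %in% names(clusters)))
  if (!all(clusters$urban_rural %in% c("urban", "rural")))
    stop("urban_rural must be 'urban' or 'rural' for every cluster")
  n <- nrow(clusters)
  with_seed(seed, {
    theta <- stats::runif(n, 0, 2 * pi)
    dmax <- ifelse(clusters$urban_rural == "urban", urban_max, rural_max)
    d <- stats::runif(n, 0, dmax)
    clusters$true_x <- clusters$x
    clusters$true_y <- clusters$y
    clusters$x <- clusters$x + d * cos(theta)
    clusters$y <- clusters$y + d * sin(theta)
    clusters
  })
}

#' Generate co-registered context rasters and toy departments
#'
#' Produces the decision-stage inputs for the synthetic country: a malaria
#' parasite-rate surface spanning 0 to 0.65 (the approximate national range
#' from near-elimination cities to high-burden districts), a population
#' surface with empty cells and clumped settlements, a travel-time-to-city
#' surface, and a tessellation of the grid into contiguous toy departments
#' (nearest-seed regions), returned as an integer label raster.
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param n_departments Number of departments (>= 3).
#' @return List of [set_raster()]s: \code{prevalence}, \code{population},
#'   \code{travel} (minutes), \code{departments} (integer labels 1..k).
#' @export
generate_context_rasters <- function(grid, seed = 1, n_departments = 6) {
  stopifnot(inherits(grid, "grid_spec"))
  if (n_departments < 3) stop("need at least 3 departments")
  m <- n_cells(grid)
  diam <- grid$cell_size * sqrt(grid$n_rows^2 + grid$n_cols^2)
  f1 <- simulate_latent_field(grid, 1, diam / 4, seed = seed + 11L)
  f2 <- simulate_latent_field(grid, 1, diam / 5, seed = seed + 23L)
  f3 <- simulate_latent_field(grid, 1, diam / 4, seed = seed + 37L)
  # prevalence: squash a smooth field into [0, 0.65]
  prevalence <- 0.65 * stats::plogis(1.2 * scale01(f1) * 6 - 3)
  # population: settlements where the field is high, exact zeros elsewhere
  raw <- exp(1.5 * f2)
  pop <- ifelse(f2 > stats::quantile(f2, 0.35), round(400 * raw), 0)
  # travel time: distance to the most "urban" cells plus smooth noise
  cc <- cell_centers(grid)
  cities <- order(pop, decreasing = TRUE)[seq_len(max(3L, m %/% 200L))]
  dcity <- apply(cross_dist(cc, cc[cities, , drop = FALSE]), 1, min)
  travel <- pmax(0, dcity / 1000 * 1.2 + 10 * scale01(f3))  # ~1.2 min/km
  departments <- with_seed(seed + 53L, {
    seeds <- sample.int(m, n_departments)
    assign_id <- apply(cross_dist(cc, cc[seeds, , drop = FALSE]), 1, which.min)
    as.numeric(assign_id)
  })
  list(prevalence = set_raster(grid, prevalence, "prevalence"),
       population = set_raster(grid, pop, "population"),
       travel = set_raster(grid, travel, "travel"),
       departments = set_raster(grid, departments, "departments"))
}

scale01 <- function(x) (x - min(x)) / max(max(x) - min(x), .Machine$double.eps)

#' Simulate a complete synthetic study dataset
#'
#' One call builds everything the pipeline consumes: standardized covariate
#' rasters, the latent Matern field, the true suitability surface
#' \eqn{p(x) = \mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j c_j(x) + S(x))},
#' survey clusters with beta-binomial suitable counts and per-household
#' material codes, DHS-style displaced coordinates, and the context rasters.
#'
#' @param grid A [grid_spec()]; default a 30 x 30 grid of 5-km cells.
#' @param truth A [synthetic_truth()].
#' @param n_clusters Number of survey clusters.
#' @param urban_fraction Proportion of clusters flagged urban. The default
#'   0.35 mirrors a mostly rural national survey frame.
#' @param covariate_range Matern scale of the covariate fields (metres).
#' @param seed Integer seed driving every random component.
#' @param displace Apply DHS displacement to the returned coordinates?
#' @return An object of class \code{set_sim_data}: list with \code{grid},
#'   \code{truth} (with \code{latent_field}, \code{true_p} filled),
#'   \code{covariates}, \code{clusters}, \code{households},
#'   \code{prevalence}, \code{population}, \code{travel},
#'   \code{departments}.
#' @examples
#' sim <- simulate_set_data(grid_spec(12, 12), n_clusters = 40, seed = 1)
#' sim$clusters[1:3, ]
#' @export
simulate_set_data <- function(grid = grid_spec(30, 30, 5000),
                              truth = synthetic_truth(),
                              n_clusters = 150, urban_fraction = 0.35,
                              covariate_range = 30000, seed = 1,
                              displace = TRUE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(truth, "synthetic_truth"))
  p <- length(truth$beta_j)
  covariates <- if (p > 0)
    generate_covariate_rasters(grid, p, covariate_range, seed = seed)
  else NULL
  truth$latent_field <- simulate_latent_field(grid, truth$gp_sigma, truth$gp_range,
                                              truth$nu, seed = seed + 101L)
  eta <- truth$beta0 + truth$latent_field
  if (p > 0)
    for (j in seq_len(p)) eta <- eta + truth$beta_j[j] * covariates$layers[[j]]
  truth$true_p <- stats::plogis(eta)
  samp <- sample_clusters(grid, n_clusters, urban_fraction, truth, seed = seed + 211L)
  clusters <- samp$clusters
  if (displace) clusters <- displace_coordinates(clusters, seed = seed + 307L)
  ctx <- generate_context_rasters(grid, seed = seed + 401L)
  structure(list(grid = grid, truth = truth, covariates = covariates,
                 clusters = clusters, households = samp$households,
                 prevalence = ctx$prevalence, population = ctx$population,
                 travel = ctx$travel, departments = ctx$departments),
            class = "set_sim_data")
}

#' @export
print.set_sim_data <- function(x, ...) {
  cat(sprintf("<set_sim_data> %d x %d grid, %d clusters, %d households, %d covariate layer(s)\n",
              x$grid$n_rows, x$grid$n_cols, nrow(x$clusters), nrow(x$households),
              length(x$covariates$layers)))
  invisible(x)
}
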