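#' Simulate a housing-improvement scenario on the household records
#'
#' Models future housing upgrades as independent per-component transitions:
#' each inappropriate wall is upgraded to an appropriate material with
#' probability \code{rate}, and likewise each inappropriate roof. The
#' default rate of 0.2 approximates the 2000-2015 pace of housing
#' improvement in sub-Saharan Africa extended forward.
#'
#' Two modes: \code{"stochastic"} returns a new household table with
#' upgraded material codes (suitability is then re-classified as usual);
#' \code{"expected"} skips the coin flips and returns per-cluster expected
#' suitable counts, where each household contributes
#' \eqn{(\mathrm{wall\ ok} ? 1 : r)\times(\mathrm{roof\ ok} ? 1 : r)}.
#' An alternative reading — adding \code{rate} to each cluster proportion,
#' capped at 1 — is available as \code{mode = "additive"}.
#'
#' @param records Household data frame (\code{cluster_id}, \code{wall_code},
#'   \code{roof_code}).
#' @param rate Upgrade probability in [0, 1].
#' @param mode \code{"stochastic"}, \code{"expected"} or \code{"additive"}.
#' @param seed Integer seed (stochastic mode).
#' @param catalog A [material_catalog()].
#' @return Stochastic mode: a household data frame. Expected/additive mode:
#'   a data frame per cluster with \code{cluster_id}, \code{n_households},
#'   \code{expected_suitable} (possibly non-integer) and
#'   \code{proportion}.
#' @export
improve_housing <- function(records, rate = 0.2,
                            mode = c("stochastic", "expected", "additive"),
                            seed = 1, catalog = material_catalog()) {
  mode <- match.arg(mode)
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  records <- as_household_records(records)
  wall_ok <- records$wall_code %in% catalog$wall_appropriate
  roof_ok <- records$roof_code %in% catalog$roof_appropriate
  if (mode == "stochastic") {
    return(with_seed(seed, {
      up_w <- !wall_ok & stats::runif(nrow(records)) < rate
      up_r <- !roof_ok & stats::runif(nrow(records)) < rate
      if (any(up_w))
        records$wall_code[up_w] <- sample(catalog$wall_appropriate, sum(up_w),
                                          replace = TRUE)
      if (any(up_r))
        records$roof_code[up_r] <- sample(catalog$roof_appropriate, sum(up_r),
                                          replace = TRUE)
      records
    }))
  }
  if (mode == "expected") {
    p_house <- ifelse(wall_ok, 1, rate) * ifelse(roof_ok, 1, rate)
  } else {                         # additive: per-cluster p' = min(1, p + rate)
    p_house <- as.numeric(wall_ok & roof_ok)
  }
  n <- tapply(p_house, records$cluster_id, length)
  ek <- tapply(p_house, records$cluster_id, sum)
  out <- data.frame(cluster_id = names(n), n_households = as.integer(n),
                    expected_suitable = as.numeric(ek), stringsAsFactors = FALSE)
  if (mode == "additive")
    out$expected_suitable <- pmin(out$n_households,
                                  out$expected_suitable + rate * out$n_households)
  if (is.numeric(records$cluster_id)) out$cluster_id <- as.numeric(out$cluster_id)
  out <- out[order(match(out$cluster_id, unique(records$cluster_id))), , drop = FALSE]
  out$proportion <- out$expected_suitable / out$n_households
  rownames(out) <- NULL
  out
}

#' Run the full targeting pipeline on one dataset
#'
#' Convenience wrapper chaining every stage: classify households, snap
#' displaced rural clusters to populated cells, extract buffered covariates,
#' build the standardized design, fit the geostatistical model, predict the
#' suitability surface, apply the exclusion rules, cost the two strategies
#' and rank the departments.
#'
#' @param sim A \code{set_sim_data} dataset (or a list with the same
#'   fields read from disk).
#' @param rule A [decision_rule()].
#' @param spec A [set_model_spec()].
#' @param threshold Exceedance threshold.
#' @param buffer_radius Covariate buffer radius in metres.
#' @param n_draws Posterior draws for the surface.
#' @param seed Integer seed for inference and prediction.
#' @param snap Snap rural clusters to populated cells first?
#' @param cluster_counts Optional replacement cluster count table (columns
#'   \code{cluster_id}, \code{n_households} and either \code{n_suitable} or
#'   \code{expected_suitable}); used by scenario refits.
#' @return List of class \code{set_pipeline}: \code{clusters} (with counts
#'   and covariates), \code{fit}, \code{surface}, \code{decisions},
#'   \code{cost_high}, \code{cost_both}, \code{ranking}, \code{snap_report}.
#' @export
run_set_pipeline <- function(sim, rule = decision_rule(), spec = set_model_spec(),
                             threshold = 0.8, buffer_radius = 2000,
                             n_draws = 1000, seed = 1, snap = TRUE,
                             cluster_counts = NULL) {
  coords <- sim$clusters[, c("cluster_id", "x", "y",
                             intersect("urban_rural", names(sim$clusters)))]
  clusters <- aggregate_clusters(sim$households, coords)
  if (!is.null(cluster_counts)) {
    cc <- as.data.frame(cluster_counts)
    kcol <- intersect(c("n_suitable", "expected_suitable"), names(cc))[1]
    i <- match(clusters$cluster_id, cc$cluster_id)
    clusters$n_suitable <- cc[[kcol]][i]
    clusters$proportion <- clusters$n_suitable / clusters$n_households
  }
  snap_report <- NULL
  if (snap && "urban_rural" %in% names(clusters)) {
    sn <- snap_rural_clusters(clusters, sim$population)
    clusters <- sn$clusters
    snap_report <- sn$report
  }
  covs <- buffer_extract(sim$covariates, clusters[, c("x", "y")],
                         radius = buffer_radius)
  des <- build_design(covs, standardize = TRUE)
  clusters <- cbind(clusters[des$kept, , drop = FALSE],
                    as.data.frame(sweep(sweep(as.matrix(covs[des$kept, , drop = FALSE]),
                                              2, des$standardization$center, "-"),
                                        2, des$standardization$scale, "/")))
  fml <- stats::as.formula(paste(
    "cbind(n_suitable, n_households - n_suitable) ~",
    paste(names(covs), collapse = " + ")))
  spec$seed <- seed
  fit <- set_fit(fml, data = clusters, coords = ~ x + y, spec = spec,
                 standardization = des$standardization)
  surface <- predict_surface(fit, sim$covariates, threshold = threshold,
                             n_draws = n_draws, seed = seed)
  decisions <- apply_exclusions(surface, sim$prevalence, sim$travel, rule)
  cost_high <- coverage_and_cost(decisions, sim$population, "high")
  cost_both <- coverage_and_cost(decisions, sim$population, "moderate_and_high")
  ranking <- rank_departments(decisions, sim$departments)
  structure(list(clusters = clusters, fit = fit, surface = surface,
                 decisions = decisions, cost_high = cost_high,
                 cost_both = cost_both, ranking = ranking,
                 snap_report = snap_report, rule = rule, threshold = threshold,
                 seed = seed),
            class = "set_pipeline")
}

#' @export
print.set_pipeline <- function(x, ...) {
  cat("SET targeting pipeline\n")
  cat(sprintf("  %d clusters fitted; %d of %d cells included (%d high, %d moderate)\n",
              nrow(x$clusters), sum(x$decisions$included), nrow(x$decisions),
              sum(x$decisions$stratum == "high"),
              sum(x$decisions$stratum == "moderate")))
  print(x$cost_high); print(x$cost_both)
  top <- utils::head(x$ranking$department, 3)
  cat("  top-ranked departments:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Propagate a housing-improvement scenario through the pipeline
#'
#' Applies [improve_housing()] at the chosen rate, reruns
#' classification, model fit, surface prediction and prioritization, and
#' reports the changes against a baseline run: cells newly included and the
#' change in covered population and cost under each strategy.
#'
#' @param sim A \code{set_sim_data} dataset.
#' @param baseline A baseline [run_set_pipeline()] result (computed if
#'   omitted).
#' @param rate Upgrade probability.
#' @param mode Passed to [improve_housing()].
#' @param seed Integer seed.
#' @param ... Passed to [run_set_pipeline()] (both runs share them).
#' @return List of class \code{set_scenario}: \code{baseline},
#'   \code{scenario} (both \code{set_pipeline}s) and \code{delta} (list with
#'   \code{newly_included} cell indices, \code{dropped} cell indices, and
#'   per-strategy population/cost deltas).
#' @export
run_scenario <- function(sim, baseline = NULL, rate = 0.2,
                         mode = c("stochastic", "expected", "additive"),
                         seed = 1, ...) {
  mode <- match.arg(mode)
  if (is.null(baseline)) baseline <- run_set_pipeline(sim, seed = seed, ...)
  if (mode == "stochastic") {
    hh <- improve_housing(sim$households, rate, "stochastic", seed = seed)
    sim2 <- sim; sim2$households <- hh
    scen <- run_set_pipeline(sim2, seed = seed, ...)
  } else {
    counts <- improve_housing(sim$households, rate, mode, seed = seed)
    scen <- run_set_pipeline(sim, seed = seed, cluster_counts = counts, ...)
  }
  b <- baseline$decisions; s <- scen$decisions
  delta <- list(
    newly_included = s$cell[s$included & !b$included],
    dropped = s$cell[!s$included & b$included],
    population_high = scen$cost_high$population_covered -
      baseline$cost_high$population_covered,
    population_both = scen$cost_both$population_covered -
      baseline$cost_both$population_covered,
    cost_point_high = scen$cost_high$cost_point - baseline$cost_high$cost_point,
    cost_point_both = scen$cost_both$cost_point - baseline$cost_both$cost_point)
  structure(list(baseline = baseline, scenario = scen, rate = rate,
                 mode = mode, delta = delta),
            class = "set_scenario")
}

#' @export
print.set_scenario <- function(x, ...) {
  cat(sprintf("Housing-improvement scenario (rate %.2f, %s mode)\n", x$rate, x$mode))
  cat(sprintf("  cells newly included: %d; dropped: %d\n",
              length(x$delta$newly_included), length(x$delta$dropped)))
  cat(sprintf("  covered population change: %+d (high), %+d (moderate+high)\n",
              round(x$delta$population_high), round(x$delta$population_both)))
  invisible(x)
}
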