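#' Decision rule for priority-area selection
#'
#' The three exclusion criteria used to shortlist grid cells for
#' ground-truthing and implementation: a cell is dropped when the modelled
#' exceedance probability is below \code{exceedance_min}, when malaria
#' transmission is low (parasite rate below \code{pfpr_min}, little
#' epidemiological payoff), or when the nearest major city is more than
#' \code{travel_max} minutes away (impractical logistics). Included cells
#' are stratified into high transmission (parasite rate strictly above
#' \code{pfpr_high}) versus moderate. All inequalities are strict, matching
#' the stated rules: a cell exactly at a boundary is NOT excluded (and a
#' cell exactly at \code{pfpr_high} is moderate, not high).
#'
#' @param exceedance_min Minimum exceedance probability (default 0.70).
#' @param pfpr_min Low-transmission cut-off on parasite rate (default 0.10).
#' @param pfpr_high High-transmission cut-off (default 0.35).
#' @param travel_max Maximum travel time in minutes (default 180).
#' @return An object of class \code{decision_rule}.
#' @export
decision_rule <- function(exceedance_min = 0.70, pfpr_min = 0.10,
                          pfpr_high = 0.35, travel_max = 180) {
  if (!(pfpr_min >= 0 && pfpr_min <= pfpr_high && pfpr_high <= 1))
    stop("need 0 <= pfpr_min <= pfpr_high <= 1")
  if (travel_max <= 0) stop("travel_max must be positive")
  structure(list(exceedance_min = exceedance_min, pfpr_min = pfpr_min,
                 pfpr_high = pfpr_high, travel_max = travel_max),
            class = "decision_rule")
}

#' Apply the exclusion rules to every grid cell
#'
#' @param surface A \code{set_surface} from [predict_surface()], or a
#'   [set_raster()] of exceedance probabilities.
#' @param prevalence,travel [set_raster()]s co-registered with the surface.
#' @param rule A [decision_rule()].
#' @return Data frame with one row per cell: \code{cell}, \code{exceedance},
#'   \code{pfpr}, \code{travel}, \code{included}, \code{stratum}
#'   ("high"/"moderate"/"excluded") and logical reason columns
#'   \code{reason_exceedance}, \code{reason_transmission},
#'   \code{reason_access} (all FALSE for included cells).
#' @export
apply_exclusions <- function(surface, prevalence, travel, rule = decision_rule()) {
  exc <- if (inherits(surface, "set_surface")) surface$exceedance else surface
  stopifnot(inherits(exc, "set_raster"), inherits(rule, "decision_rule"))
  check_registered(exc$grid, prevalence, what = "prevalence raster")
  check_registered(exc$grid, travel, what = "travel raster")
  e <- exc$values; p <- prevalence$values; tr <- travel$values
  r_exc <- e < rule$exceedance_min
  r_trans <- p < rule$pfpr_min
  r_acc <- tr > rule$travel_max
  included <- !(r_exc | r_trans | r_acc)
  stratum <- ifelse(!included, "excluded",
                    ifelse(p > rule$pfpr_high, "high", "moderate"))
  data.frame(cell = seq_along(e), exceedance = e, pfpr = p, travel = tr,
             included = included, stratum = stratum,
             reason_exceedance = r_exc, reason_transmission = r_trans,
             reason_access = r_acc, stringsAsFactors = FALSE)
}

#' Covered population and implementation cost for a targeting strategy
#'
#' Sums population over the cells a strategy targets — only the
#' high-transmission stratum, or both strata — and multiplies by the
#' per-person-per-year unit cost triplet from the cluster-randomised trial:
#' a point estimate of $21.47 with 90% credible interval $6.08 to $49.99.
#'
#' @param decisions Output of [apply_exclusions()].
#' @param population A [set_raster()] of per-cell population (non-negative).
#' @param strategy \code{"high"} or \code{"moderate_and_high"}.
#' @param unit_cost Named triplet \code{c(low, point, high)} in dollars per
#'   person protected per year.
#' @return List of class \code{cost_estimate}: \code{strategy},
#'   \code{population_covered}, \code{cost_low}, \code{cost_point},
#'   \code{cost_high}, \code{unit_cost}.
#' @examples
#' # a single included high-transmission cell with a million people:
#' d <- data.frame(cell = 1, included = TRUE, stratum = "high")
#' g <- grid_spec(1, 1)
#' coverage_and_cost(d, set_raster(g, 1e6), "high")
#' @export
coverage_and_cost <- function(decisions, population,
                              strategy = c("high", "moderate_and_high"),
                              unit_cost = c(low = 6.08, point = 21.47, high = 49.99)) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(population, "set_raster"))
  if (any(population$values < 0)) stop("population raster has negative cells")
  if (!all(c("low", "point", "high") %in% names(unit_cost)))
    stop("unit_cost must carry named elements low, point, high")
  if (!(unit_cost[["low"]] <= unit_cost[["point"]] &&
        unit_cost[["point"]] <= unit_cost[["high"]]))
    stop("unit_cost must satisfy low <= point <= high")
  strata <- if (strategy == "high") "high" else c("moderate", "high")
  cells <- decisions$cell[decisions$included & decisions$stratum %in% strata]
  pop <- sum(population$values[cells])
  structure(list(strategy = strategy, population_covered = pop,
                 cost_low = pop * unit_cost[["low"]],
                 cost_point = pop * unit_cost[["point"]],
                 cost_high = pop * unit_cost[["high"]],
                 unit_cost = unit_cost),
            class = "cost_estimate")
}

#' @export
print.cost_estimate <- function(x, ...) {
  cat(sprintf("Strategy '%s': %s people covered\n", x$strategy,
              format(round(x$population_covered), big.mark = ",")),
      sprintf("  annual cost $%s (range $%s to $%s) at $%.2f/person/year\n",
              format(round(x$cost_point), big.mark = ","),
              format(round(x$cost_low), big.mark = ","),
              format(round(x$cost_high), big.mark = ","),
              x$unit_cost[["point"]]), sep = "")
  invisible(x)
}

#' Rank departments by the signed z-score sum
#'
#' For each department, averages exceedance probability, parasite rate and
#' travel time over its included cells and computes the percentage of its
#' area made of included cells. Each variable is turned into a z-score: the
#' observed value is the department mean; the reference mean is the national
#' mean over all included cells (for the three cell variables) or the
#' national mean of included-area percentage per department (for area); the
#' denominator is the standard deviation across department means (a spread
#' is needed and the departments are the units being compared). The signed
#' sum adds exceedance, parasite rate and area and subtracts travel time
#' (shorter access is better); departments are ranked by decreasing sum,
#' ties broken by department id, and departments with no included cells are
#' ranked last and flagged.
#'
#' @param decisions Output of [apply_exclusions()].
#' @param departments A [set_raster()] of integer department labels.
#' @return Data frame of class \code{department_scores}: one row per
#'   department with means, \code{included_area_pct}, the four z-scores,
#'   \code{signed_sum}, \code{rank} and \code{has_included}.
#' @export
rank_departments <- function(decisions, departments) {
  stopifnot(inherits(departments, "set_raster"))
  dept <- departments$values
  if (length(dept) != nrow(decisions))
    stop("departments raster does not match the decision grid")
  ids <- sort(unique(dept))
  if (length(ids) < 2) stop("need at least 2 departments to rank")
  inc <- decisions$included
  nat_mean <- c(exceedance = mean(decisions$exceedance[inc]),
                pfpr = mean(decisions$pfpr[inc]),
                travel = mean(decisions$travel[inc]))
  rows <- lapply(ids, function(id) {
    in_dept <- dept == id
    sel <- in_dept & inc
    data.frame(department = id,
               n_cells = sum(in_dept), n_included = sum(sel),
               mean_exceedance = if (any(sel)) mean(decisions$exceedance[sel]) else NA_real_,
               mean_pfpr = if (any(sel)) mean(decisions$pfpr[sel]) else NA_real_,
               mean_travel = if (any(sel)) mean(decisions$travel[sel]) else NA_real_,
               included_area_pct = 100 * sum(sel) / sum(in_dept))
  })
  out <- do.call(rbind, rows)
  out$has_included <- out$n_included > 0
  if (sum(out$has_included) < 2)
    stop("need at least 2 departments with included cells")
  nat_area <- mean(out$included_area_pct)
  zsd <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(NA)
    s
  }
  sds <- c(exceedance = zsd(out$mean_exceedance), pfpr = zsd(out$mean_pfpr),
           travel = zsd(out$mean_travel), area = zsd(out$included_area_pct))
  bad <- names(sds)[is.na(sds)]
  if (length(bad))
    stop("zero national sd for variable(s): ", paste(bad, collapse = ", "))
  out$z_exceedance <- (out$mean_exceedance - nat_mean[["exceedance"]]) / sds[["exceedance"]]
  out$z_pfpr <- (out$mean_pfpr - nat_mean[["pfpr"]]) / sds[["pfpr"]]
  out$z_travel <- (out$mean_travel - nat_mean[["travel"]]) / sds[["travel"]]
  out$z_area <- (out$included_area_pct - nat_area) / sds[["area"]]
  out$signed_sum <- out$z_exceedance + out$z_pfpr - out$z_travel + out$z_area
  key <- ifelse(out$has_included, out$signed_sum, -Inf)
  ord <- order(-key, out$department)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_along(ord)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("department_scores", "data.frame")
  out
}
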