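# A 3 x 3 toy country with hand-set decision inputs, including exact
# boundary values of every rule threshold.
toy_decisions <- function() {
  g <- grid_spec(3, 3, cell_size = 1000)
  exc <- set_raster(g, c(0.90, 0.80, 0.50, 0.75, 0.95, 0.85, 0.70, 0.90, 0.65))
  pfpr <- set_raster(g, c(0.40, 0.20, 0.40, 0.50, 0.15, 0.05, 0.12, 0.36, 0.08))
  trav <- set_raster(g, c(60, 120, 60, 30, 90, 60, 180, 200, 300))
  list(grid = g, exc = exc, pfpr = pfpr, trav = trav,
       decisions = apply_exclusions(exc, pfpr, trav))
}

test_that("exclusion rules honour strict boundaries and list every violated reason", {
  d <- toy_decisions()$decisions
  expect_equal(d$included, c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(d$stratum, c("high", "moderate", "excluded", "high", "moderate",
                            "excluded", "moderate", "excluded", "excluded"))
  # cell 3: only exceedance fails; cell 6: only transmission; cell 8: only access
  expect_equal(which(d$reason_exceedance), c(3, 9))
  expect_equal(which(d$reason_transmission), c(6, 9))
  expect_equal(which(d$reason_access), c(8, 9))
  # boundary cell 7 sits exactly at 0.70 exceedance and 180 min: included;
  # a pfpr of exactly 0.35 would be moderate, exactly 0.10 included
  g1 <- grid_spec(1, 1)
  b <- apply_exclusions(set_raster(g1, 0.70), set_raster(g1, 0.35),
                        set_raster(g1, 180))
  expect_true(b$included); expect_equal(b$stratum, "moderate")
  b2 <- apply_exclusions(set_raster(g1, 0.70), set_raster(g1, 0.10),
                         set_raster(g1, 180))
  expect_true(b2$included)
  # conservation: every cell is included or carries >= 1 reason
  reasons <- d$reason_exceedance | d$reason_transmission | d$reason_access
  expect_equal(!d$included, reasons)
})

test_that("relaxing any threshold never shrinks the included set", {
  t <- toy_decisions()
  base <- t$decisions$included
  relaxed <- list(decision_rule(exceedance_min = 0.5),
                  decision_rule(pfpr_min = 0.01),
                  decision_rule(travel_max = 400))
  for (r in relaxed) {
    d <- apply_exclusions(t$exc, t$pfpr, t$trav, r)
    expect_true(all(d$included >= base))
  }
})

test_that("exclusions demand co-registered rasters", {
  t <- toy_decisions()
  other <- set_raster(grid_spec(2, 2), 0.5)
  expect_error(apply_exclusions(t$exc, other, t$trav), "co-registered")
})

test_that("cost arithmetic multiplies population by the trial's unit costs", {
  g <- grid_spec(1, 1)
  d <- data.frame(cell = 1, included = TRUE, stratum = "high")
  ce <- coverage_and_cost(d, set_raster(g, 1e6), "high")
  expect_equal(ce$population_covered, 1e6)
  expect_equal(ce$cost_point, 21470000)
  expect_equal(ce$cost_low, 6080000)
  expect_equal(ce$cost_high, 49990000)
  # empty included set
  d0 <- data.frame(cell = 1, included = FALSE, stratum = "excluded")
  ce0 <- coverage_and_cost(d0, set_raster(g, 1e6), "high")
  expect_equal(ce0$population_covered, 0)
  expect_equal(ce0$cost_point, 0)
  expect_error(coverage_and_cost(d, set_raster(g, -5), "high"), "negative")
})

test_that("cost is linear in population and monotone across strategies", {
  t <- toy_decisions()
  set.seed(2)
  pop <- set_raster(t$grid, rpois(9, 500))
  pop2 <- set_raster(t$grid, 2 * pop$values)
  high <- coverage_and_cost(t$decisions, pop, "high")
  both <- coverage_and_cost(t$decisions, pop, "moderate_and_high")
  expect_lte(high$population_covered, both$population_covered)
  expect_lte(high$cost_point, both$cost_point)
  d2 <- coverage_and_cost(t$decisions, pop2, "moderate_and_high")
  expect_equal(d2$population_covered, 2 * both$population_covered)
  expect_equal(d2$cost_point, 2 * both$cost_point)
  expect_equal(d2$cost_low, 2 * both$cost_low)
  expect_equal(d2$cost_high, 2 * both$cost_high)
})

test_that("department ranking matches a hand-computed z-score oracle", {
  t <- toy_decisions()
  dep <- set_raster(t$grid, rep(1:3, each = 3))
  out <- rank_departments(t$decisions, dep)
  # spreadsheet-style oracle, written out from first principles
  d <- t$decisions
  inc_cells <- list(`1` = c(1, 2), `2` = c(4, 5), `3` = 7)
  m_exc <- sapply(inc_cells, function(i) mean(d$exceedance[i]))
  m_pfpr <- sapply(inc_cells, function(i) mean(d$pfpr[i]))
  m_trav <- sapply(inc_cells, function(i) mean(d$travel[i]))
  area <- 100 * c(2, 2, 1) / 3
  nat <- c(mean(d$exceedance[d$included]), mean(d$pfpr[d$included]),
           mean(d$travel[d$included]), mean(area))
  z <- cbind((m_exc - nat[1]) / sd(m_exc), (m_pfpr - nat[2]) / sd(m_pfpr),
             (m_trav - nat[3]) / sd(m_trav), (area - nat[4]) / sd(area))
  sums <- z[, 1] + z[, 2] - z[, 3] + z[, 4]
  ord <- order(-sums)
  expect_equal(out$department, (1:3)[ord])
  expect_equal(out$signed_sum, unname(sums[ord]), tolerance = 1e-12)
  expect_equal(out$rank, 1:3)
  expect_equal(out$z_exceedance, unname(z[ord, 1]), tolerance = 1e-12)
  expect_equal(out$z_travel, unname(z[ord, 3]), tolerance = 1e-12)
})

test_that("identical departments tie and break by id; empty departments rank last", {
  g <- grid_spec(3, 3, cell_size = 1000)
  # departments 1 and 2 identical, department 3 different and partly excluded
  exc <- set_raster(g, c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.75, 0.75, 0.50))
  pfpr <- set_raster(g, c(0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.2, 0.2, 0.2))
  trav <- set_raster(g, c(30, 30, 30, 30, 30, 30, 90, 90, 90))
  dep <- set_raster(g, rep(1:3, each = 3))
  out <- rank_departments(apply_exclusions(exc, pfpr, trav), dep)
  expect_equal(out$signed_sum[1], out$signed_sum[2], tolerance = 1e-12)
  expect_equal(out$department[1:2], c(1, 2))   # tie broken by id
  # a department whose every cell is excluded ranks last and is flagged
  g4 <- grid_spec(2, 2, cell_size = 1000)
  exc4 <- set_raster(g4, c(0.9, 0.8, 0.75, 0.5))
  pfpr4 <- set_raster(g4, c(0.4, 0.2, 0.15, 0.4))
  trav4 <- set_raster(g4, c(30, 60, 90, 30))
  dep4 <- set_raster(g4, 1:4)
  out2 <- rank_departments(apply_exclusions(exc4, pfpr4, trav4), dep4)
  expect_false(out2$has_included[out2$department == 4])
  expect_equal(out2$rank[out2$department == 4], 4L)
})

test_that("raising one department's exceedance never lowers its rank", {
  t <- toy_decisions()
  dep <- set_raster(t$grid, rep(1:3, each = 3))
  base <- rank_departments(t$decisions, dep)
  r0 <- base$rank[base$department == 3]
  exc2 <- t$exc
  exc2$values[7] <- 0.99   # department 3's only included cell
  up <- rank_departments(apply_exclusions(exc2, t$pfpr, t$trav), dep)
  expect_lte(up$rank[up$department == 3], r0)
})
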