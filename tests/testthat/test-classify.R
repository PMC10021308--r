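test_that("suitability is the conjunction of appropriate wall and roof", {
  cases <- expand.grid(
    wall = c("cement", "bricks", "cement blocks", "stone with lime/cement",
             "mud", "uncovered adobe"),
    roof = c("metal", "cement", "ceramic tiles", "roofing shingles",
             "thatch/palm leaf", "no roof"),
    stringsAsFactors = FALSE)
  cat_ <- material_catalog()
  rec <- data.frame(cluster_id = seq_len(nrow(cases)),
                    wall_code = cases$wall, roof_code = cases$roof)
  got <- classify_household(rec, cat_)
  expect_equal(got, cases$wall %in% cat_$wall_appropriate &
                    cases$roof %in% cat_$roof_appropriate)
  # order-invariance and idempotence: a pure row-wise function
  perm <- sample(nrow(rec))
  expect_equal(classify_household(rec[perm, ], cat_), got[perm])
})

test_that("unknown codes classify unsuitable with a warning", {
  rec <- data.frame(cluster_id = 1, wall_code = "marble", roof_code = "metal")
  expect_warning(flag <- classify_household(rec), "marble")
  expect_false(flag)
})

test_that("cluster aggregation counts, conserves and errors as specified", {
  coords <- data.frame(cluster_id = c(1, 2), x = c(0, 10), y = c(0, 10))
  rec <- rbind(hh_fixture(20, 16, cluster_id = 1), hh_fixture(15, 3, cluster_id = 2))
  agg <- aggregate_clusters(rec, coords)
  expect_equal(agg$n_households, c(20, 15))
  expect_equal(agg$n_suitable, c(16, 3))
  expect_equal(agg$proportion, c(0.8, 0.2))
  # conservation against individual classification
  expect_equal(sum(agg$n_suitable), sum(classify_household(rec)))
  # empty input
  expect_warning(e <- aggregate_clusters(rec[0, ], coords), "no household")
  expect_equal(nrow(e), 0)
  # orphan record
  bad <- hh_fixture(5, 2, cluster_id = 99)
  expect_error(aggregate_clusters(bad, coords), "99")
  # coordinate rows without records are dropped with a warning
  coords3 <- rbind(coords, data.frame(cluster_id = 3, x = 1, y = 1))
  expect_warning(a3 <- aggregate_clusters(rec, coords3), "omitted")
  expect_equal(nrow(a3), 2)
})

test_that("enlarging the appropriate sets never decreases suitable counts", {
  sim <- small_sim(seed = 11)
  coords <- sim$clusters[, c("cluster_id", "x", "y")]
  base <- aggregate_clusters(sim$households, coords)
  wider <- material_catalog(
    wall_appropriate = c(material_catalog()$wall_appropriate, "mud"),
    roof_appropriate = material_catalog()$roof_appropriate)
  up <- aggregate_clusters(sim$households, coords, wider)
  expect_true(all(up$n_suitable >= base$n_suitable))
})

test_that("department summaries match an independent quantile computation", {
  g <- grid_spec(4, 4, cell_size = 1000)
  dep <- set_raster(g, rep(c(1, 2), each = 8))
  set.seed(31)
  cl <- data.frame(x = runif(40, 0, 4000), y = runif(40, 0, 4000),
                   proportion = runif(40),
                   urban_rural = sample(c("urban", "rural"), 40, replace = TRUE))
  sm <- cluster_suitability_summary(cl, dep)
  # brute-force oracle: group by hand, quantile type 7
  idx <- cell_index_at(g, cl$x, cl$y)
  d <- as.character(dep$values[idx])
  for (r in seq_len(nrow(sm))) {
    p <- cl$proportion[d == sm$department[r] & cl$urban_rural == sm$stratum[r]]
    expect_equal(unlist(sm[r, c("min", "q1", "median", "q3", "max")],
                        use.names = FALSE),
                 unname(quantile(p, c(0, .25, .5, .75, 1), type = 7)))
  }
  # degenerate cases
  one <- data.frame(x = 500, y = 500, proportion = c(0.2, 0.5, 0.8))
  s1 <- cluster_suitability_summary(one, dep)
  expect_equal(s1$median, 0.5)
  same <- data.frame(x = 500, y = 500, proportion = rep(0.7, 5))
  s2 <- cluster_suitability_summary(same, dep)
  expect_true(all(unlist(s2[, c("min", "q1", "median", "q3", "max")]) == 0.7))
})

test_that("the shipped DHS code lookup joins to the catalog labels", {
  lk <- dhs_material_lookup()
  expect_true(all(c("component", "code", "label") %in% names(lk)))
  cat_ <- material_catalog()
  expect_true(all(cat_$wall_appropriate %in% lk$label[lk$component == "wall"]))
  expect_true(all(cat_$roof_appropriate %in% lk$label[lk$component == "roof"]))
})

test_that("a full-size synthetic survey reproduces the design's cluster count", {
  sim <- simulate_set_data(grid_spec(20, 20), n_clusters = 341, seed = 8)
  agg <- aggregate_clusters(sim$households,
                            sim$clusters[, c("cluster_id", "x", "y")])
  expect_equal(nrow(agg), 341)
})
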