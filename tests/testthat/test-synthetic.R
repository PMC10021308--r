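test_that("generators are deterministic given the seed and leave the RNG alone", {
  g <- grid_spec(10, 10)
  a <- generate_covariate_rasters(g, 1, seed = 7)
  b <- generate_covariate_rasters(g, 1, seed = 7)
  expect_identical(a$layers, b$layers)
  set.seed(42); before <- runif(1)
  simulate_latent_field(g, 1, 2e4, seed = 3)
  set.seed(42); after <- runif(1)
  expect_identical(before, after)  # caller's RNG stream untouched
  s1 <- simulate_set_data(grid_spec(8, 8), n_clusters = 20, seed = 5)
  s2 <- simulate_set_data(grid_spec(8, 8), n_clusters = 20, seed = 5)
  expect_identical(s1$clusters, s2$clusters)
  expect_identical(s1$households, s2$households)
})

test_that("covariate layers are standardized and decorrelate as range shrinks", {
  g <- grid_spec(10, 10)
  st <- generate_covariate_rasters(g, 3, smoothness_range = 3e4, seed = 1)
  for (l in st$layers) {
    expect_equal(mean(l), 0, tolerance = 1e-9)
    expect_equal(sd(l), 1, tolerance = 1e-9)
  }
  # neighbouring-cell correlation collapses when the range is tiny
  neigh_cor <- function(range_m) {
    v <- sapply(1:100, function(s) {
      f <- generate_covariate_rasters(g, 1, range_m, seed = s)$layers[[1]]
      M <- matrix(f, 10, 10, byrow = TRUE)
      cor(as.vector(M[, -10]), as.vector(M[, -1]))
    })
    mean(v)
  }
  expect_lt(abs(neigh_cor(1)), 0.05)
  expect_gt(neigh_cor(3e4), 0.5)
})

test_that("latent field has the stated marginal behaviour", {
  g <- grid_spec(6, 6)
  expect_identical(simulate_latent_field(g, 0, 1e4, seed = 1), rep(0, 36))
  draws <- sapply(1:500, function(s) simulate_latent_field(g, 1, 2e4, seed = s)[15])
  expect_equal(var(draws), 1, tolerance = 0.15)
})

test_that("cluster sampling respects sizes, degenerate truth, and the beta-binomial mean", {
  g <- grid_spec(10, 10)
  tr <- synthetic_truth(0, numeric(0), gp_sigma = 0.5, gp_range = 2e4, phi = 8)
  tr$true_p <- rep(0.5, 100)
  s <- sample_clusters(g, 60, urban_fraction = 0.3, tr, seed = 2)
  expect_true(all(s$clusters$n_households >= 15 & s$clusters$n_households <= 32))
  expect_equal(sum(s$clusters$urban_rural == "urban"), 18)
  expect_equal(nrow(s$households), sum(s$clusters$n_households))
  # degenerate truth: everything suitable
  tr1 <- tr; tr1$true_p <- rep(1, 100)
  s1 <- sample_clusters(g, 10, 0.5, tr1, seed = 3)
  expect_true(all(s1$clusters$n_suitable == s1$clusters$n_households))
  expect_true(all(classify_household(s1$households)))
  # Monte-Carlo: mean proportion across many clusters ~ mu
  props <- unlist(lapply(1:4, function(s) {
    cl <- sample_clusters(g, 50, 0.5, tr, seed = s)$clusters
    cl$n_suitable / cl$n_households
  }))
  expect_equal(mean(props), 0.5, tolerance = 0.03)
  expect_error(sample_clusters(g, 101, 0.5, tr), "exceeds")
})

test_that("simulated counts match the beta-binomial variance law", {
  # one cell, mu = 0.5, phi = 8, n = 20: var = n mu (1-mu) (1 + (n-1)/(1+phi))
  g <- grid_spec(1, 1)
  tr <- synthetic_truth(0, numeric(0), phi = 8)
  tr$true_p <- 0.5
  ks <- sapply(1:2000, function(s) {
    with(sample_clusters(g, 1, 0, tr, seed = s)$clusters, n_suitable)
  })
  ns <- sapply(1:2000, function(s) {
    with(sample_clusters(g, 1, 0, tr, seed = s)$clusters, n_households)
  })
  keep <- ns == 20
  expect_gt(sum(keep), 50)
  v_expect <- 20 * 0.25 * (1 + 19 / 9)
  expect_equal(var(ks[keep]), v_expect, tolerance = 0.2 * v_expect)
})

test_that("household records reproduce each cluster's suitable count exactly", {
  sim <- small_sim(seed = 4)
  agg <- aggregate_clusters(sim$households,
                            sim$clusters[, c("cluster_id", "x", "y")])
  expect_equal(agg$n_suitable,
               sim$clusters$n_suitable[match(agg$cluster_id,
                                             sim$clusters$cluster_id)])
})

test_that("DHS-style displacement respects the urban and rural caps", {
  cl <- data.frame(cluster_id = 1:400, x = 0, y = 0,
                   urban_rural = rep(c("urban", "rural"), 200))
  d <- displace_coordinates(cl, seed = 9)
  shift <- sqrt((d$x - d$true_x)^2 + (d$y - d$true_y)^2)
  expect_true(all(shift[d$urban_rural == "urban"] <= 2000))
  expect_true(all(shift[d$urban_rural == "rural"] <= 10000))
  expect_gt(max(shift[d$urban_rural == "rural"]), 2000)  # rural cap is used
  z <- displace_coordinates(cl, seed = 9, urban_max = 0, rural_max = 0)
  expect_equal(z$x, cl$x); expect_equal(z$y, cl$y)
})

test_that("context rasters satisfy their range and tessellation contracts", {
  g <- grid_spec(12, 12)
  ctx <- generate_context_rasters(g, seed = 3, n_departments = 5)
  expect_true(all(ctx$prevalence$values >= 0 & ctx$prevalence$values <= 0.65))
  expect_true(all(ctx$population$values >= 0))
  expect_true(all(ctx$travel$values >= 0))
  # tessellation: every cell carries exactly one department label
  expect_equal(length(ctx$departments$values), 144)
  expect_true(all(ctx$departments$values %in% 1:5))
  expect_gte(length(unique(ctx$departments$values)), 3)
  # conservation: the total is the sum of the cells
  expect_equal(sum(as.matrix(ctx$population)), sum(ctx$population$values))
})
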