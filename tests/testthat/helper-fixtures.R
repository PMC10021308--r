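# Shared fixtures, built in code at test time.

# a small fully-simulated dataset for pipeline-level tests
small_sim <- function(seed = 1, n_rows = 12, n_clusters = 40,
                      truth = synthetic_truth(0.5, c(1.2, -0.6), gp_sigma = 0.8,
                                              gp_range = 20000, phi = 15)) {
  simulate_set_data(grid_spec(n_rows, n_rows, 5000), truth = truth,
                    n_clusters = n_clusters, seed = seed)
}

# households with known composition: k suitable out of n, one cluster
hh_fixture <- function(n, k, cluster_id = 1) {
  data.frame(
    cluster_id = cluster_id,
    wall_code = c(rep("cement", k), rep("mud", n - k)),
    roof_code = rep("metal", n),
    stringsAsFactors = FALSE)
}

# quadrature oracle for the beta-binomial pmf (independent of the package's
# log-Beta evaluation path). For small phi the Beta density is unbounded at
# the endpoints, so integrate over the Beta quantile transform instead.
bb_quadrature <- function(k, n, mu, phi) {
  a <- mu * phi; b <- (1 - mu) * phi
  if (phi < 2)
    stats::integrate(function(u) stats::dbinom(k, n, stats::qbeta(u, a, b)),
                     0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
  else
    stats::integrate(function(p) stats::dbinom(k, n, p) * stats::dbeta(p, a, b),
                     0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
}
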