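#' Beta-binomial log probability mass function
#'
#' Log-density of the number of successes \eqn{k} out of \eqn{n} trials when
#' the per-trial success probability is itself Beta distributed. The Beta law
#' is parameterised by its mean \eqn{\mu} and precision \eqn{\phi}
#' (\eqn{\alpha = \mu\phi}, \eqn{\beta = (1-\mu)\phi}), so the marginal mean
#' count is \eqn{n\mu} and the variance
#' \eqn{n\mu(1-\mu)\,[1 + (n-1)/(1+\phi)]}: small \eqn{\phi} means strong
#' extra-binomial (cluster-level) overdispersion, \eqn{\phi \to \infty}
#' recovers the plain binomial.
#'
#' Evaluated through log-Beta functions, so it is stable for \eqn{n} up to
#' at least 1e4. Non-integer \code{k} is accepted (the binomial coefficient
#' generalises through the gamma function); this supports expected-count
#' scenario data.
#'
#' @param k Successes, \code{0 <= k <= n}.
#' @param n Trials, \code{n >= 0}.
#' @param mu Beta mean, in (0, 1).
#' @param phi Beta precision, > 0. \code{Inf} selects the binomial limit.
#' @return Log probability, vectorised over the longest argument.
#' @examples
#' betabinomial_logpmf(1, 1, 0.5, 2)   # log(0.5)
#' betabinomial_logpmf(0, 2, 0.5, 2)   # log(1/3): Beta(1,1) mixing
#' @export
betabinomial_logpmf <- function(k, n, mu, phi) {
  m <- max(length(k), length(n), length(mu), length(phi))
  k <- rep_len(as.numeric(k), m); n <- rep_len(as.numeric(n), m)
  mu <- rep_len(as.numeric(mu), m); phi <- rep_len(as.numeric(phi), m)
  if (any(!is.finite(k) | !is.finite(n) | k < 0 | k > n))
    stop("k must satisfy 0 <= k <= n")
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie strictly inside (0, 1)")
  if (any(phi <= 0 | is.na(phi))) stop("phi must be positive")
  out <- numeric(m)
  inf <- is.infinite(phi)
  if (any(inf)) # binomial limit; dbinom handles non-integer k via its own check,
    # so use the lgamma form directly
    out[inf] <- lchoose_gen(n[inf], k[inf]) + k[inf] * log(mu[inf]) +
      (n[inf] - k[inf]) * log1p(-mu[inf])
  if (any(!inf)) {
    a <- mu[!inf] * phi[!inf]
    b <- (1 - mu[!inf]) * phi[!inf]
    out[!inf] <- lchoose_gen(n[!inf], k[!inf]) +
      lbeta(k[!inf] + a, n[!inf] - k[!inf] + b) - lbeta(a, b)
  }
  out
}

# generalised log binomial coefficient, valid for non-integer arguments
lchoose_gen <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)

#' Matern covariance function
#'
#' \deqn{C(d) = \sigma^2 \frac{2^{1-\nu}}{\Gamma(\nu)}
#'   \left(\sqrt{2\nu}\, d/\ell\right)^{\nu} K_\nu\!\left(\sqrt{2\nu}\, d/\ell\right)}
#'
#' with the \eqn{\sqrt{2\nu}} scale convention, under which \eqn{\nu = 1/2}
#' reduces exactly to the exponential kernel
#' \eqn{\sigma^2 \exp(-d/\ell)}. The correlation falls to about 0.1 near
#' \eqn{d \approx 3\ell} for moderate \eqn{\nu} (the "practical range").
#'
#' @param distances Non-negative distances (metres).
#' @param sigma Marginal standard deviation, > 0.
#' @param range_param Scale \eqn{\ell} in metres, > 0.
#' @param nu Smoothness, > 0; the default 1 matches the field implied by the
#'   common SPDE default (alpha = 2 in two dimensions).
#' @return Covariance values, same length as \code{distances}.
#' @examples
#' matern_covariance(0, 2, 1e4)            # sigma^2 = 4
#' matern_covariance(1e4, 1, 1e4, nu = 0.5) # exp(-1)
#' @export
matern_covariance <- function(distances, sigma, range_param, nu = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) stop("sigma must be > 0")
  if (!is.numeric(range_param) || length(range_param) != 1L || range_param <= 0)
    stop("range_param must be > 0")
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0) stop("nu must be > 0")
  d <- as.numeric(distances)
  if (any(d < 0 | !is.finite(d))) stop("distances must be finite and >= 0")
  x <- sqrt(2 * nu) * d / range_param
  out <- numeric(length(d))
  z <- x == 0
  out[z] <- sigma^2
  if (any(!z)) {
    xs <- x[!z]
    # log-scale evaluation; besselK(..., expon.scaled) guards against underflow
    lc <- (1 - nu) * log(2) - lgamma(nu) + nu * log(xs) +
      log(besselK(xs, nu, expon.scaled = TRUE)) - xs
    out[!z] <- sigma^2 * exp(lc)
  }
  out
}

# Matern covariance matrix over point sets, with diagonal jitter
matern_cov_matrix <- function(coords1, coords2 = NULL, sigma, range_param, nu = 1,
                              jitter = 0) {
  d <- if (is.null(coords2)) pairwise_dist(coords1) else cross_dist(coords1, coords2)
  K <- matrix(matern_covariance(d, sigma, range_param, nu), nrow = nrow(d))
  if (is.null(coords2) && jitter > 0) diag(K) <- diag(K) + jitter * sigma^2
  K
}

pairwise_dist <- function(xy) {
  as.matrix(stats::dist(xy))
}

cross_dist <- function(a, b) {
  # |a_i - b_j| for planar coordinates
  da <- outer(a[, 1], b[, 1], "-")
  db <- outer(a[, 2], b[, 2], "-")
  sqrt(da * da + db * db)
}
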