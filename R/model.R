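#' Specify priors, kernel and inference backend for the suitability model
#'
#' The model for cluster-level suitable counts is
#' \deqn{Y_i \mid P(x_i) \sim \mathrm{Bin}(n_i, P(x_i)), \quad
#'   P(x_i) \sim \mathrm{Beta}(\mu_i\phi, (1-\mu_i)\phi), \quad
#'   \mathrm{logit}(\mu_i) = \beta_0 + x_i'\beta + S(x_i)}
#' with \eqn{S} a zero-mean Gaussian process with Matern covariance.
#' Marginally the counts are beta-binomial: \eqn{\phi} absorbs within-cluster
#' overdispersion that the spatial field cannot.
#'
#' Priors (all overridable): fixed effects \eqn{N(0, 5^2)}; half-normal on
#' the GP standard deviation; log-normal on the GP range, centred by default
#' on one third of the site-cloud diameter; log-normal on \eqn{\phi}.
#'
#' @param prior_beta_sd Prior sd of the fixed effects.
#' @param prior_sigma_sd Scale of the half-normal prior on \code{gp_sigma}.
#' @param prior_range_meanlog Mean of the log-normal range prior
#'   (\code{NULL}: set at fit time to \code{log(diameter / 3)}).
#' @param prior_range_sdlog,prior_phi_meanlog,prior_phi_sdlog Remaining
#'   log-normal hyperprior parameters.
#' @param matern_nu Matern smoothness (default 1).
#' @param gp Include the spatial Gaussian process? (\code{FALSE} gives a
#'   non-spatial beta-binomial regression.)
#' @param fix_phi Fix the precision instead of estimating it; \code{Inf}
#'   selects the plain binomial likelihood.
#' @param fix_sigma,fix_range Optionally fix GP hyperparameters.
#' @param backend \code{"laplace"} (default): Gaussian approximation at the
#'   mode of the latent field with hyperparameters at their posterior mode.
#'   \code{"mcmc"}: elliptical slice sampling on the latent field with
#'   random-walk Metropolis on the log hyperparameters, as a cross-check.
#' @param skew_correction Shift the Gaussian approximation's centre from the
#'   joint mode toward the posterior mean using the third derivative of the
#'   log-likelihood (the skewness correction of simplified-Laplace
#'   inference); without it, exceedance probabilities are biased low when
#'   many clusters sit near saturation. Laplace backend only.
#' @param mcmc_iter,mcmc_burn MCMC length and burn-in (mcmc backend only).
#' @param jitter Relative diagonal jitter added to GP covariance matrices.
#' @param seed Integer seed for the stochastic parts of inference.
#' @return An object of class \code{set_model_spec}.
#' @export
set_model_spec <- function(prior_beta_sd = 5, prior_sigma_sd = 2,
                           prior_range_meanlog = NULL, prior_range_sdlog = 1,
                           prior_phi_meanlog = log(10), prior_phi_sdlog = 1.5,
                           matern_nu = 1, gp = TRUE,
                           fix_phi = NULL, fix_sigma = NULL, fix_range = NULL,
                           backend = c("laplace", "mcmc"),
                           skew_correction = TRUE,
                           mcmc_iter = 3000, mcmc_burn = 1000,
                           jitter = 1e-8, seed = 1) {
  backend <- match.arg(backend)
  if (prior_beta_sd <= 0 || prior_sigma_sd <= 0 || prior_range_sdlog <= 0 ||
      prior_phi_sdlog <= 0 || matern_nu <= 0)
    stop("all prior scales and matern_nu must be positive")
  if (!is.null(fix_phi) && fix_phi <= 0) stop("fix_phi must be positive (or Inf)")
  structure(list(prior_beta_sd = prior_beta_sd, prior_sigma_sd = prior_sigma_sd,
                 prior_range_meanlog = prior_range_meanlog,
                 prior_range_sdlog = prior_range_sdlog,
                 prior_phi_meanlog = prior_phi_meanlog,
                 prior_phi_sdlog = prior_phi_sdlog,
                 matern_nu = matern_nu, gp = gp, fix_phi = fix_phi,
                 fix_sigma = fix_sigma, fix_range = fix_range,
                 backend = backend, skew_correction = skew_correction,
                 mcmc_iter = mcmc_iter, mcmc_burn = mcmc_burn,
                 jitter = jitter, seed = seed),
            class = "set_model_spec")
}

# ---- beta-binomial log-likelihood and eta-derivatives -----------------------

bb_ll_parts <- function(k, n, eta, phi) {
  eta <- pmin(pmax(eta, -30), 30)  # keep 1 - mu away from exact 0
  mu <- stats::plogis(eta)
  if (is.infinite(phi)) {
    ll <- k * log(mu) + (n - k) * log1p(-mu)   # constants in eta dropped
    g <- k - n * mu
    h <- -n * mu * (1 - mu)
    return(list(ll = sum(ll), g = g, h = h))
  }
  a <- mu * phi; b <- (1 - mu) * phi
  ll <- lgamma(k + a) - lgamma(a) + lgamma(n - k + b) - lgamma(b)
  dmu <- phi * (digamma(k + a) - digamma(a) - digamma(n - k + b) + digamma(b))
  d2mu <- phi^2 * (trigamma(k + a) - trigamma(a) + trigamma(n - k + b) - trigamma(b))
  mup <- mu * (1 - mu)
  g <- dmu * mup
  h <- d2mu * mup^2 + dmu * mup * (1 - 2 * mu)
  list(ll = sum(ll), g = g, h = h)
}

# third derivative of the log-likelihood with respect to eta, for the
# skewness (mean) correction of the Gaussian approximation
bb_ll_d3 <- function(k, n, eta, phi) {
  eta <- pmin(pmax(eta, -30), 30)
  mu <- stats::plogis(eta)
  u <- mu * (1 - mu)
  up <- u * (1 - 2 * mu)
  upp <- u * (1 - 6 * mu + 6 * mu^2)
  if (is.infinite(phi)) {
    # ll = k log mu + (n-k) log(1-mu): L1 = k/mu - (n-k)/(1-mu), L2, L3
    L1 <- k / mu - (n - k) / (1 - mu)
    L2 <- -k / mu^2 - (n - k) / (1 - mu)^2
    L3 <- 2 * k / mu^3 - 2 * (n - k) / (1 - mu)^3
  } else {
    a <- mu * phi; b <- (1 - mu) * phi
    L1 <- phi * (digamma(k + a) - digamma(a) - digamma(n - k + b) + digamma(b))
    L2 <- phi^2 * (trigamma(k + a) - trigamma(a) + trigamma(n - k + b) - trigamma(b))
    L3 <- phi^3 * (psigamma(k + a, 2) - psigamma(a, 2) - psigamma(n - k + b, 2) +
                     psigamma(b, 2))
  }
  L3 * u^3 + 3 * L2 * u * up + L1 * upp
}

bb_ll_const <- function(k, n, phi) {
  if (is.infinite(phi)) return(sum(lchoose_gen(n, k)))
  sum(lchoose_gen(n, k) - lgamma(n + phi) + lgamma(phi))
}

# ---- Laplace machinery ------------------------------------------------------

# Newton ascent of the penalized log-posterior over z = (beta, S).
# A = cbind(X, I_m) conceptually; exploited implicitly.
newton_latent <- function(k, n, X, Kinv = NULL, prior_prec_beta, phi,
                          z0 = NULL, maxit = 100, tol = 1e-9) {
  p <- ncol(X); m <- if (is.null(Kinv)) 0L else nrow(Kinv)
  d <- p + m
  z <- if (is.null(z0)) numeric(d) else z0
  obj <- function(z) {
    eta <- drop(X %*% z[seq_len(p)]) + if (m) z[p + seq_len(m)] else 0
    lp <- bb_ll_parts(k, n, eta, phi)
    pen <- -0.5 * sum(prior_prec_beta * z[seq_len(p)]^2)
    if (m) pen <- pen - 0.5 * drop(crossprod(z[p + seq_len(m)], Kinv %*% z[p + seq_len(m)]))
    list(val = lp$ll + pen, g_eta = lp$g, h_eta = lp$h, eta = eta)
  }
  cur <- obj(z)
  H <- NULL
  for (it in seq_len(maxit)) {
    w <- pmax(-cur$h_eta, 1e-10)      # clamped negative Hessian (Fisher-like)
    # gradient of penalized objective
    gb <- drop(crossprod(X, cur$g_eta)) - prior_prec_beta * z[seq_len(p)]
    g <- if (m) c(gb, cur$g_eta - drop(Kinv %*% z[p + seq_len(m)])) else gb
    # Hessian blocks: X'WX + Pb ; X'W ; W + Kinv
    XtW <- t(X * w)
    Hbb <- XtW %*% X + diag(prior_prec_beta, p)
    if (m) {
      H <- rbind(cbind(Hbb, XtW),
                 cbind(t(XtW), Kinv + diag(w)))
    } else H <- Hbb
    step <- solve(H, g)
    # backtracking line search
    alpha <- 1
    repeat {
      znew <- z + alpha * step
      nxt <- obj(znew)
      if (is.finite(nxt$val) && nxt$val >= cur$val - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { nxt <- cur; znew <- z; break }
    }
    moved <- sqrt(sum((znew - z)^2))
    z <- znew; cur <- nxt
    if (moved < tol * (1 + sqrt(sum(z^2)))) break
  }
  w <- pmax(-cur$h_eta, 1e-10)
  XtW <- t(X * w)
  Hbb <- XtW %*% X + diag(prior_prec_beta, p)
  H <- if (m) rbind(cbind(Hbb, XtW), cbind(t(XtW), Kinv + diag(w))) else Hbb
  gb <- drop(crossprod(X, cur$g_eta)) - prior_prec_beta * z[seq_len(p)]
  g <- if (m) c(gb, cur$g_eta - drop(Kinv %*% z[p + seq_len(m)])) else gb
  list(z = z, value = cur$val, H = H, grad_norm = sqrt(sum(g^2)), iter = it,
       eta = cur$eta)
}

# log-marginal (Laplace) of the data given hyperparameters, plus hyperpriors
laplace_objective <- function(theta, free, fixed, k, n, X, coords, spec, cache) {
  pars <- fixed
  pars[free] <- exp(theta)
  p <- ncol(X)
  prior_prec_beta <- 1 / spec$prior_beta_sd^2
  m <- if (spec$gp) nrow(coords) else 0L
  Kinv <- NULL; ldK <- 0
  if (spec$gp) {
    K <- matern_cov_matrix(coords, sigma = pars[["sigma"]],
                           range_param = pars[["range"]], nu = spec$matern_nu,
                           jitter = spec$jitter)
    cK <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(cK)) return(list(val = -1e10))
    Kinv <- chol2inv(cK)
    ldK <- 2 * sum(log(diag(cK)))
  }
  nl <- newton_latent(k, n, X, Kinv, prior_prec_beta, pars[["phi"]],
                      z0 = cache$z)
  cH <- tryCatch(chol(nl$H), error = function(e) NULL)
  if (is.null(cH)) return(list(val = -1e10))
  ldH <- 2 * sum(log(diag(cH)))
  ldQ0 <- -p * log(spec$prior_beta_sd^2) - ldK
  lmarg <- nl$value + bb_ll_const(k, n, pars[["phi"]]) + 0.5 * ldQ0 - 0.5 * ldH
  lp <- hyperprior_logdens(pars, free, spec)
  list(val = lmarg + lp, newton = nl, Kinv = Kinv, cK = if (spec$gp) cK else NULL,
       pars = pars)
}

# log-density of the hyperpriors, on the log scale of each free parameter
# (Jacobians included)
hyperprior_logdens <- function(pars, free, spec) {
  lp <- 0
  if ("sigma" %in% free)
    lp <- lp + stats::dnorm(pars[["sigma"]], 0, spec$prior_sigma_sd, log = TRUE) +
      log(2) + log(pars[["sigma"]])
  if ("range" %in% free)
    lp <- lp + stats::dnorm(log(pars[["range"]]), spec$prior_range_meanlog,
                            spec$prior_range_sdlog, log = TRUE)
  if ("phi" %in% free)
    lp <- lp + stats::dnorm(log(pars[["phi"]]), spec$prior_phi_meanlog,
                            spec$prior_phi_sdlog, log = TRUE)
  lp
}

#' Fit the beta-binomial geostatistical suitability model
#'
#' Fits, by default with a Laplace approximation, the Bayesian model
#' described in [set_model_spec()]: a logit-linear fixed-effect predictor
#' plus a Matern Gaussian process at the cluster sites, with beta-binomial
#' observation noise. Inference follows the latent-Gaussian recipe: Newton
#' ascent finds the joint mode of \eqn{(\beta, S)} for given
#' hyperparameters, the hyperparameters \eqn{(\sigma, \ell, \phi)} are
#' optimised on their marginal posterior, and a Gaussian approximation at
#' the mode propagates fixed-effect and latent-field uncertainty.
#'
#' @param formula Model formula whose response is a two-column matrix of
#'   (successes, failures), e.g.
#'   \code{cbind(n_suitable, n_households - n_suitable) ~ cov1 + cov2}.
#' @param data Data frame with one row per cluster.
#' @param coords Either a one-sided formula naming the coordinate columns
#'   (default \code{~ x + y}) or a two-column matrix.
#' @param spec A [set_model_spec()].
#' @param standardization Optional standardization record (from
#'   [build_design()]) stored with the fit so predictions can replay the
#'   covariate transform.
#' @return An object of class \code{set_fit} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{vcov}, \code{fitted},
#'   \code{residuals}, \code{simulate}, \code{predict} and \code{plot}.
#' @examples
#' \donttest{
#' sim <- simulate_set_data(grid_spec(15, 15), n_clusters = 60, seed = 2)
#' df <- cbind(sim$clusters,
#'             buffer_extract(sim$covariates, sim$clusters[, c("x", "y")]))
#' fit <- set_fit(cbind(n_suitable, n_households - n_suitable) ~ cov1 + cov2,
#'                data = df, coords = ~ x + y)
#' summary(fit)
#' }
#' @export
set_fit <- function(formula, data, coords = ~ x + y, spec = set_model_spec(),
                    standardization = NULL) {
  stopifnot(inherits(spec, "set_model_spec"))
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  tt <- attr(mf, "terms")
  omitted <- attr(mf, "na.action")
  Y <- stats::model.response(mf)
  if (is.null(dim(Y)) || ncol(Y) != 2)
    stop("the response must be a two-column matrix: cbind(successes, failures)")
  k <- as.numeric(Y[, 1]); n <- as.numeric(Y[, 1] + Y[, 2])
  if (any(k < 0 | k > n)) stop("successes must lie in [0, trials]")
  X <- stats::model.matrix(tt, mf)
  if (inherits(coords, "formula")) {
    cv <- all.vars(coords)
    if (length(cv) != 2) stop("coords formula must name exactly two columns")
    coords <- as.matrix(as.data.frame(data)[, cv])
  } else coords <- as.matrix(coords)[, 1:2]
  if (!is.null(omitted)) coords <- coords[-omitted, , drop = FALSE]
  if (nrow(coords) != nrow(X)) stop("coords rows must align with the model frame")
  if (nrow(X) < 10) stop("need at least 10 clusters to fit the spatial model")

  # guard the degenerate all-zero / all-n likelihood plateaus via the priors:
  # nothing special needed, but warn when data carry no variation
  if (stats::sd(k / n) == 0)
    warning("all clusters have identical suitability proportion; ",
            "the fit is prior-driven")

  if (is.null(spec$prior_range_meanlog)) {
    diam <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
    spec$prior_range_meanlog <- log(max(diam / 3, .Machine$double.eps))
  }

  if (spec$backend == "mcmc")
    return(fit_mcmc(k, n, X, coords, spec, tt, standardization, formula))

  # free vs fixed hyperparameters
  fixed <- c(sigma = if (is.null(spec$fix_sigma)) NA else spec$fix_sigma,
             range = if (is.null(spec$fix_range)) NA else spec$fix_range,
             phi = if (is.null(spec$fix_phi)) NA else spec$fix_phi)
  if (!spec$gp) { fixed[["sigma"]] <- 0; fixed[["range"]] <- 1 }
  free <- names(fixed)[is.na(fixed)]
  init <- c(sigma = log(0.8), range = spec$prior_range_meanlog,
            phi = spec$prior_phi_meanlog)
  cache <- new.env()
  cache$z <- NULL
  negobj <- function(theta) {
    o <- laplace_objective(theta, free, fixed, k, n, X, coords, spec, cache)
    if (!is.null(o$newton)) cache$z <- o$newton$z
    -o$val
  }
  if (length(free) > 0) {
    opt <- stats::optim(init[free], negobj,
                        method = if (length(free) == 1) "Brent" else "Nelder-Mead",
                        lower = if (length(free) == 1) init[free] - 8 else -Inf,
                        upper = if (length(free) == 1) init[free] + 8 else Inf,
                        control = list(maxit = 500, reltol = 1e-8))
    theta_hat <- opt$par
    optim_conv <- opt$convergence
  } else { theta_hat <- numeric(0); optim_conv <- 0L }
  final <- laplace_objective(theta_hat, free, fixed, k, n, X, coords, spec, cache)
  if (is.null(final$newton) || final$val <= -1e9)
    stop("Laplace fit failed: covariance or Hessian not positive definite at the ",
         "hyperparameter optimum")
  nl <- final$newton
  if (nl$grad_norm > 1e-3 * (1 + abs(nl$value)))
    stop(sprintf(paste0("inner Newton did not converge (gradient norm %.3g after ",
                        "%d iterations)"), nl$grad_norm, nl$iter))
  cH <- chol(nl$H)
  p <- ncol(X)
  Sigma <- chol2inv(cH)
  m <- if (spec$gp) nrow(coords) else 0L
  # skewness correction: shift the Gaussian centre from the joint mode toward
  # the posterior mean, z_mean ~= z* + Sigma A' (T .* var(eta) / 2), with T the
  # third eta-derivative of the log-likelihood at the mode
  z_center <- nl$z
  if (isTRUE(spec$skew_correction)) {
    AS <- X %*% Sigma[seq_len(p), , drop = FALSE]
    if (m) AS <- AS + Sigma[p + seq_len(m), , drop = FALSE]
    v_eta <- rowSums(AS[, seq_len(p), drop = FALSE] * X)
    if (m) v_eta <- v_eta + AS[cbind(seq_len(m), p + seq_len(m))]
    w3 <- 0.5 * bb_ll_d3(k, n, nl$eta, final$pars[["phi"]]) * v_eta
    aw <- c(drop(crossprod(X, w3)), if (m) w3 else NULL)
    z_center <- nl$z + drop(Sigma %*% aw)
  }
  beta_mean <- z_center[seq_len(p)]
  beta_sd <- sqrt(diag(Sigma)[seq_len(p)])
  # approximate log-scale posterior sds for the hyperparameters from the
  # curvature of the marginal posterior
  hyper_sd <- rep(NA_real_, length(free)); names(hyper_sd) <- free
  if (length(free) > 0) {
    hess <- tryCatch(stats::optimHess(theta_hat, negobj), error = function(e) NULL)
    if (!is.null(hess)) {
      v <- tryCatch(diag(solve(hess)), error = function(e) rep(NA_real_, length(free)))
      hyper_sd[] <- sqrt(pmax(v, 0))
    }
  }
  beta_table <- data.frame(
    term = colnames(X), mean = beta_mean, sd = beta_sd,
    lower = beta_mean - stats::qnorm(0.975) * beta_sd,
    upper = beta_mean + stats::qnorm(0.975) * beta_sd,
    row.names = NULL, stringsAsFactors = FALSE)
  hyper <- data.frame(
    term = names(final$pars), value = unname(final$pars),
    fixed = !names(final$pars) %in% free, row.names = NULL,
    stringsAsFactors = FALSE)
  hyper$lower <- NA_real_
  hyper$upper <- NA_real_
  for (f in free) {
    i <- match(f, hyper$term)
    if (is.finite(hyper_sd[[f]])) {
      hyper$lower[i] <- exp(log(hyper$value[i]) - stats::qnorm(0.975) * hyper_sd[[f]])
      hyper$upper[i] <- exp(log(hyper$value[i]) + stats::qnorm(0.975) * hyper_sd[[f]])
    }
  }
  structure(list(
    backend = "laplace", formula = formula, terms = tt,
    coefficients = stats::setNames(beta_mean, colnames(X)),
    beta_table = beta_table, hyper = hyper,
    z_mode = nl$z, z_center = z_center, chol_H = cH, Sigma = Sigma,
    k = k, n = n, X = X, coords = coords, spec = spec,
    Kinv = final$Kinv, chol_K = final$cK,
    pars = final$pars,
    standardization = standardization,
    diagnostics = list(grad_norm = nl$grad_norm, newton_iter = nl$iter,
                       optim_convergence = optim_conv,
                       log_posterior = final$val)),
    class = "set_fit")
}

# ---- MCMC cross-check backend ----------------------------------------------
# Elliptical slice sampling for the latent Gaussian block (beta, S) with
# random-walk Metropolis on the log hyperparameters.
fit_mcmc <- function(k, n, X, coords, spec, tt, standardization, formula) {
  p <- ncol(X); m <- if (spec$gp) nrow(coords) else 0L
  fixed <- c(sigma = if (is.null(spec$fix_sigma)) NA else spec$fix_sigma,
             range = if (is.null(spec$fix_range)) NA else spec$fix_range,
             phi = if (is.null(spec$fix_phi)) NA else spec$fix_phi)
  if (!spec$gp) { fixed[["sigma"]] <- 0; fixed[["range"]] <- 1 }
  free <- names(fixed)[is.na(fixed)]
  theta <- c(sigma = log(0.8), range = spec$prior_range_meanlog,
             phi = spec$prior_phi_meanlog)[free]
  pars <- fixed; pars[free] <- exp(theta)
  loglik <- function(z, phi) {
    eta <- drop(X %*% z[seq_len(p)]) + if (m) z[p + seq_len(m)] else 0
    bb_ll_parts(k, n, eta, phi)$ll + bb_ll_const(k, n, phi)
  }
  chol_prior <- function(pars) {
    if (!m) return(NULL)
    chol(matern_cov_matrix(coords, sigma = pars[["sigma"]],
                           range_param = pars[["range"]], nu = spec$matern_nu,
                           jitter = spec$jitter))
  }
  with_seed(spec$seed, {
    cK <- chol_prior(pars)
    z <- numeric(p + m)
    draw_prior <- function(cK)
      c(stats::rnorm(p, 0, spec$prior_beta_sd),
        if (m) drop(crossprod(cK, stats::rnorm(m))) else NULL)
    logprior_S <- function(S, cK) {
      if (!m) return(0)
      u <- backsolve(cK, S, transpose = TRUE)
      -0.5 * sum(u^2) - sum(log(diag(cK)))
    }
    n_iter <- spec$mcmc_iter; burn <- spec$mcmc_burn
    keep <- matrix(NA_real_, n_iter - burn, p + m + length(free))
    step <- rep(0.3, length(free)); acc <- 0L
    ll <- loglik(z, pars[["phi"]])
    for (it in seq_len(n_iter)) {
      # elliptical slice update of the whole latent Gaussian block
      nu <- draw_prior(cK)
      logy <- ll + log(stats::runif(1))
      ang <- stats::runif(1, 0, 2 * pi)
      lo <- ang - 2 * pi; hi <- ang
      repeat {
        zp <- z * cos(ang) + nu * sin(ang)
        llp <- loglik(zp, pars[["phi"]])
        if (llp > logy) break
        if (ang < 0) lo <- ang else hi <- ang
        ang <- stats::runif(1, lo, hi)
      }
      z <- zp; ll <- llp
      # random-walk Metropolis on the free log hyperparameters
      if (length(free) > 0) {
        prop <- theta + stats::rnorm(length(free), 0, step)
        pp <- fixed; pp[free] <- exp(prop)
        cKp <- tryCatch(chol_prior(pp), error = function(e) NULL)
        if (!is.null(cKp) || !m) {
          S <- if (m) z[p + seq_len(m)] else numeric(0)
          llp2 <- loglik(z, pp[["phi"]])
          lr <- llp2 - ll +
            logprior_S(S, cKp) - logprior_S(S, cK) +
            hyperprior_logdens(pp, free, spec) - hyperprior_logdens(pars, free, spec)
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            theta <- prop; pars <- pp; cK <- cKp; ll <- llp2; acc <- acc + 1L
          }
        }
      }
      if (it > burn) keep[it - burn, ] <- c(z, theta)
    }
    beta_draws <- keep[, seq_len(p), drop = FALSE]
    beta_mean <- colMeans(beta_draws)
    beta_sd <- apply(beta_draws, 2, stats::sd)
    qs <- apply(beta_draws, 2, stats::quantile, c(0.025, 0.975))
    beta_table <- data.frame(term = colnames(X), mean = beta_mean, sd = beta_sd,
                             lower = qs[1, ], upper = qs[2, ], row.names = NULL,
                             stringsAsFactors = FALSE)
    hd <- exp(keep[, p + m + seq_along(free), drop = FALSE])
    hyper <- data.frame(term = names(fixed), value = unname(fixed),
                        fixed = !names(fixed) %in% free,
                        lower = NA_real_, upper = NA_real_,
                        stringsAsFactors = FALSE)
    for (j in seq_along(free)) {
      i <- match(free[j], hyper$term)
      hyper$value[i] <- mean(hd[, j])
      hyper$lower[i] <- stats::quantile(hd[, j], 0.025)
      hyper$upper[i] <- stats::quantile(hd[, j], 0.975)
    }
    pars_mean <- fixed
    for (j in seq_along(free)) pars_mean[free[j]] <- mean(hd[, j])
    structure(list(
      backend = "mcmc", formula = formula, terms = tt,
      coefficients = stats::setNames(beta_mean, colnames(X)),
      beta_table = beta_table, hyper = hyper,
      draws = keep, k = k, n = n, X = X, coords = coords, spec = spec,
      pars = pars_mean, standardization = standardization,
      diagnostics = list(mh_acceptance = acc / n_iter,
                         n_draws = nrow(keep))),
      class = "set_fit")
  })
}

# ---- methods ----------------------------------------------------------------

#' @export
print.set_fit <- function(x, ...) {
  cat("Beta-binomial geostatistical suitability model (backend:", x$backend, ")\n")
  cat(sprintf("%d clusters, %d fixed effect(s)%s\n", length(x$k), ncol(x$X),
              if (x$spec$gp) ", Matern GP" else ", no spatial field"))
  cat("\nFixed effects (posterior mean):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.set_fit <- function(object, ...) {
  structure(list(beta = object$beta_table, hyper = object$hyper,
                 backend = object$backend, n_clusters = length(object$k),
                 diagnostics = object$diagnostics),
            class = "summary.set_fit")
}

#' @export
print.summary.set_fit <- function(x, ...) {
  cat(sprintf("Beta-binomial geostatistical fit (%s), %d clusters\n\n",
              x$backend, x$n_clusters))
  cat("Fixed effects (posterior mean, sd, 95% interval):\n")
  print(cbind(x$beta[1], round(x$beta[-1], 4)), row.names = FALSE)
  cat("\nHyperparameters:\n")
  h <- x$hyper
  h$value <- signif(h$value, 4); h$lower <- signif(h$lower, 4)
  h$upper <- signif(h$upper, 4)
  print(h, row.names = FALSE)
  if (!is.null(x$diagnostics$grad_norm))
    cat(sprintf("\nNewton gradient norm %.2e; optimiser code %d\n",
                x$diagnostics$grad_norm, x$diagnostics$optim_convergence))
  if (!is.null(x$diagnostics$mh_acceptance))
    cat(sprintf("\nMH acceptance rate %.2f over %d kept draws\n",
                x$diagnostics$mh_acceptance, x$diagnostics$n_draws))
  invisible(x)
}

#' @export
coef.set_fit <- function(object, ...) object$coefficients

#' @export
vcov.set_fit <- function(object, ...) {
  p <- ncol(object$X)
  if (object$backend == "mcmc")
    return(stats::cov(object$draws[, seq_len(p), drop = FALSE]))
  V <- object$Sigma[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(V) <- list(colnames(object$X), colnames(object$X))
  V
}

#' @export
fitted.set_fit <- function(object, ...) {
  p <- ncol(object$X)
  z <- if (object$backend == "mcmc") colMeans(object$draws)[seq_len(p + length(object$k) * object$spec$gp)]
       else object$z_center
  eta <- drop(object$X %*% z[seq_len(p)]) +
    if (object$spec$gp) z[p + seq_along(object$k)] else 0
  stats::plogis(eta)
}

#' Pearson residuals under the beta-binomial variance
#'
#' \eqn{(k - n\hat\mu) / \sqrt{n\hat\mu(1-\hat\mu)[1 + (n-1)/(1+\phi)]}}
#' with \eqn{\hat\mu} the fitted (mode/posterior-mean) proportion.
#'
#' @param object A [set_fit()] object.
#' @param ... Unused.
#' @export
residuals.set_fit <- function(object, ...) {
  mu <- fitted(object)
  n <- object$n; k <- object$k
  phi <- object$pars[["phi"]]
  infl <- if (is.infinite(phi)) 1 else 1 + (n - 1) / (1 + phi)
  (k - n * mu) / sqrt(n * mu * (1 - mu) * infl)
}

#' Draw from the posterior predictive distribution of cluster counts
#'
#' For each posterior draw of the linear predictor at the cluster sites,
#' draws \eqn{P \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)} then
#' \eqn{Y \sim \mathrm{Bin}(n, P)}.
#'
#' @param object A [set_fit()] object.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Matrix with one column per simulation, one row per cluster.
#' @export
simulate.set_fit <- function(object, nsim = 1, seed = 1, ...) {
  dr <- posterior_draws(object, n_draws = nsim, seed = seed)
  with_seed(seed + 1L, {
    phi <- object$pars[["phi"]]
    out <- matrix(NA_real_, length(object$k), nsim)
    for (s in seq_len(nsim)) {
      mu <- stats::plogis(dr$eta_sites[, s])
      p <- if (is.infinite(phi)) mu else stats::rbeta(length(mu), mu * phi, (1 - mu) * phi)
      out[, s] <- stats::rbinom(length(mu), object$n, p)
    }
    out
  })
}

#' Observed-versus-fitted plot for a suitability fit
#'
#' @param x A [set_fit()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.set_fit <- function(x, ...) {
  graphics::plot(fitted(x), x$k / x$n,
                 xlab = "fitted suitability", ylab = "observed proportion",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

# Joint posterior draws of (beta, S at sites) and the site linear predictor.
posterior_draws <- function(fit, n_draws, seed = 1) {
  p <- ncol(fit$X)
  m <- if (fit$spec$gp) length(fit$k) else 0L
  if (fit$backend == "mcmc") {
    idx <- with_seed(seed, sample.int(nrow(fit$draws), n_draws, replace = TRUE))
    Z <- t(fit$draws[idx, seq_len(p + m), drop = FALSE])
  } else {
    Z <- with_seed(seed, {
      E <- matrix(stats::rnorm((p + m) * n_draws), p + m, n_draws)
      fit$z_center + backsolve(fit$chol_H, E)
    })
  }
  beta <- Z[seq_len(p), , drop = FALSE]
  S <- if (m) Z[p + seq_len(m), , drop = FALSE] else NULL
  eta_sites <- fit$X %*% beta + if (m) S else 0
  list(beta = beta, S = S, eta_sites = eta_sites)
}
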