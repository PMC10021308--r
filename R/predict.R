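#' Predict the suitability surface and exceedance probabilities
#'
#' Propagates the joint posterior of the fitted model to every grid cell:
#' each posterior draw of \eqn{(\beta, S_{\mathrm{sites}})} is extended to
#' the cell centres through the Gaussian-process conditional
#' \eqn{S_{\mathrm{cell}} \mid S_{\mathrm{sites}}}, giving draws of the cell
#' linear predictor \eqn{\eta = \beta_0 + x'\beta + S}. The per-cell outputs
#' are the posterior mean and sd of \eqn{\mathrm{logit}^{-1}(\eta)} and the
#' exceedance probability — the fraction of draws whose suitability exceeds
#' the threshold (0.8 by default, the trial's village-inclusion criterion).
#'
#' Cell covariates use cell-centre values (the radius-0 convention); when
#' the fit carries a standardization record, the same affine transform is
#' replayed before evaluating the linear predictor. Cells are processed in
#' blocks so grids beyond a few thousand cells stay tractable; draws are
#' conditionally independent across cells given \eqn{(\beta,
#' S_{\mathrm{sites}})}, which leaves all per-cell summaries exact while not
#' representing residual cross-cell correlation.
#'
#' @param fit A [set_fit()] object.
#' @param stack A [covariate_stack()] providing every covariate named in the
#'   model formula (an informative error names any missing term). May be
#'   \code{NULL} for intercept-only models, in which case \code{grid} must
#'   be given.
#' @param threshold Exceedance threshold in (0, 1).
#' @param n_draws Number of posterior draws (>= 100).
#' @param seed Integer seed.
#' @param grid A [grid_spec()] (only needed when \code{stack} is NULL).
#' @param block_size Cells per prediction block.
#' @return An object of class \code{set_surface}: list with [set_raster()]s
#'   \code{mean}, \code{sd}, \code{exceedance}, plus \code{threshold},
#'   \code{n_draws} and the draw \code{seed}.
#' @export
predict_surface <- function(fit, stack, threshold = 0.8, n_draws = 1000,
                            seed = 1, grid = NULL, block_size = 2000) {
  stopifnot(inherits(fit, "set_fit"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (n_draws < 100) stop("n_draws must be at least 100")
  if (is.null(stack)) {
    if (is.null(grid)) stop("either a covariate stack or a grid must be supplied")
  } else {
    stopifnot(inherits(stack, "covariate_stack"))
    grid <- stack$grid
  }
  tt <- stats::delete.response(fit$terms)
  need <- all.vars(tt)
  have <- if (is.null(stack)) character(0) else names(stack$layers)
  miss <- setdiff(need, have)
  if (length(miss))
    stop("covariate stack lacks model term(s): ", paste(miss, collapse = ", "))
  m <- n_cells(grid)
  nd <- if (length(need)) as.data.frame(stack$layers[need])
        else as.data.frame(matrix(nrow = m, ncol = 0))
  if (!is.null(fit$standardization) && length(need)) {
    std <- fit$standardization
    for (nm in intersect(names(nd), std$layer)) {
      i <- match(nm, std$layer)
      nd[[nm]] <- (nd[[nm]] - std$center[i]) / std$scale[i]
    }
  }
  Xg <- stats::model.matrix(tt, nd)
  dr <- posterior_draws(fit, n_draws = n_draws, seed = seed)
  cc <- cell_centers(grid)
  pars <- fit$pars
  if (fit$spec$gp && pars[["sigma"]] > 0 && is.null(fit$chol_K))
    fit$chol_K <- chol(matern_cov_matrix(fit$coords, sigma = pars[["sigma"]],
                                         range_param = pars[["range"]],
                                         nu = fit$spec$matern_nu,
                                         jitter = fit$spec$jitter))
  pm <- psd <- pexc <- numeric(m)
  with_seed(seed + 999L, {
    for (start in seq(1, m, by = block_size)) {
      idx <- start:min(start + block_size - 1, m)
      eta <- Xg[idx, , drop = FALSE] %*% dr$beta
      if (fit$spec$gp && pars[["sigma"]] > 0) {
        Kcg <- matern_cov_matrix(fit$coords, cc[idx, , drop = FALSE],
                                 sigma = pars[["sigma"]],
                                 range_param = pars[["range"]],
                                 nu = fit$spec$matern_nu)
        B <- backsolve(fit$chol_K,
                       backsolve(fit$chol_K, Kcg, transpose = TRUE))  # Kss^-1 Kcg
        condvar <- pmax(pars[["sigma"]]^2 * (1 + fit$spec$jitter) -
                          colSums(Kcg * B), 0)
        eta <- eta + crossprod(B, dr$S) +
          sqrt(condvar) * matrix(stats::rnorm(length(idx) * n_draws),
                                 length(idx), n_draws)
      }
      p <- stats::plogis(eta)
      pm[idx] <- rowMeans(p)
      psd[idx] <- apply(p, 1, stats::sd)
      pexc[idx] <- rowMeans(p > threshold)
    }
  })
  structure(list(grid = grid,
                 mean = set_raster(grid, pm, "posterior mean suitability"),
                 sd = set_raster(grid, psd, "posterior sd"),
                 exceedance = set_raster(grid, pexc,
                                         sprintf("P(suitability > %.2f)", threshold)),
                 threshold = threshold, n_draws = n_draws, seed = seed),
            class = "set_surface")
}

#' @rdname predict_surface
#' @param object A [set_fit()] object.
#' @param ... Passed on to [predict_surface()].
#' @export
predict.set_fit <- function(object, stack = NULL, ...) {
  predict_surface(object, stack, ...)
}

#' @export
print.set_surface <- function(x, ...) {
  cat(sprintf("<set_surface> %d x %d cells; threshold %.2f; %d draws\n",
              x$grid$n_rows, x$grid$n_cols, x$threshold, x$n_draws))
  cat(sprintf("  mean suitability range [%.3f, %.3f]; exceedance range [%.3f, %.3f]\n",
              min(x$mean$values), max(x$mean$values),
              min(x$exceedance$values), max(x$exceedance$values)))
  invisible(x)
}

#' Plot the three layers of a suitability surface
#'
#' @param x A \code{set_surface}.
#' @param which Layers to draw (any of "mean", "sd", "exceedance").
#' @param ... Passed to [plot.set_raster()].
#' @export
plot.set_surface <- function(x, which = c("mean", "sd", "exceedance"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  for (w in which) plot(x[[w]], ...)
  invisible(x)
}
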