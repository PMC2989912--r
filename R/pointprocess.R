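#' Construct a spatial point pattern
#'
#' @param points Data frame with columns `x`, `y` (metres).
#' @param window A `spatial_window` containing every point.
#' @return Object of class `point_pattern`.
#' @export
point_pattern <- function(points, window) {
  points <- tibble::as_tibble(points)[, c("x", "y")]
  stopifnot(inherits(window, "spatial_window"))
  if (nrow(points) > 0 &&
      !all(points_in_window(window, points$x, points$y))) {
    stop("all points must lie inside the window", call. = FALSE)
  }
  structure(list(points = points, window = window), class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern> %d points in a window of %.4g m^2\n",
              nrow(x$points), x$window$area))
  invisible(x)
}

#' Number of points in a pattern
#' @param pattern A `point_pattern`.
#' @export
npoints <- function(pattern) nrow(pattern$points)

new_poisson_fit <- function(kind, window, n, lambda_hat = NULL, alpha = NULL,
                            beta = NULL, se = NULL, loglik = NULL,
                            covariate = NULL, expected_count = NULL,
                            sigma_kernel = NULL) {
  structure(list(kind = kind, window = window, n = n, lambda_hat = lambda_hat,
                 alpha = alpha, beta = beta, se = se, loglik = loglik,
                 covariate = covariate, expected_count = expected_count,
                 sigma_kernel = sigma_kernel),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  if (x$kind == "homogeneous") {
    cat(sprintf("<poisson_fit> homogeneous: lambda = %.6g /m^2 (n = %d), loglik = %.4g\n",
                x$lambda_hat, x$n, x$loglik))
  } else {
    cat(sprintf("<poisson_fit> inhomogeneous: log lambda = %.4g + %.4g * Z (n = %d), loglik = %.4g\n",
                x$alpha, x$beta, x$n, x$loglik))
  }
  invisible(x)
}

#' Fit a homogeneous Poisson point process
#'
#' The maximum-likelihood intensity is the observed density
#' \eqn{\hat\lambda = n / |A|}; the reported log-likelihood is
#' \eqn{n \log\hat\lambda - \hat\lambda |A|}.
#'
#' @param pattern A `point_pattern`.
#' @return A `poisson_fit` of kind `"homogeneous"`.
#' @export
fit_homogeneous_poisson <- function(pattern) {
  n <- npoints(pattern)
  A <- pattern$window$area
  lambda <- n / A
  if (n == 0) {
    warning("empty pattern: lambda_hat = 0", call. = FALSE)
    ll <- 0
  } else {
    ll <- n * log(lambda) - lambda * A
  }
  new_poisson_fit("homogeneous", pattern$window, n, lambda_hat = lambda,
                  loglik = ll, expected_count = n)
}

#' Fit an inhomogeneous Poisson process with a gridded covariate
#'
#' Maximizes the point-process log-likelihood
#' \eqn{\sum_i \log\lambda(s_i) - \int_A \lambda(s)\,ds} with
#' \eqn{\log\lambda(s) = \alpha + \beta Z(s)} by Berman--Turner quadrature:
#' dummy points at covariate cell centres plus the data points, with counting
#' weights, passed to a weighted Poisson GLM. At the optimum the score
#' identity \eqn{\sum_q w_q \hat\lambda_q = n} holds to GLM convergence
#' tolerance.
#'
#' A proportional link (\eqn{\lambda = \beta Z}, closed form
#' \eqn{\hat\beta = n / \int Z}) is available via `link = "prop"`.
#'
#' @param pattern A `point_pattern`.
#' @param covariate A `density_surface` defined on the pattern's window.
#' @param link `"log"` (default) or `"prop"`.
#' @param covariate_at_data Optional covariate values at the data points,
#'   overriding interpolation from the grid (used for leave-one-out
#'   bandwidth selection).
#' @return A `poisson_fit` of kind `"inhomogeneous"` with coefficients,
#'   standard errors, log-likelihood and quadrature-based expected count.
#' @export
fit_inhomogeneous_poisson <- function(pattern, covariate, link = "log",
                                      covariate_at_data = NULL) {
  link <- match.arg(link, c("log", "prop"))
  n <- npoints(pattern)
  window <- pattern$window
  mask <- covariate$mask
  cellarea <- covariate$cell^2
  zgrid <- covariate$values[mask]
  if (stats::sd(zgrid) < 1e-12) {
    warning("covariate is constant over the window; ",
            "falling back to the homogeneous fit", call. = FALSE)
    hom <- fit_homogeneous_poisson(pattern)
    hom$alpha <- log(max(hom$lambda_hat, .Machine$double.xmin))
    hom$beta <- 0
    return(hom)
  }
  zdata <- if (is.null(covariate_at_data)) {
    eval_surface(covariate, pattern$points$x, pattern$points$y)
  } else covariate_at_data
  if (link == "prop") {
    if (any(zgrid < 0) || any(zdata <= 0)) {
      stop("proportional link requires a positive covariate", call. = FALSE)
    }
    int_z <- sum(zgrid) * cellarea
    beta <- n / int_z
    ll <- sum(log(beta * zdata)) - n
    return(new_poisson_fit("inhomogeneous", window, n, alpha = NA_real_,
                           beta = beta, loglik = ll, covariate = covariate,
                           expected_count = n))
  }
  # Berman-Turner: dummies at masked cell centres + data points
  g <- surface_grid(covariate)
  cx <- rep(g$x, each = length(g$y))[as.vector(mask)]
  cy <- rep(g$y, times = length(g$x))[as.vector(mask)]
  # counting weights: each cell's area split among its quadrature points
  di <- .cell_index(covariate, pattern$points$x, pattern$points$y)
  ci <- .cell_index(covariate, cx, cy)
  pos <- match(di, ci)
  ndata_in_cell <- tabulate(pos[!is.na(pos)], nbins = length(ci))
  w_cell <- cellarea / (ndata_in_cell + 1)
  w_data <- w_cell[pos]
  w_data[is.na(w_data)] <- cellarea  # data in a masked-out sliver cell
  z <- c(zdata, zgrid)
  w <- c(w_data, unname(w_cell))
  y <- c(1 / w_data, rep(0, length(zgrid)))
  fit <- suppressWarnings(
    stats::glm(y ~ z, family = stats::poisson(), weights = w,
               control = list(epsilon = 1e-10, maxit = 100)))
  co <- stats::coef(fit)
  lam_q <- exp(co[1] + co[2] * z)
  ll <- sum(log(exp(co[1] + co[2] * zdata))) - sum(exp(co[1] + co[2] * zgrid)) * cellarea
  new_poisson_fit("inhomogeneous", window, n,
                  alpha = unname(co[1]), beta = unname(co[2]),
                  se = unname(sqrt(diag(stats::vcov(fit)))),
                  loglik = ll, covariate = covariate,
                  expected_count = sum(w * lam_q),
                  sigma_kernel = attr(covariate, "sigma"))
}

.cell_index <- function(surface, x, y) {
  nx <- ncol(surface$values); ny <- nrow(surface$values)
  ix <- pmin(pmax(floor((x - surface$x0) / surface$cell), 0), nx - 1)
  iy <- pmin(pmax(floor((y - surface$y0) / surface$cell), 0), ny - 1)
  iy * nx + ix
}

#' Fitted intensity surface of a Poisson fit
#'
#' @param fit A `poisson_fit`.
#' @param cell Cell size for the homogeneous case (ignored when the fit
#'   carries a covariate grid).
#' @return A `density_surface` of \eqn{\hat\lambda(s)} (trees per m^2).
#' @export
fitted_intensity_surface <- function(fit, cell = 50) {
  if (fit$kind == "homogeneous" || is.null(fit$covariate)) {
    bb <- window_bbox(fit$window)
    nx <- max(1L, ceiling((bb["xmax"] - bb["xmin"]) / cell))
    ny <- max(1L, ceiling((bb["ymax"] - bb["ymin"]) / cell))
    gx <- bb["xmin"] + (seq_len(nx) - 0.5) * cell
    gy <- bb["ymin"] + (seq_len(ny) - 0.5) * cell
    mask <- outer(gy, gx, function(yy, xx) points_in_window(fit$window, xx, yy))
    lam <- if (fit$kind == "homogeneous") fit$lambda_hat else exp(fit$alpha)
    return(density_surface(bb["xmin"], bb["ymin"], cell,
                           matrix(lam, ny, nx), mask, fit$window))
  }
  transform_surface(fit$covariate, function(z) exp(fit$alpha + fit$beta * z))
}

#' Simulate a Poisson point pattern by thinning
#'
#' For a constant rate, draws \eqn{N \sim \mathrm{Poisson}(\lambda |A|)}
#' uniform points. For a gridded intensity, generates at the maximal rate
#' \eqn{\lambda_{max}} and keeps each point independently with probability
#' \eqn{\lambda(s)/\lambda_{max}} (rejection thinning), so counts are
#' Poisson with mean \eqn{\int_A \lambda}.
#'
#' @param intensity A `density_surface`, or a single non-negative number
#'   (trees per m^2).
#' @param window Required when `intensity` is a number; otherwise taken from
#'   the surface.
#' @return A `point_pattern`.
#' @export
simulate_poisson <- function(intensity, window = NULL) {
  if (is.numeric(intensity) && length(intensity) == 1) {
    stopifnot(!is.null(window), intensity >= 0)
    n <- stats::rpois(1, intensity * window$area)
    return(point_pattern(runif_in_window(window, n), window))
  }
  stopifnot(inherits(intensity, "density_surface"))
  if (is.null(window)) window <- intensity$window
  lam_max <- max(intensity$values[intensity$mask], 0)
  if (lam_max == 0) return(point_pattern(tibble::tibble(x = numeric(0),
                                                        y = numeric(0)),
                                         window))
  if (lam_max * window$area > 5e6) {
    stop("dominating rate lambda_max * |A| = ", format(lam_max * window$area),
         " candidate points: intensity too peaked for rejection thinning",
         call. = FALSE)
  }
  n0 <- stats::rpois(1, lam_max * window$area)
  cand <- runif_in_window(window, n0)
  if (n0 == 0) return(point_pattern(cand, window))
  p_keep <- pmin(pmax(eval_surface(intensity, cand$x, cand$y), 0), lam_max) / lam_max
  keep <- stats::runif(n0) < p_keep
  point_pattern(cand[keep, , drop = FALSE], window)
}

#' Select the kernel bandwidth by cross-validated likelihood
#'
#' For each candidate bandwidth, the covariate surface is rebuilt from the
#' detected (aerial) points and the inhomogeneous model refit to the full
#' pattern with the covariate evaluated at each data point leaving out that
#' point's own kernel contribution (leave-one-out, which removes the
#' degenerate preference for vanishing bandwidth). The criterion is the
#' negative of this cross-validated point-process log-likelihood.
#'
#' @param pattern `point_pattern` the model is fit to.
#' @param detected `point_pattern` (or data frame) of covariate source
#'   points, e.g. aerial-survey trees.
#' @param weights Optional per-source weights (inverse detection
#'   probabilities).
#' @param sigma_grid Candidate bandwidths (m), all positive.
#' @param cell Covariate grid cell size (m).
#' @param edge_correct Passed to [kernel_density_surface()].
#' @return A list with `sigma_star` (the minimizer) and `profile`, a tibble
#'   of `(sigma, criterion)` covering the whole grid.
#' @export
optimize_sigma <- function(pattern, detected, weights = NULL, sigma_grid,
                           cell = 50, edge_correct = TRUE) {
  stopifnot(length(sigma_grid) >= 1, all(sigma_grid > 0))
  det_pts <- if (inherits(detected, "point_pattern")) detected$points else
    tibble::as_tibble(detected)
  crit <- purrr::map_dbl(sigma_grid, function(sg) {
    surf <- kernel_density_surface(det_pts, pattern$window, sg,
                                   weights = weights, cell = cell,
                                   edge_correct = edge_correct)
    attr(surf, "sigma") <- sg
    z_loo <- kernel_values_at(det_pts, pattern$points, sg, weights = weights,
                              leave_one_out = TRUE)
    fit <- tryCatch(
      fit_inhomogeneous_poisson(pattern, surf, covariate_at_data = z_loo),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik)) NA_real_ else -fit$loglik
  })
  if (all(!is.finite(crit))) {
    stop("bandwidth criterion non-finite at every grid value", call. = FALSE)
  }
  best <- which.min(crit)
  list(sigma_star = sigma_grid[best],
       profile = tibble::tibble(sigma = sigma_grid, criterion = crit))
}

# Gaussian blur of a gridded field, edge-normalized at the target cell:
# returns (K * (V on mask)) / (K * mask), with K a separable Gaussian.
.blur_grid <- function(values, mask, gx, gy, h) {
  Kx <- exp(-outer(gx, gx, "-")^2 / (2 * h^2))
  Ky <- exp(-outer(gy, gy, "-")^2 / (2 * h^2))
  Vm <- values * mask
  num <- Ky %*% Vm %*% Kx
  den <- Ky %*% (mask * 1) %*% Kx
  num / pmax(den, 1e-12)
}

# smoothed intensity estimate of a point set on the cells of `ref` surface,
# normalized by the smoothing mass inside the window at each target cell
.smoothed_data_field <- function(points, ref, h) {
  g <- surface_grid(ref)
  konst <- 1 / (2 * pi * h^2)
  if (nrow(points) == 0) {
    raw <- matrix(0, length(g$y), length(g$x))
  } else {
    Ex <- exp(-outer(points$x, g$x, "-")^2 / (2 * h^2))
    Ey <- exp(-outer(points$y, g$y, "-")^2 / (2 * h^2))
    raw <- konst * t(Ey) %*% Ex
  }
  Kx <- exp(-outer(g$x, g$x, "-")^2 / (2 * h^2))
  Ky <- exp(-outer(g$y, g$y, "-")^2 / (2 * h^2))
  den <- konst * ref$cell^2 * (Ky %*% (ref$mask * 1) %*% Kx)
  raw / pmax(den, 1e-12)
}

#' Simulation-envelope goodness-of-fit diagnostic (qq-plot)
#'
#' Computes a smoothed residual field (kernel intensity estimate of the
#' pattern minus the equally smoothed fitted intensity, both edge-normalized)
#' and its quantiles over grid cells, then compares them quantile-by-quantile
#' with the mean and pointwise 95% envelope of the same statistic on
#' `n_sim` patterns simulated from the fitted model. The observed pattern is
#' judged consistent with the model (`inside = TRUE`) when its quantile
#' curve lies within the envelope everywhere.
#'
#' @param fit A `poisson_fit`.
#' @param pattern The observed `point_pattern`.
#' @param n_sim Number of simulations (>= 20; 39 gives an exact min/max 5%
#'   pointwise envelope, 100 is the conventional default).
#' @param smooth_sigma Residual smoothing bandwidth (m); defaults to half the
#'   covariate kernel bandwidth when known, else an eighth of the shorter
#'   window side.
#' @param probs Quantile probabilities of the residual field.
#' @param cell Grid cell size for the homogeneous case.
#' @return An object of class `envelope_diagnostic`: a tibble
#'   `(prob, observed, mean, lower, upper)` with attributes `n_sim` and
#'   `inside`.
#' @export
gof_envelope <- function(fit, pattern, n_sim = 100, smooth_sigma = NULL,
                         probs = seq(0.05, 0.95, by = 0.05), cell = 50) {
  stopifnot(n_sim >= 20)
  lam_surf <- fitted_intensity_surface(fit, cell = cell)
  g <- surface_grid(lam_surf)
  if (is.null(smooth_sigma)) {
    smooth_sigma <- if (!is.null(fit$sigma_kernel)) fit$sigma_kernel / 2 else {
      bb <- window_bbox(pattern$window)
      min(bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"]) / 8
    }
  }
  lam_smooth <- .blur_grid(lam_surf$values, lam_surf$mask, g$x, g$y,
                           smooth_sigma)
  resid_q <- function(pts) {
    fld <- .smoothed_data_field(pts, lam_surf, smooth_sigma) - lam_smooth
    stats::quantile(fld[lam_surf$mask], probs = probs, names = FALSE)
  }
  obs <- resid_q(pattern$points)
  sims <- vapply(seq_len(n_sim), function(i) {
    resid_q(simulate_poisson(lam_surf)$points)
  }, numeric(length(probs)))
  k <- floor((n_sim + 1) * 0.025)
  lower <- apply(sims, 1, function(v) if (k < 1) min(v) else sort(v)[k])
  upper <- apply(sims, 1, function(v) if (k < 1) max(v) else
    sort(v)[n_sim + 1 - k])
  out <- tibble::tibble(prob = probs, observed = obs,
                        mean = rowMeans(sims), lower = lower, upper = upper)
  structure(out, n_sim = n_sim,
            inside = all(obs >= lower & obs <= upper),
            smooth_sigma = smooth_sigma,
            class = c("envelope_diagnostic", class(out)))
}

#' @export
print.envelope_diagnostic <- function(x, ...) {
  cat(sprintf("<envelope_diagnostic> %d simulations; observed curve %s the 95%% envelope\n",
              attr(x, "n_sim"),
              if (attr(x, "inside")) "INSIDE" else "OUTSIDE"))
  NextMethod()
}
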