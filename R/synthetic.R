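#' Generating parameter set for synthetic datasets
#'
#' Bundles every parameter of the observation process the package models:
#' the log-linear spatial intensity (`alpha`, `beta` on a standardized
#' covariate smoothed at `sigma_kernel`), the logistic aerial-detection
#' model (`beta0`, `beta1`), the Poisson fruit-production model (`c1`, `c2`,
#' `sd_u`, `sd_v`) and the Gaussian fruit-date model (`c3`, `sd_w`, `sd_z`,
#' `sigma_resid`). Phenology defaults are the published BCI estimates; the
#' spatial intercept/slope and the detection parameters default to values
#' giving realistic tree densities and the published 14.7% visibility.
#'
#' @param ... Overrides for any field.
#' @return Object of class `synthetic_truth` (a named list).
#' @export
synthetic_truth <- function(...) {
  p <- bci_defaults()
  truth <- list(
    alpha = -9, beta = 2, sigma_kernel = p$sigma_kernel,
    beta0 = -4, beta1 = 0.003,
    c1 = p$c1, c2 = p$c2, sd_u = p$sd_u, sd_v = p$sd_v,
    c3 = p$c3, sd_w = p$sd_w, sd_z = p$sd_z, sigma_resid = p$sigma_resid
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(truth))
  if (length(unknown) > 0) {
    stop("unknown truth field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  truth[names(dots)] <- dots
  for (nm in c("sd_u", "sd_v", "sd_w", "sd_z", "sigma_resid",
               "sigma_kernel")) {
    if (truth[[nm]] < 0) stop(nm, " must be non-negative", call. = FALSE)
  }
  structure(truth, class = c("synthetic_truth", "list"))
}

#' Serialize / restore a generating parameter set as JSON
#' @param truth A `synthetic_truth`.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  do.call(synthetic_truth, jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' A smooth random covariate surface
#'
#' Kernel-smooths a sparse set of random weighted knots and standardizes the
#' result to mean 0 and SD 1 over the window, emulating an environmental
#' gradient at the spatial scale `sigma`. Standardized values are clipped to
#' ±2.5 so that exponential (log-link) intensities built on the covariate
#' stay bounded.
#'
#' @param window A `spatial_window`.
#' @param sigma Smoothing scale (m).
#' @param cell Grid cell size (m).
#' @param n_knots Number of knots (default 30).
#' @return A standardized `density_surface`.
#' @export
random_covariate_surface <- function(window, sigma, cell = 50,
                                     n_knots = 30) {
  knots <- runif_in_window(window, n_knots)
  wts <- stats::rlnorm(n_knots, 0, 1)
  surf <- kernel_density_surface(knots, window, sigma, weights = wts,
                                 cell = cell, edge_correct = FALSE)
  v <- surf$values
  mu <- mean(v[surf$mask]); s <- stats::sd(v[surf$mask])
  vals <- pmin(pmax((v - mu) / max(s, 1e-12), -2.5), 2.5)
  out <- surf
  out$values <- vals
  attr(out, "sigma") <- sigma
  out
}

#' Synthetic reference DBH sample
#'
#' Lognormal stem diameters (median 550 mm, log-SD 0.45) truncated to
#' [150, 2500] mm — the size range of canopy-statured adults of a large
#' emergent tree. Used as the reference pool when no census is supplied.
#'
#' @param n Sample size.
#' @return DBH values (mm).
#' @export
synthetic_dbh_sample <- function(n) {
  d <- stats::rlnorm(n, log(550), 0.45)
  pmin(pmax(d, 150), 2500)
}

#' Generate a synthetic tree census
#'
#' Builds a smooth covariate, draws trees from the inhomogeneous Poisson
#' process \eqn{\log\lambda = \alpha + \beta Z}, assigns DBH from the
#' synthetic reference distribution and Bernoulli aerial visibility from the
#' logistic detection model.
#'
#' @param truth A `synthetic_truth`.
#' @param window A `spatial_window`.
#' @param cell Covariate grid cell (m).
#' @param n_knots Knots of the random covariate.
#' @return List with `trees` (tibble `tree_id, x, y, dbh, visible_aerial,
#'   source`), `covariate` (standardized `density_surface`), `intensity`
#'   (the generating intensity surface) and `truth`.
#' @export
generate_census <- function(truth, window, cell = 50, n_knots = 30) {
  stopifnot(inherits(truth, "synthetic_truth"))
  Z <- random_covariate_surface(window, truth$sigma_kernel, cell, n_knots)
  lam <- transform_surface(Z, function(z) exp(truth$alpha + truth$beta * z))
  attr(lam, "sigma") <- truth$sigma_kernel
  pat <- simulate_poisson(lam, window)
  n <- npoints(pat)
  dbh <- synthetic_dbh_sample(n)
  p_vis <- stats::plogis(truth$beta0 + truth$beta1 * dbh)
  trees <- tibble::tibble(
    tree_id = sprintf("syn%05d", seq_len(n)),
    x = pat$points$x, y = pat$points$y,
    dbh = dbh,
    visible_aerial = stats::runif(n) < p_vis,
    source = "simulated"
  )
  list(trees = trees, covariate = Z, intensity = lam, truth = truth)
}

#' Generate synthetic fruit-trap records
#'
#' Per tree-season totals are Poisson with log-mean
#' \eqn{c_1 + c_2\,\mathrm{dbh} + u_i + v_j} (times `fruits_scale`), and
#' each fruit's fall day is normal around the tree-and-season-shifted peak
#' \eqn{c_3 + w_i + z_j} with SD `sigma_resid`, truncated to the season
#' window [0, 365]. With `weekly = TRUE`, fruits are binned to the 7-day
#' trap-visit schedule, as in weekly trap checks.
#'
#' @param truth A `synthetic_truth`.
#' @param n_trees,s Numbers of trees and seasons (>= 2).
#' @param fruits_scale Multiplier on expected totals; raise above 1 for
#'   well-conditioned recovery experiments, keep 1 for the sparse
#'   trap-count realism of the study system.
#' @param dbh Optional per-tree DBH (mm); drawn uniformly from `dbh_range`
#'   when NULL.
#' @param dbh_range Range for the default DBH draw.
#' @param weekly Bin fruit days to weekly visits (default FALSE).
#' @return List with `phenology` (tibble `tree_id, season_id, day, count`),
#'   `trees` (tibble `tree_id, dbh`), `effects` (the generating `u, v, w,
#'   z`) and `truth`.
#' @export
generate_trap_data <- function(truth, n_trees, s, fruits_scale = 1,
                               dbh = NULL, dbh_range = c(500, 1500),
                               weekly = FALSE) {
  stopifnot(inherits(truth, "synthetic_truth"), n_trees >= 2, s >= 2)
  if (is.null(dbh)) dbh <- stats::runif(n_trees, dbh_range[1], dbh_range[2])
  stopifnot(length(dbh) == n_trees)
  eff <- draw_random_effects(n_trees, s,
                             list(sd_u = truth$sd_u, sd_v = truth$sd_v),
                             list(sd_w = truth$sd_w, sd_z = truth$sd_z))
  cells <- tidyr::expand_grid(i = seq_len(n_trees), j = seq_len(s))
  mu <- fruits_scale * exp(truth$c1 + truth$c2 * dbh[cells$i] +
                             eff$u[cells$i] + eff$v[cells$j])
  totals <- stats::rpois(nrow(cells), mu)
  peak <- truth$c3 + eff$w[cells$i] + eff$z[cells$j]
  days <- purrr::map2(totals, peak, function(n, pk) {
    if (n == 0) return(numeric(0))
    d <- stats::rnorm(n, pk, truth$sigma_resid)
    while (any(bad <- d < 0 | d > 365)) {           # truncate to the season
      d[bad] <- stats::rnorm(sum(bad), pk, truth$sigma_resid)
    }
    d
  })
  rec <- tibble::tibble(
    tree_id = rep(sprintf("t%03d", cells$i), totals),
    season_id = rep(sprintf("s%03d", cells$j), totals),
    day = unlist(days),
    count = 1L
  )
  if (weekly) {
    rec$day <- pmin(7 * ceiling(rec$day / 7), 365)
    rec <- rec |>
      dplyr::count(.data$tree_id, .data$season_id, .data$day,
                   name = "count") |>
      dplyr::mutate(count = as.integer(.data$count))
  }
  list(phenology = rec,
       trees = tibble::tibble(tree_id = sprintf("t%03d", seq_len(n_trees)),
                              dbh = dbh),
       effects = eff, truth = truth)
}
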