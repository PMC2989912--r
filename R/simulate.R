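#' Simulate a forest of trees from fitted spatial models
#'
#' Draws tree positions from a fitted intensity surface by Poisson thinning
#' and assigns each tree a DBH from the rank-transform sampler. None of the
#' observed trees are reused: every stem is a fresh draw from the fitted
#' process.
#'
#' @param window A `spatial_window`.
#' @param intensity A `density_surface` of trees per m^2 (e.g. from
#'   [fitted_intensity_surface()]), or a constant rate.
#' @param dbh_model A `dbh_distribution`.
#' @param id_prefix Prefix for generated tree ids.
#' @return A tibble with columns `tree_id`, `x`, `y`, `dbh`, `source`.
#' @export
simulate_forest <- function(window, intensity, dbh_model,
                            id_prefix = "sim") {
  pat <- simulate_poisson(intensity, window)
  n <- npoints(pat)
  tibble::tibble(
    tree_id = sprintf("%s%05d", id_prefix, seq_len(n)),
    x = pat$points$x, y = pat$points$y,
    dbh = if (n > 0) sample_dbh(dbh_model, n) else numeric(0),
    source = "simulated"
  )
}

#' Draw the four random-effect vectors of the phenology models
#'
#' The tree and season effects on log fruit production (`u`, `v`) and on the
#' peak fruit-fall date (`w`, `z`) are drawn independently from mean-zero
#' normal distributions with the fitted standard deviations.
#'
#' @param n Number of trees.
#' @param s Number of seasons.
#' @param modelI A `model_I_fit` (or any list with `sd_u`, `sd_v`).
#' @param modelII A `model_II_fit` (or any list with `sd_w`, `sd_z`).
#' @return List with vectors `u` (n), `v` (s), `w` (n, days), `z` (s, days).
#' @export
draw_random_effects <- function(n, s, modelI, modelII) {
  list(u = stats::rnorm(n, 0, modelI$sd_u),
       v = stats::rnorm(s, 0, modelI$sd_v),
       w = stats::rnorm(n, 0, modelII$sd_w),
       z = stats::rnorm(s, 0, modelII$sd_z))
}

#' Expected season fruit total for one tree-season
#'
#' \eqn{\lambda_{ij} = \exp(c_1 + c_2\,\mathrm{dbh}_i + u_i + v_j)}; the
#' exponential undoes the log link of the production model. Vectorized over
#' all arguments.
#'
#' @param dbh DBH (mm).
#' @param u_i,v_j Tree and season effects (log scale).
#' @param modelI A `model_I_fit` (or list with `c1`, `c2`).
#' @return Expected fruits per season (trap-count scale).
#' @export
expected_season_total <- function(dbh, u_i, v_j, modelI) {
  exp(modelI$c1 + modelI$c2 * dbh + u_i + v_j)
}

#' Expected fruit-fall intensity at a given day
#'
#' The season total is spread over time as a Gaussian curve centred on the
#' tree-season peak:
#' \deqn{\lambda_{ij}(t) = \lambda_{ij}\,
#'   (\sigma\sqrt{2\pi})^{-1} \exp(-(t - peak_{ij})^2 / 2\sigma^2),}
#' so the daily values sum back to \eqn{\lambda_{ij}}.
#'
#' @param t Day (days since July 1).
#' @param lambda_ij Season total(s).
#' @param peak_ij Peak day(s), \eqn{c_3 + w_i + z_j}.
#' @param sigma_resid Within tree-season SD of fruit-fall dates (days).
#' @return Fruits per day.
#' @export
expected_fruit_intensity <- function(t, lambda_ij, peak_ij, sigma_resid) {
  stopifnot(sigma_resid > 0)
  lambda_ij * stats::dnorm(t, mean = peak_ij, sd = sigma_resid)
}

#' Simulate a multi-season fruit-availability landscape
#'
#' Composes the fitted production model (model I) and fruit-date model
#' (model II) over a simulated (or observed) forest: draws the four
#' random-effect vectors, computes the expected daily fruit-fall intensity
#' of every tree in every season on a regular time grid, and optionally
#' realizes independent Poisson counts per time bin. Seasons run 365 days
#' from July 1; all seasons share the same trees, so between-season
#' variation comes only from the season effects.
#'
#' @param forest Tibble with `tree_id`, `x`, `y`, `dbh` (from
#'   [simulate_forest()] or a census).
#' @param modelI A `model_I_fit` (or list with `c1`, `c2`, `sd_u`, `sd_v`).
#' @param modelII A `model_II_fit` (or list with `c3`, `sd_w`, `sd_z`,
#'   `sigma_resid`).
#' @param s Number of seasons (default 6).
#' @param time_step Time bin width in days (default 1; 7 mimics weekly trap
#'   visits).
#' @param realize Draw Poisson counts per bin (default FALSE).
#' @param effects Optional pre-drawn random effects (see
#'   [draw_random_effects()]); drawn internally when NULL.
#' @return Object of class `fruit_landscape`: list with `table` (long
#'   tibble `tree_id, season, day, expected[, realized]`), `forest`,
#'   `effects`, `s`, `time_step`.
#' @export
simulate_landscape <- function(forest, modelI, modelII, s = 6,
                               time_step = 1, realize = FALSE,
                               effects = NULL) {
  stopifnot(time_step > 0, time_step <= 365, s >= 1)
  n <- nrow(forest)
  if (n == 0) stop("forest is empty", call. = FALSE)
  if (is.null(effects)) effects <- draw_random_effects(n, s, modelI, modelII)
  stopifnot(length(effects$u) == n, length(effects$v) == s,
            length(effects$w) == n, length(effects$z) == s)
  t_mid <- seq(time_step / 2, 365, by = time_step)
  nt <- length(t_mid)
  cells <- tidyr::expand_grid(i = seq_len(n), j = seq_len(s))
  lambda <- expected_season_total(forest$dbh[cells$i], effects$u[cells$i],
                                  effects$v[cells$j], modelI)
  peak <- modelII$c3 + effects$w[cells$i] + effects$z[cells$j]
  tab <- tibble::tibble(
    tree_id = rep(forest$tree_id[cells$i], each = nt),
    season = rep(cells$j, each = nt),
    day = rep(t_mid, times = nrow(cells)),
    expected = expected_fruit_intensity(rep(t_mid, times = nrow(cells)),
                                        rep(lambda, each = nt),
                                        rep(peak, each = nt),
                                        modelII$sigma_resid)
  )
  if (realize) {
    tab$realized <- stats::rpois(nrow(tab), tab$expected * time_step)
  }
  structure(list(table = tab, forest = forest, effects = effects,
                 lambda_ij = tibble::tibble(tree_id = forest$tree_id[cells$i],
                                            season = cells$j,
                                            lambda = lambda, peak = peak),
                 s = s, time_step = time_step),
            class = "fruit_landscape")
}

#' @export
print.fruit_landscape <- function(x, ...) {
  cat(sprintf("<fruit_landscape> %d trees x %d seasons, %g-day bins (%d rows)%s\n",
              nrow(x$forest), x$s, x$time_step, nrow(x$table),
              if ("realized" %in% names(x$table)) ", realized" else ""))
  invisible(x)
}

#' Extract one day of a landscape as a map frame
#'
#' @param landscape A `fruit_landscape`.
#' @param season Season index.
#' @param day Day since July 1; snapped to the nearest time bin.
#' @return Tibble of tree positions with that day's expected (and realized,
#'   if present) fruit fall.
#' @export
landscape_frame <- function(landscape, season, day) {
  tab <- landscape$table[landscape$table$season == season, ]
  bins <- unique(tab$day)
  target <- bins[which.min(abs(bins - day))]
  frame <- tab[tab$day == target, ]
  dplyr::left_join(frame,
                   landscape$forest[, c("tree_id", "x", "y", "dbh")],
                   by = "tree_id")
}

#' Write the long-format landscape table as CSV
#' @param landscape A `fruit_landscape`.
#' @param path Output CSV path.
#' @export
write_landscape <- function(landscape, path) {
  utils::write.csv(as.data.frame(landscape$table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
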