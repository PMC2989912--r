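#' Per tree-season phenology metrics
#'
#' Summarizes trap records into the three descriptive traits of a fruiting
#' season: production (total fruits trapped), peak (count-weighted mean trap
#' day, days since July 1) and duration (four times the count-weighted
#' sample standard deviation of trap days, computed over individual fruits
#' with an n-1 denominator). Peak requires at least one fruit and duration
#' at least two; undefined metrics are `NA`.
#'
#' @param records Tibble with columns `tree_id`, `season_id`, `day`,
#'   `count`.
#' @param complete Complete the crossing of all observed trees and seasons,
#'   so tree-seasons with no trapped fruit appear with production 0 (default
#'   TRUE: monitored trees are observed every season whether or not they
#'   fruit).
#' @return A tibble with one row per tree-season: `tree_id`, `season_id`,
#'   `production`, `peak`, `duration`.
#' @export
compute_season_metrics <- function(records, complete = TRUE) {
  stopifnot(all(c("tree_id", "season_id", "day", "count") %in%
                  names(records)))
  out <- records |>
    dplyr::group_by(.data$tree_id, .data$season_id) |>
    dplyr::summarise(
      production = sum(.data$count),
      peak = {
        n <- sum(.data$count)
        if (n >= 1) sum(.data$day * .data$count) / n else NA_real_
      },
      duration = {
        n <- sum(.data$count)
        if (n >= 2) {
          m <- sum(.data$day * .data$count) / n
          4 * sqrt(sum(.data$count * (.data$day - m)^2) / (n - 1))
        } else NA_real_
      },
      .groups = "drop"
    )
  if (complete) {
    grid <- tidyr::expand_grid(tree_id = unique(out$tree_id),
                               season_id = unique(out$season_id))
    out <- dplyr::left_join(grid, out, by = c("tree_id", "season_id")) |>
      dplyr::mutate(production = dplyr::coalesce(.data$production, 0))
  }
  out
}

.vc_sd <- function(merMod, grp) {
  vc <- lme4::VarCorr(merMod)
  if (!grp %in% names(vc)) return(0)
  unname(attr(vc[[grp]], "stddev"))
}

#' Fit the season fruit-production model (model I)
#'
#' A Poisson log-link generalized linear mixed model of per tree-season
#' fruit totals,
#' \deqn{N_{ij} \sim \mathrm{Poisson}(\exp(c_1 + c_2\,\mathrm{dbh}_i + u_i + v_j)),}
#' with crossed tree (\eqn{u_i \sim N(0, sd_u^2)}) and season
#' (\eqn{v_j \sim N(0, sd_v^2)}) random intercepts, estimated by Laplace
#' approximation.
#'
#' @param totals Tibble with columns `tree_id`, `season_id`, `production`
#'   (non-negative integers).
#' @param dbh Per-tree DBH (mm): a tibble with `tree_id`, `dbh`, or a named
#'   vector keyed by tree id.
#' @return Object of class `model_I_fit` with elements `c1`, `c2`, `sd_u`,
#'   `sd_v`, standard errors, `loglik`, bootstrap p-value slots (`p_u`,
#'   `p_v`, `p_c2`, `NA` until [bootstrap_variance_pvalue()] is run) and the
#'   underlying fitted model.
#' @export
fit_model_I <- function(totals, dbh) {
  stopifnot(all(c("tree_id", "season_id", "production") %in% names(totals)))
  y <- totals$production
  if (any(is.na(y)) || any(y < 0) || any(y != round(y))) {
    stop("production totals must be non-negative integers", call. = FALSE)
  }
  if (all(y == 0)) {
    stop("all totals are zero: the log-link intercept is unbounded below",
         call. = FALSE)
  }
  if (length(unique(totals$tree_id)) < 3 ||
      length(unique(totals$season_id)) < 3) {
    stop("need at least 3 trees and 3 seasons", call. = FALSE)
  }
  if (is.data.frame(dbh)) dbh <- stats::setNames(dbh$dbh, dbh$tree_id)
  d <- tibble::tibble(
    tree_id = factor(totals$tree_id),
    season_id = factor(totals$season_id),
    production = as.integer(round(y)),
    dbh = as.numeric(dbh[as.character(totals$tree_id)])
  )
  if (any(is.na(d$dbh))) {
    stop("dbh missing for tree(s): ",
         paste(unique(d$tree_id[is.na(d$dbh)]), collapse = ", "),
         call. = FALSE)
  }
  # centre and scale DBH for the optimizer; coefficients are reported on the
  # raw mm scale
  mu_d <- mean(d$dbh); sc_d <- max(stats::sd(d$dbh), 1)
  d$dbh_s <- (d$dbh - mu_d) / sc_d
  m <- suppressMessages(lme4::glmer(
    production ~ dbh_s + (1 | tree_id) + (1 | season_id),
    data = d, family = stats::poisson(),
    control = lme4::glmerControl(check.conv.grad =
                                   lme4::.makeCC("warning", tol = 2e-3))))
  fe <- lme4::fixef(m)
  V <- as.matrix(stats::vcov(m))
  # back-transform: c2 = c2'/s, c1 = c1' - c2' m/s
  a <- c(1, -mu_d / sc_d)
  se <- c(sqrt(drop(t(a) %*% V %*% a)), sqrt(V[2, 2]) / sc_d)
  structure(list(
    c1 = unname(fe[1] - fe[2] * mu_d / sc_d), c2 = unname(fe[2] / sc_d),
    sd_u = .vc_sd(m, "tree_id"), sd_v = .vc_sd(m, "season_id"),
    se_c1 = unname(se[1]), se_c2 = unname(se[2]),
    loglik = as.numeric(stats::logLik(m)),
    p_u = NA_real_, p_v = NA_real_, p_c2 = NA_real_,
    merMod = m, data = d,
    n_trees = nlevels(d$tree_id), n_seasons = nlevels(d$season_id)
  ), class = "model_I_fit")
}

#' @export
print.model_I_fit <- function(x, ...) {
  cat(sprintf("<model_I_fit> log E[N] = %.4g + %.4g * dbh + u + v\n",
              x$c1, x$c2))
  cat(sprintf("  sd_u (tree) = %.4g, sd_v (season) = %.4g; %d trees x %d seasons; loglik %.4g\n",
              x$sd_u, x$sd_v, x$n_trees, x$n_seasons, x$loglik))
  invisible(x)
}

#' Fit the fruit-date model (model II)
#'
#' A Gaussian linear mixed model for the day each individual fruit was
#' trapped,
#' \deqn{day = c_3 + w_i + z_j + \varepsilon,}
#' with crossed tree (\eqn{w_i \sim N(0, sd_w^2)}) and season
#' (\eqn{z_j \sim N(0, sd_z^2)}) random intercepts, fit by REML. The
#' residual SD \eqn{\sigma} quantifies the within tree-season spread of
#' fruit-fall dates, i.e. the duration of the fruiting season.
#'
#' @param fruit_dates One row per trapped fruit: tibble with `tree_id`,
#'   `season_id`, `day` (days since July 1). Trap tables with a `count`
#'   column are expanded to one row per fruit automatically.
#' @return Object of class `model_II_fit` with `c3`, `sd_w` (tree), `sd_z`
#'   (season), `sigma_resid`, `se_c3`, `loglik` and the underlying model.
#' @export
fit_model_II <- function(fruit_dates) {
  stopifnot(all(c("tree_id", "season_id", "day") %in% names(fruit_dates)))
  if ("count" %in% names(fruit_dates)) {
    fruit_dates <- fruit_dates[rep(seq_len(nrow(fruit_dates)),
                                   fruit_dates$count), ]
  }
  if (nrow(fruit_dates) < 2) stop("need at least 2 fruits", call. = FALSE)
  d <- tibble::tibble(tree_id = factor(fruit_dates$tree_id),
                      season_id = factor(fruit_dates$season_id),
                      day = as.numeric(fruit_dates$day))
  cells <- unique(paste(d$tree_id, d$season_id))
  if (length(cells) < 2 || nlevels(d$tree_id) < 2 ||
      nlevels(d$season_id) < 2) {
    stop("variance components are unidentifiable: need at least 2 trees, ",
         "2 seasons and 2 tree-season cells", call. = FALSE)
  }
  if (max(table(paste(d$tree_id, d$season_id))) == 1) {
    warning("one fruit per tree-season cell: the residual SD absorbs any ",
            "tree-by-season interaction and is not separately identified",
            call. = FALSE)
  }
  m <- lme4::lmer(day ~ 1 + (1 | tree_id) + (1 | season_id), data = d,
                  REML = TRUE)
  fe <- lme4::fixef(m)
  structure(list(
    c3 = unname(fe["(Intercept)"]),
    sd_w = .vc_sd(m, "tree_id"), sd_z = .vc_sd(m, "season_id"),
    sigma_resid = stats::sigma(m),
    se_c3 = sqrt(as.matrix(stats::vcov(m))[1, 1]),
    loglik = as.numeric(stats::logLik(m)),
    merMod = m, data = d,
    n_trees = nlevels(d$tree_id), n_seasons = nlevels(d$season_id),
    n_fruits = nrow(d)
  ), class = "model_II_fit")
}

#' @export
print.model_II_fit <- function(x, ...) {
  cat(sprintf("<model_II_fit> day = %.5g + w + z + eps (%d fruits)\n",
              x$c3, x$n_fruits))
  cat(sprintf("  sd_w (tree) = %.4g d, sd_z (season) = %.4g d, sigma_resid = %.4g d\n",
              x$sd_w, x$sd_z, x$sigma_resid))
  invisible(x)
}

#' Fit a descriptive crossed-random-effects model for one season metric
#'
#' The peak and duration metrics are modelled as Gaussian crossed
#' random-intercept models (REML) with no fixed covariate; the production
#' metric delegates to the Poisson log-link model ([fit_model_I()]), which
#' includes DBH as a fixed effect.
#'
#' @param metrics Output of [compute_season_metrics()].
#' @param metric `"production"`, `"peak"` or `"duration"`.
#' @param dbh Per-tree DBH, required for `"production"`.
#' @return A `descriptive_fit` (or a `model_I_fit` for production).
#' @export
fit_descriptive_lmm <- function(metrics, metric = c("peak", "duration",
                                                    "production"),
                                dbh = NULL) {
  metric <- match.arg(metric)
  if (metric == "production") {
    if (is.null(dbh)) stop("production model requires per-tree dbh",
                           call. = FALSE)
    return(fit_model_I(metrics, dbh))
  }
  d <- tibble::tibble(tree_id = factor(metrics$tree_id),
                      season_id = factor(metrics$season_id),
                      value = metrics[[metric]])
  d <- d[!is.na(d$value), ]
  if (nrow(d) == 0) stop("metric '", metric, "' is undefined for every ",
                         "tree-season", call. = FALSE)
  if (length(unique(d$tree_id)) < 3 || length(unique(d$season_id)) < 3) {
    stop("need at least 3 trees and 3 seasons with a defined '", metric,
         "'", call. = FALSE)
  }
  d$tree_id <- droplevels(d$tree_id); d$season_id <- droplevels(d$season_id)
  m <- lme4::lmer(value ~ 1 + (1 | tree_id) + (1 | season_id), data = d,
                  REML = TRUE)
  structure(list(
    metric = metric,
    intercept = unname(lme4::fixef(m)["(Intercept)"]),
    sd_tree = .vc_sd(m, "tree_id"), sd_season = .vc_sd(m, "season_id"),
    sd_resid = stats::sigma(m),
    p_tree = NA_real_, p_season = NA_real_,
    loglik = as.numeric(stats::logLik(m)),
    merMod = m, data = d
  ), class = "descriptive_fit")
}

#' @export
print.descriptive_fit <- function(x, ...) {
  cat(sprintf("<descriptive_fit> %s: intercept %.5g, sd_tree %.4g, sd_season %.4g, sd_resid %.4g\n",
              x$metric, x$intercept, x$sd_tree, x$sd_season, x$sd_resid))
  invisible(x)
}

.drop_component <- function(formula, component) {
  f <- deparse1(formula)
  f <- switch(component,
              tree = gsub("\\+?\\s*\\(1 \\| tree_id\\)", "", f),
              season = gsub("\\+?\\s*\\(1 \\| season_id\\)", "", f),
              fixed = gsub("(?<=~)(.*?)dbh\\w* \\+", "\\1", f, perl = TRUE),
              stop("unknown component: ", component, call. = FALSE))
  stats::as.formula(gsub("\\+\\s*\\+", "+", f))
}

#' Parametric-bootstrap p-value for a model component
#'
#' Tests a random-effect variance (whose null value lies on the boundary of
#' the parameter space, where the chi-square approximation fails) or the
#' fixed DBH effect by a parametric bootstrap of the likelihood-ratio
#' statistic: the component is removed, data are repeatedly simulated from
#' the fitted null model, both models are refit to each simulated dataset,
#' and \eqn{p = (1 + \#\{LR^* \ge LR_{obs}\})/(n_{boot} + 1)}. Likelihoods
#' are maximum likelihood (not REML) for both models.
#'
#' @param fit A `model_I_fit`, `model_II_fit` or `descriptive_fit`.
#' @param component `"tree"`, `"season"` or (model I only) `"fixed"` for the
#'   DBH slope.
#' @param n_boot Bootstrap replicates (default 1000).
#' @return Scalar p-value in (0, 1], with attributes `lr_obs` and
#'   `n_failed`.
#' @export
bootstrap_variance_pvalue <- function(fit, component = c("tree", "season",
                                                         "fixed"),
                                      n_boot = 1000) {
  component <- match.arg(component)
  m <- fit$merMod
  if (!inherits(m, "merMod")) stop("fit carries no mixed model", call. = FALSE)
  if (component == "fixed" && !inherits(fit, "model_I_fit")) {
    stop("component 'fixed' applies to the production model only",
         call. = FALSE)
  }
  is_glmm <- lme4::isGLMM(m)
  if (!is_glmm && component %in% c("tree", "season")) {
    return(.bootstrap_lmm_fast(fit, component, n_boot))
  }
  if (!is_glmm && lme4::isREML(m)) {
    m <- lme4::refitML(m)
  }
  f_null <- .drop_component(stats::formula(m), component)
  d <- fit$data
  has_bars <- length(lme4::findbars(f_null)) > 0
  fit_null <- function(data) {
    if (has_bars) {
      if (is_glmm) {
        suppressMessages(suppressWarnings(
          lme4::glmer(f_null, data = data, family = stats::poisson())))
      } else {
        suppressMessages(suppressWarnings(
          lme4::lmer(f_null, data = data, REML = FALSE)))
      }
    } else {
      if (is_glmm) stats::glm(f_null, data = data, family = stats::poisson())
      else stats::glm(f_null, data = data, family = stats::gaussian())
    }
  }
  m0 <- fit_null(d)
  lr_obs <- max(0, 2 * (as.numeric(stats::logLik(m)) -
                          as.numeric(stats::logLik(m0))))
  yname <- all.vars(stats::formula(m))[1]
  lr_star <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    ysim <- stats::simulate(m0)[[1]]
    lr_star[b] <- tryCatch({
      m1b <- suppressMessages(suppressWarnings(lme4::refit(m, ysim)))
      m0b <- if (inherits(m0, "merMod")) {
        suppressMessages(suppressWarnings(lme4::refit(m0, ysim)))
      } else {
        db <- d; db[[yname]] <- ysim
        fit_null(db)
      }
      max(0, 2 * (as.numeric(stats::logLik(m1b)) -
                    as.numeric(stats::logLik(m0b))))
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(lr_star))
  if (n_failed > 0.1 * n_boot) {
    stop(n_failed, " of ", n_boot, " bootstrap refits failed", call. = FALSE)
  }
  ok <- lr_star[!is.na(lr_star)]
  p <- (1 + sum(ok >= lr_obs)) / (length(ok) + 1)
  structure(p, lr_obs = lr_obs, n_failed = n_failed)
}

# Gaussian crossed-intercept bootstrap via the profiled-ML engine in lrt.R.
# Dropping a variance component keeps the model Gaussian and intercept-only,
# so each bootstrap refit is a tiny box-constrained optimization over the
# variance ratios rather than a full mixed-model fit.
.bootstrap_lmm_fast <- function(fit, component, n_boot) {
  d <- fit$data
  yname <- if (inherits(fit, "model_II_fit")) "day" else "value"
  y <- d[[yname]]
  # order factors so the KEPT factor comes first in the null structure
  keep <- if (component == "tree") d$season_id else d$tree_id
  drop <- if (component == "tree") d$tree_id else d$season_id
  st_alt <- .lmm_struct(keep, drop)
  st_null <- .lmm_struct(keep)
  alt <- .lmm_mldev_min(st_alt, y)
  null <- .lmm_mldev_min(st_null, y, start = alt$gamma[1])
  lr_obs <- max(0, null$dev - alt$dev)
  if (lr_obs < 1e-8) {
    # every bootstrap statistic is >= 0 = LR_obs, so p = 1 exactly
    return(structure(1, lr_obs = 0, n_failed = 0L))
  }
  par0 <- .lmm_null_params(st_null, y, null$gamma)
  idx <- as.integer(droplevels(as.factor(keep)))
  q <- st_null$q1; n <- st_null$n
  lr_star <- vapply(seq_len(n_boot), function(b) {
    ysim <- par0$mu + stats::rnorm(q, 0, par0$sds[1])[idx] +
      stats::rnorm(n, 0, par0$sigma)
    a <- .lmm_mldev_min(st_alt, ysim, start = alt$gamma)
    n0 <- .lmm_mldev_min(st_null, ysim, start = null$gamma)
    max(0, n0$dev - a$dev)
  }, numeric(1))
  p <- (1 + sum(lr_star >= lr_obs)) / (n_boot + 1)
  structure(p, lr_obs = lr_obs, n_failed = 0L)
}
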