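#' Fit the logistic model of aerial visibility against stem diameter
#'
#' Canopy-statured trees are more likely to be identified on aerial
#' photographs than small ones. This fits
#' \deqn{\mathrm{logit}\, p(\mathrm{visible}) = \beta_0 + \beta_1\,\mathrm{DBH}}
#' by maximum likelihood and tests \eqn{\beta_1 = 0} with a likelihood-ratio
#' test against \eqn{\chi^2_1}.
#'
#' @param trees Tibble with columns `dbh` (mm) and `visible_aerial`
#'   (logical, no missing values).
#' @return An object of class `detection_model` with elements `beta0`,
#'   `beta1` and `fit_meta` (log-likelihoods, LR statistic, p-value, n).
#' @export
fit_detection_glm <- function(trees) {
  stopifnot(all(c("dbh", "visible_aerial") %in% names(trees)))
  y <- as.logical(trees$visible_aerial)
  dbh <- as.numeric(trees$dbh)
  keep <- !is.na(y) & !is.na(dbh)
  y <- y[keep]; dbh <- dbh[keep]
  if (any(dbh <= 0)) stop("dbh must be positive", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("visibility labels are single-class (all ",
         if (all(y)) "visible" else "hidden",
         "); the logistic model is degenerate", call. = FALSE)
  }
  if (sum(y) < 2 || sum(!y) < 2) {
    stop("need at least 2 records of each visibility class", call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm(y ~ dbh, family = stats::binomial()))
  p_hat <- stats::fitted(fit)
  if (all(p_hat[y] > 1 - 1e-8) && all(p_hat[!y] < 1e-8)) {
    stop("complete separation: visibility is perfectly predicted by dbh; ",
         "consider a penalized (Firth) fit", call. = FALSE)
  }
  null <- stats::glm(y ~ 1, family = stats::binomial())
  lr <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(null)))
  new_detection_model(
    beta0 = unname(stats::coef(fit)[1]),
    beta1 = unname(stats::coef(fit)[2]),
    fit_meta = list(
      loglik = as.numeric(stats::logLik(fit)),
      loglik_null = as.numeric(stats::logLik(null)),
      lr_statistic = lr,
      p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
      se_beta1 = unname(sqrt(diag(stats::vcov(fit)))[2]),
      n = length(y),
      method = "ml"
    )
  )
}

new_detection_model <- function(beta0, beta1, fit_meta = list()) {
  stopifnot(is.finite(beta0), is.finite(beta1))
  structure(list(beta0 = beta0, beta1 = beta1, fit_meta = fit_meta),
            class = "detection_model")
}

#' Aerial detection probability for a given stem diameter
#'
#' @param model A `detection_model`.
#' @param dbh Stem diameter(s), mm, positive.
#' @return Probabilities in (0, 1), same length as `dbh`.
#' @export
detection_probability <- function(model, dbh) {
  stopifnot(inherits(model, "detection_model"))
  if (any(dbh <= 0)) stop("dbh must be positive", call. = FALSE)
  stats::plogis(model$beta0 + model$beta1 * dbh)
}

#' Calibrate the detection intercept to an overall visibility fraction
#'
#' When labelled ground-truth data are unavailable but the overall fraction
#' of visible trees is known (14.7% of stems over 200 mm DBH in the BCI
#' survey), the intercept \eqn{\beta_0} is solved so that the mean detection
#' probability over a reference DBH sample equals that fraction, for a fixed
#' slope \eqn{\beta_1}.
#'
#' @param target_fraction Target mean detection probability, in (0, 1).
#' @param dbh_sample Reference DBH values (mm). Only values above `dbh_min`
#'   enter the average, matching the published fraction's definition.
#' @param beta1 Fixed slope (log-odds per mm).
#' @param dbh_min Lower DBH cut for the averaging set (mm); default 200.
#' @return A `detection_model` with the solved `beta0`.
#' @export
calibrate_detection <- function(target_fraction, dbh_sample, beta1 = 0.003,
                                dbh_min = 200) {
  stopifnot(target_fraction > 0, target_fraction < 1,
            length(dbh_sample) > 0)
  d <- dbh_sample[dbh_sample > dbh_min]
  if (length(d) == 0) {
    stop("no dbh values above dbh_min = ", dbh_min, " mm", call. = FALSE)
  }
  f <- function(b0) mean(stats::plogis(b0 + beta1 * d)) - target_fraction
  if (f(-50) > 0 || f(50) < 0) {
    stop("no calibration root for beta0 in [-50, 50]", call. = FALSE)
  }
  root <- stats::uniroot(f, c(-50, 50), tol = 1e-12)
  b0 <- root$root
  achieved <- mean(stats::plogis(b0 + beta1 * d))
  if (abs(achieved - target_fraction) > 1e-8) {
    stop("calibration failed to reach tolerance 1e-8 on the fraction",
         call. = FALSE)
  }
  new_detection_model(b0, beta1,
                      fit_meta = list(method = "calibrated",
                                      target_fraction = target_fraction,
                                      dbh_min = dbh_min,
                                      n_ref = length(d)))
}

#' Thin a tree table by aerial detection
#'
#' Draws independent Bernoulli visibility for each stem from the detection
#' model and its DBH.
#'
#' @param trees Tibble with a `dbh` column.
#' @param model A `detection_model`.
#' @return `trees` with a `visible_aerial` column filled in.
#' @export
apply_detection <- function(trees, model) {
  p <- detection_probability(model, trees$dbh)
  dplyr::mutate(trees,
                visible_aerial = stats::runif(length(p)) < p)
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf("<detection_model> logit p = %.4g + %.4g * dbh[mm]\n",
              x$beta0, x$beta1))
  if (!is.null(x$fit_meta$p_value)) {
    cat(sprintf("  LR test of slope: chi^2 = %.3g, p = %.3g (n = %d)\n",
                x$fit_meta$lr_statistic, x$fit_meta$p_value, x$fit_meta$n))
  }
  if (identical(x$fit_meta$method, "calibrated")) {
    cat(sprintf("  calibrated to fraction %.3g over %d stems > %g mm\n",
                x$fit_meta$target_fraction, x$fit_meta$n_ref,
                x$fit_meta$dbh_min))
  }
  invisible(x)
}

#' Persist / restore a detection model as JSON
#' @param model A `detection_model`.
#' @param path JSON file path.
#' @export
write_detection_model <- function(model, path) {
  jsonlite::write_json(list(beta0 = model$beta0, beta1 = model$beta1,
                            fit_meta = model$fit_meta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detection_model
#' @export
read_detection_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  new_detection_model(obj$beta0, obj$beta1, as.list(obj$fit_meta))
}
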