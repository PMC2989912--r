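#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted detection model
#' @param x A `detection_model`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient.
#' @method tidy detection_model
#' @export
tidy.detection_model <- function(x, ...) {
  tibble::tibble(term = c("beta0", "beta1"),
                 estimate = c(x$beta0, x$beta1))
}

#' @rdname tidy.detection_model
#' @method glance detection_model
#' @export
glance.detection_model <- function(x, ...) {
  m <- x$fit_meta
  tibble::tibble(logLik = m$loglik %||% NA_real_,
                 lr_statistic = m$lr_statistic %||% NA_real_,
                 p_value = m$p_value %||% NA_real_,
                 nobs = m$n %||% NA_integer_,
                 method = m$method %||% NA_character_)
}

#' Tidy a fitted Poisson point-process model
#' @param x A `poisson_fit`.
#' @param ... Unused.
#' @method tidy poisson_fit
#' @export
tidy.poisson_fit <- function(x, ...) {
  if (x$kind == "homogeneous") {
    tibble::tibble(term = "lambda", estimate = x$lambda_hat,
                   std.error = NA_real_)
  } else {
    tibble::tibble(term = c("alpha", "beta"),
                   estimate = c(x$alpha, x$beta),
                   std.error = if (is.null(x$se)) c(NA_real_, NA_real_)
                   else x$se)
  }
}

#' @rdname tidy.poisson_fit
#' @method glance poisson_fit
#' @export
glance.poisson_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, nobs = x$n, logLik = x$loglik,
                 expected_count = x$expected_count %||% NA_real_)
}

#' Tidy the fruit-production model (model I)
#'
#' One row per parameter: the fixed intercept and DBH slope (with standard
#' errors) and the tree/season random-effect SDs (with bootstrap p-values
#' when computed).
#'
#' @param x A `model_I_fit`.
#' @param ... Unused.
#' @method tidy model_I_fit
#' @export
tidy.model_I_fit <- function(x, ...) {
  tibble::tibble(
    term = c("c1", "c2", "sd_u", "sd_v"),
    type = c("fixed", "fixed", "ran_sd", "ran_sd"),
    estimate = c(x$c1, x$c2, x$sd_u, x$sd_v),
    std.error = c(x$se_c1, x$se_c2, NA_real_, NA_real_),
    p.value = c(NA_real_, x$p_c2, x$p_u, x$p_v)
  )
}

#' @rdname tidy.model_I_fit
#' @method glance model_I_fit
#' @export
glance.model_I_fit <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, n_seasons = x$n_seasons,
                 nobs = nrow(x$data), logLik = x$loglik)
}

#' Tidy the fruit-date model (model II)
#' @param x A `model_II_fit`.
#' @param ... Unused.
#' @method tidy model_II_fit
#' @export
tidy.model_II_fit <- function(x, ...) {
  tibble::tibble(
    term = c("c3", "sd_w", "sd_z", "sigma_resid"),
    type = c("fixed", "ran_sd", "ran_sd", "resid_sd"),
    estimate = c(x$c3, x$sd_w, x$sd_z, x$sigma_resid),
    std.error = c(x$se_c3, NA_real_, NA_real_, NA_real_)
  )
}

#' @rdname tidy.model_II_fit
#' @method glance model_II_fit
#' @export
glance.model_II_fit <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, n_seasons = x$n_seasons,
                 n_fruits = x$n_fruits, logLik = x$loglik)
}

#' Tidy a descriptive season-metric model
#' @param x A `descriptive_fit`.
#' @param ... Unused.
#' @method tidy descriptive_fit
#' @export
tidy.descriptive_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "sd_tree", "sd_season", "sd_resid"),
    estimate = c(x$intercept, x$sd_tree, x$sd_season, x$sd_resid),
    p.value = c(NA_real_, x$p_tree, x$p_season, NA_real_)
  )
}

#' @rdname tidy.descriptive_fit
#' @method glance descriptive_fit
#' @export
glance.descriptive_fit <- function(x, ...) {
  tibble::tibble(metric = x$metric, nobs = nrow(x$data), logLik = x$loglik)
}

#' Persist a phenology fit as JSON
#' @param fit A `model_I_fit`, `model_II_fit` or `descriptive_fit`.
#' @param path JSON path.
#' @export
write_fit_json <- function(fit, path) {
  keep <- setdiff(names(fit), c("merMod", "data"))
  obj <- fit[keep]
  obj$class <- class(fit)[1]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
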