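#' Fit a stem-diameter distribution by rank-transformation to normality
#'
#' Stores the empirical quantile map between observed DBH values and
#' standard-normal scores \eqn{\Phi^{-1}((r - 0.5)/n)} (midranks for ties),
#' so that simulated trees can be assigned diameters matching the observed
#' distribution without assuming a parametric form.
#'
#' @param dbhs Reference DBH values (mm), at least 10, all positive.
#' @return Object of class `dbh_distribution` with the sorted reference
#'   values, their normal scores, and `n_ref`.
#' @export
fit_dbh_distribution <- function(dbhs) {
  dbhs <- as.numeric(dbhs)
  dbhs <- dbhs[!is.na(dbhs)]
  if (length(dbhs) < 10) {
    stop("need at least 10 reference DBH values (quantile map unstable)",
         call. = FALSE)
  }
  if (any(dbhs <= 0)) stop("DBH values must be positive", call. = FALSE)
  r <- rank(dbhs, ties.method = "average")
  n <- length(dbhs)
  score <- stats::qnorm((r - 0.5) / n)
  ord <- order(dbhs)
  # collapse ties so the (score, dbh) map is strictly monotone in score
  d_sorted <- dbhs[ord]; s_sorted <- score[ord]
  keep <- !duplicated(d_sorted)
  structure(list(dbh = d_sorted[keep], score = s_sorted[keep],
                 n_ref = n, min_ref = min(dbhs), max_ref = max(dbhs)),
            class = "dbh_distribution")
}

#' Sample stem diameters from a fitted distribution
#'
#' Draws standard-normal deviates and inverts the stored quantile map by
#' monotone linear interpolation in (score, dbh) space. Deviates beyond the
#' reference scores extrapolate linearly along the boundary slope, clamped
#' to 10% beyond the reference range.
#'
#' @param model A `dbh_distribution`.
#' @param n Number of draws (>= 1).
#' @return Numeric vector of DBH values (mm).
#' @export
sample_dbh <- function(model, n) {
  stopifnot(inherits(model, "dbh_distribution"), n >= 1)
  z <- stats::rnorm(n)
  dbh_from_scores(model, z)
}

#' Map normal scores to DBH values (the deterministic back-transform)
#' @param model A `dbh_distribution`.
#' @param z Standard-normal scores.
#' @return DBH values (mm).
#' @export
dbh_from_scores <- function(model, z) {
  s <- model$score; d <- model$dbh
  if (length(d) == 1) return(rep(d, length(z)))  # degenerate reference
  out <- stats::approx(s, d, xout = z, rule = 2)$y
  # linear tail extrapolation beyond the reference scores
  k <- length(s)
  slope_lo <- (d[2] - d[1]) / (s[2] - s[1])
  slope_hi <- (d[k] - d[k - 1]) / (s[k] - s[k - 1])
  lo <- z < s[1]; hi <- z > s[k]
  out[lo] <- d[1] + slope_lo * (z[lo] - s[1])
  out[hi] <- d[k] + slope_hi * (z[hi] - s[k])
  pmin(pmax(out, model$min_ref * 0.9), model$max_ref * 1.1)
}

#' @export
print.dbh_distribution <- function(x, ...) {
  cat(sprintf("<dbh_distribution> %d reference stems, DBH range [%.4g, %.4g] mm\n",
              x$n_ref, x$min_ref, x$max_ref))
  invisible(x)
}

#' Persist / restore a DBH distribution as a CSV of (dbh, score) pairs
#' @param model A `dbh_distribution`.
#' @param path CSV path.
#' @export
write_dbh_distribution <- function(model, path) {
  utils::write.csv(data.frame(dbh = model$dbh, score = model$score),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dbh_distribution
#' @export
read_dbh_distribution <- function(path) {
  df <- utils::read.csv(path)
  structure(list(dbh = df$dbh, score = df$score,
                 n_ref = nrow(df), min_ref = min(df$dbh),
                 max_ref = max(df$dbh)),
            class = "dbh_distribution")
}
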