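#' Read a tree census table
#'
#' Expects a delimited text file with header columns `id,x,y,dbh` and an
#' optional `visible` column (0/1 or TRUE/FALSE) recording whether the stem
#' was identified on the aerial survey. Positions are projected metres and
#' DBH is in millimetres.
#'
#' @param path Path to the CSV file.
#' @param window Optional `spatial_window`; when given, every positioned
#'   record must fall inside it.
#' @param source Tag recorded on each row (e.g. `"plot50"`, `"aerial"`,
#'   `"simulated"`).
#' @return A tibble with columns `tree_id`, `x`, `y`, `dbh`,
#'   `visible_aerial` (logical, `NA` when the file has no `visible` column)
#'   and `source`.
#' @export
read_tree_table <- function(path, window = NULL, source = "unknown") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "x", "y", "dbh")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("tree table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    tree_id = as.character(df$id),
    x = as.numeric(df$x),
    y = as.numeric(df$y),
    dbh = as.numeric(df$dbh),
    visible_aerial = if ("visible" %in% names(df)) {
      as.logical(as.numeric(df$visible) > 0 | df$visible %in% c("TRUE", "true"))
    } else NA,
    source = source
  )
  # data rows start at line 2 (header is line 1)
  line_no <- seq_len(nrow(out)) + 1L
  bad_dbh <- which(!is.na(out$dbh) & out$dbh <= 0)
  if (length(bad_dbh) > 0) {
    stop("tree table ", path, ": dbh must be > 0 mm; offending line(s): ",
         paste(line_no[bad_dbh], collapse = ", "), call. = FALSE)
  }
  bad_xy <- which(is.na(out$x) != is.na(out$y))
  if (length(bad_xy) > 0) {
    stop("tree table ", path, ": x and y must be both present or both absent; ",
         "offending line(s): ", paste(line_no[bad_xy], collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(window)) {
    has_pos <- !is.na(out$x)
    inside <- rep(TRUE, nrow(out))
    inside[has_pos] <- points_in_window(window, out$x[has_pos], out$y[has_pos])
    if (any(!inside)) {
      stop("tree table ", path, ": point(s) outside the window; line(s): ",
           paste(line_no[!inside], collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Write a tree census table
#' @param trees Tibble as returned by [read_tree_table()].
#' @param path Output CSV path.
#' @export
write_tree_table <- function(trees, path) {
  df <- data.frame(id = trees$tree_id, x = trees$x, y = trees$y,
                   dbh = trees$dbh)
  if (!all(is.na(trees$visible_aerial))) {
    df$visible <- as.integer(trees$visible_aerial)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fruit-trap phenology records
#'
#' Expects header `tree_id,season_id,day,count` where `day` is days since the
#' July 1 that opened the season (0--365) and `count` the number of fruits
#' found at that visit.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `tree_id`, `season_id`, `day`, `count`.
#' @export
read_phenology_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("tree_id", "season_id", "day", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("phenology table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    tree_id = as.character(df$tree_id),
    season_id = as.character(df$season_id),
    day = as.numeric(df$day),
    count = as.integer(df$count)
  )
  line_no <- seq_len(nrow(out)) + 1L
  bad_day <- which(is.na(out$day) | out$day < 0 | out$day > 365)
  if (length(bad_day) > 0) {
    stop("phenology table ", path, ": day must lie in [0, 365] ",
         "(days since July 1); offending line(s): ",
         paste(line_no[bad_day], collapse = ", "), call. = FALSE)
  }
  bad_count <- which(is.na(out$count) | out$count < 0)
  if (length(bad_count) > 0) {
    stop("phenology table ", path, ": count must be a non-negative integer; ",
         "offending line(s): ", paste(line_no[bad_count], collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Write fruit-trap phenology records
#' @param records Tibble as returned by [read_phenology_table()].
#' @param path Output CSV path.
#' @export
write_phenology_table <- function(records, path) {
  utils::write.csv(as.data.frame(records[, c("tree_id", "season_id", "day",
                                             "count")]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default fitted parameter set for the Barro Colorado Island study system
#'
#' The published parameter values for *Dipteryx oleifera* on BCI: the Poisson
#' fruit-production model (intercept `c1`, DBH slope `c2` per mm, tree and
#' season random-effect SDs `sd_u`, `sd_v`), the fruit-date model (intercept
#' `c3` and tree/season/residual SDs `sd_w`, `sd_z`, `sigma_resid`, days),
#' the kernel bandwidth `sigma_kernel` (m) and the overall aerial visibility
#' fraction `detect_fraction` for stems over 200 mm DBH.
#'
#' @return Named list of parameter values.
#' @export
bci_defaults <- function() {
  list(
    c1 = -0.12,
    c2 = 1.50e-3,
    sd_u = 0.49,
    sd_v = 0.87,
    c3 = 209.3,
    sd_w = 13.31,
    sd_z = 8.51,
    sigma_resid = 19.62,
    sigma_kernel = 172,
    detect_fraction = 0.147
  )
}

#' Build a run configuration
#'
#' Collects the knobs shared across the pipeline: RNG seed, analysis grid
#' resolution, the bandwidth grid for kernel optimization, simulation-envelope
#' and bootstrap replicate counts, and the model parameter defaults (the BCI
#' published values unless overridden).
#'
#' @param rng_seed Integer seed.
#' @param grid_cell Analysis grid cell size (m).
#' @param sigma_grid Candidate kernel bandwidths (m).
#' @param n_envelope_sims Simulations per goodness-of-fit envelope.
#' @param n_bootstrap Parametric bootstrap replicates for variance tests.
#' @param ... Overrides for entries of [bci_defaults()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(rng_seed = 1L, grid_cell = 50,
                       sigma_grid = c(50, 100, 172, 250, 400),
                       n_envelope_sims = 100L, n_bootstrap = 1000L, ...) {
  params <- bci_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params[names(dots)] <- dots
  for (nm in c("sd_u", "sd_v", "sd_w", "sd_z", "sigma_resid", "sigma_kernel")) {
    if (params[[nm]] < 0) {
      stop("configuration field ", nm, " must be non-negative", call. = FALSE)
    }
  }
  if (params$detect_fraction <= 0 || params$detect_fraction >= 1) {
    stop("detect_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(rng_seed = as.integer(rng_seed), grid_cell = grid_cell,
                 sigma_grid = sigma_grid,
                 n_envelope_sims = as.integer(n_envelope_sims),
                 n_bootstrap = as.integer(n_bootstrap),
                 params = params),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Absent fields take the defaults of [run_config()], so an empty file yields
#' the BCI parameter set with seed 1. Model parameters may be given at top
#' level or under a `params:` block.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return An object of class `run_config`.
#' @export
load_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  if (!is.null(cfg$params)) {
    cfg <- c(cfg[setdiff(names(cfg), "params")], cfg$params)
  }
  top <- c("rng_seed", "grid_cell", "sigma_grid", "n_envelope_sims",
           "n_bootstrap")
  args <- cfg[intersect(names(cfg), c(top, names(bci_defaults())))]
  ignored <- setdiff(names(cfg), names(args))
  if (length(ignored) > 0) {
    warning("ignoring unknown configuration field(s): ",
            paste(ignored, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, args)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  seed:", x$rng_seed, " grid_cell:", x$grid_cell, "m\n")
  cat("  sigma_grid:", paste(x$sigma_grid, collapse = ", "), "m\n")
  cat("  n_envelope_sims:", x$n_envelope_sims,
      " n_bootstrap:", x$n_bootstrap, "\n")
  cat("  params:",
      paste(sprintf("%s=%.4g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  invisible(x)
}
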