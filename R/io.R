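#' Read a spike map from CSV
#'
#' Expects a header with columns `x`, `y` (meters) and optionally `t`
#' (seconds, nondecreasing). The arena is taken from the argument or, if
#' absent, inferred as the tight bounding box of the spikes expanded by 1%
#' per side.
#'
#' @param path Path to the CSV file.
#' @param arena Optional arena `c(x_min, x_max, y_min, y_max)`.
#' @return A [spike_map()].
#' @export
read_spike_map <- function(path, arena = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop(sprintf("'%s': required columns x,y missing (found: %s)",
                 path, paste(names(df), collapse = ",")))
  for (col in intersect(c("x", "y", "t"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("'%s': non-numeric value in column '%s' at data line %d",
                   path, col, bad[1L]))
    if (anyNA(v))
      stop(sprintf("'%s': missing value in column '%s' at data line %d",
                   path, col, which(is.na(v))[1L]))
    df[[col]] <- v
  }
  spike_map(df$x, df$y, times = if ("t" %in% names(df)) df$t else NULL,
            arena = arena)
}

#' Write a spike map to CSV
#'
#' Columns `x`, `y` and, when present, `t`. Full double precision is kept
#' so that write-then-read round-trips reproduce the map.
#'
#' @param map A [spike_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_map <- function(map, path) {
  stopifnot(inherits(map, "spike_map"))
  df <- data.frame(x = map$positions[, 1L], y = map$positions[, 2L])
  if (!is.null(map$times)) df$t <- map$times
  write_csv_full(df, path)
  invisible(path)
}

# write.csv with full double precision and "" for NA
write_csv_full <- function(df, path) {
  for (col in names(df))
    if (is.double(df[[col]])) {
      v <- vapply(df[[col]], function(x) sprintf("%.17g", x), character(1))
      v[is.na(df[[col]])] <- NA_character_
      df[[col]] <- v
    }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
}

#' Write per-spike scores to CSV
#'
#' One row per spike with columns `x`, `y`, `t` (empty when the map has no
#' times), `psi_hat`, `theta_deg` (empty where undefined), `n_neighbors`
#' and the order-parameter moduli `psi2` ... `psi7` (or whichever orders
#' were computed).
#'
#' @param scores A `spike_scores` object.
#' @param map The [spike_map()] the scores belong to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, map, path) {
  stopifnot(inherits(scores, "spike_scores"), inherits(map, "spike_map"))
  n <- length(scores$psi_hat)
  if (n != nrow(map$positions)) stop("`scores` and `map` are not aligned")
  df <- data.frame(x = map$positions[, 1L], y = map$positions[, 2L],
                   t = if (is.null(map$times)) rep(NA_real_, n)
                       else map$times,
                   psi_hat = scores$psi_hat,
                   theta_deg = scores$theta_deg,
                   n_neighbors = scores$n_neighbors)
  if (!is.null(scores$psi))
    for (m in scores$M_set)
      df[[paste0("psi", m)]] <- Mod(scores$psi[, as.character(m)])
  write_csv_full(df, path)
  invisible(path)
}

#' Dump diagnostics to CSV
#'
#' `write_histogram()` writes a [distance_histogram()] as
#' `bin_center,count,smoothed` rows; `write_grid_csv()` writes the dense
#' value grid of a [rate_map()] or [autocorrelogram()] (rows indexed by
#' x-bin, columns by y-bin, `NA` for masked lags). Both exist for
#' inspection of the automatic shell/annulus decisions.
#'
#' @param hist A `dist_histogram`.
#' @param x A `rate_map` or `correlogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "dist_histogram"))
  write_csv_full(data.frame(bin_center = hist$bin_centers,
                            count = hist$counts,
                            smoothed = hist$smoothed), path)
  invisible(path)
}

#' @rdname write_histogram
#' @export
write_grid_csv <- function(x, path) {
  stopifnot(inherits(x, "rate_map") || inherits(x, "correlogram"))
  utils::write.table(x$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their package defaults:
#' shell detection (`shell_mode`, `cutoff_fraction`, `manual_ell`,
#' `bin_fraction`), symmetry (`M_target`, `M_set`), rate-map/correlogram
#' parameters (`bin_size`, `sigma`, `min_overlap`, `center_threshold`,
#' `inner_factor`, `outer_factor`), classification (`n_shuffles`, `percentile`), temporal
#' smoothing (`window`) and `seed`.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    shell_mode = "second_peak", cutoff_fraction = 0.15, manual_ell = NULL,
    bin_fraction = 0.005, M_target = 6L, M_set = 2:7,
    bin_size = NULL, sigma = NULL, min_overlap = 20L,
    center_threshold = 0.1, inner_factor = 0.5, outer_factor = 1.15,
    n_shuffles = 100L, percentile = 95, window = 100, seed = NULL),
    class = "run_config")
}

#' Read or write a run configuration
#'
#' Configurations are stored as JSON or YAML (by file extension); loading
#' merges the file over the defaults, so partial files are fine, and
#' `save_config()` then `read_config()` restores an identical
#' configuration.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_config()`: a `run_config` list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else stop("config must be .json, .yaml or .yml")
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  if (!is.null(cfg$M_set)) cfg$M_set <- as.integer(cfg$M_set)
  for (k in c("M_target", "min_overlap", "n_shuffles"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.integer(cfg[[k]])
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_config
#' @param cfg A `run_config` list.
#' @return `save_config()`: `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  if (ext == "json") {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), path)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else stop("config must be .json, .yaml or .yml")
  invisible(path)
}
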