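#' Histogram of pairwise spike distances
#'
#' For periodic firing patterns the histogram of all pairwise distances has
#' pronounced peaks: the first reflects the grid field size, the second the
#' grid spacing, and further peaks its multiples. The histogram is smoothed
#' with a Gaussian kernel whose standard deviation is 1% of the maximal
#' pairwise distance, which suppresses the noise arising from finite spike
#' counts.
#'
#' @param map A [spike_map()] with at least two distinct positions.
#' @param bin_fraction Bin width as a fraction of the maximal pairwise
#'   distance (default 0.005, so the smoothing kernel spans two bins).
#' @param smooth_fraction Kernel standard deviation as a fraction of the
#'   maximal pairwise distance (default 0.01).
#' @return An object of class `dist_histogram`: list with `bin_centers`,
#'   `counts`, `smoothed`, `bin_width`, `d_max`.
#' @export
distance_histogram <- function(map, bin_fraction = 0.005,
                               smooth_fraction = 0.01) {
  stopifnot(inherits(map, "spike_map"))
  if (nrow(map$positions) < 2L)
    stop(degenerate_error("need at least two spikes for a distance histogram"))
  d_max <- .pair_dist_counts(map$positions, 0, 0L)$d_max
  if (d_max <= 0)
    stop(degenerate_error(
      "all spikes are coincident; distance histogram is degenerate"))
  bw <- bin_fraction * d_max
  nb <- as.integer(ceiling(d_max / bw - 1e-9))
  # bins cover (0, nb * bw]; zero distances (duplicate spikes) are dropped
  counts <- .pair_dist_counts(map$positions, bw, nb)$counts
  sm <- gauss_smooth_1d(counts, sigma_bins = smooth_fraction * d_max / bw)
  structure(list(bin_centers = (seq_len(nb) - 0.5) * bw,
                 counts = counts, smoothed = sm,
                 bin_width = bw, d_max = d_max),
            class = "dist_histogram")
}

# Gaussian smoothing by direct convolution, zero padding at the edges.
gauss_smooth_1d <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(as.numeric(x))
  r <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(-r:r, sd = sigma_bins)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(numeric(r), x, numeric(r))
  out <- stats::filter(xp, k, method = "convolution", sides = 2L)
  as.numeric(out[(r + 1L):(r + n)])
}

#' @export
print.dist_histogram <- function(x, ...) {
  cat(sprintf("Pairwise-distance histogram: %d bins of %.4g m, d_max = %.4g m\n",
              length(x$counts), x$bin_width, x$d_max))
  invisible(x)
}

# Indices of strict local maxima of a numeric vector; for plateaus the
# leftmost bin is reported. End bins never qualify.
find_local_maxima <- function(y) {
  r <- rle(as.numeric(y))
  k <- length(r$values)
  if (k < 3L) return(integer())
  starts <- cumsum(r$lengths) - r$lengths + 1L
  i <- 2:(k - 1L)
  sel <- r$values[i] > r$values[i - 1L] & r$values[i] > r$values[i + 1L]
  starts[i][sel]
}

spacing_error <- function(msg, hist) {
  structure(class = c("gridspike_spacing_error", "error", "condition"),
            list(message = msg, call = sys.call(-1L), histogram = hist))
}

degenerate_error <- function(msg) {
  structure(class = c("gridspike_degenerate_error", "error", "condition"),
            list(message = msg, call = sys.call(-1L)))
}

#' Detect the grid spacing from a distance histogram
#'
#' In `second_peak` mode (the default) the spacing is the location of the
#' second local maximum of the smoothed histogram: the first peak is the
#' field size, the second the grid spacing. When the first peak is hard to
#' detect (noisy patterns), `cutoff` mode instead takes the first local
#' maximum beyond a cutoff distance chosen between the field size and the
#' spacing; 15% of the arena side length works reliably. `manual` mode
#' passes a user-supplied spacing through, for data where automatic
#' detection fails altogether.
#'
#' @param hist A [distance_histogram()].
#' @param mode One of `"second_peak"`, `"cutoff"`, `"manual"`.
#' @param cutoff_fraction Cutoff as a fraction of `arena_side`
#'   (default 0.15).
#' @param arena_side Arena side length in meters (required for `cutoff`).
#' @param manual_ell Spacing in meters (required for `manual`).
#' @return The grid spacing in meters. On failure a condition of class
#'   `gridspike_spacing_error` is signalled, carrying the histogram for
#'   diagnostics; the scoring pipeline converts this into all-zero scores
#'   with a failure flag.
#' @export
detect_spacing <- function(hist, mode = c("second_peak", "cutoff", "manual"),
                           cutoff_fraction = 0.15, arena_side = NULL,
                           manual_ell = NULL) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(manual_ell) || !is.finite(manual_ell) || manual_ell <= 0)
      stop("`manual` mode requires a positive `manual_ell`")
    return(as.numeric(manual_ell))
  }
  stopifnot(inherits(hist, "dist_histogram"))
  peaks <- find_local_maxima(hist$smoothed)
  if (mode == "second_peak") {
    if (length(peaks) < 2L)
      stop(spacing_error(
        "spacing detection failed: fewer than two local maxima", hist))
    return(hist$bin_centers[peaks[2L]])
  }
  # cutoff mode
  if (is.null(arena_side) || !is.finite(arena_side) || arena_side <= 0)
    stop("`cutoff` mode requires a positive `arena_side`")
  cut <- cutoff_fraction * arena_side
  above <- peaks[hist$bin_centers[peaks] > cut]
  if (length(above) < 1L)
    stop(spacing_error(
      "spacing detection failed: no local maximum beyond the cutoff", hist))
  hist$bin_centers[above[1L]]
}

#' Neighborhood shell for a given symmetry
#'
#' For hexagonal symmetry (M = 6) the shell spans 5/6 to 7/6 of the grid
#' spacing. For quadratic symmetry (M = 4) the shell is centered at
#' (2/3) ell so that only the four nearest fields are included; for
#' band-like symmetry (M = 2) at ell / 2, so the next band stays outside.
#' The relative half-width ell/6 of the hexagonal shell is reused for the
#' other symmetries.
#'
#' @param ell Grid spacing in meters.
#' @param M Symmetry order: 2, 4 or 6.
#' @return A [shell()].
#' @export
shell_for_symmetry <- function(ell, M = 6L) {
  if (!is.finite(ell) || ell <= 0) stop("`ell` must be positive")
  center <- switch(as.character(M),
                   "6" = ell,
                   "4" = 2 / 3 * ell,
                   "2" = ell / 2,
                   stop("shell radii are defined for M in {2, 4, 6}"))
  shell(ell, r_inner = center - ell / 6, r_outer = center + ell / 6)
}

#' Pool the grid spacing across cells of a module
#'
#' Anatomically nearby grid cells share their spacing, so the shell for a
#' noisy cell can be borrowed from cleaner cells of the same module. The
#' pooled estimate is the median of the spacings detected in the maps where
#' detection succeeds; failing maps are skipped (with a message).
#'
#' @param maps List of [spike_map()] objects.
#' @param ... Passed to [detect_spacing()] (e.g. `mode`, `arena_side`).
#' @param bin_fraction Passed to [distance_histogram()].
#' @return Pooled spacing in meters. Signals a `gridspike_spacing_error`
#'   if detection fails on every map.
#' @export
spacing_from_module <- function(maps, ..., bin_fraction = 0.005) {
  if (!is.list(maps) || length(maps) < 1L)
    stop("`maps` must be a nonempty list of spike maps")
  ells <- rep(NA_real_, length(maps))
  for (i in seq_along(maps)) {
    ells[i] <- tryCatch(
      detect_spacing(distance_histogram(maps[[i]],
                                        bin_fraction = bin_fraction), ...),
      gridspike_spacing_error = function(e) {
        message(sprintf("map %d skipped: %s", i, conditionMessage(e)))
        NA_real_
      })
  }
  if (!any(is.finite(ells)))
    stop(spacing_error("spacing detection failed on every map of the module",
                       NULL))
  stats::median(ells[is.finite(ells)])
}
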