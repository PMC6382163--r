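#' Construct a spike map
#'
#' A spike map is the basic data object of the package: the set of 2-D
#' locations (in meters) at which a cell fired, optionally with spike times
#' (in seconds), inside an axis-aligned rectangular arena.
#'
#' @param x,y Numeric vectors of spike coordinates in meters. Alternatively
#'   `x` may be a two-column matrix or data frame of coordinates, in which
#'   case `y` must be missing.
#' @param times Optional numeric vector of spike times in seconds, same
#'   length as the positions and nondecreasing.
#' @param arena Numeric vector `c(x_min, x_max, y_min, y_max)` in meters.
#'   If `NULL`, the tight bounding box of the spikes expanded by 1% on each
#'   side is used.
#' @return An object of class `spike_map`: a list with elements `positions`
#'   (n x 2 matrix), `times` (numeric or `NULL`) and `arena`.
#' @examples
#' m <- spike_map(runif(50), runif(50), arena = c(0, 1, 0, 1))
#' n_spikes(m)
#' @export
spike_map <- function(x, y, times = NULL, arena = NULL) {
  if (missing(y)) {
    x <- as.matrix(x)
    if (ncol(x) != 2L)
      stop("when `y` is missing, `x` must be a two-column matrix")
    pos <- cbind(as.numeric(x[, 1L]), as.numeric(x[, 2L]))
  } else {
    if (length(x) != length(y))
      stop("`x` and `y` must have the same length")
    pos <- cbind(as.numeric(x), as.numeric(y))
  }
  if (nrow(pos) < 1L) stop("a spike map needs at least one spike")
  if (anyNA(pos)) stop("spike positions contain missing values")
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != nrow(pos))
      stop("`times` must have one entry per spike")
    if (anyNA(times)) stop("spike times contain missing values")
    if (is.unsorted(times)) stop("spike times must be nondecreasing")
  }
  if (is.null(arena)) {
    arena <- infer_arena(pos)
  } else {
    arena <- validate_arena(arena)
    tol <- 1e-9
    out <- pos[, 1L] < arena[1L] - tol | pos[, 1L] > arena[2L] + tol |
      pos[, 2L] < arena[3L] - tol | pos[, 2L] > arena[4L] + tol
    if (any(out))
      stop(sprintf("%d spike(s) outside the arena (first at row %d)",
                   sum(out), which(out)[1L]))
  }
  colnames(pos) <- c("x", "y")
  structure(list(positions = pos, times = times, arena = arena),
            class = "spike_map")
}

validate_arena <- function(arena) {
  arena <- as.numeric(arena)
  if (length(arena) != 4L || anyNA(arena))
    stop("`arena` must be c(x_min, x_max, y_min, y_max)")
  if (arena[2L] <= arena[1L] || arena[4L] <= arena[3L])
    stop("arena must have positive width and height")
  arena
}

infer_arena <- function(pos) {
  rx <- range(pos[, 1L]); ry <- range(pos[, 2L])
  wx <- max(diff(rx), 1e-6); wy <- max(diff(ry), 1e-6)
  c(rx[1L] - 0.01 * wx, rx[2L] + 0.01 * wx,
    ry[1L] - 0.01 * wy, ry[2L] + 0.01 * wy)
}

#' Number of spikes in a spike map
#' @param map A [spike_map()].
#' @return Integer spike count.
#' @export
n_spikes <- function(map) {
  stopifnot(inherits(map, "spike_map"))
  nrow(map$positions)
}

#' @export
print.spike_map <- function(x, ...) {
  a <- x$arena
  cat(sprintf("Spike map: %d spikes%s\n", nrow(x$positions),
              if (is.null(x$times)) "" else " (with times)"))
  cat(sprintf("  arena: [%.3g, %.3g] x [%.3g, %.3g] m\n",
              a[1L], a[2L], a[3L], a[4L]))
  invisible(x)
}

arena_side <- function(arena) max(arena[2L] - arena[1L], arena[4L] - arena[3L])

#' Neighborhood shell (annulus)
#'
#' The neighborhood of a spike is the set of spikes whose distance from it
#' falls inside an annulus. For hexagonal symmetry the annulus spans
#' 5/6 to 7/6 of the grid spacing, so that spikes of the six adjacent grid
#' fields -- not spikes of the same field -- count as neighbors.
#'
#' @param ell Grid spacing in meters.
#' @param r_inner,r_outer Inner and outer radii in meters. Defaults are the
#'   hexagonal choice `(5/6) * ell` and `(7/6) * ell`.
#' @return An object of class `shell`.
#' @seealso [shell_for_symmetry()] for the radii adapted to 4-fold and
#'   2-fold symmetry.
#' @export
shell <- function(ell, r_inner = 5 / 6 * ell, r_outer = 7 / 6 * ell) {
  if (!is.numeric(ell) || length(ell) != 1L || !is.finite(ell) || ell <= 0)
    stop("`ell` must be a positive number")
  if (!(r_inner > 0 && r_inner < r_outer))
    stop("shell requires 0 < r_inner < r_outer")
  structure(list(ell = ell, r_inner = r_inner, r_outer = r_outer),
            class = "shell")
}

#' @export
print.shell <- function(x, ...) {
  cat(sprintf("Neighborhood shell: ell = %.4g m, radii [%.4g, %.4g] m\n",
              x$ell, x$r_inner, x$r_outer))
  invisible(x)
}
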