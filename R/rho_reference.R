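#' Smoothed spike-density map
#'
#' Bins spike locations over the arena and smooths the counts with an
#' isotropic Gaussian kernel. No trajectory data is modeled, so the map is
#' a spike density, not an occupancy-normalized firing rate; for the
#' synthetic and comparison purposes of this package the two coincide up
#' to a constant under uniform coverage.
#'
#' @param map A [spike_map()].
#' @param bin_size Bin side in meters; default 1/50 of the longer arena
#'   side (2 cm for a 1 m arena).
#' @param sigma Smoothing kernel standard deviation in meters; default
#'   half the bin size (1 cm for a 1 m arena). See the methods
#'   vignette for how this default was fixed.
#' @return An object of class `rate_map`: list with `values` (nx x ny
#'   matrix, x indexing rows), `bin_size`, `sigma`, `arena`.
#' @export
rate_map <- function(map, bin_size = NULL, sigma = NULL) {
  stopifnot(inherits(map, "spike_map"))
  a <- map$arena
  if (is.null(bin_size)) bin_size <- arena_side(a) / 50
  if (is.null(sigma)) sigma <- bin_size / 2
  nx <- max(1L, round((a[2L] - a[1L]) / bin_size))
  ny <- max(1L, round((a[4L] - a[3L]) / bin_size))
  if (nx < 3L || ny < 3L)
    stop("arena smaller than 3 x 3 bins; decrease `bin_size`")
  bx <- (a[2L] - a[1L]) / nx
  by <- (a[4L] - a[3L]) / ny
  ix <- pmin(pmax(ceiling((map$positions[, 1L] - a[1L]) / bx), 1L), nx)
  iy <- pmin(pmax(ceiling((map$positions[, 2L] - a[3L]) / by), 1L), ny)
  counts <- matrix(0, nx, ny)
  tab <- table(factor(ix, levels = 1:nx), factor(iy, levels = 1:ny))
  counts[] <- as.numeric(tab)
  vals <- gauss_smooth_2d(counts, sigma / bx, sigma / by)
  structure(list(values = vals, bin_size = bin_size, sigma = sigma,
                 arena = a),
            class = "rate_map")
}

# Separable 2-D Gaussian smoothing with zero padding (mass preserved up to
# boundary truncation).
gauss_smooth_2d <- function(m, sx, sy) {
  sm_rows <- apply(m, 2L, gauss_smooth_1d, sigma_bins = sx)
  t(apply(sm_rows, 1L, gauss_smooth_1d, sigma_bins = sy))
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("Rate map: %d x %d bins of %.3g m, smoothing sigma = %.3g m\n",
              nrow(x$values), ncol(x$values), x$bin_size, x$sigma))
  invisible(x)
}

# Full 2-D cross-correlation C[d] = sum_i a[i] * b[i + d] via FFT.
# Result has dims (2*n1-1, 2*n2-1) with zero lag at the center.
xcorr2 <- function(a, b) {
  n1 <- nrow(a); n2 <- ncol(a)
  p1 <- 2L * n1 - 1L; p2 <- 2L * n2 - 1L
  pa <- matrix(0, p1, p2); pa[1:n1, 1:n2] <- a
  pb <- matrix(0, p1, p2); pb[1:n1, 1:n2] <- b
  r <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb), inverse = TRUE)) /
    (p1 * p2)
  # reorder circular lags 0..p-1 into -(n-1)..(n-1)
  r[c((n1 + 1L):p1, 1:n1), c((n2 + 1L):p2, 1:n2)]
}

#' Spatial autocorrelogram of a rate map
#'
#' For every integer lag, the Pearson correlation between the map and its
#' shifted copy over their overlap region. Lags whose overlap contains
#' fewer than `min_overlap` bins, or where either side has zero variance,
#' are masked invalid.
#'
#' @param rmap A [rate_map()].
#' @param min_overlap Minimal overlap in bins (default 20).
#' @return An object of class `correlogram`: list with `values`
#'   ((2 nx - 1) x (2 ny - 1) matrix, `NA` where invalid), `valid`
#'   (logical matrix), `bin_size`, `center` (index of zero lag).
#' @export
autocorrelogram <- function(rmap, min_overlap = 20L) {
  stopifnot(inherits(rmap, "rate_map"))
  A <- rmap$values
  O <- matrix(1, nrow(A), ncol(A))
  n   <- round(xcorr2(O, O))
  Sxy <- xcorr2(A, A)
  Sx  <- xcorr2(A, O)
  Sy  <- xcorr2(O, A)
  Sxx <- xcorr2(A * A, O)
  Syy <- xcorr2(O, A * A)
  num <- n * Sxy - Sx * Sy
  v1 <- pmax(n * Sxx - Sx^2, 0)
  v2 <- pmax(n * Syy - Sy^2, 0)
  den <- sqrt(v1 * v2)
  scale2 <- mean(A^2) * nrow(A) * ncol(A)
  eps <- 1e-10 * max(scale2, 1e-300)
  valid <- n >= min_overlap & v1 > eps & v2 > eps
  vals <- matrix(NA_real_, nrow(num), ncol(num))
  vals[valid] <- pmin(pmax(num[valid] / den[valid], -1), 1)
  center <- c(nrow(A), ncol(A))
  vals[center[1L], center[2L]] <- if (valid[center[1L], center[2L]]) 1 else NA
  structure(list(values = vals, valid = valid, bin_size = rmap$bin_size,
                 center = center),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("Autocorrelogram: %d x %d lags, bin %.3g m, %d%% valid\n",
              nrow(x$values), ncol(x$values), x$bin_size,
              round(100 * mean(x$valid))))
  invisible(x)
}

# Mean correlation per radial ring (ring width = 1 bin); used to find the
# extent of the central peak.
radial_profile <- function(corr) {
  d <- lag_distance_bins(corr)
  ring <- round(d)
  v <- corr$values
  ok <- is.finite(v)
  means <- tapply(v[ok], ring[ok], mean)
  r <- as.integer(names(means))
  o <- order(r)
  list(r = r[o], value = as.numeric(means)[o])
}

lag_distance_bins <- function(corr) {
  nx <- nrow(corr$values); ny <- ncol(corr$values)
  dx <- matrix(seq_len(nx) - corr$center[1L], nx, ny)
  dy <- matrix(seq_len(ny) - corr$center[2L], nx, ny, byrow = TRUE)
  sqrt(dx^2 + dy^2)
}

# Strict 2-D local maxima over the 8-neighborhood; NA bins never qualify
# and block their neighbors' comparisons conservatively (NA treated as -Inf).
local_maxima_2d <- function(v) {
  nx <- nrow(v); ny <- ncol(v)
  vv <- v
  vv[!is.finite(vv)] <- -Inf
  big <- matrix(-Inf, nx + 2L, ny + 2L)
  big[2:(nx + 1L), 2:(ny + 1L)] <- vv
  res <- matrix(TRUE, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- big[(2:(nx + 1L)) + di, (2:(ny + 1L)) + dj]
    res <- res & vv > nb
  }
  res & is.finite(v)
}

#' Rotation-correlation grid score of a correlogram
#'
#' The conventional ("gridness") score. The six autocorrelogram peaks
#' closest to the center define an annulus; the annulus-cropped
#' correlogram is rotated by 30, 60, 90, 120 and 150 degrees (bilinear
#' interpolation) and correlated with its unrotated copy. The score is
#' `min(r60, r120) - max(r30, r90, r150)`: large when the 60-degree
#' periodicity of a hexagonal pattern is present, near or below zero
#' otherwise. Annulus construction: the central peak extends to where the
#' radial correlation profile first falls below `center_threshold` or
#' reaches its first local minimum (whichever radius is smaller); the
#' annulus runs from the larger of that radius and `inner_factor` times
#' the mean distance of the six peaks, out to `outer_factor` times that
#' mean distance, so it brackets the inner peak ring while excluding the
#' isotropic shoulder of the central peak.
#'
#' @param corr A [autocorrelogram()].
#' @param center_threshold Correlation level delimiting the central peak
#'   (default 0.1).
#' @param inner_factor,outer_factor Annulus radii as fractions of the
#'   mean six-peak distance (defaults 0.5 and 1.15; a joint calibration
#'   with the rate-map smoothing, see the methods vignette).
#' @return An object of class `rho_score`: list with `rho` (`NA` on peak
#'   detection failure, with `failure_reason`), `rotation_cor` (named
#'   vector over angles), `r_inner`, `r_outer` (meters), `peaks` (six
#'   peak lags in meters).
#' @export
rho_score <- function(corr, center_threshold = 0.1, inner_factor = 0.5,
                      outer_factor = 1.15) {
  stopifnot(inherits(corr, "correlogram"))
  fail <- function(reason)
    structure(list(rho = NA_real_, rotation_cor = NULL,
                   r_inner = NA_real_, r_outer = NA_real_, peaks = NULL,
                   failure_reason = reason),
              class = "rho_score")
  prof <- radial_profile(corr)
  below <- prof$r[prof$value < center_threshold]
  r_thr <- if (length(below)) min(below) else Inf
  lm <- find_local_maxima(-prof$value)       # local minima of the profile
  r_min <- if (length(lm)) prof$r[lm[1L]] else Inf
  r_inner_bins <- min(r_thr, r_min)
  if (!is.finite(r_inner_bins))
    return(fail("central peak of the correlogram does not decay"))
  d <- lag_distance_bins(corr)
  cand <- which(local_maxima_2d(corr$values) & d > r_inner_bins)
  if (length(cand) < 6L)
    return(fail("fewer than six off-center peaks in the correlogram"))
  cand <- cand[order(d[cand])][1:6]
  mean_peak <- mean(d[cand])
  r_inner_bins <- max(r_inner_bins, inner_factor * mean_peak)
  r_outer_bins <- outer_factor * mean_peak
  annulus <- d >= r_inner_bins & d <= r_outer_bins & is.finite(corr$values)
  angles <- c(30, 60, 90, 120, 150)
  rots <- vapply(angles, function(a) {
    rot <- rotate_bilinear(corr$values, a, corr$center)
    ok <- annulus & is.finite(rot)
    if (sum(ok) < 3L || stats::sd(corr$values[ok]) == 0 ||
        stats::sd(rot[ok]) == 0) return(NA_real_)
    stats::cor(corr$values[ok], rot[ok])
  }, numeric(1))
  names(rots) <- paste0("r", angles)
  if (anyNA(rots))
    return(fail("degenerate rotation correlation"))
  rho <- min(rots[["r60"]], rots[["r120"]]) -
    max(rots[["r30"]], rots[["r90"]], rots[["r150"]])
  structure(list(rho = rho, rotation_cor = rots,
                 r_inner = r_inner_bins * corr$bin_size,
                 r_outer = r_outer_bins * corr$bin_size,
                 peaks = cbind(x = (((cand - 1L) %% nrow(d)) + 1L -
                                      corr$center[1L]) * corr$bin_size,
                               y = (((cand - 1L) %/% nrow(d)) + 1L -
                                      corr$center[2L]) * corr$bin_size),
                 failure_reason = NULL),
            class = "rho_score")
}

#' @export
print.rho_score <- function(x, ...) {
  if (is.na(x$rho)) {
    cat(sprintf("rho score: failed (%s)\n", x$failure_reason))
  } else {
    cat(sprintf("rho = %.3f  annulus [%.3g, %.3g] m\n",
                x$rho, x$r_inner, x$r_outer))
  }
  invisible(x)
}

# Rotate a matrix about a center index by `deg` degrees using bilinear
# interpolation; cells sampling outside the matrix or from any NA source
# cell become NA.
rotate_bilinear <- function(v, deg, center) {
  nx <- nrow(v); ny <- ncol(v)
  th <- deg * pi / 180
  i <- matrix(seq_len(nx) - center[1L], nx, ny)
  j <- matrix(seq_len(ny) - center[2L], nx, ny, byrow = TRUE)
  # source coordinates: rotate backwards
  si <- cos(th) * i + sin(th) * j + center[1L]
  sj <- -sin(th) * i + cos(th) * j + center[2L]
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  out <- matrix(NA_real_, nx, ny)
  ok <- i0 >= 1L & i0 + 1L <= nx & j0 >= 1L & j0 + 1L <= ny
  idx <- function(ii, jj) (jj - 1L) * nx + ii
  g <- which(ok)
  v00 <- v[idx(i0[g], j0[g])]
  v10 <- v[idx(i0[g] + 1L, j0[g])]
  v01 <- v[idx(i0[g], j0[g] + 1L)]
  v11 <- v[idx(i0[g] + 1L, j0[g] + 1L)]
  out[g] <- (1 - fi[g]) * (1 - fj[g]) * v00 + fi[g] * (1 - fj[g]) * v10 +
    (1 - fi[g]) * fj[g] * v01 + fi[g] * fj[g] * v11
  out
}
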