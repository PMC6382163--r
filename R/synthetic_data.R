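#' Specification of a synthetic grid-cell firing pattern
#'
#' Collects the generative parameters for synthetic spike maps: a
#' triangular lattice of Gaussian firing fields inside a rectangular arena.
#'
#' @param ell Grid spacing in meters (default 0.5).
#' @param orientation Lattice orientation in degrees (default 0).
#' @param phase 2-D lattice offset in meters, or `NULL` (default) to draw
#'   the offset uniformly over one lattice unit cell when spikes are
#'   generated, so that independent realizations differ in grid phase.
#' @param field_sigma Standard deviation of the isotropic Gaussian firing
#'   fields in meters. The default `ell / 7` keeps the ratio of field size
#'   to grid spacing fixed at a value consistent with experimental
#'   observations and places the mean grid score of a perfect grid at the
#'   commonly reported operating point (about 0.35); see the methods
#'   vignette for how this reconstruction was chosen.
#' @param n_spikes Number of spikes to generate (default 2000).
#' @param arena Arena bounding box `c(x_min, x_max, y_min, y_max)` in
#'   meters; default the 1 m x 1 m unit arena.
#' @param seed Optional integer seed; all generators are deterministic
#'   given the seed.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(ell = 0.5, orientation = 0, phase = NULL,
                      field_sigma = ell / 7, n_spikes = 2000L,
                      arena = c(0, 1, 0, 1), seed = NULL) {
  arena <- validate_arena(arena)
  if (!is.finite(ell) || ell <= 0) stop("`ell` must be positive")
  if (!is.finite(field_sigma) || field_sigma <= 0 || field_sigma >= ell / 2)
    stop("`field_sigma` must lie in (0, ell/2)")
  if (n_spikes < 1L) stop("`n_spikes` must be at least 1")
  if (!is.null(phase) && length(phase) != 2L)
    stop("`phase` must be NULL or a length-2 numeric")
  structure(list(ell = ell, orientation = orientation, phase = phase,
                 field_sigma = field_sigma, n_spikes = as.integer(n_spikes),
                 arena = arena, seed = seed),
            class = "grid_spec")
}

lattice_vectors <- function(ell, orientation_deg) {
  a <- orientation_deg * pi / 180
  rbind(ell * c(cos(a), sin(a)),
        ell * c(cos(a + pi / 3), sin(a + pi / 3)))
}

#' Field centers of a perfect hexagonal grid
#'
#' Triangular-lattice points with the requested spacing, orientation and
#' phase, covering the arena plus a margin of one grid spacing so that
#' fields at the arena boundary keep their six lattice neighbors.
#'
#' @param spec A [grid_spec()]. A `NULL` phase resolves to `c(0, 0)` here;
#'   random phases are drawn by [sample_grid_spikes()].
#' @param margin Margin around the arena in meters (default `spec$ell`).
#' @return A matrix of field centers (columns `x`, `y`).
#' @export
hexagonal_field_centers <- function(spec, margin = spec$ell) {
  stopifnot(inherits(spec, "grid_spec"))
  phase <- if (is.null(spec$phase)) c(0, 0) else spec$phase
  A <- lattice_vectors(spec$ell, spec$orientation)
  a <- spec$arena
  lo <- c(a[1L] - margin, a[3L] - margin)
  hi <- c(a[2L] + margin, a[4L] + margin)
  # generous index range: corners of the box in lattice coordinates
  corners <- rbind(c(lo[1L], lo[2L]), c(lo[1L], hi[2L]),
                   c(hi[1L], lo[2L]), c(hi[1L], hi[2L]))
  ij <- t(solve(t(A), t(sweep(corners, 2L, phase))))
  ir <- floor(min(ij[, 1L]) - 1):ceiling(max(ij[, 1L]) + 1)
  jr <- floor(min(ij[, 2L]) - 1):ceiling(max(ij[, 2L]) + 1)
  g <- as.matrix(expand.grid(i = ir, j = jr))
  pts <- g %*% A
  pts[, 1L] <- pts[, 1L] + phase[1L]
  pts[, 2L] <- pts[, 2L] + phase[2L]
  keep <- pts[, 1L] >= lo[1L] & pts[, 1L] <= hi[1L] &
    pts[, 2L] >= lo[2L] & pts[, 2L] <= hi[2L]
  pts <- pts[keep, , drop = FALSE]
  colnames(pts) <- c("x", "y")
  pts
}

random_phase <- function(spec) {
  A <- lattice_vectors(spec$ell, spec$orientation)
  u <- stats::runif(2)
  as.numeric(u[1L] * A[1L, ] + u[2L] * A[2L, ])
}

#' Draw spikes from Gaussian grid fields
#'
#' Each spike picks a field uniformly among the centers and adds isotropic
#' Gaussian scatter of width `field_sigma`; draws falling outside the
#' arena are rejected and redrawn (field choice included), so the spike
#' count is exact.
#'
#' @param centers Matrix of field centers, e.g. from
#'   [hexagonal_field_centers()].
#' @param spec A [grid_spec()] (supplies `field_sigma`, `n_spikes`, `arena`
#'   and `seed`).
#' @param times Optional spike times to attach.
#' @return A [spike_map()].
#' @export
sample_grid_spikes <- function(centers, spec, times = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(dim(centers)) || nrow(centers) < 1L)
    stop("`centers` must be a nonempty matrix")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  a <- spec$arena
  n <- spec$n_spikes
  out <- matrix(NA_real_, n, 2L)
  need <- n
  tried <- 0
  while (need > 0L) {
    nb <- max(need, 64L)
    f <- sample.int(nrow(centers), nb, replace = TRUE)
    x <- centers[f, 1L] + stats::rnorm(nb, sd = spec$field_sigma)
    y <- centers[f, 2L] + stats::rnorm(nb, sd = spec$field_sigma)
    ok <- x >= a[1L] & x <= a[2L] & y >= a[3L] & y <= a[4L]
    k <- min(sum(ok), need)
    if (k > 0L) {
      sel <- which(ok)[seq_len(k)]
      out[(n - need + 1L):(n - need + k), ] <- cbind(x[sel], y[sel])
      need <- need - k
    }
    tried <- tried + nb
    if (tried > 1000L * n && need > 0L)
      stop("degenerate grid specification: rejection rate above 99.9%")
  }
  spike_map(out, times = times, arena = a)
}

#' Generate a synthetic grid-cell spike map
#'
#' Full generator: lattice centers (with a random phase per realization
#' when `spec$phase` is `NULL`), optional field-location jitter and
#' shearing, Gaussian spike scatter, optional background spikes.
#'
#' @param spec A [grid_spec()].
#' @param jitter_sigma Std. dev. (m) of random field displacements
#'   (default 0, i.e. a perfect grid).
#' @param jitter_region Optional region restricting the jitter, see
#'   [jitter_fields()].
#' @param shear_strength Horizontal shear strength (default 0).
#' @param background_fraction Fraction of spikes drawn uniformly over the
#'   arena instead of from the fields (default 0).
#' @return A [spike_map()].
#' @examples
#' m <- generate_grid_map(grid_spec(n_spikes = 500, seed = 42))
#' @export
generate_grid_map <- function(spec, jitter_sigma = 0, jitter_region = NULL,
                              shear_strength = 0, background_fraction = 0) {
  stopifnot(inherits(spec, "grid_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  spec2 <- spec
  spec2$seed <- NULL                      # RNG already seeded once here
  if (is.null(spec2$phase)) spec2$phase <- random_phase(spec)
  centers <- hexagonal_field_centers(spec2)
  if (jitter_sigma > 0)
    centers <- jitter_fields(centers, jitter_sigma, region = jitter_region)
  if (shear_strength != 0)
    centers <- shear_fields(centers, shear_strength, arena = spec$arena)
  map <- sample_grid_spikes(centers, spec2)
  if (background_fraction > 0)
    map <- add_background(map, background_fraction)
  map
}

region_mask <- function(centers, region) {
  if (is.null(region)) return(rep(TRUE, nrow(centers)))
  if (is.function(region)) {
    as.logical(region(centers[, 1L], centers[, 2L]))
  } else {
    r <- as.numeric(region)
    if (length(r) != 4L) stop("`region` must be a rectangle or a predicate")
    centers[, 1L] >= r[1L] & centers[, 1L] <= r[2L] &
      centers[, 2L] >= r[3L] & centers[, 2L] <= r[4L]
  }
}

#' Randomly displace grid field centers
#'
#' Adds isotropic Gaussian displacements to field centers, optionally only
#' inside a region of the arena (e.g. the eastern half, to create a
#' spatially localized grid defect).
#'
#' @param centers Matrix of field centers.
#' @param jitter_sigma Standard deviation of the displacement in meters.
#' @param region `NULL` (whole plane), a rectangle
#'   `c(x_min, x_max, y_min, y_max)`, or a predicate `function(x, y)`.
#' @param seed Optional seed.
#' @return The displaced centers.
#' @export
jitter_fields <- function(centers, jitter_sigma, region = NULL, seed = NULL) {
  if (jitter_sigma < 0) stop("`jitter_sigma` must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  if (jitter_sigma == 0) return(centers)
  sel <- region_mask(centers, region)
  k <- sum(sel)
  if (k > 0L) {
    centers[sel, 1L] <- centers[sel, 1L] + stats::rnorm(k, sd = jitter_sigma)
    centers[sel, 2L] <- centers[sel, 2L] + stats::rnorm(k, sd = jitter_sigma)
  }
  centers
}

#' Horizontally shear grid field centers
#'
#' Applies the area-preserving map `(x, y) -> (x + strength * (y - y_mid),
#' y)` about the arena's vertical midline, producing the elliptic
#' distortion of sheared grids.
#'
#' @param centers Matrix of field centers.
#' @param strength Dimensionless shear strength.
#' @param arena Arena bounding box (supplies the vertical midline).
#' @return The sheared centers.
#' @export
shear_fields <- function(centers, strength, arena) {
  arena <- validate_arena(arena)
  y_mid <- (arena[3L] + arena[4L]) / 2
  centers[, 1L] <- centers[, 1L] + strength * (centers[, 2L] - y_mid)
  centers
}

#' Replace a fraction of spikes by uniform background spikes
#'
#' Keeps the total spike count fixed and replaces `round(fraction * n)`
#' randomly chosen spikes by draws from a spatially homogeneous
#' distribution over the arena, emulating, e.g., contamination from poor
#' single-cell isolation.
#'
#' @param map A [spike_map()].
#' @param fraction Fraction in `[0, 1]`.
#' @param seed Optional seed.
#' @return A [spike_map()] with the same spike count (times preserved).
#' @export
add_background <- function(map, fraction, seed = NULL) {
  stopifnot(inherits(map, "spike_map"))
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("`fraction` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(map$positions)
  k <- round(fraction * n)
  if (k == 0L) return(map)
  a <- map$arena
  idx <- sample.int(n, k)
  map$positions[idx, 1L] <- stats::runif(k, a[1L], a[2L])
  map$positions[idx, 2L] <- stats::runif(k, a[3L], a[4L])
  map
}

#' Grid patterns with spatially varying orientation
#'
#' `abrupt` mode builds the lattice with the base orientation in the
#' southern half of the arena and with orientation `orientation + delta`
#' in the northern half. `drift` mode splits the arena into horizontal
#' strips whose orientation increases linearly from the base value to
#' `orientation + delta` from south to north (piecewise-constant
#' realization of a drifting grid).
#'
#' @param spec A [grid_spec()].
#' @param mode `"abrupt"` or `"drift"`.
#' @param delta Total orientation change in degrees, `|delta| < 30`.
#' @param n_strips Number of strips in `drift` mode (default 6).
#' @return A [spike_map()].
#' @export
orientation_variants <- function(spec, mode = c("abrupt", "drift"),
                                 delta = 10, n_strips = 6L) {
  stopifnot(inherits(spec, "grid_spec"))
  mode <- match.arg(mode)
  if (abs(delta) >= 30) stop("`delta` must satisfy |delta| < 30 degrees")
  if (mode == "drift" && n_strips < 6L) stop("`drift` mode needs >= 6 strips")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  spec2 <- spec
  spec2$seed <- NULL
  if (is.null(spec2$phase)) spec2$phase <- random_phase(spec)
  a <- spec$arena
  if (mode == "abrupt") {
    bounds <- c(a[3L], mean(a[3:4]), a[4L])
    oris <- spec$orientation + c(0, delta)
  } else {
    bounds <- seq(a[3L], a[4L], length.out = n_strips + 1L)
    oris <- spec$orientation + seq(0, delta, length.out = n_strips)
  }
  # keep the lattice margin beyond the outer arena edges so boundary
  # fields retain neighbors there; the split itself is sharp
  bounds[1L] <- bounds[1L] - spec$ell
  bounds[length(bounds)] <- bounds[length(bounds)] + spec$ell
  centers <- NULL
  for (s in seq_along(oris)) {
    sp <- spec2
    sp$orientation <- oris[s]
    cs <- hexagonal_field_centers(sp)
    keep <- cs[, 2L] >= bounds[s] & cs[, 2L] < bounds[s + 1L]
    centers <- rbind(centers, cs[keep, , drop = FALSE])
  }
  if (nrow(centers) < 1L)
    stop("no field centers fell inside the arena strips")
  sample_grid_spikes(centers, spec2)
}

#' Temporal switch from uniform to grid firing
#'
#' Generates a spike map with times: the first `n_uniform` spikes are
#' drawn from a spatially uniform distribution, the following `n_grid`
#' spikes from the grid model, all at a constant firing rate, so spike `k`
#' occurs at time `k / rate_hz`.
#'
#' @param spec A [grid_spec()] (its `n_spikes` is ignored).
#' @param n_uniform,n_grid Spike counts of the two regimes.
#' @param rate_hz Firing rate in spikes per second (default 1).
#' @return A [spike_map()] with times.
#' @export
temporal_transition <- function(spec, n_uniform = 1000L, n_grid = 1000L,
                                rate_hz = 1) {
  stopifnot(inherits(spec, "grid_spec"))
  if (n_uniform < 0L || n_grid < 0L || n_uniform + n_grid < 1L)
    stop("need a positive total spike count")
  if (rate_hz <= 0) stop("`rate_hz` must be positive")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  spec2 <- spec
  spec2$seed <- NULL
  if (is.null(spec2$phase)) spec2$phase <- random_phase(spec)
  a <- spec$arena
  pos_u <- if (n_uniform > 0L)
    cbind(stats::runif(n_uniform, a[1L], a[2L]),
          stats::runif(n_uniform, a[3L], a[4L])) else NULL
  pos_g <- if (n_grid > 0L) {
    spec2$n_spikes <- as.integer(n_grid)
    sample_grid_spikes(hexagonal_field_centers(spec2), spec2)$positions
  } else NULL
  pos <- rbind(pos_u, pos_g)
  n <- nrow(pos)
  spike_map(pos, times = seq_len(n) / rate_hz, arena = a)
}
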