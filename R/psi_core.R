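#' Angles to the neighbors of a spike
#'
#' Returns the angle, measured counter-clockwise from the positive
#' horizontal axis, of the vector pointing from spike `k` to every other
#' spike whose distance from spike `k` lies inside the neighborhood shell
#' (boundaries included).
#'
#' @param map A [spike_map()].
#' @param k Index of the reference spike.
#' @param sh A [shell()].
#' @return Numeric vector of angles in radians, in `(-pi, pi]`, ordered by
#'   neighbor index.
#' @export
neighbor_angles <- function(map, k, sh) {
  stopifnot(inherits(map, "spike_map"), inherits(sh, "shell"))
  n <- nrow(map$positions)
  if (!(is.numeric(k) && length(k) == 1L && k == as.integer(k) &&
        k >= 1L && k <= n))
    stop("`k` must be a valid spike index")
  dx <- map$positions[, 1L] - map$positions[k, 1L]
  dy <- map$positions[, 2L] - map$positions[k, 2L]
  d <- sqrt(dx^2 + dy^2)
  nb <- which(d >= sh$r_inner & d <= sh$r_outer)
  nb <- nb[nb != k]
  atan2(dy[nb], dx[nb])
}

#' M-fold bond-orientational order parameter
#'
#' For neighbor angles `phi_l`, computes the complex order parameter
#' `psi^(M) = (1/N) * sum_l exp(1i * M * phi_l)`. Its modulus (between 0
#' and 1) measures how strongly the neighbors are arranged with M-fold
#' angular symmetry; its argument divided by M is the orientation of the
#' M-polygon.
#'
#' @param angles Numeric vector of neighbor angles in radians.
#' @param M Symmetry order, an integer `>= 2`.
#' @return A complex scalar, or `NA_complex_` if `angles` is empty (a spike
#'   with no neighbors has an undefined profile, not an error).
#' @examples
#' psi_m(seq(0, 300, by = 60) * pi / 180, 6)  # perfect hexagon -> 1+0i
#' @export
psi_m <- function(angles, M) {
  if (!(is.numeric(M) && length(M) == 1L && M >= 2 && M == as.integer(M)))
    stop("`M` must be an integer >= 2")
  if (length(angles) == 0L) return(NA_complex_)
  mean(exp(1i * M * angles))
}

#' Per-spike symmetry profile
#'
#' Evaluates `psi^(M)` for one spike over a set of symmetry orders.
#'
#' @inheritParams neighbor_angles
#' @param M_set Integer vector of symmetry orders, default `2:7`.
#' @return A list of class `symmetry_profile` with elements `psi` (named
#'   complex vector, one entry per order) and `n_neighbors`.
#' @export
symmetry_profile <- function(map, k, sh, M_set = 2:7) {
  ang <- neighbor_angles(map, k, sh)
  psi <- vapply(M_set, function(M) psi_m(ang, M), complex(1))
  names(psi) <- as.character(M_set)
  structure(list(psi = psi, n_neighbors = length(ang)),
            class = "symmetry_profile")
}

#' Grid score of a single spike
#'
#' The score is the modulus of the target-symmetry order parameter,
#' but only if that symmetry is strictly the strongest among all tested
#' orders; otherwise the score is 0. The comparison suppresses false
#' positives from, e.g., collinear field arrangements, which produce a
#' large 6-fold modulus alongside an equally large 2-fold modulus.
#'
#' @param profile A [symmetry_profile()].
#' @param M_target Symmetry of interest (default 6, hexagonal).
#' @return The spike grid score in `[0, 1]`. A spike with no neighbors
#'   scores 0 and carries attribute `no_neighbors = TRUE`.
#' @export
psi_hat <- function(profile, M_target = 6L) {
  stopifnot(inherits(profile, "symmetry_profile"))
  if (profile$n_neighbors == 0L)
    return(structure(0, no_neighbors = TRUE))
  mags <- Mod(profile$psi)
  tgt <- as.character(M_target)
  if (!tgt %in% names(mags))
    stop("target symmetry not present in the profile")
  others <- mags[setdiff(names(mags), tgt)]
  if (length(others) && any(others >= mags[[tgt]])) 0 else mags[[tgt]]
}

#' Orientation of a single spike
#'
#' The orientation is `arg(psi^(M)) / M` in degrees. Since `arg` maps to
#' `(-pi, pi]`, the orientation lies in `(-180/M, 180/M]` degrees -- for
#' hexagonal symmetry, `(-30, 30]`.
#'
#' @inheritParams psi_hat
#' @return Orientation in degrees, or `NA` if the spike has no neighbors or
#'   the order parameter vanishes.
#' @export
spike_orientation <- function(profile, M_target = 6L) {
  stopifnot(inherits(profile, "symmetry_profile"))
  if (profile$n_neighbors == 0L) return(NA_real_)
  z <- profile$psi[[as.character(M_target)]]
  if (Mod(z) == 0) return(NA_real_)
  Arg(z) / M_target * 180 / pi
}

#' Score every spike of a map
#'
#' Computes, for each spike, the neighbor angles within the shell, the
#' order parameters `psi^(M)` for all orders in `M_set`, the grid score
#' `psi_hat` (modulus of the target symmetry if strictly dominant, else 0)
#' and the orientation `theta` in degrees.
#'
#' @param map A [spike_map()].
#' @param sh A [shell()].
#' @param M_set Symmetry orders to compare, default `2:7`; must contain
#'   `M_target`.
#' @param M_target The symmetry being scored (default 6).
#' @return An object of class `spike_scores`: a list with `psi_hat`
#'   (numeric, `[0, 1]`), `theta_deg` (degrees in `(-180/M, 180/M]`, `NA`
#'   where undefined), `n_neighbors`, `psi` (n x length(M_set) complex
#'   matrix), plus `M_set`, `M_target`, `shell` and a `failed` flag (used by
#'   the pipeline when shell detection fails).
#' @export
score_spike_map <- function(map, sh, M_set = 2:7, M_target = 6L) {
  stopifnot(inherits(map, "spike_map"), inherits(sh, "shell"))
  M_set <- sort(unique(as.integer(M_set)))
  if (!M_target %in% M_set) stop("`M_set` must contain `M_target`")
  k <- .psi_kernel(map$positions, map$positions, sh$r_inner, sh$r_outer,
                   M_set, TRUE, 0)
  scores_from_psi(k$psi, k$n_neighbors, M_set, M_target, sh)
}

# Shared back end: per-spike score and orientation from the complex
# order-parameter matrix.
scores_from_psi <- function(psi, nn, M_set, M_target, sh) {
  colnames(psi) <- as.character(M_set)
  nm <- length(M_set)
  mags <- Mod(psi)
  tgt_col <- match(M_target, M_set)
  other_max <- do.call(pmax, c(lapply(setdiff(seq_len(nm), tgt_col),
                                      function(j) mags[, j]), list(-Inf)))
  ph <- ifelse(nn == 0L, 0, ifelse(mags[, tgt_col] > other_max,
                                   mags[, tgt_col], 0))
  theta <- Arg(psi[, tgt_col]) / M_target * 180 / pi
  theta[nn == 0L | mags[, tgt_col] == 0] <- NA_real_
  structure(list(psi_hat = as.numeric(ph), theta_deg = as.numeric(theta),
                 n_neighbors = as.integer(nn), psi = psi, M_set = M_set,
                 M_target = as.integer(M_target), shell = sh,
                 failed = FALSE),
            class = "spike_scores")
}

#' @export
print.spike_scores <- function(x, ...) {
  cat(sprintf(
    "Spike scores (M = %d): %d spikes, mean psi_hat = %.3f, %d with score 0\n",
    x$M_target, length(x$psi_hat), mean(x$psi_hat), sum(x$psi_hat == 0)))
  if (isTRUE(x$failed))
    cat("  [shell detection failed; all scores set to 0]\n")
  invisible(x)
}

#' Circular mean of orientations on a periodic scale
#'
#' @param theta_deg Angles in degrees.
#' @param period Period in degrees (60 for hexagonal orientations).
#' @param weights Optional nonnegative weights.
#' @return Mean angle in degrees, wrapped to `(-period/2, period/2]`;
#'   `NA` if no finite input or a vanishing resultant.
#' @export
circular_mean_deg <- function(theta_deg, period = 60, weights = NULL) {
  ok <- is.finite(theta_deg)
  if (!is.null(weights)) ok <- ok & is.finite(weights) & weights > 0
  if (!any(ok)) return(NA_real_)
  th <- theta_deg[ok] * 2 * pi / period
  w <- if (is.null(weights)) rep(1, sum(ok)) else weights[ok]
  z <- sum(w * exp(1i * th)) / sum(w)
  if (Mod(z) < 1e-12) return(NA_real_)
  Arg(z) * period / (2 * pi)
}

#' Arena-wide grid score and orientation
#'
#' The global score `Psi` is the arithmetic mean of the per-spike scores,
#' zeros included. The global orientation `Theta` is the circular mean (on
#' the 60-degree-periodic circle for hexagonal symmetry) of the per-spike
#' orientations; by default only spikes with a positive grid score
#' contribute.
#'
#' @param scores A [score_spike_map()] result.
#' @param theta_spikes Which spikes enter `Theta`: `"scored"` (default,
#'   spikes with `psi_hat > 0`) or `"all"` (every spike with a defined
#'   orientation).
#' @return A list of class `global_scores` with `Psi`, `Theta_deg`
#'   (`NA` if no spike has a defined orientation), `n_spikes` and
#'   `n_theta` (number of spikes contributing to `Theta`).
#' @export
global_scores <- function(scores, theta_spikes = c("scored", "all")) {
  stopifnot(inherits(scores, "spike_scores"))
  theta_spikes <- match.arg(theta_spikes)
  period <- 360 / scores$M_target
  use <- if (theta_spikes == "scored") scores$psi_hat > 0
         else is.finite(scores$theta_deg)
  th <- scores$theta_deg[use]
  structure(list(Psi = mean(scores$psi_hat),
                 Theta_deg = circular_mean_deg(th, period = period),
                 n_spikes = length(scores$psi_hat),
                 n_theta = sum(is.finite(th))),
            class = "global_scores")
}

#' @export
print.global_scores <- function(x, ...) {
  cat(sprintf("Psi = %.4f  Theta = %s deg  (n = %d spikes, %d in Theta)\n",
              x$Psi,
              if (is.finite(x$Theta_deg)) sprintf("%.2f", x$Theta_deg)
              else "undefined",
              x$n_spikes, x$n_theta))
  invisible(x)
}
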