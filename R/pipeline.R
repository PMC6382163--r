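#' Spike-level grid scores with automatic shell detection
#'
#' End-to-end scoring of a spike map: estimate the grid spacing from the
#' pairwise-distance histogram (unless a shell is supplied), construct the
#' neighborhood shell for the target symmetry, and score every spike.
#' If spacing detection fails, the map cannot be scored meaningfully; in
#' that case all spikes receive a score of 0 and the result is flagged via
#' its `failed` element rather than raising an error, mirroring how such
#' cells are treated downstream (they simply obtain wrongfully low scores).
#'
#' @param map A [spike_map()].
#' @param sh Optional [shell()]; when supplied, detection is skipped.
#' @param shell_mode Spacing detection mode, see [detect_spacing()].
#' @param cutoff_fraction,manual_ell Passed to [detect_spacing()].
#' @param bin_fraction Passed to [distance_histogram()].
#' @param M_set,M_target Passed to [score_spike_map()].
#' @return A `spike_scores` object (see [score_spike_map()]); `failed` is
#'   `TRUE` and all scores are 0 when shell detection failed. The detected
#'   shell (or `NULL`) is stored in the `shell` element.
#' @examples
#' m <- generate_grid_map(grid_spec(n_spikes = 400, seed = 1))
#' s <- psi_scores(m)
#' global_scores(s)
#' @export
psi_scores <- function(map, sh = NULL,
                       shell_mode = c("second_peak", "cutoff", "manual"),
                       cutoff_fraction = 0.15, manual_ell = NULL,
                       bin_fraction = 0.005, M_set = 2:7, M_target = 6L) {
  stopifnot(inherits(map, "spike_map"))
  shell_mode <- match.arg(shell_mode)
  if (is.null(sh)) {
    ell <- tryCatch({
      h <- if (shell_mode == "manual") NULL else distance_histogram(
        map, bin_fraction = bin_fraction)
      detect_spacing(h, mode = shell_mode,
                     cutoff_fraction = cutoff_fraction,
                     arena_side = arena_side(map$arena),
                     manual_ell = manual_ell)
    }, gridspike_spacing_error = function(e) e,
       gridspike_degenerate_error = function(e) e)
    if (inherits(ell, "condition")) {
      n <- nrow(map$positions)
      return(structure(list(psi_hat = numeric(n),
                            theta_deg = rep(NA_real_, n),
                            n_neighbors = rep(NA_integer_, n),
                            psi = NULL, M_set = sort(unique(as.integer(M_set))),
                            M_target = as.integer(M_target), shell = NULL,
                            failed = TRUE,
                            failure_reason = conditionMessage(ell)),
                       class = "spike_scores"))
    }
    sh <- shell_for_symmetry(ell, M = M_target)
  }
  score_spike_map(map, sh, M_set = M_set, M_target = M_target)
}

#' Correlogram-based grid score of a spike map
#'
#' Convenience wrapper running the conventional pipeline: rate map,
#' spatial autocorrelogram, rotation-correlation score.
#'
#' @param map A [spike_map()].
#' @param bin_size,sigma Passed to [rate_map()].
#' @param min_overlap Passed to [autocorrelogram()].
#' @param ... Passed to [rho_score()].
#' @return A `rho_score` object; its `rho` element is `NA` when peak
#'   detection in the correlogram fails.
#' @export
rho_pipeline <- function(map, bin_size = NULL, sigma = NULL,
                         min_overlap = 20L, ...) {
  rm <- rate_map(map, bin_size = bin_size, sigma = sigma)
  ac <- autocorrelogram(rm, min_overlap = min_overlap)
  rho_score(ac, ...)
}
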