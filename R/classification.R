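#' Shuffle the spike locations of a map
#'
#' Redraws every spike position uniformly over the arena, keeping the
#' spike count and the spike times (in order). This destroys all spatial
#' structure while preserving the number of spikes, which is exactly what
#' the per-cell flexible classification threshold needs: a pattern with
#' many background spikes is compared against nulls carrying the same
#' spike count.
#'
#' @param map A [spike_map()].
#' @param seed Optional seed for reproducibility.
#' @return A [spike_map()] with uniformly redistributed positions.
#' @export
shuffle_spike_map <- function(map, seed = NULL) {
  stopifnot(inherits(map, "spike_map"))
  if (!is.null(seed)) set.seed(seed)
  a <- map$arena
  n <- nrow(map$positions)
  spike_map(stats::runif(n, a[1L], a[2L]), stats::runif(n, a[3L], a[4L]),
            times = map$times, arena = a)
}

#' Classify a cell as a grid cell via a shuffled-score threshold
#'
#' Computes the chosen grid score on the actual map and on `n_shuffles`
#' spike maps with uniformly shuffled positions. The per-cell threshold is
#' the given percentile (linear interpolation between order statistics) of
#' the shuffled scores; the cell is called a grid cell only if its actual
#' score strictly exceeds the threshold.
#'
#' Score failures (shell or annulus detection) are mapped to the score's
#' floor value (0 for `Psi`, -2 for `rho`) on shuffled maps; a failure on
#' the actual map yields a negative classification with a failure flag.
#' Shell/annulus detection is re-run on every shuffled map, matching the
#' end-to-end pipeline.
#'
#' @param map A [spike_map()].
#' @param score `"psi"` (mean spike-based score `Psi`) or `"rho"`
#'   (correlogram score).
#' @param n_shuffles Number of shuffles (default 100).
#' @param percentile Threshold percentile (default 95).
#' @param seed Optional seed governing all shuffles.
#' @param ... Passed to [psi_scores()] or [rho_pipeline()] (e.g.
#'   `shell_mode`, `cutoff_fraction`).
#' @return A list of class `grid_classification`: `is_grid`, `score`
#'   (actual), `threshold`, `shuffled_scores`, `score_type`, `n_shuffles`,
#'   `percentile`, `failed` (actual-map score failure), `seed`.
#' @export
classify_cell <- function(map, score = c("psi", "rho"), n_shuffles = 100L,
                          percentile = 95, seed = NULL, ...) {
  stopifnot(inherits(map, "spike_map"))
  score <- match.arg(score)
  if (!is.null(seed)) set.seed(seed)
  floor_value <- if (score == "psi") 0 else -2
  eval_score <- function(m) {
    if (score == "psi") {
      s <- psi_scores(m, ...)
      if (isTRUE(s$failed)) c(NA_real_) else mean(s$psi_hat)
    } else {
      r <- rho_pipeline(m, ...)
      r$rho
    }
  }
  actual <- eval_score(map)
  shuffled <- vapply(seq_len(n_shuffles),
                     function(i) eval_score(shuffle_spike_map(map)),
                     numeric(1))
  shuffled[is.na(shuffled)] <- floor_value
  threshold <- as.numeric(
    stats::quantile(shuffled, percentile / 100, type = 7, names = FALSE))
  failed <- is.na(actual)
  structure(list(is_grid = !failed && actual > threshold,
                 score = actual, threshold = threshold,
                 shuffled_scores = shuffled, score_type = score,
                 n_shuffles = as.integer(n_shuffles),
                 percentile = percentile, failed = failed, seed = seed),
            class = "grid_classification")
}

#' @export
print.grid_classification <- function(x, ...) {
  cat(sprintf(
    "%s-based classification: %s (score %s, threshold %.4f, %d shuffles, p%g)\n",
    toupper(x$score_type),
    if (x$failed) "FAILED (score undefined)"
    else if (x$is_grid) "grid cell" else "not a grid cell",
    if (x$failed) "NA" else sprintf("%.4f", x$score),
    x$threshold, x$n_shuffles, x$percentile))
  invisible(x)
}

#' Serialize a classification to JSON
#'
#' @param x A [classify_cell()] result.
#' @param path Optional file path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
classification_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "grid_classification"))
  obj <- list(score_type = x$score_type, actual = x$score,
              threshold = x$threshold, n_shuffles = x$n_shuffles,
              percentile = x$percentile, is_grid = x$is_grid,
              failed = x$failed, seed = x$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
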