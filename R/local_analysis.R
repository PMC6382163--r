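#' Rectangular partitionings of the arena
#'
#' A partitioning is an ordered set of named axis-aligned rectangles.
#' Membership uses half-open rectangles `[min, max)` except at the arena's
#' outer maximum edges, which are closed, so a tiling assigns every spike
#' to exactly one region; where rectangles overlap, the first match wins.
#'
#' `strip_partition()` splits the arena into `n` equal strips along one
#' axis; `grid_partition()` into an `nx` by `ny` checkerboard.
#'
#' @param arena Arena bounding box `c(x_min, x_max, y_min, y_max)`.
#' @param n Number of strips.
#' @param axis `"x"` for west-east strips, `"y"` for south-north strips.
#' @return A data frame of class `arena_partition` with columns `name`,
#'   `xmin`, `xmax`, `ymin`, `ymax` and the arena as an attribute.
#' @export
strip_partition <- function(arena, n, axis = c("x", "y")) {
  arena <- validate_arena(arena)
  axis <- match.arg(axis)
  if (n < 1L) stop("`n` must be at least 1")
  if (axis == "x") {
    b <- seq(arena[1L], arena[2L], length.out = n + 1L)
    p <- data.frame(name = sprintf("x%d", seq_len(n)),
                    xmin = b[-(n + 1L)], xmax = b[-1L],
                    ymin = arena[3L], ymax = arena[4L])
  } else {
    b <- seq(arena[3L], arena[4L], length.out = n + 1L)
    p <- data.frame(name = sprintf("y%d", seq_len(n)),
                    xmin = arena[1L], xmax = arena[2L],
                    ymin = b[-(n + 1L)], ymax = b[-1L])
  }
  structure(p, arena = arena, class = c("arena_partition", "data.frame"))
}

#' @rdname strip_partition
#' @param nx,ny Number of columns and rows of the checkerboard.
#' @export
grid_partition <- function(arena, nx, ny) {
  arena <- validate_arena(arena)
  bx <- seq(arena[1L], arena[2L], length.out = nx + 1L)
  by <- seq(arena[3L], arena[4L], length.out = ny + 1L)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  p <- data.frame(name = sprintf("x%dy%d", g$i, g$j),
                  xmin = bx[g$i], xmax = bx[g$i + 1L],
                  ymin = by[g$j], ymax = by[g$j + 1L])
  structure(p, arena = arena, class = c("arena_partition", "data.frame"))
}

# First-match region index per spike (NA if no region matches).
assign_regions <- function(map, parts) {
  stopifnot(inherits(parts, "arena_partition"))
  arena <- attr(parts, "arena")
  x <- map$positions[, 1L]; y <- map$positions[, 2L]
  out <- rep(NA_integer_, length(x))
  for (r in seq_len(nrow(parts))) {
    x_hi <- x < parts$xmax[r] |
      (parts$xmax[r] >= arena[2L] & x <= parts$xmax[r])
    y_hi <- y < parts$ymax[r] |
      (parts$ymax[r] >= arena[4L] & y <= parts$ymax[r])
    hit <- is.na(out) & x >= parts$xmin[r] & x_hi &
      y >= parts$ymin[r] & y_hi
    out[hit] <- r
  }
  out
}

#' Mean grid score and orientation per arena partition
#'
#' The local score of a region is simply the mean of the per-spike scores
#' of the spikes inside it (zeros included), and the local orientation the
#' circular mean of their orientations on the 60-degree-periodic scale --
#' the same construction as the global averages, restricted to a region.
#' Empty regions are reported as `NA`, never as zero.
#'
#' @param scores A [score_spike_map()]/[psi_scores()] result.
#' @param map The [spike_map()] the scores were computed from.
#' @param parts An [strip_partition()]/[grid_partition()] partitioning.
#' @return A data frame of class `partition_summary` with one row per
#'   region: `name`, `n_spikes`, `mean_psi`, `theta_deg`, `n_theta`,
#'   `n_cells`.
#' @export
partition_means <- function(scores, map, parts) {
  stopifnot(inherits(scores, "spike_scores"), inherits(map, "spike_map"))
  if (length(scores$psi_hat) != nrow(map$positions))
    stop("`scores` and `map` are not aligned")
  reg <- assign_regions(map, parts)
  period <- 360 / scores$M_target
  rows <- lapply(seq_len(nrow(parts)), function(r) {
    in_r <- which(reg == r)
    if (length(in_r) == 0L)
      return(data.frame(name = parts$name[r], n_spikes = 0L,
                        mean_psi = NA_real_, theta_deg = NA_real_,
                        n_theta = 0L, n_cells = 1L))
    th <- scores$theta_deg[in_r][scores$psi_hat[in_r] > 0]
    data.frame(name = parts$name[r], n_spikes = length(in_r),
               mean_psi = mean(scores$psi_hat[in_r]),
               theta_deg = circular_mean_deg(th, period = period),
               n_theta = sum(is.finite(th)), n_cells = 1L)
  })
  out <- do.call(rbind, rows)
  structure(out, partition = parts, period = period,
            class = c("partition_summary", "data.frame"))
}

#' Pool partition summaries over cells
#'
#' Combines the per-region summaries of several cells (computed on the
#' same partitioning): the pooled score is the spike-count-weighted mean
#' of the per-cell means, and the pooled orientation the count-weighted
#' circular mean. Pooling over cells with different grid phases sharpens
#' local trends because every region then contains grid fields of some
#' cell.
#'
#' @param summaries List of [partition_means()] results over an identical
#'   partitioning.
#' @return A `partition_summary` with `n_cells` counting the cells that
#'   contributed spikes per region.
#' @export
pool_cells <- function(summaries) {
  if (!is.list(summaries) || length(summaries) < 1L)
    stop("`summaries` must be a nonempty list")
  ref <- attr(summaries[[1L]], "partition")
  for (s in summaries) {
    p <- attr(s, "partition")
    if (is.null(p) || nrow(p) != nrow(ref) || !isTRUE(all.equal(
      p[c("xmin", "xmax", "ymin", "ymax")],
      ref[c("xmin", "xmax", "ymin", "ymax")])))
      stop("all summaries must share the same partitioning")
  }
  period <- attr(summaries[[1L]], "period")
  if (is.null(period)) period <- 60
  rows <- lapply(seq_len(nrow(ref)), function(r) {
    n <- vapply(summaries, function(s) s$n_spikes[r], numeric(1))
    psi <- vapply(summaries, function(s) s$mean_psi[r], numeric(1))
    th <- vapply(summaries, function(s) s$theta_deg[r], numeric(1))
    nth <- vapply(summaries, function(s) s$n_theta[r], numeric(1))
    ok <- n > 0 & is.finite(psi)
    data.frame(
      name = ref$name[r], n_spikes = as.integer(sum(n)),
      mean_psi = if (any(ok)) sum(n[ok] * psi[ok]) / sum(n[ok]) else NA_real_,
      theta_deg = circular_mean_deg(th, period = period, weights = nth),
      n_theta = as.integer(sum(nth)), n_cells = as.integer(sum(ok)))
  })
  out <- do.call(rbind, rows)
  structure(out, partition = ref, period = period,
            class = c("partition_summary", "data.frame"))
}

#' Time series of per-spike scores
#'
#' @param times Nondecreasing spike times in seconds.
#' @param values Per-spike values (scores or orientations).
#' @return A list of class `score_series` with `times`, `values` and,
#'   after [temporal_filter()], `smoothed` and `window`.
#' @export
score_series <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have the same length")
  if (is.unsorted(times)) stop("`times` must be nondecreasing")
  structure(list(times = times, values = values, smoothed = NULL,
                 window = NULL),
            class = "score_series")
}

#' Boxcar smoothing of a score series in time
#'
#' The smoothed value at spike `k` is the mean of the values of all spikes
#' within `window / 2` seconds of `t_k` (a centered boxcar over time, not
#' over spike index; windows at the edges of the recording are truncated).
#'
#' @param series A [score_series()].
#' @param window Window length in seconds.
#' @return The series with `smoothed` filled in.
#' @export
temporal_filter <- function(series, window) {
  stopifnot(inherits(series, "score_series"))
  if (!is.finite(window) || window < 0) stop("`window` must be >= 0")
  t <- series$times
  cs <- cumsum(series$values)
  hi <- findInterval(t + window / 2, t)                    # count t_j <= t+w/2
  lo <- findInterval(t - window / 2, t, left.open = TRUE)  # count t_j <  t-w/2
  series$smoothed <- (cs[hi] - c(0, cs)[lo + 1L]) / (hi - lo)
  series$window <- window
  series
}

#' Score spikes against a reference spike map
#'
#' Adds each query spike individually to a reference map and scores it
#' there: the spike's neighbors are drawn from the reference spikes only
#' (reference spikes coinciding with the query location, i.e. the spike
#' itself when scoring a map against itself, are excluded). This
#' quantifies how well each spike fits into the grid of the reference
#' pattern -- e.g. spikes fired in darkness scored against the pattern
#' fired in light.
#'
#' @param map Query [spike_map()].
#' @param reference Reference [spike_map()] (nonempty); the shell should
#'   be detected from this map.
#' @param sh A [shell()].
#' @param M_set,M_target As in [score_spike_map()].
#' @return A `spike_scores` object for the query spikes.
#' @export
reference_scores <- function(map, reference, sh, M_set = 2:7,
                             M_target = 6L) {
  stopifnot(inherits(map, "spike_map"), inherits(reference, "spike_map"),
            inherits(sh, "shell"))
  M_set <- sort(unique(as.integer(M_set)))
  if (!M_target %in% M_set) stop("`M_set` must contain `M_target`")
  k <- .psi_kernel(map$positions, reference$positions, sh$r_inner,
                   sh$r_outer, M_set, FALSE, 1e-12)
  scores_from_psi(k$psi, k$n_neighbors, M_set, M_target, sh)
}

#' Mean scores in within-trial time blocks
#'
#' Divides each trial of length `trial_len` into `trial_len / block_len`
#' blocks and averages the per-spike scores of all spikes falling into a
#' given block, separately per trial label (e.g. `"light"` / `"dark"`).
#' Block indices are aligned to trial onsets: a spike at time `t` falls
#' into block `floor((t mod trial_len) / block_len)`.
#'
#' @param values Per-spike scores.
#' @param times Spike times in seconds.
#' @param trial_len Trial length in seconds (must be a multiple of
#'   `block_len`).
#' @param block_len Block length in seconds.
#' @param trial_labels Per-spike labels (factor or character).
#' @return A data frame with `label`, `block` (0-based), `mean_psi`, `n`;
#'   empty blocks are absent rather than reported as zero.
#' @export
block_average <- function(values, times, trial_len, block_len,
                          trial_labels) {
  if (length(values) != length(times) ||
      length(values) != length(trial_labels))
    stop("`values`, `times` and `trial_labels` must be aligned")
  if (trial_len %% block_len != 0)
    stop("`trial_len` must be divisible by `block_len`")
  block <- floor((times %% trial_len) / block_len)
  agg <- stats::aggregate(values,
                          by = list(label = as.character(trial_labels),
                                    block = block),
                          FUN = mean)
  cnt <- stats::aggregate(values,
                          by = list(label = as.character(trial_labels),
                                    block = block),
                          FUN = length)
  out <- data.frame(label = agg$label, block = as.integer(agg$block),
                    mean_psi = agg$x, n = as.integer(cnt$x))
  out[order(out$label, out$block), , drop = FALSE]
}

#' Correlation between smoothed scores and a time-varying covariate
#'
#' Pearson correlation between the temporally smoothed per-spike scores
#' and an external covariate (e.g. the lighting condition) evaluated at
#' the spike times.
#'
#' @param series A [temporal_filter()]-smoothed [score_series()].
#' @param covariate A `function(t)` returning the covariate at time `t`,
#'   or a numeric vector aligned with the spikes.
#' @return The correlation coefficient; `NA` with attribute `reason` if
#'   either series has zero variance.
#' @export
covariate_correlation <- function(series, covariate) {
  stopifnot(inherits(series, "score_series"))
  if (is.null(series$smoothed))
    stop("apply temporal_filter() before correlating")
  cv <- if (is.function(covariate)) covariate(series$times)
        else as.numeric(covariate)
  if (length(cv) != length(series$times))
    stop("covariate must be evaluable at every spike time")
  if (stats::sd(series$smoothed) == 0 || stats::sd(cv) == 0)
    return(structure(NA_real_, reason = "zero variance"))
  stats::cor(series$smoothed, cv)
}
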