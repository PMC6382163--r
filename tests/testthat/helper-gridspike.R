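# Shared builders and an independent brute-force oracle for the
# order-parameter pipeline. The oracle deliberately uses plain loops and
# trigonometric sums so that it shares no code path with the package
# implementation.

hexagon_map <- function(ell = 1, orientation_deg = 0, center = c(0, 0),
                        arena = c(-3, 3, -3, 3)) {
  ang <- (orientation_deg + seq(0, 300, by = 60)) * pi / 180
  pos <- rbind(center,
               cbind(center[1] + ell * cos(ang), center[2] + ell * sin(ang)))
  spike_map(pos, arena = arena)
}

random_map <- function(n, seed, arena = c(0, 1, 0, 1)) {
  set.seed(seed)
  spike_map(runif(n, arena[1], arena[2]), runif(n, arena[3], arena[4]),
            arena = arena)
}

brute_neighbor_angles <- function(map, k, sh) {
  pos <- unname(map$positions)
  out <- numeric(0)
  for (j in seq_len(nrow(pos))) {
    if (j == k) next
    dx <- pos[j, 1] - pos[k, 1]
    dy <- pos[j, 2] - pos[k, 2]
    d <- sqrt(dx^2 + dy^2)
    if (d >= sh$r_inner && d <= sh$r_outer) out <- c(out, atan2(dy, dx))
  }
  out
}

brute_scores <- function(map, sh, M_set = 2:7, M_target = 6) {
  n <- nrow(map$positions)
  psi_hat <- numeric(n)
  theta <- rep(NA_real_, n)
  nn <- integer(n)
  for (k in seq_len(n)) {
    ang <- brute_neighbor_angles(map, k, sh)
    nn[k] <- length(ang)
    if (length(ang) == 0) next
    mags <- sapply(M_set, function(M) Mod(mean(exp(1i * M * ang))))
    names(mags) <- M_set
    tgt <- mags[[as.character(M_target)]]
    if (all(mags[names(mags) != as.character(M_target)] < tgt))
      psi_hat[k] <- tgt
    z6 <- mean(exp(1i * M_target * ang))
    if (Mod(z6) > 0) theta[k] <- Arg(z6) / M_target * 180 / pi
  }
  list(psi_hat = psi_hat, theta_deg = theta, n_neighbors = nn)
}

# first uniform 2000-spike map (scanning seeds upward) on which
# second-peak spacing detection fails
uniform_failing_map <- function() {
  for (seed in 1:100) {
    set.seed(seed)
    m <- spike_map(runif(2000), runif(2000), arena = c(0, 1, 0, 1))
    bad <- tryCatch({
      detect_spacing(distance_histogram(m))
      FALSE
    }, gridspike_spacing_error = function(e) TRUE)
    if (bad) return(m)
  }
  stop("no failing uniform map found in 100 seeds")
}

# wrap an angle difference onto (-period/2, period/2]
wrap_half <- function(x, period = 60) {
  y <- x - period * floor(x / period)
  ifelse(y > period / 2, y - period, y)
}
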