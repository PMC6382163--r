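test_that("a single arena-wide region reproduces the global averages", {
  m <- generate_grid_map(grid_spec(n_spikes = 500, seed = 1))
  s <- psi_scores(m)
  g <- global_scores(s)
  parts <- strip_partition(m$arena, 1, axis = "x")
  pm <- partition_means(s, m, parts)
  expect_equal(nrow(pm), 1)
  expect_equal(pm$mean_psi, g$Psi)
  expect_equal(pm$theta_deg, g$Theta_deg, tolerance = 1e-12)
  expect_equal(pm$n_spikes, 500L)
})

test_that("partition membership tiles the arena without loss", {
  m <- generate_grid_map(grid_spec(n_spikes = 400, seed = 2))
  s <- psi_scores(m)
  parts <- grid_partition(m$arena, 3, 2)
  pm <- partition_means(s, m, parts)
  expect_equal(sum(pm$n_spikes), 400L)
  ok <- pm$n_spikes > 0
  expect_equal(sum(pm$mean_psi[ok] * pm$n_spikes[ok]), sum(s$psi_hat),
               tolerance = 1e-9)
})

test_that("empty regions are flagged undefined, never zero", {
  m <- spike_map(c(0.1, 0.15), c(0.1, 0.2), arena = c(0, 1, 0, 1))
  s <- score_spike_map(m, shell(0.5))
  parts <- strip_partition(m$arena, 4, axis = "x")
  pm <- partition_means(s, m, parts)
  expect_true(all(is.na(pm$mean_psi[pm$n_spikes == 0])))
  expect_gte(sum(pm$n_spikes == 0), 2)
})

test_that("east-side jitter produces a west-to-east gridness gradient", {
  # spacing well below the strip width so each strip samples many fields
  drops <- vapply(1:10, function(i) {
    m <- generate_grid_map(grid_spec(ell = 0.25, seed = 700 + i),
                           jitter_sigma = 0.1,
                           jitter_region = c(0.5, Inf, -Inf, Inf))
    s <- psi_scores(m, shell_mode = "cutoff")
    pm <- partition_means(s, m, strip_partition(m$arena, 3, axis = "x"))
    all(diff(pm$mean_psi) < 0)
  }, logical(1))
  expect_gte(sum(drops), 8)
})

test_that("pooling cells is the identity for one or identical cells", {
  m <- generate_grid_map(grid_spec(n_spikes = 400, seed = 3))
  s <- psi_scores(m)
  pm <- partition_means(s, m, strip_partition(m$arena, 3, axis = "y"))
  p1 <- pool_cells(list(pm))
  expect_equal(p1$mean_psi, pm$mean_psi)
  expect_equal(p1$theta_deg, pm$theta_deg, tolerance = 1e-9)
  p3 <- pool_cells(list(pm, pm, pm))
  expect_equal(p3$mean_psi, pm$mean_psi)
  expect_equal(p3$n_spikes, 3L * pm$n_spikes)
  expect_equal(p3$n_cells, rep(3L, 3))

  other <- partition_means(s, m, strip_partition(m$arena, 4, axis = "y"))
  expect_error(pool_cells(list(pm, other)), "same partitioning")
})

test_that("pooling an ensemble sharpens the west-east trend", {
  summaries <- lapply(1:6, function(i) {
    m <- generate_grid_map(grid_spec(seed = 800 + i), jitter_sigma = 0.2,
                           jitter_region = c(0.5, Inf, -Inf, Inf))
    s <- psi_scores(m, shell_mode = "cutoff")
    partition_means(s, m, strip_partition(m$arena, 3, axis = "x"))
  })
  pooled <- pool_cells(summaries)
  expect_true(all(diff(pooled$mean_psi) < 0))
})

test_that("temporal filtering is a centered boxcar over time", {
  ser <- score_series(times = c(0, 1, 2, 10, 11), values = c(1, 2, 3, 4, 5))
  out <- temporal_filter(ser, window = 2)
  expect_equal(out$smoothed, c(1.5, 2, 2.5, 4.5, 4.5))
  # constant scores stay constant
  cs <- temporal_filter(score_series(1:50, rep(0.3, 50)), window = 7)
  expect_equal(cs$smoothed, rep(0.3, 50))
  # zero window is the identity
  id <- temporal_filter(ser, window = 0)
  expect_equal(id$smoothed, ser$values)
  # commutes with time translation
  sh <- temporal_filter(score_series(ser$times + 100, ser$values), 2)
  expect_equal(sh$smoothed, out$smoothed)
  expect_error(temporal_filter(score_series(c(2, 1), c(0, 0)), 1),
               "nondecreasing")
})

test_that("scoring a map against itself matches the direct pipeline", {
  m <- generate_grid_map(grid_spec(n_spikes = 400, seed = 4))
  sh <- shell(0.5)
  direct <- score_spike_map(m, sh)
  via_ref <- reference_scores(m, m, sh)
  expect_equal(via_ref$psi_hat, direct$psi_hat, tolerance = 1e-12)
  expect_equal(via_ref$theta_deg, direct$theta_deg, tolerance = 1e-12)
  expect_identical(via_ref$n_neighbors, direct$n_neighbors)
})

test_that("query spikes outside the reference shell score zero", {
  ref <- hexagon_map(ell = 0.5, arena = c(-3, 3, -3, 3))
  q <- spike_map(c(2.5, 0), c(2.5, 0), arena = c(-3, 3, -3, 3))
  s <- reference_scores(q, ref, shell(0.5))
  expect_equal(s$n_neighbors[1], 0L)
  expect_equal(s$psi_hat[1], 0)
  # the second query sits on the reference center: six hexagon neighbors
  expect_equal(s$psi_hat[2], 1, tolerance = 1e-12)
})

test_that("block averages group spikes by within-trial time blocks", {
  times <- seq(1, 480, by = 1)                  # 4 trials of 120 s
  labels <- rep(rep(c("light", "dark"), each = 120), 2)
  vals <- ifelse(labels == "light", 0.5, 0.1)
  ba <- block_average(vals, times, trial_len = 120, block_len = 10, labels)
  expect_equal(sort(unique(ba$block)), 0:11)
  expect_equal(nrow(ba), 24)
  expect_true(all(ba$mean_psi[ba$label == "light"] == 0.5))
  expect_true(all(ba$mean_psi[ba$label == "dark"] == 0.1))
  expect_error(block_average(vals, times, 120, 11, labels), "divisible")

  const <- block_average(rep(1, 480), times, 120, 10, labels)
  expect_true(all(const$mean_psi == 1))
})

test_that("covariate correlation behaves at its extremes", {
  ser <- temporal_filter(score_series(1:200, runif(200)), window = 10)
  expect_equal(covariate_correlation(ser, ser$smoothed), 1)
  flat <- temporal_filter(score_series(1:50, rep(1, 50)), window = 4)
  r <- covariate_correlation(flat, function(t) t %% 2)
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "variance")
})

test_that("light-dark alternation with dark degradation yields positive r", {
  pos <- vapply(1:20, function(i) {
    spec <- grid_spec(seed = 900 + i)
    n <- 1200
    times <- seq_len(n)
    light <- (floor((times - 1) / 120) %% 2) == 0
    set.seed(1900 + i)
    mg <- generate_grid_map(grid_spec(seed = 900 + i, n_spikes = n))
    a <- spec$arena
    px <- ifelse(light, mg$positions[, 1], runif(n, a[1], a[2]))
    py <- ifelse(light, mg$positions[, 2], runif(n, a[3], a[4]))
    m <- spike_map(px, py, times = times, arena = a)
    s <- psi_scores(m, shell_mode = "cutoff")
    ser <- temporal_filter(score_series(times, s$psi_hat), window = 60)
    covariate_correlation(ser, as.numeric(light)) > 0
  }, logical(1))
  expect_gte(sum(pos), 17)
})
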