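test_that("lattice centers form a triangular grid with the exact spacing", {
  spec <- grid_spec(ell = 0.5, seed = 1, phase = c(0, 0))
  centers <- hexagonal_field_centers(spec)
  d <- as.matrix(dist(centers))
  diag(d) <- Inf
  expect_equal(min(d), 0.5, tolerance = 1e-9)
  # an interior center has exactly six neighbors at distance ell
  mid <- which.min((centers[, 1] - 0.5)^2 + (centers[, 2] - 0.5)^2)
  expect_equal(sum(abs(d[mid, ] - 0.5) < 1e-9), 6)
  # margin: fields beyond the arena border are kept
  expect_true(any(centers[, 1] < 0) && any(centers[, 1] > 1))
})

test_that("lattice bonds realize the requested orientation", {
  spec <- grid_spec(ell = 0.4, orientation = 10, seed = 1, phase = c(0, 0))
  centers <- hexagonal_field_centers(spec)
  d <- as.matrix(dist(centers))
  mid <- which.min((centers[, 1] - 0.5)^2 + (centers[, 2] - 0.5)^2)
  nb <- which(abs(d[mid, ] - 0.4) < 1e-9)
  ang <- atan2(centers[nb, 2] - centers[mid, 2],
               centers[nb, 1] - centers[mid, 1]) * 180 / pi
  expect_equal(wrap_half(ang - 10), rep(0, 6), tolerance = 1e-9)
})

test_that("spike sampling hits the exact count inside the arena", {
  spec <- grid_spec(n_spikes = 777, seed = 5)
  m <- generate_grid_map(spec)
  expect_equal(nrow(m$positions), 777)
  a <- m$arena
  expect_true(all(m$positions[, 1] >= a[1] & m$positions[, 1] <= a[2] &
                    m$positions[, 2] >= a[3] & m$positions[, 2] <= a[4]))
})

test_that("vanishing field width collapses spikes onto the centers", {
  spec <- grid_spec(field_sigma = 1e-9, n_spikes = 200, seed = 6,
                    phase = c(0.05, 0.05))
  centers <- hexagonal_field_centers(spec)
  m <- sample_grid_spikes(centers, spec)
  d <- sqrt(outer(m$positions[, 1], centers[, 1], "-")^2 +
              outer(m$positions[, 2], centers[, 2], "-")^2)
  expect_lt(max(apply(d, 1, min)), 1e-6)
})

test_that("generators are deterministic given the seed", {
  m1 <- generate_grid_map(grid_spec(seed = 7), jitter_sigma = 0.1)
  m2 <- generate_grid_map(grid_spec(seed = 7), jitter_sigma = 0.1)
  expect_identical(m1$positions, m2$positions)
  t1 <- temporal_transition(grid_spec(seed = 8))
  t2 <- temporal_transition(grid_spec(seed = 8))
  expect_identical(t1$positions, t2$positions)
})

test_that("field jitter displaces by the Rayleigh mean and honors regions", {
  centers <- hexagonal_field_centers(grid_spec(seed = 1, phase = c(0, 0)))
  expect_identical(jitter_fields(centers, 0), centers)

  set.seed(10)
  big <- matrix(runif(20000), ncol = 2)
  moved <- jitter_fields(big, jitter_sigma = 0.05)
  disp <- sqrt(rowSums((moved - big)^2))
  expect_equal(mean(disp), 0.05 * sqrt(pi / 2), tolerance = 0.02)

  east <- jitter_fields(centers, 0.1, region = c(0.5, Inf, -Inf, Inf),
                        seed = 3)
  west <- centers[, 1] < 0.5
  expect_identical(east[west, ], centers[west, ])
  expect_false(any(east[!west, 1] == centers[!west, 1]))
})

test_that("shearing is the area-preserving horizontal map", {
  centers <- hexagonal_field_centers(grid_spec(seed = 2, phase = c(0, 0)))
  expect_equal(shear_fields(centers, 0, c(0, 1, 0, 1)), centers)
  sheared <- shear_fields(centers, 0.3, c(0, 1, 0, 1))
  expect_equal(sheared[, 2], centers[, 2])
  expect_equal(sheared[, 1], centers[, 1] + 0.3 * (centers[, 2] - 0.5))
  # determinant-1 transform: pairwise areas preserved
  tri <- function(p) abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                           (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
  expect_equal(tri(sheared[1:3, ]), tri(centers[1:3, ]), tolerance = 1e-12)
})

test_that("background replacement keeps the spike count fixed", {
  m <- generate_grid_map(grid_spec(n_spikes = 400, seed = 9))
  expect_identical(add_background(m, 0), m)
  half <- add_background(m, 0.5, seed = 4)
  expect_equal(nrow(half$positions), 400)
  changed <- rowSums(half$positions != m$positions) > 0
  expect_equal(sum(changed), 200)
  all_bg <- add_background(m, 1, seed = 5)
  expect_equal(mean(rowSums(all_bg$positions != m$positions) > 0), 1)
  expect_error(add_background(m, 1.2), "fraction")
})

test_that("abrupt orientation change shows up as a north-south contrast", {
  # spacing well below the arena size, so each half holds several rows of
  # fields with single-orientation shells
  ok <- vapply(1:6, function(i) {
    m <- orientation_variants(grid_spec(ell = 0.25, seed = 20 + i),
                              mode = "abrupt", delta = 15)
    s <- psi_scores(m, shell_mode = "cutoff")
    pm <- partition_means(s, m, strip_partition(m$arena, 3, axis = "y"))
    contrast <- wrap_half(pm$theta_deg[3] - pm$theta_deg[1])
    abs(contrast - 15) < 5
  }, logical(1))
  expect_gte(sum(ok), 5)
})

test_that("drifting orientation increases monotonically to the north", {
  ok <- vapply(1:6, function(i) {
    m <- orientation_variants(grid_spec(ell = 0.25, seed = 40 + i),
                              mode = "drift", delta = 12, n_strips = 6)
    s <- psi_scores(m, shell_mode = "cutoff")
    pm <- partition_means(s, m, strip_partition(m$arena, 4, axis = "y"))
    all(diff(pm$theta_deg) > -2) &&
      wrap_half(pm$theta_deg[4] - pm$theta_deg[1]) > 4
  }, logical(1))
  expect_gte(sum(ok), 5)
  expect_error(orientation_variants(grid_spec(seed = 1), delta = 31),
               "delta")
})

test_that("temporal transitions stamp times at the firing rate", {
  m <- temporal_transition(grid_spec(seed = 30), n_uniform = 1000,
                           n_grid = 1000, rate_hz = 1)
  expect_equal(nrow(m$positions), 2000)
  expect_equal(m$times, 1:2000)
  pure <- temporal_transition(grid_spec(seed = 31), n_uniform = 0,
                              n_grid = 500)
  s <- psi_scores(pure)
  expect_gt(mean(s$psi_hat), 0.2)
  half <- temporal_transition(grid_spec(seed = 32), rate_hz = 2)
  expect_equal(max(half$times), 1000)
})
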