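test_that("neighbor angles use the positive horizontal reference axis", {
  m <- spike_map(c(0, 1), c(0, 0), arena = c(-2, 2, -2, 2))
  expect_equal(neighbor_angles(m, 1, shell(1, 0.9, 1.1)), 0)

  m2 <- spike_map(c(0, 0, 0), c(0, 1, -1), arena = c(-2, 2, -2, 2))
  expect_equal(neighbor_angles(m2, 1, shell(1, 0.9, 1.1)),
               c(pi / 2, -pi / 2))

  expect_error(neighbor_angles(m, 5, shell(1, 0.9, 1.1)), "index")
  expect_error(shell(1, 1.2, 1.1), "r_inner")
})

test_that("neighbor angles agree with a brute-force pair scan", {
  m <- random_map(200, seed = 11)
  sh <- shell(0.3)
  for (k in c(1, 57, 200)) {
    expect_equal(neighbor_angles(m, k, sh), brute_neighbor_angles(m, k, sh))
  }
})

test_that("psi_m is the normalized complex sum over neighbor angles", {
  expect_equal(psi_m(0, 6), 1 + 0i)
  hexa <- seq(0, 300, by = 60) * pi / 180
  expect_equal(psi_m(hexa, 6), 1 + 0i, tolerance = 1e-12)
  # direct complex-sum value, frozen from an independent evaluation
  expect_equal(Mod(psi_m(c(10, 70, 130, 37) * pi / 180, 6)),
               0.518028769847117, tolerance = 1e-12)
  expect_true(is.na(psi_m(numeric(0), 6)))
  expect_error(psi_m(0.3, 1.5), "integer")
  set.seed(4)
  for (i in 1:25) {
    ang <- runif(sample(1:40, 1), -pi, pi)
    for (M in 2:7) expect_lte(Mod(psi_m(ang, M)), 1 + 1e-12)
  }
})

test_that("competing symmetries suppress the grid score", {
  # two opposite neighbors: |psi6| = 1 but |psi2| = 1, a tie -> 0
  m <- spike_map(c(0, 1, -1), c(0, 0, 0), arena = c(-2, 2, -2, 2))
  p <- symmetry_profile(m, 1, shell(1, 0.9, 1.1))
  expect_equal(Mod(p$psi[["6"]]), 1, tolerance = 1e-12)
  expect_equal(Mod(p$psi[["2"]]), 1, tolerance = 1e-12)
  expect_equal(psi_hat(p), 0)

  # collinear fields: large |psi6| but 2-fold symmetry dominates
  m2 <- spike_map(c(0, 1, -1, 2, -2), c(0, 0, 0, 0, 0),
                  arena = c(-3, 3, -3, 3))
  p2 <- symmetry_profile(m2, 1, shell(1, 0.9, 2.1))
  expect_gt(Mod(p2$psi[["6"]]), 0.5)
  expect_equal(psi_hat(p2), 0)

  # weakly jittered hexagon corners: hexagonal symmetry strictly dominant
  set.seed(7)
  ang <- seq(0, 300, by = 60) + runif(6, -2, 2)
  pos <- rbind(c(0, 0), cbind(cos(ang * pi / 180), sin(ang * pi / 180)))
  m3 <- spike_map(pos, arena = c(-2, 2, -2, 2))
  p3 <- symmetry_profile(m3, 1, shell(1, 0.9, 1.1))
  expect_gt(psi_hat(p3), 0.98)
  mags <- Mod(p3$psi)
  expect_true(all(mags[names(mags) != "6"] < mags[["6"]]))
  expect_equal(psi_hat(p3), mags[["6"]])
})

test_that("zero-neighbor spikes score zero with an explicit flag", {
  m <- spike_map(c(0, 5), c(0, 5), arena = c(-1, 6, -1, 6))
  p <- symmetry_profile(m, 1, shell(1, 0.9, 1.1))
  expect_equal(p$n_neighbors, 0L)
  v <- psi_hat(p)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "no_neighbors"))
  expect_true(is.na(spike_orientation(p)))
})

test_that("spike orientation wraps the 60-degree period onto (-30, 30]", {
  m10 <- hexagon_map(orientation_deg = 10)
  expect_equal(spike_orientation(symmetry_profile(m10, 1, shell(1))), 10,
               tolerance = 1e-9)
  m40 <- hexagon_map(orientation_deg = 40)
  expect_equal(spike_orientation(symmetry_profile(m40, 1, shell(1))), -20,
               tolerance = 1e-9)
  # arbitrary profiles stay inside the half-open interval
  set.seed(12)
  for (i in 1:20) {
    mm <- random_map(40, seed = 100 + i)
    s <- score_spike_map(mm, shell(0.3))
    th <- s$theta_deg[is.finite(s$theta_deg)]
    expect_true(all(th > -30 & th <= 30))
  }
})

test_that("score_spike_map matches the per-spike brute-force oracle", {
  # exact hexagon: the center spike scores 1
  m <- hexagon_map(ell = 0.6, arena = c(-2, 2, -2, 2))
  s <- score_spike_map(m, shell(0.6))
  expect_equal(s$psi_hat[1], 1, tolerance = 1e-12)

  for (seed in c(3, 19)) {
    mm <- random_map(300, seed = seed)
    sh <- shell(0.25)
    got <- score_spike_map(mm, sh)
    want <- brute_scores(mm, sh)
    expect_equal(got$psi_hat, want$psi_hat, tolerance = 1e-12)
    expect_equal(got$theta_deg, want$theta_deg, tolerance = 1e-12)
    expect_identical(got$n_neighbors, want$n_neighbors)
    expect_true(all(Mod(got$psi[got$n_neighbors > 0, ]) <= 1 + 1e-12))
  }
})

test_that("global averages follow the per-spike definitions", {
  m <- random_map(50, seed = 5)
  s <- score_spike_map(m, shell(1e-6, 1e-7, 2e-7))  # nobody has neighbors
  g <- global_scores(s)
  expect_equal(g$Psi, 0)
  expect_true(is.na(g$Theta_deg))

  # circular mean on the 60-degree circle: {29, -29} -> 30, not 0
  expect_equal(circular_mean_deg(c(29, -29)), 30, tolerance = 1e-9)

  mm <- generate_grid_map(grid_spec(n_spikes = 400, seed = 21))
  s2 <- psi_scores(mm)
  g2 <- global_scores(s2)
  expect_equal(g2$Psi, mean(s2$psi_hat))
  th <- s2$theta_deg[s2$psi_hat > 0]
  z <- sum(exp(1i * 6 * th * pi / 180))          # vector-sum oracle
  expect_equal(g2$Theta_deg, Arg(z) / 6 * 180 / pi, tolerance = 1e-12)
  g_all <- global_scores(s2, theta_spikes = "all")
  expect_true(is.finite(g_all$Theta_deg))
  expect_gte(g_all$n_theta, g2$n_theta)
})

test_that("scores are invariant under translation, scaling and rotation", {
  m <- generate_grid_map(grid_spec(n_spikes = 300, seed = 31))
  sh <- shell(0.5)
  base <- score_spike_map(m, sh)

  shift <- spike_map(m$positions[, 1] + 0.37, m$positions[, 2] - 0.21,
                     arena = m$arena + c(0.37, 0.37, -0.21, -0.21))
  s_shift <- score_spike_map(shift, sh)
  expect_equal(s_shift$psi_hat, base$psi_hat, tolerance = 1e-9)
  expect_equal(s_shift$theta_deg, base$theta_deg, tolerance = 1e-9)

  sc <- 2.5
  scaled <- spike_map(m$positions * sc, arena = m$arena * sc)
  s_scaled <- score_spike_map(scaled, shell(sh$ell * sc))
  expect_equal(s_scaled$psi_hat, base$psi_hat, tolerance = 1e-9)
  expect_equal(s_scaled$theta_deg, base$theta_deg, tolerance = 1e-9)

  for (alpha in c(17, 45, 90)) {
    a <- alpha * pi / 180
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    pos <- t(R %*% t(m$positions))
    rot <- spike_map(pos, arena = c(range(pos[, 1]) + c(-0.01, 0.01),
                                    range(pos[, 2]) + c(-0.01, 0.01)))
    s_rot <- score_spike_map(rot, sh)
    expect_equal(s_rot$psi_hat, base$psi_hat, tolerance = 1e-9)
    ok <- is.finite(base$theta_deg)
    expect_equal(wrap_half(s_rot$theta_deg[ok] - base$theta_deg[ok] - alpha),
                 rep(0, sum(ok)), tolerance = 1e-6)
  }

  # reflection about the horizontal axis negates orientations
  refl <- spike_map(m$positions[, 1], -m$positions[, 2],
                    arena = c(m$arena[1], m$arena[2], -m$arena[4],
                              -m$arena[3]))
  s_refl <- score_spike_map(refl, sh)
  expect_equal(s_refl$psi_hat, base$psi_hat, tolerance = 1e-9)
  ok <- is.finite(base$theta_deg)
  expect_equal(wrap_half(s_refl$theta_deg[ok] + base$theta_deg[ok]),
               rep(0, sum(ok)), tolerance = 1e-6)
})
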