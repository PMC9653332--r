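cfg <- sim_config(seed = 1L)

test_that("pair geometry: chi, surface gap and normalized overlap coordinate", {
  g <- pair_geometry(c(0, 0, 0), 10, c(20, 0, 0), 10)
  expect_equal(g$chi, 1)
  expect_equal(g$d, 0)             # surfaces just touching
  expect_equal(g$s, 0.1)           # (0 - (-1)) / 10
  expect_equal(g$min_dist, -1)
  g2 <- pair_geometry(c(0, 0, 0), 10, c(11, 0, 0), 2)
  expect_equal(g2$chi, 3)          # (10/2)(1/10 + 1/2)
  g3 <- pair_geometry(c(0, 0, 0), 10, c(19, 0, 0), 10)
  expect_equal(g3$s, 0, tolerance = 1e-12)  # d = min_dist
  expect_error(pair_geometry(c(0, 0, 0), 10, c(0, 0, 0), 10), "coincident")
})

test_that("force law: continuity at s = 0, matching-constant cancellation, Gaussian decay", {
  st_cc <- list(F_rep = cfg$F_rep_cc, F_adh = cfg$F_adh_cc)
  # x0 e^{-lambda x0^2} - v0 = 0 by construction of the matching constants
  x0 <- sqrt(1 / (2 * cfg$lambda))
  v0 <- x0 * exp(-cfg$lambda * x0^2)
  expect_equal(x0 * exp(-cfg$lambda * x0^2) - v0, 0)
  # both branches vanish at the equilibrium gap
  g_eq <- pair_geometry(c(0, 0, 0), 10, c(19, 0, 0), 10)
  expect_equal(pair_force(g_eq, st_cc, cfg$lambda), c(0, 0, 0),
               tolerance = 1e-14)
  eps <- 1e-8
  g_m <- pair_geometry(c(0, 0, 0), 10, c(19 - eps, 0, 0), 10)
  g_p <- pair_geometry(c(0, 0, 0), 10, c(19 + eps, 0, 0), 10)
  expect_lt(max(abs(pair_force(g_m, st_cc, cfg$lambda))), 1e-10)
  expect_lt(max(abs(pair_force(g_p, st_cc, cfg$lambda))), 1e-10)
  # far field: negligible at s >= 3
  g_far <- pair_geometry(c(0, 0, 0), 10, c(49, 0, 0), 10)
  expect_lt(max(abs(pair_force(g_far, st_cc, cfg$lambda))),
            1e-6 * cfg$F_adh_cc)
})

test_that("overlap repels and a small positive gap attracts", {
  st_cc <- list(F_rep = cfg$F_rep_cc, F_adh = cfg$F_adh_cc)
  g_ov <- pair_geometry(c(0, 0, 0), 10, c(15, 0, 0), 10)   # s < 0
  f_ov <- pair_force(g_ov, st_cc, cfg$lambda)
  expect_lt(f_ov[1], 0)  # pushes i away from j (j at +x)
  g_ad <- pair_geometry(c(0, 0, 0), 10, c(22, 0, 0), 10)   # s = 0.3
  f_ad <- pair_force(g_ad, st_cc, cfg$lambda)
  expect_gt(f_ad[1], 0)  # pulls i toward j
  # cell-particle: no adhesion at positive s
  st_cp <- list(F_rep = cfg$F_rep_cp, F_adh = cfg$F_adh_cp)
  expect_equal(pair_force(g_ad, st_cp, cfg$lambda), c(0, 0, 0))
})

test_that("symmetric dimer carries equal and opposite forces", {
  st <- make_state(cells_xyz = rbind(c(0, 0, 0), c(15, 0, 0)))
  f <- net_forces(st, st$config)
  expect_equal(f$f[1, ], -f$f[2, ], tolerance = 1e-12)
  expect_equal(f$fnet_cells[1], f$fnet_cells[2], tolerance = 1e-12)
})

test_that("neighbor-listed kernel matches the all-pairs R oracle on random 50-agent states", {
  for (trial in 1:3) {
    set.seed(100 + trial)
    nc <- 12L; np <- 38L
    st <- make_state(cells_xyz = matrix(rnorm(nc * 3, sd = 14), nc, 3),
                     cell_radius = runif(nc, 9, 12.5),
                     particles_xyz = matrix(rnorm(np * 3, sd = 6), np, 3),
                     lumen_seed = c(0, 0, 0))
    fb <- net_forces(st, st$config, method = "brute")
    fk <- net_forces(st, st$config, method = "kernel")
    expect_lt(max(abs(fk$f - fb$f)), 1e-9)
    # the sub-stepped integrator path (0 steps = pure force evaluation)
    ar <- lumensim:::agent_arrays(st)
    ks <- lumensim:::cpp_substeps(ar$pos, ar$radius, ar$is_cell,
                                  lumensim:::force_par(st$config), 0L,
                                  0.01, 20, st$config$skin, 0.2)
    expect_lt(max(abs(ks$f - fb$f)), 1e-9)
    expect_lt(max(abs(ks$f_cp - fb$f_cp)), 1e-9)
  }
})

test_that("three-agent forces equal the brute-force double loop to 1e-12", {
  st <- make_state(cells_xyz = rbind(c(0, 0, 0), c(16, 0, 0)),
                   particles_xyz = c(8, 6, 0), lumen_seed = c(8, 6, 0))
  fb <- net_forces(st, st$config, method = "brute")
  fk <- net_forces(st, st$config, method = "kernel")
  expect_lt(max(abs(fk$f - fb$f)), 1e-12)
})

test_that("Stokes drag and overdamped velocities", {
  expect_equal(drag_coefficient(20, 10), 62.83185, tolerance = 1e-6)
  v <- agent_velocities(matrix(c(1, 0, 0), 1, 3), 10, 20)
  expect_equal(v[1, 1], 1 / (20 * pi), tolerance = 1e-12)  # ~0.0159 um/min
  expect_equal(agent_velocities(matrix(0, 1, 3), 10, 20), matrix(0, 1, 3))
  v5 <- agent_velocities(matrix(c(1, 0, 0), 1, 3), 10, 100)
  expect_equal(v5[1, 1], v[1, 1] / 5, tolerance = 1e-12)
})

test_that("a relaxed pair settles at the equilibrium gap d = -0.1 R and stays", {
  # the restoring force vanishes as s^{3/2} (overlap) / s^2 (adhesion), so
  # convergence is algebraic: integrate 100 h and accept a small residual
  relax <- function(x2, n) {
    st <- make_state(cells_xyz = rbind(c(0, 0, 0), c(x2, 0, 0)))
    st <- step_mechanics(st, st$config, n)
    abs(st$cells$x[2] - st$cells$x[1]) - 20
  }
  d_mid <- relax(15, 60000L)    # 10 h from the overlap side
  d_end <- relax(15, 600000L)   # 100 h
  expect_equal(d_end, -1, tolerance = 0.02)
  expect_lt(abs(d_end - (-1)), abs(d_mid - (-1)))  # still approaching
  d_adh <- relax(23, 600000L)   # from the adhesive side
  expect_equal(d_adh, -1, tolerance = 0.03)
})

test_that("explicit Euler: one sub-step displaces exactly v * dt; halving dt is stable", {
  st <- make_state(cells_xyz = rbind(c(0, 0, 0), c(15, 0, 0)))
  f <- net_forces(st, st$config)
  v <- agent_velocities(f$f, c(10, 10), st$config$eta)
  st1 <- step_mechanics(st, st$config, 1L)
  moved <- cbind(st1$cells$x, st1$cells$y, st1$cells$z) -
    cbind(st$cells$x, st$cells$y, st$cells$z)
  expect_equal(moved, v * st$config$dt_mech, tolerance = 1e-12,
               ignore_attr = TRUE)
  # 1-hour relaxation endpoint changes < 1 % when dt is halved
  ar <- lumensim:::agent_arrays(st)
  fp <- lumensim:::force_par(st$config)
  a <- lumensim:::cpp_substeps(ar$pos, ar$radius, ar$is_cell, fp, 6000L,
                               0.01, 20, 0.4, 0.2)
  b <- lumensim:::cpp_substeps(ar$pos, ar$radius, ar$is_cell, fp, 12000L,
                               0.005, 20, 0.4, 0.2)
  gap_a <- a$pos[2, 1] - a$pos[1, 1]
  gap_b <- b$pos[2, 1] - b$pos[1, 1]
  expect_lt(abs(gap_a - gap_b) / abs(gap_b), 0.01)
})

test_that("trajectories rescale exactly with viscosity: (eta, dt) equals (5 eta, 5 dt)", {
  set.seed(11)
  st <- make_state(cells_xyz = matrix(rnorm(15, sd = 12), 5, 3))
  ar <- lumensim:::agent_arrays(st)
  fp <- lumensim:::force_par(st$config)
  a <- lumensim:::cpp_substeps(ar$pos, ar$radius, ar$is_cell, fp, 2000L,
                               0.01, 20, 0.4, 0.2)
  b <- lumensim:::cpp_substeps(ar$pos, ar$radius, ar$is_cell, fp, 2000L,
                               0.05, 100, 0.4, 0.2)
  expect_equal(a$pos, b$pos, tolerance = 1e-12)
})

test_that("mean interactive force averages the per-tick per-cell mean", {
  tr <- data.frame(sum_fnet = c(1, 2), n_cells = c(2, 1))
  expect_equal(mean_interactive_force(tr), 1.25)
  tr2 <- data.frame(fnet_mean = c(0.5, 0.5, 0.5))
  expect_equal(mean_interactive_force(tr2), 0.5)
  expect_error(mean_interactive_force(data.frame()), "empty")
})

test_that("luminal pressure is total cell-particle force over surface area (pN/um^2 = Pa)", {
  st <- make_state(cells_xyz = sphere_points(6, 12), cell_radius = 10,
                   lumen_seed = c(0, 0, 0),
                   particles_xyz = ball_points(5, 1))
  st$cells$polarized <- TRUE
  st$cells$lumen_id <- st$lumens$id[1]
  st$cells$fcp <- 0.1
  A <- 4 * pi * 100  # 1256.6 um^2
  expect_equal(lumen_pressure(st, st$lumens$id[1], A), 0.6 / A,
               tolerance = 1e-12)
  expect_true(is.na(lumen_pressure(st, st$lumens$id[1], 0)))
  # monotone in 1/area
  expect_gt(lumen_pressure(st, st$lumens$id[1], A / 2),
            lumen_pressure(st, st$lumens$id[1], A))
})
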