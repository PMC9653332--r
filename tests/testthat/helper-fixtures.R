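# Shared fixture builders. All fixtures are generated in code.

# a state with arbitrary hand-placed cells/particles, bypassing the scheduler
make_state <- function(cells_xyz = NULL, cell_radius = 10,
                       particles_xyz = NULL, config = sim_config(seed = 1L),
                       lumen_seed = NULL) {
  st <- init_state(config)
  if (!is.null(cells_xyz)) {
    cells_xyz <- matrix(cells_xyz, ncol = 3)
    n <- nrow(cells_xyz)
    R <- rep(cell_radius, length.out = n)
    st$cells <- data.frame(
      id = seq_len(n), x = cells_xyz[, 1], y = cells_xyz[, 2],
      z = cells_xyz[, 3], volume = 4 / 3 * pi * R^3, radius = R,
      v_birth = 4 / 3 * pi * R^3, alpha_base = 1, active = TRUE,
      polarized = FALSE, lumen_id = NA_integer_, c_steps = 0L, t_exo = 0,
      t_unfaced = 0, fnet = 0, fcp = 0)
    st$next_cell_id <- n + 1L
  }
  if (!is.null(lumen_seed)) {
    st <- create_midbody(st, lumen_seed)
  }
  if (!is.null(particles_xyz)) {
    particles_xyz <- matrix(particles_xyz, ncol = 3)
    np <- nrow(particles_xyz)
    st$particles <- data.frame(
      id = seq_len(np), x = particles_xyz[, 1], y = particles_xyz[, 2],
      z = particles_xyz[, 3],
      lumen_id = rep(if (is.null(lumen_seed)) 1L else st$lumens$id[1], np),
      fnet = 0)
    st$next_particle_id <- np + 1L
  }
  st
}

# uniform random points in a ball (rejection-free)
ball_points <- function(n, radius) {
  v <- matrix(rnorm(n * 3), n, 3)
  v / sqrt(rowSums(v^2)) * radius * runif(n)^(1 / 3)
}

# quasi-uniform points on a sphere (Fibonacci lattice)
sphere_points <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
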