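# Pairwise adhesive-repulsive mechanics, Stokes drag, overdamped velocities.
#
# The scalar pair force on receiver i from partner j multiplies the unit
# vector from i to j: negative values repel, positive values attract. With
# s = (d - min_dist)/R_i, min_dist = -0.1 R_i and d the surface gap,
#   s < 0 : -F_rep * chi * (-s)^(3/2)
#   s >= 0: -F_adh * chi * ((s + x0) e^(-lambda (s+x0)^2) - v0 e^(-lambda s^2))
# with x0 = sqrt(1/(2 lambda)) and v0 = x0 e^(-lambda x0^2), so both branches
# vanish at s = 0 and the pair equilibrates at d = min_dist. The geometric
# factor chi = (R_i/2)(1/R_i + 1/R_j) and the normalization by the receiver
# radius are kept as asymmetric quantities of the receiver.

#' Pair geometry for the interaction potential
#'
#' @param pos_i,pos_j 3-vectors, agent centers (um)
#' @param R_i,R_j radii (um); `R_i` is the force-receiving agent
#' @return a list with `chi`, `d` (surface gap), `min_dist` (`-0.1 R_i`),
#'   `s` (normalized gap), `r` (center distance) and `unit` (unit vector
#'   from i to j)
#' @export
pair_geometry <- function(pos_i, R_i, pos_j, R_j) {
  rij <- pos_j - pos_i
  r <- sqrt(sum(rij^2))
  if (r < 1e-12) stop("coincident agent centers")
  d <- r - R_i - R_j
  min_dist <- -0.1 * R_i
  list(chi = (R_i / 2) * (1 / R_i + 1 / R_j),
       d = d, min_dist = min_dist, s = (d - min_dist) / R_i,
       r = r, unit = rij / r)
}

scalar_pair_force <- function(s, chi, F_rep, F_adh, lambda) {
  x0 <- sqrt(1 / (2 * lambda))
  v0 <- x0 * exp(-lambda * x0^2)
  ifelse(s < 0,
         -F_rep * chi * (-pmin(s, 0))^1.5,
         -F_adh * chi * ((s + x0) * exp(-lambda * (s + x0)^2) -
                           v0 * exp(-lambda * s^2)))
}

#' Pairwise interaction force (reference implementation)
#'
#' Exact scalar-potential evaluation, used as the independent oracle for the
#' compiled force kernel. Strengths are magnitudes; the repulsive branch acts
#' for overlap beyond the equilibrium gap (`s < 0`) and the adhesive branch
#' for `s >= 0`.
#'
#' @param params output of [pair_geometry()]
#' @param strengths list with elements `F_rep` and `F_adh` (pN, magnitudes)
#' @param lambda matching constant of the potential
#' @return force on agent i, pN 3-vector
#' @export
pair_force <- function(params, strengths, lambda = 7) {
  f <- scalar_pair_force(params$s, params$chi, strengths$F_rep,
                         strengths$F_adh, lambda)
  f * params$unit
}

#' Stokes drag coefficient in internal units
#'
#' `6 pi eta R`, converted from SI (eta in Pa.s, R in um) to pN.min/um.
#'
#' @param eta dynamic viscosity of the matrix, Pa.s
#' @param R agent radius, um
#' @return drag coefficient, pN.min/um
#' @examples
#' drag_coefficient(20, 10)  # ~62.83
#' @export
drag_coefficient <- function(eta, R) {
  stopifnot(eta > 0, all(R >= 0))
  si_to_internal_drag(6 * pi * eta * R * 1e-6)
}

strengths_for <- function(config, class) {
  switch(class,
         cc = list(F_rep = config$F_rep_cc, F_adh = config$F_adh_cc),
         pp = list(F_rep = config$F_rep_pp, F_adh = config$F_adh_pp),
         cp = list(F_rep = config$F_rep_cp, F_adh = config$F_adh_cp),
         stop("unknown pair class"))
}

# all-pairs double loop through the R reference force; independent of the
# compiled kernel, used as oracle in tests
brute_force_net <- function(pos, radius, is_cell, config) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  fcp <- matrix(0, n, 3)
  if (n < 2L) return(list(f = f, f_cp = fcp))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      cls_ij <- if (is_cell[i] == is_cell[j]) {
        if (is_cell[i]) "cc" else "pp"
      } else "cp"
      st <- strengths_for(config, cls_ij)
      gi <- pair_geometry(pos[i, ], radius[i], pos[j, ], radius[j])
      fi <- pair_force(gi, st, config$lambda)
      gj <- pair_geometry(pos[j, ], radius[j], pos[i, ], radius[i])
      fj <- pair_force(gj, st, config$lambda)
      f[i, ] <- f[i, ] + fi
      f[j, ] <- f[j, ] + fj
      if (cls_ij == "cp") {
        if (is_cell[i]) fcp[i, ] <- fcp[i, ] + fi else fcp[j, ] <- fcp[j, ] + fj
      }
    }
  }
  list(f = f, f_cp = fcp)
}

#' Net interaction forces on all agents
#'
#' Sums the pairwise cell-cell, cell-particle and particle-particle forces
#' for every agent (drag excluded; it enters only the velocity solve). The
#' default path is the compiled neighbor-listed kernel; `method = "brute"`
#' runs the all-pairs R reference implementation.
#'
#' @param state a `sim_state`
#' @param config a [sim_config()] object
#' @param method `"kernel"` or `"brute"`
#' @return a list with `f` (n x 3 force matrix, cells first then particles),
#'   `f_cp` (cell-particle component), and magnitude vectors `fnet_cells`,
#'   `fnet_particles`
#' @export
net_forces <- function(state, config = state$config,
                       method = c("kernel", "brute")) {
  method <- match.arg(method)
  ar <- agent_arrays(state)
  if (nrow(ar$pos) == 0L)
    return(list(f = matrix(0, 0, 3), f_cp = matrix(0, 0, 3),
                fnet_cells = numeric(0), fnet_particles = numeric(0)))
  res <- if (method == "kernel") {
    cpp_forces(ar$pos, ar$radius, ar$is_cell, force_par(config))
  } else {
    brute_force_net(ar$pos, ar$radius, ar$is_cell, config)
  }
  mag <- sqrt(rowSums(res$f^2))
  list(f = res$f, f_cp = res$f_cp,
       fnet_cells = mag[seq_len(ar$n_cells)],
       fnet_particles = if (ar$n_particles > 0)
         mag[ar$n_cells + seq_len(ar$n_particles)] else numeric(0))
}

#' Overdamped agent velocities
#'
#' With inertia neglected (Re << 1), each agent's velocity is its interaction
#' force divided by its Stokes drag coefficient.
#'
#' @param f n x 3 interaction-force matrix, pN
#' @param radius agent radii, um
#' @param eta matrix viscosity, Pa.s
#' @return n x 3 velocity matrix, um/min
#' @export
agent_velocities <- function(f, radius, eta) {
  f / drag_coefficient(eta, radius)
}

#' Mean interactive cell net force of a run
#'
#' Time-average over the recorded biology steps of the per-step mean net
#' cell force (the sum of cell net-force magnitudes divided by the number of
#' cells at that step).
#'
#' @param trajectory a trajectory data frame with column `fnet_mean`, or
#'   columns `sum_fnet` and `n_cells`
#' @return mean interactive force, pN
#' @export
mean_interactive_force <- function(trajectory) {
  if (NROW(trajectory) == 0L) stop("empty trajectory record")
  if (!is.null(trajectory$fnet_mean)) return(mean(trajectory$fnet_mean))
  if (is.null(trajectory$sum_fnet) || is.null(trajectory$n_cells))
    stop("trajectory must carry fnet_mean or sum_fnet and n_cells")
  mean(trajectory$sum_fnet / trajectory$n_cells)
}

#' Luminal hydrostatic pressure
#'
#' The summed magnitudes of the cell-particle interaction forces on the
#' cells polarized to a lumen, divided by the lumen surface area. In
#' internal units 1 pN/um^2 equals exactly 1 Pa.
#'
#' @param state a `sim_state`
#' @param lumen_id integer lumen id
#' @param surface_area lumen surface area, um^2 (from volumetry)
#' @return pressure in Pa, or `NA` for a non-positive surface area
#' @export
lumen_pressure <- function(state, lumen_id, surface_area) {
  if (!is.finite(surface_area) || surface_area <= 0) return(NA_real_)
  idx <- !is.na(state$cells$lumen_id) & state$cells$lumen_id == lumen_id
  sum(state$cells$fcp[idx]) / surface_area
}
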