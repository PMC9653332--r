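# Cell cycle: exponential volume growth with a mechanosensitive,
# pressure-dependent rate; symmetric division with oriented cleavage;
# probabilistic post-mitotic quiescence (restriction point).

#' Mechanosensitive growth-rate modifier
#'
#' Piecewise-linear ramp of the fractional growth-rate increase as a function
#' of the net interaction force on a cell: 0 below `F_bottom`, `a_max` above
#' `F_top`, linear in between. `F_bottom` and `F_top` correspond to typical
#' per-cell net forces in low- and high-viscosity matrices, so the ramp
#' transduces matrix density into proliferation speed.
#'
#' @param f_net net cell force magnitude(s), pN (non-negative)
#' @param config a [sim_config()] object
#' @return modifier value(s) in `[0, a_max]` (dimensionless)
#' @examples
#' cfg <- sim_config()
#' mechano_growth_modifier(c(0.2, 0.795, 2), cfg)  # 0, 0.30, 0.60
#' @export
mechano_growth_modifier <- function(f_net, config) {
  if (any(f_net < 0)) stop("f_net must be non-negative")
  a <- (f_net - config$F_bottom) * config$a_max /
    (config$F_top - config$F_bottom)
  pmin(pmax(a, 0), config$a_max)
}

#' Growth rate of a cell
#'
#' Quiescent cells do not grow. Active cells grow at
#' `(1/T) * (1 + a_i) * alpha_base`, with `T = T_pol` when the cell is
#' polarized to a pressurized lumen (one that holds fluid under non-zero
#' force) and `T = T_ini` otherwise; `a_i` is the mechanosensitive modifier
#' of the cell's current net force and `alpha_base` its inherited lineage
#' multiplier.
#'
#' @param cell a single-row cell record (fields `active`, `fnet`, `alpha_base`)
#' @param lumen_pressurized logical: is the cell's lumen pressurized?
#' @param config a [sim_config()] object
#' @return growth rate in 1/h
#' @export
growth_rate <- function(cell, lumen_pressurized, config) {
  if (!isTRUE(cell$active)) return(0)
  T_c <- if (isTRUE(lumen_pressurized)) config$T_pol else config$T_ini
  a_i <- mechano_growth_modifier(cell$fnet, config)
  (1 / T_c) * (1 + a_i) * cell$alpha_base
}

#' Advance a cell volume by exponential growth
#'
#' Exact integral of `dV/dt = alpha V` over one step with `alpha` held
#' constant, so splitting a step in two reproduces the full step to machine
#' precision.
#'
#' @param V volume, um^3
#' @param alpha growth rate, 1/h
#' @param dt step length, minutes
#' @return updated volume, um^3
#' @export
grow_cell <- function(V, alpha, dt) {
  stopifnot(all(V > 0), dt >= 0)
  V * exp(alpha * dt / 60)
}

#' Probability of entering quiescence after division
#'
#' Proportional to the number of divisions since the lineage's last
#' polarization reset, clamped into `[0, 1]`.
#'
#' @param c_steps division count(s), non-negative integer
#' @param config a [sim_config()] object
#' @return probability in `[0, 1]`
#' @examples
#' quiescence_probability(c(0, 3, 12), sim_config())  # 0, 0.3, 1
#' @export
quiescence_probability <- function(c_steps, config) {
  stopifnot(all(c_steps >= 0))
  pmin(1, config$b * c_steps)
}

#' Apply the restriction point to a freshly created daughter cell
#'
#' Draws one uniform number; values below the daughter's quiescence
#' probability switch it to the quiescent state (`active = FALSE`), in which
#' it no longer grows or divides.
#'
#' @param daughter a single-row cell record
#' @param config a [sim_config()] object
#' @return the daughter with its `active` flag updated
#' @export
restriction_point <- function(daughter, config) {
  p <- quiescence_probability(daughter$c_steps, config)
  if (runif(1) < p) daughter$active <- FALSE
  daughter
}

#' Inherited growth-rate jitter at division
#'
#' Each daughter receives the parent's lineage multiplier scaled by
#' `1 + eps`, where `eps` is drawn from a normal distribution (sd
#' `jitter_sd`) truncated to `[-jitter_max, +jitter_max]` by rejection.
#' With `jitter_sd = 0` the parent multiplier is inherited unchanged.
#'
#' @param parent_multiplier the parent's multiplier (> 0)
#' @param config a [sim_config()] object
#' @return the daughter multiplier
#' @export
daughter_rate_jitter <- function(parent_multiplier, config) {
  stopifnot(parent_multiplier > 0)
  if (config$jitter_sd == 0) return(parent_multiplier)
  repeat {
    eps <- rnorm(1, 0, config$jitter_sd)
    if (abs(eps) <= config$jitter_max) break
  }
  parent_multiplier * (1 + eps)
}

# Random unit vector; for polarized cells, a random direction perpendicular
# to the cell-to-lumen axis (the normal of a random cleavage plane containing
# that axis). Draw order: 3 normals per attempt.
division_direction <- function(polarized, axis = NULL) {
  repeat {
    v <- rnorm(3)
    if (polarized) {
      u <- axis / sqrt(sum(axis^2))
      v <- v - sum(v * u) * u
    }
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(v / nv)
  }
}

#' Divide a cell if it has doubled its birth volume
#'
#' Returns `NULL` when the cell has not yet reached twice its volume at
#' birth. Otherwise two daughters are produced at
#' `x_parent +/- (R_c - R_c/2^(1/3)) n`, each with half the parent volume
#' (hence radius `R_c / 2^(1/3)`), secretion timer reset and independently
#' jittered growth multipliers. Daughters of a polarized parent carry the
#' incremented division counter; a nonpolarized parent is founding a new
#' lumen at this division, so its count resets and the daughters start at
#' one — the route by which escaped lineages avoid inherited quiescence. For a
#' nonpolarized parent the orientation `n` is uniform on the sphere; for a
#' polarized parent it is the normal of a random cleavage plane containing
#' the axis from the cell center to its lumen's center of mass, so division
#' stays in the plane of the monolayer. RNG draw order: orientation draws,
#' then the jitter of daughter 1, then of daughter 2.
#'
#' @param cell a single-row cell record
#' @param state a `sim_state` (used for the lumen center of mass)
#' @param config a [sim_config()] object
#' @return `NULL`, or a list with elements `d1`, `d2` (daughter rows without
#'   ids) and `n` (the unit orientation vector)
#' @export
maybe_divide <- function(cell, state, config) {
  if (cell$volume < 2 * cell$v_birth) return(NULL)
  axis <- NULL
  if (cell$polarized && !is.na(cell$lumen_id)) {
    lum <- state$lumens[state$lumens$id == cell$lumen_id, ]
    axis <- c(lum$sx - cell$x, lum$sy - cell$y, lum$sz - cell$z)
    if (sum(axis^2) < 1e-16) axis <- NULL  # degenerate: fall back to uniform
  }
  n <- division_direction(!is.null(axis), axis)
  R_c <- cell$radius
  off <- (R_c - R_c / 2^(1 / 3)) * n
  mk_daughter <- function(sgn) {
    d <- cell
    d$id <- NA_integer_
    d$x <- cell$x + sgn * off[1]
    d$y <- cell$y + sgn * off[2]
    d$z <- cell$z + sgn * off[3]
    d$volume <- cell$volume / 2
    d$radius <- radius_from_volume(d$volume)
    d$v_birth <- d$volume
    # a nonpolarized divider founds a new lumen: its division count resets at
    # that founding, so the daughters (count 1) escape inherited quiescence
    d$c_steps <- if (cell$polarized) cell$c_steps + 1L else 1L
    d$t_exo <- 0
    d$t_unfaced <- 0
    d$active <- TRUE
    d
  }
  d1 <- mk_daughter(+1); d2 <- mk_daughter(-1)
  d1$alpha_base <- daughter_rate_jitter(cell$alpha_base, config)
  d2$alpha_base <- daughter_rate_jitter(cell$alpha_base, config)
  list(d1 = d1, d2 = d2, n = n)
}
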