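# Midbody creation, apical-basal polarization bookkeeping, preapical-patch
# formation, pressure-gated fluid secretion.

#' Create a midbody lumen seed
#'
#' Called when an active nonpolarized cell divides: the division site becomes
#' the seed point of a new (still fluid-free) lumen, and the caller polarizes
#' the two daughters towards it.
#'
#' @param state a `sim_state`
#' @param position 3-vector, the parent cell center (um)
#' @return the state with one more lumen; its id is `state$next_lumen_id - 1`
#'   after the call
#' @export
create_midbody <- function(state, position) {
  id <- state$next_lumen_id
  state$lumens <- rbind(state$lumens, data.frame(
    id = id, sx = position[1], sy = position[2], sz = position[3],
    pap = FALSE, f_in = 0, n_pol = 0L))
  state$next_lumen_id <- id + 1L
  state
}

# Facing predicate. A cell faces a fluid-holding lumen when the gap between
# its surface and the nearest member particle's surface is below
# facing_frac * R_c; cells pushed into a second layer fall cleanly outside
# this band and depolarize. While the lumen holds no fluid (midbody stage)
# the test is against the seed point with a permissive one-radius band, so
# the nascent rosette is not disbanded before the patch closes. Vectorized
# over the rows of `cells`.
faces_lumen <- function(cells, lumen, particles, facing_frac = 0.5) {
  if (nrow(cells) == 0L) return(logical(0))
  if (nrow(particles) > 0L) {
    dx <- outer(cells$x, particles$x, "-")
    dy <- outer(cells$y, particles$y, "-")
    dz <- outer(cells$z, particles$z, "-")
    dmin <- sqrt(apply(dx^2 + dy^2 + dz^2, 1L, min))
    R_p <- particles$R_p[1]
    dmin - cells$radius - R_p < facing_frac * cells$radius
  } else {
    d <- sqrt((cells$x - lumen$sx)^2 + (cells$y - lumen$sy)^2 +
                (cells$z - lumen$sz)^2)
    d < 2 * cells$radius
  }
}

#' Update polarization flags and lumen membership
#'
#' A polarized cell that fails the facing test accrues "unfaced" time; once
#' the failure has persisted for `facing_grace` hours the cell depolarizes
#' (transient post-division excursions, which relax back into the monolayer
#' within a few hours in a low-viscosity matrix, do not strip polarity; in a
#' dense matrix second-layer residence persists and does). An escaped
#' active cell that later divides founds a new lumen, and its division
#' counter resets at that founding (see [maybe_divide()]), so the new
#' lineage escapes inherited quiescence. Nonpolarized cells that face some
#' lumen become polarized to the nearest such seed. Per-lumen
#' polarized-cell counts are refreshed.
#'
#' @param state a `sim_state`
#' @param config a [sim_config()] object
#' @return the updated state; depolarization events (cell ids) are attached
#'   as attribute `"depolarized"`
#' @export
update_polarity <- function(state, config) {
  cells <- state$cells
  depol <- integer(0)
  grace_min <- config$facing_grace * 60
  if (nrow(state$lumens) > 0L && nrow(cells) > 0L) {
    for (li in seq_len(nrow(state$lumens))) {
      lum <- state$lumens[li, ]
      members <- which(!is.na(cells$lumen_id) & cells$lumen_id == lum$id)
      if (!length(members)) next
      parts <- state$particles[state$particles$lumen_id == lum$id, ]
      parts$R_p <- rep(config$R_p, nrow(parts))
      ok <- faces_lumen(cells[members, ], lum, parts, config$facing_frac)
      cells$t_unfaced[members[ok]] <- 0
      failing <- members[!ok]
      cells$t_unfaced[failing] <- cells$t_unfaced[failing] + config$dt_bio
      lost <- failing[cells$t_unfaced[failing] >= grace_min]
      if (length(lost)) {
        depol <- c(depol, cells$id[lost])
        cells$polarized[lost] <- FALSE
        cells$lumen_id[lost] <- NA_integer_
        cells$t_unfaced[lost] <- 0
      }
    }
    # acquisition: nonpolarized cells facing some lumen join the nearest seed
    free <- which(!cells$polarized)
    if (length(free)) {
      cand_d <- matrix(Inf, length(free), nrow(state$lumens))
      for (li in seq_len(nrow(state$lumens))) {
        lum <- state$lumens[li, ]
        parts <- state$particles[state$particles$lumen_id == lum$id, ]
        parts$R_p <- rep(config$R_p, nrow(parts))
        ok <- faces_lumen(cells[free, ], lum, parts, config$facing_frac)
        d <- sqrt((cells$x[free] - lum$sx)^2 + (cells$y[free] - lum$sy)^2 +
                    (cells$z[free] - lum$sz)^2)
        cand_d[ok, li] <- d[ok]
      }
      for (k in seq_along(free)) {
        if (any(is.finite(cand_d[k, ]))) {
          li <- which.min(cand_d[k, ])
          cells$polarized[free[k]] <- TRUE
          cells$lumen_id[free[k]] <- state$lumens$id[li]
          cells$t_unfaced[free[k]] <- 0
        }
      }
    }
  }
  state$cells <- cells
  if (nrow(state$lumens) > 0L) {
    state$lumens$n_pol <- vapply(state$lumens$id, function(id)
      sum(!is.na(cells$lumen_id) & cells$lumen_id == id), integer(1))
  }
  attr(state, "depolarized") <- depol
  state
}

#' Has a lumen formed its preapical patch?
#'
#' The preapical patch (the closed multicellular arrangement required before
#' secretion can pressurize a lumen) is formed once the number of polarized
#' cells reaches `n_tc`; the flag is sticky, since fluid already secreted
#' cannot unform the patch.
#'
#' @param lumen a single-row lumen record (fields `pap`, `n_pol`)
#' @param config a [sim_config()] object
#' @return logical
#' @export
pap_formed_check <- function(lumen, config) {
  isTRUE(lumen$pap) || lumen$n_pol >= config$n_tc
}

#' Secretion pressure gate
#'
#' Cells may only secrete while the luminal force estimate is strictly below
#' the threshold `F_lim`; an empty lumen (nothing to pressurize) passes.
#' Evaluated only for lumens whose preapical patch has formed.
#'
#' @param lumen a single-row lumen record (field `f_in`)
#' @param config a [sim_config()] object
#' @return logical
#' @export
secretion_gate <- function(lumen, config) {
  lumen$f_in < config$F_lim
}

#' Luminal force estimate
#'
#' The hydrostatic-pressure proxy of a lumen: the arithmetic mean of the
#' interaction net-force magnitudes of its member fluid particles (drag
#' excluded); zero for a fluid-free lumen.
#'
#' @param state a `sim_state`
#' @param lumen_id integer lumen id
#' @return mean particle net-force magnitude, pN
#' @export
luminal_force_estimate <- function(state, lumen_id) {
  f <- state$particles$fnet[state$particles$lumen_id == lumen_id]
  if (!length(f)) 0 else mean(f)
}

#' Secrete fluid into a lumen
#'
#' One secretion event by one polarized cell. Into a fluid-free lumen,
#' `n_secrete` particles are created at the seed point, jittered by at most
#' `0.1 * R_p` to avoid coincident centers. Otherwise `n_secrete` uniformly
#' chosen existing particles are duplicated, each copy offset by
#' `R_p - R_p / 2^(1/3)` along a random unit direction (division-like
#' placement). The cell's secretion timer is reset. RNG draw order per
#' particle: (empty lumen) 3 normals then 1 uniform radius draw;
#' (duplication) 1 uniform index draw then 3 normals.
#'
#' @param state a `sim_state`
#' @param cell_id id of the secreting cell
#' @param lumen_id id of the target lumen
#' @param config a [sim_config()] object
#' @return the updated state; created particle ids attached as attribute
#'   `"secreted"`
#' @export
secrete <- function(state, cell_id, lumen_id, config) {
  R_p <- config$R_p
  members <- which(state$particles$lumen_id == lumen_id)
  lum <- state$lumens[state$lumens$id == lumen_id, ]
  new_rows <- vector("list", config$n_secrete)
  for (k in seq_len(config$n_secrete)) {
    if (!length(members) && k == 1L) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      rad <- 0.1 * R_p * runif(1)^(1 / 3)
      pos <- c(lum$sx, lum$sy, lum$sz) + rad * dir
    } else {
      pool <- rbind(state$particles[members, c("x", "y", "z")],
                    do.call(rbind, lapply(new_rows[seq_len(k - 1L)],
                                          function(r) r[, c("x", "y", "z")])))
      idx <- sample.int(nrow(pool), 1L)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      pos <- as.numeric(pool[idx, ]) + (R_p - R_p / 2^(1 / 3)) * dir
    }
    new_rows[[k]] <- data.frame(id = state$next_particle_id + k - 1L,
                                x = pos[1], y = pos[2], z = pos[3],
                                lumen_id = lumen_id, fnet = 0)
  }
  created <- vapply(new_rows, function(r) r$id, integer(1))
  state$particles <- rbind(state$particles, do.call(rbind, new_rows))
  state$next_particle_id <- state$next_particle_id + config$n_secrete
  state$cells$t_exo[state$cells$id == cell_id] <- 0
  attr(state, "secreted") <- created
  state
}
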