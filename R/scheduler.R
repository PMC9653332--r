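# Two-timescale main loop: biology (growth, division, polarity, secretion)
# every dt_bio; mechanics (forces -> overdamped velocities -> explicit Euler)
# every dt_mech, executed in compiled sub-step batches between biology ticks.

store_forces <- function(state, f, f_cp) {
  nc <- nrow(state$cells)
  np <- nrow(state$particles)
  if (nc > 0L) {
    state$cells$fnet <- sqrt(rowSums(f[seq_len(nc), , drop = FALSE]^2))
    state$cells$fcp <- sqrt(rowSums(f_cp[seq_len(nc), , drop = FALSE]^2))
  }
  if (np > 0L)
    state$particles$fnet <-
      sqrt(rowSums(f[nc + seq_len(np), , drop = FALSE]^2))
  if (nrow(state$lumens) > 0L)
    state$lumens$f_in <- vapply(state$lumens$id, function(id)
      luminal_force_estimate(state, id), numeric(1))
  state
}

#' Advance the mechanics by explicit-Euler sub-steps
#'
#' Runs `n_steps` overdamped steps of length `dt_mech`: pairwise interaction
#' forces, velocities `F / (6 pi eta R)`, and position updates, with a
#' per-step displacement cap of `cap_frac * R_p` guarding against force
#' spikes from freshly inserted particles. Net forces (and the cell-particle
#' components and per-lumen force estimates) are refreshed at the final
#' positions.
#'
#' @param state a `sim_state`
#' @param config a [sim_config()] object
#' @param n_steps number of mechanics sub-steps
#' @return the advanced state
#' @export
step_mechanics <- function(state, config = state$config, n_steps = 1L) {
  ar <- agent_arrays(state)
  n <- nrow(ar$pos)
  if (n == 0L) {
    state$t <- state$t + n_steps * config$dt_mech
    return(state)
  }
  res <- cpp_substeps(ar$pos, ar$radius, ar$is_cell, force_par(config),
                      as.integer(n_steps), config$dt_mech, config$eta,
                      config$skin, config$cap_frac * config$R_p)
  if (any(!is.finite(res$pos)))
    stop("integrity error: non-finite agent position after mechanics")
  nc <- ar$n_cells
  if (nc > 0L) {
    state$cells$x <- res$pos[seq_len(nc), 1]
    state$cells$y <- res$pos[seq_len(nc), 2]
    state$cells$z <- res$pos[seq_len(nc), 3]
  }
  if (ar$n_particles > 0L) {
    pidx <- nc + seq_len(ar$n_particles)
    state$particles$x <- res$pos[pidx, 1]
    state$particles$y <- res$pos[pidx, 2]
    state$particles$z <- res$pos[pidx, 3]
  }
  state <- store_forces(state, res$f, res$f_cp)
  state$t <- state$t + n_steps * config$dt_mech
  state
}

#' Advance the biology by one tick
#'
#' In order: (1) for each cell present at the start of the tick, in ascending
#' id order: exponential growth at its current rate, division once the birth
#' volume has doubled, the restriction point for each daughter; a dividing
#' nonpolarized cell deposits a midbody that becomes a new lumen seed and
#' polarizes its daughters. (2) Polarity update (escaped cells depolarize and
#' reset their division counter; facing cells polarize to the nearest seed).
#' (3) Preapical-patch checks. (4) Pressure-gated secretion, at most one
#' event per cell per tick; timers of non-secreting cells accrue. (5) Lumen
#' seed points move to their fluid's center of mass.
#'
#' @param state a `sim_state`
#' @param config a [sim_config()] object
#' @return the advanced state; division/secretion/depolarization events of
#'   the tick are attached as attribute `"events"`
#' @export
step_biology <- function(state, config = state$config) {
  ev_div <- list(); ev_sec <- list(); ev_dep <- list()

  # --- cell cycle -----------------------------------------------------------
  cells <- state$cells
  if (nrow(cells) > 0L) {
    pressurized <- rep(FALSE, nrow(cells))
    if (nrow(state$lumens) > 0L) {
      has_fluid <- state$lumens$id[state$lumens$f_in > 0]
      pressurized <- cells$polarized & !is.na(cells$lumen_id) &
        cells$lumen_id %in% has_fluid
    }
    a_i <- mechano_growth_modifier(cells$fnet, config)
    T_c <- ifelse(pressurized, config$T_pol, config$T_ini)
    alpha <- ifelse(cells$active, (1 / T_c) * (1 + a_i) * cells$alpha_base, 0)
    cells$volume <- grow_cell(cells$volume, alpha, config$dt_bio)
    cells$radius <- radius_from_volume(cells$volume)
    state$cells <- cells

    ids <- sort(cells$id)
    for (cid in ids) {
      ci <- which(state$cells$id == cid)
      cell <- state$cells[ci, ]
      if (!cell$active || cell$volume < 2 * cell$v_birth) next
      div <- maybe_divide(cell, state, config)
      if (is.null(div)) next
      was_nonpolarized <- !cell$polarized
      d1 <- div$d1; d2 <- div$d2
      if (was_nonpolarized) {
        state <- create_midbody(state, c(cell$x, cell$y, cell$z))
        mb <- state$next_lumen_id - 1L
        d1$polarized <- TRUE; d1$lumen_id <- mb
        d2$polarized <- TRUE; d2$lumen_id <- mb
      }
      d1 <- restriction_point(d1, config)
      d2 <- restriction_point(d2, config)
      d1$id <- state$next_cell_id
      d2$id <- state$next_cell_id + 1L
      state$next_cell_id <- state$next_cell_id + 2L
      state$cells <- rbind(state$cells[-ci, ], d1, d2)
      ev_div[[length(ev_div) + 1L]] <- data.frame(
        t = state$t, parent = cid, d1 = d1$id, d2 = d2$id,
        nx = div$n[1], ny = div$n[2], nz = div$n[3],
        midbody = was_nonpolarized)
    }
  }

  # --- polarity and preapical patches --------------------------------------
  state <- update_polarity(state, config)
  dep <- attr(state, "depolarized")
  if (length(dep))
    ev_dep[[1L]] <- data.frame(t = state$t, cell = dep)
  if (nrow(state$lumens) > 0L) {
    state$lumens$pap <- vapply(seq_len(nrow(state$lumens)), function(li)
      pap_formed_check(state$lumens[li, ], config), logical(1))
  }

  # --- gated secretion ------------------------------------------------------
  dt_exo_min <- config$dt_exo * 60
  secreted <- integer(0)
  if (nrow(state$lumens) > 0L) {
    for (li in which(state$lumens$pap)) {
      lum <- state$lumens[li, ]
      gate <- secretion_gate(lum, config)
      members <- state$cells$id[!is.na(state$cells$lumen_id) &
                                  state$cells$lumen_id == lum$id]
      for (cid in sort(members)) {
        te <- state$cells$t_exo[state$cells$id == cid]
        if (gate && te >= dt_exo_min) {
          state <- secrete(state, cid, lum$id, config)
          secreted <- c(secreted, cid)
          ev_sec[[length(ev_sec) + 1L]] <- data.frame(
            t = state$t, cell = cid, lumen = lum$id,
            particles = paste(attr(state, "secreted"), collapse = ";"))
        }
      }
    }
  }
  keep <- !(state$cells$id %in% secreted)
  state$cells$t_exo[keep] <- state$cells$t_exo[keep] + config$dt_bio

  # --- seed points follow the fluid ----------------------------------------
  if (nrow(state$lumens) > 0L && nrow(state$particles) > 0L) {
    for (li in seq_len(nrow(state$lumens))) {
      id <- state$lumens$id[li]
      m <- state$particles$lumen_id == id
      if (any(m)) {
        state$lumens$sx[li] <- mean(state$particles$x[m])
        state$lumens$sy[li] <- mean(state$particles$y[m])
        state$lumens$sz[li] <- mean(state$particles$z[m])
      }
    }
  }

  state$t_bio <- state$t_bio + config$dt_bio
  state$tick <- state$tick + 1L
  attr(state, "events") <- list(
    divisions = if (length(ev_div)) do.call(rbind, ev_div) else NULL,
    secretions = if (length(ev_sec)) do.call(rbind, ev_sec) else NULL,
    depolarizations = if (length(ev_dep)) ev_dep[[1L]] else NULL)
  state
}

observe_row <- function(state, config) {
  cells <- state$cells
  n_pap <- if (nrow(state$lumens)) sum(state$lumens$pap) else 0L
  n_blocked <- if (n_pap > 0L)
    sum(state$lumens$pap & state$lumens$f_in >= config$F_lim) else 0L
  label_lumens <- if (nrow(state$particles))
    length(unique(state$particles$lumen_id)) else 0L
  data.frame(
    t = state$t,
    n_cells = nrow(cells),
    n_active = sum(cells$active),
    n_polarized = sum(cells$polarized),
    n_particles = nrow(state$particles),
    n_lumens = label_lumens,
    n_lumens_seeded = nrow(state$lumens),
    sum_fnet = sum(cells$fnet),
    fnet_mean = if (nrow(cells)) sum(cells$fnet) / nrow(cells) else 0,
    n_pap = n_pap,
    n_gate_blocked = n_blocked)
}

volumetry_rows <- function(state, config) {
  if (nrow(state$particles) == 0L) return(NULL)
  labels <- identify_lumens(state$particles, config$R_p, config$clustering_gap)
  out <- list()
  for (cl in sort(unique(labels))) {
    sel <- labels == cl
    centers <- as.matrix(state$particles[sel, c("x", "y", "z")])
    vs <- lumen_volume_surface(centers, config$R_p, config$alpha_value,
                               config$voxel_h)
    lumen_ids <- unique(state$particles$lumen_id[sel])
    pcells <- !is.na(state$cells$lumen_id) &
      state$cells$lumen_id %in% lumen_ids
    pressure <- if (vs$area > 0) sum(state$cells$fcp[pcells]) / vs$area
      else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      t = state$t, cluster = cl, n_particles = sum(sel),
      n_source_lumens = length(lumen_ids),
      volume = vs$volume, area = vs$area, pressure = pressure)
  }
  do.call(rbind, out)
}

#' Run a full simulation
#'
#' Executes the two-timescale loop from a single founder cell until `t_sim`
#' simulated days are reached. Per-tick observables are recorded (one row per
#' biology tick plus the initial row); spatially clustered lumen volumetry,
#' surface area and pressure are recorded every `snapshot_every` minutes.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object
#' @param out_dir optional directory: trajectory, events, volumetry, resolved
#'   configuration and point-cloud snapshots are written there
#' @param quiet suppress progress messages
#' @return an object of class `lumen_sim`: list with `config`, `trajectory`,
#'   `lumen_obs`, `volumetry`, `events`, `state` (final) and `runtime_s`
#' @export
run_simulation <- function(config, out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  t0 <- proc.time()[["elapsed"]]
  state <- init_state(config)
  total_ticks <- as.integer(round(config$t_sim * 1440 / config$dt_bio))
  substeps <- as.integer(round(config$dt_bio / config$dt_mech))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  obs <- vector("list", total_ticks + 1L)
  lobs <- vector("list", total_ticks + 1L)
  vol <- list()
  evd <- list(); evs <- list(); evp <- list()
  obs[[1L]] <- observe_row(state, config)

  snap_ticks <- if (config$snapshot_every > 0)
    as.integer(round(config$snapshot_every / config$dt_bio)) else 0L

  for (tick in seq_len(total_ticks)) {
    n_before <- nrow(state$cells); p_before <- nrow(state$particles)
    state <- step_biology(state, config)
    ev <- attr(state, "events")
    if (!is.null(ev$divisions)) evd[[length(evd) + 1L]] <- ev$divisions
    if (!is.null(ev$secretions)) evs[[length(evs) + 1L]] <- ev$secretions
    if (!is.null(ev$depolarizations)) evp[[length(evp) + 1L]] <- ev$depolarizations
    # conservation audit: cells change only by division, particles by secretion
    dn <- nrow(state$cells) - n_before
    if (dn != NROW(ev$divisions))
      stop("integrity error: cell count changed without matching divisions")
    dp <- nrow(state$particles) - p_before
    if (dp != NROW(ev$secretions) * config$n_secrete)
      stop("integrity error: particle count changed without matching secretions")

    state <- step_mechanics(state, config, substeps)
    obs[[tick + 1L]] <- observe_row(state, config)
    if (nrow(state$lumens) > 0L) {
      lobs[[tick + 1L]] <- data.frame(
        t = state$t, lumen_id = state$lumens$id,
        n_particles = vapply(state$lumens$id, function(id)
          sum(state$particles$lumen_id == id), integer(1)),
        n_pol = state$lumens$n_pol, f_in = state$lumens$f_in,
        pap = state$lumens$pap,
        gate_open = state$lumens$pap & state$lumens$f_in < config$F_lim)
    }
    if (snap_ticks > 0L && tick %% snap_ticks == 0L) {
      vr <- volumetry_rows(state, config)
      if (!is.null(vr)) vol[[length(vol) + 1L]] <- vr
      if (!is.null(out_dir))
        write_snapshot_ply(state, file.path(out_dir,
          sprintf("snapshot_t%07d.ply", as.integer(round(state$t)))))
      if (!quiet)
        message(sprintf("t = %.0f min: %d cells, %d particles, %d lumens",
                        state$t, nrow(state$cells), nrow(state$particles),
                        obs[[tick + 1L]]$n_lumens))
    }
  }

  sim <- structure(list(
    config = config,
    trajectory = do.call(rbind, obs),
    lumen_obs = if (length(lobs)) do.call(rbind, lobs[!vapply(lobs, is.null, logical(1))]) else NULL,
    volumetry = if (length(vol)) do.call(rbind, vol) else NULL,
    events = list(
      divisions = if (length(evd)) do.call(rbind, evd) else NULL,
      secretions = if (length(evs)) do.call(rbind, evs) else NULL,
      depolarizations = if (length(evp)) do.call(rbind, evp) else NULL),
    state = state,
    runtime_s = proc.time()[["elapsed"]] - t0), class = "lumen_sim")
  if (!is.null(out_dir)) write_run(sim, out_dir)
  sim
}

#' @export
print.lumen_sim <- function(x, ...) {
  fin <- x$trajectory[nrow(x$trajectory), ]
  cat("<lumen_sim> eta =", x$config$eta, "Pa.s, seed =", x$config$seed,
      "|", fin$t / 1440, "days simulated\n")
  cat("  final:", fin$n_cells, "cells,", fin$n_particles, "particles,",
      fin$n_lumens, "lumens with fluid\n")
  if (!is.null(x$volumetry)) {
    vfin <- x$volumetry[x$volumetry$t == max(x$volumetry$t), ]
    cat("  largest lumen volume:", format(max(vfin$volume), digits = 4),
        "um^3 of", format(sum(vfin$volume), digits = 4), "um^3 total\n")
  }
  cat("  mean interactive cell force:",
      format(mean_interactive_force(x$trajectory), digits = 4), "pN\n")
  invisible(x)
}
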