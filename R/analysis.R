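# Lumen identification, volumetry, replicate statistics.

#' Partition fluid particles into spatial lumens
#'
#' Single-linkage clustering of particle centers: two particles are linked
#' when the gap between their surfaces is at most `clustering_gap`, i.e.
#' centers within `2 R_p + clustering_gap`. The partition is invariant under
#' particle relabeling and rigid-body motion. Where a spatial cluster joins
#' particles secreted into different seeded lumens, the fluids have merged;
#' such clusters are reported through the `"merges"` attribute.
#'
#' @param particles a particle data frame (columns `x`, `y`, `z`, optionally
#'   `lumen_id`) or an n x 3 coordinate matrix
#' @param R_p particle radius, um
#' @param clustering_gap linkage gap between particle surfaces, um
#' @return integer cluster labels (1-based), with attribute `"merges"`: a
#'   data frame of clusters spanning more than one source lumen (or `NULL`)
#' @export
identify_lumens <- function(particles, R_p, clustering_gap = 0.5 * R_p) {
  if (is.matrix(particles))
    particles <- data.frame(x = particles[, 1], y = particles[, 2],
                            z = particles[, 3])
  n <- nrow(particles)
  if (n == 0L) return(integer(0))
  if (n == 1L) {
    labels <- 1L
  } else {
    hc <- hclust(dist(particles[, c("x", "y", "z")]), method = "single")
    labels <- cutree(hc, h = 2 * R_p + clustering_gap)
  }
  merges <- NULL
  if (!is.null(particles$lumen_id)) {
    tab <- unique(data.frame(cluster = labels, source = particles$lumen_id))
    multi <- tab$cluster[duplicated(tab$cluster)]
    if (length(multi))
      merges <- tab[tab$cluster %in% unique(multi), ]
  }
  attr(labels, "merges") <- merges
  labels
}

#' Lumen volume and surface area
#'
#' Measures the fluid body of a lumen as the morphological closing of the
#' union of its particle spheres with a ball of radius `alpha_value`: gaps
#' between packed particles up to that scale are filled, and the particle
#' radius is included, so the measured body is the cavity the fluid occupies.
#' Volume and area are evaluated on a voxel grid of spacing `h` using exact
#' Euclidean distance transforms; the area is a central difference of the
#' volume under one-voxel erosion/dilation. A single particle is returned
#' analytically. The volume is nondecreasing in `alpha_value` and approaches
#' the convex-hull-like envelope as `alpha_value` grows.
#'
#' @param centers n x 3 matrix of particle centers, um
#' @param R_p particle radius, um
#' @param alpha_value closing-ball radius, um
#' @param h voxel spacing, um
#' @return list with `volume` (um^3), `area` (um^2), `h` (spacing actually
#'   used) and `method`
#' @examples
#' lumen_volume_surface(matrix(0, 1, 3), R_p = 2)  # sphere: 33.51, 50.27
#' @export
lumen_volume_surface <- function(centers, R_p, alpha_value = 2 * R_p,
                                 h = 0.5) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (nrow(centers) < 1L) stop("at least one particle required")
  if (nrow(centers) == 1L)
    return(list(volume = 4 / 3 * pi * R_p^3, area = 4 * pi * R_p^2,
                h = NA_real_, method = "analytic"))
  res <- cpp_closing_volume(centers, R_p, alpha_value, h)
  list(volume = res$volume, area = res$area, h = res$h, method = "closing")
}

#' Per-run summary metrics
#'
#' Extracts the final-architecture and whole-run quantities used in replicate
#' comparisons: final cell and (spatially clustered) lumen counts, largest
#' and total lumen volume, the day-3 to day-6 growth factor of the principal
#' lumen, the mean interactive cell force, and the fraction of post-patch
#' ticks on which the secretion gate was pressure-blocked.
#'
#' @param sim a `lumen_sim` object
#' @return a one-row data frame
#' @export
run_metrics <- function(sim) {
  stopifnot(inherits(sim, "lumen_sim"))
  traj <- sim$trajectory
  fin <- traj[nrow(traj), ]
  st <- sim$state
  cfg <- sim$config
  n_lumens <- 0L
  vol_largest <- 0; vol_total <- 0
  if (nrow(st$particles) > 0L) {
    labels <- identify_lumens(st$particles, cfg$R_p, cfg$clustering_gap)
    n_lumens <- length(unique(labels))
  }
  vol_d3 <- NA_real_; vol_d6 <- NA_real_
  if (!is.null(sim$volumetry)) {
    vv <- sim$volumetry
    vfin <- vv[vv$t == max(vv$t), ]
    vol_largest <- max(vfin$volume)
    vol_total <- sum(vfin$volume)
    principal_at <- function(day) {
      rows <- vv[abs(vv$t - day * 1440) < cfg$dt_bio / 2, ]
      if (nrow(rows)) max(rows$volume) else NA_real_
    }
    vol_d3 <- principal_at(3)
    vol_d6 <- principal_at(6)
  }
  pap_rows <- traj$n_pap > 0
  gate_blocked_frac <- if (any(pap_rows))
    mean(traj$n_gate_blocked[pap_rows] / traj$n_pap[pap_rows]) else NA_real_
  data.frame(
    eta = cfg$eta, seed = cfg$seed,
    n_cells = fin$n_cells, n_lumens = n_lumens,
    n_particles = fin$n_particles,
    vol_largest = vol_largest, vol_total = vol_total,
    vol_d3 = vol_d3, vol_d6 = vol_d6,
    vol_ratio_6_3 = if (!is.na(vol_d3) && vol_d3 > 0) vol_d6 / vol_d3
      else NA_real_,
    fbar = mean_interactive_force(traj),
    gate_blocked_frac = gate_blocked_frac,
    single_lumen = n_lumens == 1L)
}

#' Replicate summary across matrix conditions
#'
#' Aggregates per-run metrics by viscosity: medians, means, standard
#' deviations and quartiles of the largest-lumen volume, lumen count, cell
#' count and mean interactive force, plus the count of single-lumen runs.
#' For every pair of conditions the cross-condition comparisons are
#' reported: the median largest-volume difference (as a percentage of the
#' lower-viscosity condition) and the ratio of median forces.
#'
#' @param metrics a data frame of [run_metrics()] rows (or a list of
#'   `lumen_sim` objects)
#' @return list with `per_eta` and `comparisons` data frames
#' @export
replicate_summary <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics))
    metrics <- do.call(rbind, lapply(metrics, run_metrics))
  stopifnot(nrow(metrics) >= 1L)
  agg <- function(x) c(median = median(x), mean = mean(x),
                       sd = if (length(x) > 1L) sd(x) else 0,
                       q25 = unname(quantile(x, 0.25)),
                       q75 = unname(quantile(x, 0.75)))
  etas <- sort(unique(metrics$eta))
  per <- do.call(rbind, lapply(etas, function(e) {
    m <- metrics[metrics$eta == e, ]
    v <- agg(m$vol_largest); l <- agg(m$n_lumens); f <- agg(m$fbar)
    c0 <- agg(m$n_cells)
    data.frame(eta = e, n_runs = nrow(m), n_single_lumen = sum(m$single_lumen),
               vol_median = v["median"], vol_mean = v["mean"], vol_sd = v["sd"],
               vol_q25 = v["q25"], vol_q75 = v["q75"],
               lumens_median = l["median"], lumens_mean = l["mean"],
               cells_median = c0["median"], cells_mean = c0["mean"],
               fbar_median = f["median"], fbar_mean = f["mean"],
               fbar_sd = f["sd"], row.names = NULL)
  }))
  comp <- NULL
  if (length(etas) > 1L) {
    pairs <- utils::combn(etas, 2L)
    comp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      lo <- per[per$eta == pairs[1, k], ]
      hi <- per[per$eta == pairs[2, k], ]
      data.frame(
        eta_low = lo$eta, eta_high = hi$eta,
        vol_median_diff_pct = 100 * (1 - hi$vol_median / lo$vol_median),
        vol_sd_ratio = lo$vol_sd / hi$vol_sd,
        fbar_median_ratio = hi$fbar_median / lo$fbar_median,
        fbar_sd_ratio = hi$fbar_sd / lo$fbar_sd,
        lumens_median_low = lo$lumens_median,
        lumens_median_high = hi$lumens_median)
    }))
  }
  list(per_eta = per, comparisons = comp)
}
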