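# Configuration and unit system.
#
# Internal units are micrometres, minutes and piconewtons; configuration
# values are accepted in the units customary for each quantity (viscosity in
# Pa.s, cycle constants in hours, simulated time in days) and converted at the
# point of use. 1 N.s/m = 1e12/(60e6) pN.min/um.

.NSM_TO_INTERNAL <- 1e12 / (60 * 1e6)

#' Convert a drag coefficient from SI to internal units
#'
#' Internal units are pN.min/um; SI drag (as in Stokes' law, 6*pi*eta*R) is
#' N.s/m. The conversion factor is 1e12/(60e6).
#'
#' @param x drag coefficient in N.s/m
#' @return drag coefficient in pN.min/um
#' @seealso [internal_to_si_drag()], [drag_coefficient()]
#' @export
si_to_internal_drag <- function(x) x * .NSM_TO_INTERNAL

#' Convert a drag coefficient from internal units to SI
#' @param x drag coefficient in pN.min/um
#' @return drag coefficient in N.s/m
#' @export
internal_to_si_drag <- function(x) x / .NSM_TO_INTERNAL

default_values <- function() {
  list(
    # matrix and gating
    eta = 20,           # Pa.s, low-density matrix; 100 for high-density
    F_lim = 0.07,       # pN, secretion pressure gate
    # cell cycle
    T_ini = 30,         # h, cycle constant before luminal pressurization
    T_pol = 100,        # h, cycle constant once the lumen is pressurized
    F_bottom = 0.42,    # pN, lower knee of the mechanosensitive ramp
    F_top = 1.17,       # pN, upper knee of the ramp
    a_max = 0.6,        # max fractional growth-rate increase
    b = 0.1,            # quiescence probability per completed division
    # polarity and secretion
    n_tc = 5,           # polarized cells required to close the preapical patch
    dt_exo = 5,         # h, fluid production period per cell
    n_secrete = 1L,     # particles created per secretion event
    facing_frac = 0.15, # facing threshold: surface gap < facing_frac * R_c
    facing_grace = 2,   # h of sustained facing failure before depolarization
    # geometry
    R_p = 2,            # um, fluid-particle radius
    R_c0 = 10,          # um, initial cell radius
    # pairwise force strengths (magnitudes, pN)
    F_rep_cc = 4.80, F_adh_cc = 24,
    F_rep_pp = 4.80, F_adh_pp = 24,
    F_rep_cp = 0.60, F_adh_cp = 0,
    lambda = 7,         # matching constant of the potential
    # time stepping
    dt_mech = 0.01,     # min, mechanics step
    dt_bio = 6,         # min, biology step
    t_sim = 7,          # days
    seed = 42L,
    # growth-rate inheritance jitter (truncated normal)
    jitter_sd = 0.10, jitter_max = 0.20,
    # numerics
    s_cut = 2.0,        # neighbor cutoff in normalized-gap units
    skin = 0.4,         # um, Verlet-list skin
    cap_frac = 0.1,     # displacement cap per mech step, fraction of R_p
    # analysis
    clustering_gap = 1,   # um, surface gap for single-linkage lumen clustering
    alpha_value = 4,      # um, closing-ball radius for volumetry (2 * R_p)
    voxel_h = 0.5,        # um, volumetry voxel spacing
    snapshot_every = 360  # min, volumetry/snapshot cadence
  )
}

mandatory_keys <- function() {
  c("eta", "T_ini", "T_pol", "F_bottom", "F_top", "F_lim", "a_max", "b",
    "n_tc", "dt_exo", "R_p", "F_rep_cc", "F_adh_cc", "F_rep_pp", "F_adh_pp",
    "F_rep_cp", "lambda")
}

#' Build a validated simulation configuration
#'
#' Returns the full parameter set of the model with any named overrides
#' applied. Defaults are the reference parameterization of the simulator
#' (low-density matrix, `eta = 20` Pa.s). Force strengths are stored as
#' magnitudes; overlap always repels and positive normalized gaps adhere
#' (cell-cell and particle-particle only; cell-particle contact is
#' repulsion-only, `F_adh_cp = 0`).
#'
#' @param ... named overrides of the default values, e.g. `eta = 100`
#' @return an object of class `sim_config` (a validated named list)
#' @examples
#' cfg <- sim_config(eta = 100, seed = 1L)
#' cfg$T_pol / cfg$T_ini
#' @export
sim_config <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  cfg <- default_values()
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_pos <- c("eta", "T_ini", "T_pol", "a_max", "dt_exo", "R_p", "R_c0",
               "lambda", "dt_mech", "dt_bio", "voxel_h", "alpha_value",
               "s_cut", "skin", "snapshot_every")
  for (k in num_pos) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("configuration error: '", k, "' must be a positive number")
  }
  num_nonneg <- c("F_bottom", "F_top", "F_lim", "b", "F_rep_cc", "F_adh_cc",
                  "F_rep_pp", "F_adh_pp", "F_rep_cp", "F_adh_cp", "t_sim",
                  "jitter_sd", "cap_frac", "clustering_gap", "facing_frac",
                  "facing_grace")
  for (k in num_nonneg) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("configuration error: '", k, "' must be a non-negative number")
  }
  if (cfg$T_pol <= cfg$T_ini)
    stop("validation error: T_pol must exceed T_ini")
  if (cfg$F_top <= cfg$F_bottom)
    stop("validation error: F_top must exceed F_bottom")
  if (cfg$dt_mech >= cfg$dt_bio)
    stop("validation error: dt_mech must be smaller than dt_bio")
  if (cfg$F_adh_cp != 0)
    stop("validation error: cell-particle interaction is repulsion-only (F_adh_cp = 0)")
  if (cfg$jitter_max < 0 || cfg$jitter_max >= 1)
    stop("validation error: jitter_max must lie in [0, 1)")
  cfg$n_tc <- as.integer(cfg$n_tc)
  cfg$n_secrete <- as.integer(cfg$n_secrete)
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$n_tc < 1L) stop("validation error: n_tc must be >= 1")
  if (cfg$n_secrete < 1L) stop("validation error: n_secrete must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Load a simulation configuration from a YAML file
#'
#' The file is a flat key-value mapping mirroring the field names of
#' [sim_config()]. The mandatory keys are the core model parameter set
#' (viscosity, cycle constants, force thresholds and strengths, particle
#' radius); all other keys take documented defaults, so two loads of the same
#' file always yield identical configurations.
#'
#' @param path path to a YAML file
#' @return a `sim_config` object
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration file does not parse to a mapping: ", path)
  missing <- setdiff(mandatory_keys(), names(raw))
  if (length(missing))
    stop("configuration error: missing mandatory key(s): ",
         paste(missing, collapse = ", "))
  do.call(sim_config, raw)
}

#' Write a configuration to a YAML file
#'
#' The written file round-trips losslessly through [load_config()].
#'
#' @param config a `sim_config` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> eta =", x$eta, "Pa.s, t_sim =", x$t_sim,
      "d, seed =", x$seed, "\n")
  invisible(x)
}

# force-strength parameter list handed to the C++ kernel
force_par <- function(config) {
  config[c("F_rep_cc", "F_adh_cc", "F_rep_pp", "F_adh_pp", "F_rep_cp",
           "lambda", "s_cut")]
}
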