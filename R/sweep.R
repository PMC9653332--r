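# Paired-seed replicate sweeps across matrix viscosities.

#' Run a replicate sweep across matrix viscosities
#'
#' Draws `replicates` run seeds once from the master `seed`, then executes
#' every (seed, eta) combination — the paired-seed design: the same seed is
#' replayed under each viscosity, so morphological differences between
#' conditions are attributable to the matrix and not to sampling.
#'
#' @param etas vector of matrix viscosities, Pa.s
#' @param replicates number of seeds per condition
#' @param config base configuration (its `eta`/`seed` are overridden per run)
#' @param seed master seed for generating the run seeds
#' @param out_dir optional directory; per-run outputs are written in
#'   `eta<eta>_seed<seed>` subdirectories plus a `summary.csv`
#' @param keep_runs keep the full `lumen_sim` objects (memory-heavy) instead
#'   of metrics only
#' @param quiet suppress per-run progress messages
#' @return list with `metrics` (one row per run), `summary`
#'   ([replicate_summary()] output), `seeds`, and `runs` (if kept)
#' @export
run_sweep <- function(etas = c(20, 100), replicates = 10L,
                      config = sim_config(), seed = config$seed,
                      out_dir = NULL, keep_runs = FALSE, quiet = TRUE) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  metrics <- list(); runs <- list()
  for (s in seeds) {
    for (e in etas) {
      cfg <- sim_config(modifyList(unclass(config),
                                   list(eta = e, seed = as.integer(s))))
      dir_i <- if (!is.null(out_dir))
        file.path(out_dir, sprintf("eta%g_seed%d", e, s)) else NULL
      if (!quiet) message(sprintf("run eta=%g seed=%d ...", e, s))
      sim <- run_simulation(cfg, out_dir = dir_i, quiet = TRUE)
      metrics[[length(metrics) + 1L]] <- run_metrics(sim)
      if (keep_runs) runs[[sprintf("eta%g_seed%d", e, s)]] <- sim
    }
  }
  metrics <- do.call(rbind, metrics)
  summ <- replicate_summary(metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(summ$per_eta, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    if (!is.null(summ$comparisons))
      write.csv(summ$comparisons, file.path(out_dir, "comparisons.csv"),
                row.names = FALSE)
  }
  out <- list(metrics = metrics, summary = summ, seeds = seeds)
  if (keep_runs) out$runs <- runs
  out
}
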