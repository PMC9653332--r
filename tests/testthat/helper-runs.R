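# Long-running replicate simulations shared across acceptance checks,
# computed once per test session. The sweep pairs each seed across the two
# matrix conditions (paired-seed design).

.run_cache <- new.env(parent = emptyenv())

acceptance_sweep <- function(n_seeds = 10L) {
  key <- paste0("sweep", n_seeds)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  sw <- run_sweep(etas = c(20, 100), replicates = n_seeds,
                  config = sim_config(), seed = 20260924L, keep_runs = TRUE)
  .run_cache[[key]] <- sw
  sw
}

# the designated single-run pair (first seed of the sweep)
acceptance_pair <- function() {
  sw <- acceptance_sweep()
  s <- sw$seeds[1]
  list(low = sw$runs[[sprintf("eta20_seed%d", s)]],
       high = sw$runs[[sprintf("eta100_seed%d", s)]])
}
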