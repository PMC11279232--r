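# Shared fixtures, built in code at test time.

# Four 96-array preculture plates with n isolates each (n <= 96).
make_source_plates <- function(n = 96L, prefix = "ISO") {
  pos <- all_positions(96)[seq_len(n)]
  plates <- lapply(1:4, function(q) {
    occ <- sprintf("%s%03d", prefix, (q - 1L) * n + seq_len(n))
    names(occ) <- pos
    occ
  })
  names(plates) <- paste0("P", 1:4)
  plates
}

# Deterministic small quant data.frame for IO tests.
make_quant_df <- function(n = 12L) {
  pos <- pos_parse(all_positions(384)[seq_len(n)])
  data.frame(row = pos$row, column = pos$col,
             size = seq_len(n) * 7 + 0.25, opacity = rev(seq_len(n)) * 3 + 0.5)
}

# Small simulated bundle shared across tests (cached; ~2 s to build).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 11L, n_isolates = 16L, msd_draws = 120L)
      cache <<- simulate_experiment(cfg)
    }
    cache
  }
})

# The full-scale validation bundle (384 isolates, sigma = 0.05, injected
# pair effects at 6 expected MSD) plus its pipeline run; built once and
# shared by the acceptance tests. Scale and noise are the stated
# experimental world, not tuning knobs.
acceptance_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 20260911L %% 100000L, n_isolates = 384L,
                               sigma = 0.05, delta_msd = 6)
      bundle <- simulate_experiment(cfg)
      cache <<- list(bundle = bundle, result = run_pipeline(bundle))
    }
    cache
  }
})
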