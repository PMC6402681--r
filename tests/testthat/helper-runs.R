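# Shared simulation runs, computed once per test session and reused by
# several test files (scheme properties, long-horizon ordering, published
# 20-year comparisons).

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# Small scheme used by fast structural tests: 20 BQs (4 dams x 5
# daughters), 2 stations.
small_config <- function(years = 5L, engine = "INF", ...) {
  bee_config(n_bq_per_year = 20L, n_stations_per_year = 2L, n_dams_bq = 4L,
             daughters_per_dam = 5L, years = years, engine = engine, ...)
}

small_sim <- function() {
  cached_run("small_inf_5y",
             run_simulation(small_config(pedigree_mode = "exact"),
                            bee_params(), seed = 42))
}

# Reduced-scale long-horizon runs (100 BQs, 2 stations, 50 years, 3
# replicates) used for the cross-engine ordering and trajectory-shape
# checks. Long-run divergence between the engines needs upwards of 20
# female generations to emerge, hence the horizon.
smoke_config <- function(engine) {
  bee_config(n_bq_per_year = 100L, n_stations_per_year = 2L,
             n_dams_bq = 20L, daughters_per_dam = 5L, years = 50L,
             engine = engine)
}

smoke_runs <- function(engine) {
  cached_run(paste0("smoke_", engine),
             run_replicates(smoke_config(engine),
                            bee_params(sigma_Amd = -0.25),
                            replicates = 3L, master_seed = 7L))
}

# Full-scale 20-year scenarios at the repetition counts that give a 10%
# error bound with 99% confidence for the compared statistic.
scenario_20y <- function(engine, sigma_Amd, replicates, master_seed,
                         n_locus_sets = 1L) {
  key <- sprintf("sc20_%s_%s", engine, sigma_Amd)
  cached_run(key,
             run_replicates(bee_config(years = 20L, engine = engine),
                            bee_params(sigma_Amd = sigma_Amd),
                            replicates = replicates,
                            master_seed = master_seed,
                            n_locus_sets = n_locus_sets))
}
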