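# ------------------------------------------------------------------------
# Configuration files, replicate seeding and orchestration, CLI backend.
# ------------------------------------------------------------------------

#' Read a simulation configuration file
#'
#' YAML key/value file combining scheme, genetic-parameter and run
#' settings. Recognized keys: the [bee_config()] fields
#' (`n_bq_per_year`, `n_stations_per_year`, `n_dams_bq`,
#' `daughters_per_dam`, `n_dpq_per_station`, `drones_per_mating`,
#' `dam_age_bq`, `dam_age_dpq`, `years`, `engine`, `pedigree_mode`), the
#' [bee_params()] fields (`sigma2_Ad`, `sigma2_Am`, `sigma_Amd`,
#' `sigma2_E`) and the run keys `replicates`, `seed`, `n_locus_sets`,
#' `out`. Unknown keys raise a configuration error listing them. See
#' `system.file("extdata", "example_config.yaml", package = "beesim")`
#' for an annotated example.
#'
#' @param path Path to the YAML file.
#' @return List with elements `config` ([bee_config()]), `params`
#'   ([bee_params()]), `replicates`, `seed`, `n_locus_sets`, `out`.
#' @export
read_bee_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg_keys <- c("n_bq_per_year", "n_stations_per_year", "n_dams_bq",
                "daughters_per_dam", "n_dpq_per_station",
                "drones_per_mating", "dam_age_bq", "dam_age_dpq", "years",
                "engine", "pedigree_mode")
  par_keys <- c("sigma2_Ad", "sigma2_Am", "sigma_Amd", "sigma2_E")
  run_keys <- c("replicates", "seed", "n_locus_sets", "out")
  unknown <- setdiff(names(raw), c(cfg_keys, par_keys, run_keys))
  if (length(unknown))
    stop("configuration error: unknown keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  config <- do.call(bee_config, raw[intersect(names(raw), cfg_keys)])
  params <- do.call(bee_params, raw[intersect(names(raw), par_keys)])
  list(config = config, params = params,
       replicates = raw$replicates %||% 1L,
       seed = raw$seed %||% 1L,
       n_locus_sets = raw$n_locus_sets %||% 1L,
       out = raw$out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive reproducible replicate seeds
#'
#' Draws `n` distinct seeds from a master seed so replicate streams are
#' decoupled from the replicate count. For finite-locus engines,
#' [seed_fl_design()] supports the two-level design: a small number of
#' independently drawn founder locus sets, each simulated with several
#' run seeds.
#'
#' @param master_seed Integer master seed.
#' @param n Number of replicate seeds.
#' @return Integer vector of `n` distinct seeds.
#' @export
seed_replicates <- function(master_seed, n) {
  stopifnot(n >= 1L)
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' @rdname seed_replicates
#' @param n_locus_sets Number of founder locus sets.
#' @param runs_per_set Run seeds per locus set.
#' @return `seed_fl_design`: list with `locus_set_seeds` (length
#'   `n_locus_sets`) and matrix `run_seeds` (`runs_per_set` x
#'   `n_locus_sets`).
#' @export
seed_fl_design <- function(master_seed, n_locus_sets, runs_per_set) {
  seeds <- seed_replicates(master_seed, n_locus_sets * (1L + runs_per_set))
  list(locus_set_seeds = seeds[seq_len(n_locus_sets)],
       run_seeds = matrix(seeds[-seq_len(n_locus_sets)],
                          nrow = runs_per_set, ncol = n_locus_sets))
}

#' Run a scenario with replicates
#'
#' Runs `replicates` independent simulations of one scenario. For the
#' finite-locus engines the replicates are spread over `n_locus_sets`
#' independently drawn founder locus sets (allele frequencies and
#' effects), the remaining randomness differing between runs within a
#' set. Seeds are derived from `master_seed` before any simulation and
#' recorded in the manifest.
#'
#' @param config A [bee_config()].
#' @param params A [bee_params()].
#' @param replicates Number of runs.
#' @param master_seed Master seed.
#' @param n_locus_sets Locus sets to spread finite-locus replicates over
#'   (ignored for the infinitesimal engine).
#' @param out_dir Optional directory: per-replicate yearly-stats CSVs, a
#'   pedigree CSV and EBV CSV of the first replicate, the aggregated CSV
#'   and a manifest are written there.
#' @param verbose Per-year progress.
#' @return List of class `bee_replicates`: `runs` (list of `bee_sim`),
#'   `aggregate` (from [aggregate_replicates()]), `manifest`.
#' @export
run_replicates <- function(config, params = bee_params(), replicates = 1L,
                           master_seed = 1L, n_locus_sets = 1L,
                           out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "bee_config"))
  fl <- config$engine != "INF"
  if (!fl) n_locus_sets <- 1L
  runs_per_set <- ceiling(replicates / n_locus_sets)
  des <- seed_fl_design(master_seed, n_locus_sets, runs_per_set)
  manifest <- list(engine = config$engine,
                   n_bq_per_year = config$n_bq_per_year,
                   years = config$years,
                   replicates = replicates,
                   master_seed = master_seed,
                   n_locus_sets = if (fl) n_locus_sets else NA_integer_,
                   locus_set_seeds = if (fl) des$locus_set_seeds else NULL,
                   run_seeds = as.integer(des$run_seeds)[seq_len(replicates)],
                   version = as.character(utils::packageVersion("beesim")))
  runs <- vector("list", replicates)
  r <- 0L
  for (ls_i in seq_len(n_locus_sets)) {
    locus_set <- NULL
    if (fl) {
      set.seed(des$locus_set_seeds[ls_i])
      locus_set <- build_founder_locus_set(params, config$n_loci)
    }
    for (k in seq_len(runs_per_set)) {
      r <- r + 1L
      if (r > replicates) break
      runs[[r]] <- run_simulation(config, params,
                                  seed = des$run_seeds[k, ls_i],
                                  locus_set = locus_set, verbose = verbose)
    }
  }
  agg <- aggregate_replicates(runs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(runs))
      write_year_stats(runs[[i]]$stats,
                       file.path(out_dir, sprintf("stats_rep%03d.csv", i)))
    write_year_stats(agg, file.path(out_dir, "stats_aggregate.csv"))
    write_pedigree(runs[[1L]]$pedigree, file.path(out_dir, "pedigree.csv"))
    if (!is.null(runs[[1L]]$ebv))
      write_ebv(runs[[1L]]$ebv, file.path(out_dir, "ebv.csv"))
    writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  }
  structure(list(runs = runs, aggregate = agg, manifest = manifest),
            class = "bee_replicates")
}

#' @export
print.bee_replicates <- function(x, ...) {
  ny <- nrow(x$aggregate)
  cat(sprintf("%d replicates, %s engine, %d years\n", length(x$runs),
              x$manifest$engine, ny))
  cat(sprintf("  year-%d PC gain: %.3f (SD %.3f)\n", x$aggregate$year[ny],
              x$aggregate$mean_PC_mean[ny], x$aggregate$mean_PC_sd[ny]))
  invisible(x)
}

#' Scenario grid presets
#'
#' The 12 standard scenarios: engines INF/FL200/FL400 crossed with the
#' moderate (`sigma_Amd = -0.25`) and strong (`-0.75`) negative
#' direct-maternal covariance and the small (300 BQs, 4 stations) and
#' large (1000 BQs, 10 stations) program.
#'
#' @param years Years per scenario.
#' @param pedigree_mode Relationship mode for all scenarios.
#' @return Named list of `list(config =, params =)` pairs.
#' @export
scenario_grid <- function(years = 20L, pedigree_mode = "exact") {
  grid <- expand.grid(engine = c("FL200", "FL400", "INF"),
                      cov = c(-0.25, -0.75),
                      size = c("300", "1000"), stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    big <- grid$size[i] == "1000"
    cfg <- bee_config(n_bq_per_year = if (big) 1000L else 300L,
                      n_stations_per_year = if (big) 10L else 4L,
                      n_dams_bq = if (big) 200L else 60L,
                      years = years, engine = grid$engine[i],
                      pedigree_mode = pedigree_mode)
    par <- bee_params(sigma_Amd = grid$cov[i])
    nm <- sprintf("%s_%s_%sBQ", grid$engine[i],
                  ifelse(grid$cov[i] == -0.25, "r018", "r053"), grid$size[i])
    out[[nm]] <- list(config = cfg, params = par)
  }
  out
}

#' Long-horizon engine contrasts
#'
#' Convenience driver for the expensive 100-year comparisons between the
#' infinitesimal and finite-locus engines: runs each requested engine for
#' `years` years with `replicates` replicates under one parameter set and
#' population size, and returns the aggregated trajectories together with
#' the INF/FL ratio tables of gain and PC variance and the variance
#' retention (late-year PC variance over the mean base-cohort value).
#' At full scale (100 years, 300 or 1000 BQs, 30+ replicates) this takes
#' hours on one core; reduced settings give qualitative orderings only.
#'
#' @param engines Engines to contrast (first entry is the ratio
#'   numerator's opponent: ratios are INF over each finite-locus engine).
#' @param years,replicates Horizon and replication per engine.
#' @param params A [bee_params()].
#' @param config_base A [bee_config()] supplying the population structure;
#'   its `engine` and `years` fields are overridden.
#' @param master_seed Master seed (replicate seeds derived per engine).
#' @param n_locus_sets Locus sets per finite-locus engine.
#' @return List with per-engine aggregates (`aggregates`), ratio tables
#'   (`ratios`, INF over each FL engine at `years/2` and `years`) and the
#'   variance retention per engine (`retention`).
#' @export
long_horizon_contrasts <- function(engines = c("INF", "FL400", "FL200"),
                                   years = 100L, replicates = 30L,
                                   params = bee_params(),
                                   config_base = bee_config(),
                                   master_seed = 1L, n_locus_sets = 2L) {
  aggs <- list()
  for (i in seq_along(engines)) {
    cfg_args <- unclass(config_base)
    cfg_args$n_loci <- NULL
    cfg_args$engine <- engines[i]
    cfg_args$years <- as.integer(years)
    cfg <- do.call(bee_config, cfg_args)
    aggs[[engines[i]]] <-
      run_replicates(cfg, params, replicates = replicates,
                     master_seed = master_seed + i - 1L,
                     n_locus_sets = n_locus_sets)$aggregate
  }
  ratios <- list()
  if ("INF" %in% engines)
    for (e in setdiff(engines, "INF"))
      ratios[[paste0("INF_over_", e)]] <-
        cross_model_ratios(aggs[["INF"]], aggs[[e]],
                           years = c(floor(years / 2), years))
  retention <- vapply(aggs, function(a)
    a$var_PC_mean[years] / mean(a$var_PC_mean[1:2]), numeric(1L))
  list(aggregates = aggs, ratios = ratios, retention = retention)
}

#' Command-line entry point
#'
#' Backend of the `exec/beesim` script. Subcommands: `run` (one scenario
#' from a YAML config, with flag overrides), `grid` (all 12 preset
#' scenarios), `aggregate` (recompute the aggregated CSV from the
#' per-replicate CSVs in `--out`) and `report` (print the final-year
#' summary of an aggregated CSV). `run` and `grid` write per-replicate
#' and aggregated CSVs plus a manifest under the output directory.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE)) {
    message("the optparse package is required for the command line interface")
    return(invisible(1L))
  }
  if (length(args) < 1L ||
      !args[1L] %in% c("run", "grid", "aggregate", "report")) {
    message("usage: beesim <run|grid|aggregate|report> [options]")
    return(invisible(1L))
  }
  sub <- args[1L]
  opts <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--engine", type = "character", default = NULL),
    optparse::make_option("--years", type = "integer", default = NULL),
    optparse::make_option("--replicates", type = "integer", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--pedigree-mode", type = "character",
                          default = NULL, dest = "pedigree_mode"),
    optparse::make_option("--out", type = "character", default = "out"))
  op <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                             args = args[-1L])
  status <- tryCatch({
    if (sub == "run") {
      cf <- if (!is.null(op$config)) read_bee_config(op$config)
            else list(config = bee_config(), params = bee_params(),
                      replicates = 1L, seed = 1L, n_locus_sets = 1L,
                      out = NULL)
      cfg_args <- unclass(cf$config)
      cfg_args$n_loci <- NULL
      for (k in c("engine", "years", "pedigree_mode"))
        if (!is.null(op[[k]])) cfg_args[[k]] <- op[[k]]
      cfg <- do.call(bee_config, cfg_args)
      reps <- op$replicates %||% cf$replicates
      seed <- op$seed %||% cf$seed
      out <- op$out %||% cf$out %||% "out"
      res <- run_replicates(cfg, cf$params, replicates = reps,
                            master_seed = seed, out_dir = out)
      print(res)
    } else if (sub == "aggregate") {
      files <- sort(list.files(op$out, "^stats_rep[0-9]+\\.csv$",
                               full.names = TRUE))
      if (!length(files)) stop("no per-replicate stats CSVs in ", op$out)
      stats <- lapply(files, utils::read.csv)
      write_year_stats(aggregate_replicates(stats),
                       file.path(op$out, "stats_aggregate.csv"))
      message("aggregated ", length(files), " replicates")
    } else if (sub == "report") {
      agg <- utils::read.csv(file.path(op$out, "stats_aggregate.csv"))
      ny <- nrow(agg)
      message(sprintf(
        "%d years, %d replicates | gain: maternal %.2f, direct %.2f, PC %.2f | var(PC) %.3f | mean F %.3f",
        ny, agg$n_replicates[1], agg$mean_m_BQ_mean[ny],
        agg$mean_d_BQ_mean[ny], agg$mean_PC_mean[ny], agg$var_PC_mean[ny],
        agg$mean_F_mean[ny]))
    } else {
      seed <- op$seed %||% 1L
      years <- op$years %||% 20L
      reps <- op$replicates %||% 1L
      for (nm in names(scenario_grid(years))) {
        sc <- scenario_grid(years)[[nm]]
        message("scenario ", nm)
        run_replicates(sc$config, sc$params, replicates = reps,
                       master_seed = seed,
                       out_dir = file.path(op$out, nm))
      }
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
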