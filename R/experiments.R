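#' Named forest scenario presets
#'
#' The nine study scenarios: four natural-dynamics scenarios with stem
#' turnover targets 1.6 (very-low), 2.2 (low), 2.7 (reference) and 3.2
#' (high) % per year on a 0.25-ha plot; a static (frozen) reference stand;
#' three selective-logging scenarios on reference dynamics with target
#' diameters 40, 45 and 50 cm; and the reference dynamics at fragment sizes
#' 0.25, 0.5 and 1 ha.
#'
#' @param years Snapshot years per scenario (default 600).
#' @param seed Base seed stored in each config.
#' @return Named list of [forest_config()] objects.
#' @export
scenario_presets <- function(years = 600, seed = 1L) {
  base <- function(...) forest_config(years = years, seed = seed, ...)
  list(
    very_low_turnover = base(target_turnover = 1.6),
    low_turnover = base(target_turnover = 2.2),
    reference = base(target_turnover = 2.7),
    high_turnover = base(target_turnover = 3.2),
    static = base(static = TRUE),
    logging40 = base(logging_dbh = 40),
    logging45 = base(logging_dbh = 45),
    logging50 = base(logging_dbh = 50),
    fragment_0.25ha = base(plot_x = 50, plot_y = 50),
    fragment_0.5ha = base(plot_x = 50, plot_y = 100),
    fragment_1ha = base(plot_x = 100, plot_y = 100)
  )
}

#' Experiment design
#'
#' A crossed replicate design: every scenario is simulated on
#' `n_forest_replicates` independent forests, each combined with
#' `n_species_sets` independently sampled species sets (the study design
#' uses 5 x 10 = 50 runs per scenario). Seeds for each (scenario, forest
#' replicate, species set) cell derive deterministically from `base_seed`.
#'
#' @param scenarios Named list of [forest_config()] objects.
#' @param n_forest_replicates,n_species_sets Replicate counts, >= 1.
#' @param years Simulated years per run.
#' @param init_density Initial epiphytes per ha (split evenly over
#'   `n_species` species).
#' @param n_species Species per sampled set.
#' @param base_seed Integer base seed.
#' @param trait_ranges,globals Sampling ranges and global parameters.
#' @param species_sets Optional list of `n_species_sets` pre-built
#'   `epx_species` sets (e.g. drawn from a [viable_species_pool()]); the
#'   same sets are then reused across all scenarios and forest replicates,
#'   as in the study design. When `NULL`, sets are sampled fresh from
#'   `trait_ranges` per cell.
#' @return Object of class `epx_design`.
#' @export
experiment_design <- function(scenarios = scenario_presets(),
                              n_forest_replicates = 5, n_species_sets = 10,
                              years = 600, init_density = 40000,
                              n_species = 100, base_seed = 1L,
                              trait_ranges = default_trait_ranges(),
                              globals = global_params(),
                              species_sets = NULL) {
  if (n_forest_replicates < 1 || n_species_sets < 1)
    stopf("replicate counts must be >= 1")
  if (!is.null(species_sets) && length(species_sets) != n_species_sets)
    stopf("species_sets must hold %d sets", n_species_sets)
  structure(list(
    scenarios = scenarios, n_forest_replicates = as.integer(n_forest_replicates),
    n_species_sets = as.integer(n_species_sets), years = as.integer(years),
    init_density = init_density, n_species = as.integer(n_species),
    base_seed = as.integer(base_seed), trait_ranges = trait_ranges,
    globals = globals, species_sets = species_sets
  ), class = "epx_design")
}

#' @export
print.epx_design <- function(x, ...) {
  cat(sprintf(
    "<epx_design> %d scenario(s) x %d forest replicate(s) x %d species set(s) = %d runs, %d years each\n",
    length(x$scenarios), x$n_forest_replicates, x$n_species_sets,
    length(x$scenarios) * x$n_forest_replicates * x$n_species_sets, x$years))
  invisible(x)
}

#' Run a full simulation experiment
#'
#' Executes forest generation, microhabitat streaming and the epiphyte
#' simulation for every (scenario x forest replicate x species set) cell.
#' Forests are generated once per (scenario, forest replicate) and shared
#' across species sets. Failures are isolated per run: the failed cell is
#' reported with a warning and the aggregate is computed over completed
#' runs.
#'
#' @param design An [experiment_design()] object.
#' @param quiet Suppress per-run progress lines.
#' @return Object of class `epx_experiment`: `runs` (per-run, per-year
#'   summary records with scenario / replicate / set ids), `aggregate`
#'   (per scenario and year: mean and SD of saturation, abundance per ha
#'   and richness over runs), `failures`, and the `design`.
#' @export
run_experiment <- function(design, quiet = FALSE) {
  stopifnot(inherits(design, "epx_design"))
  runs <- list()
  failures <- list()
  for (sc_i in seq_along(design$scenarios)) {
    sc_name <- names(design$scenarios)[sc_i]
    for (fr in seq_len(design$n_forest_replicates)) {
      fcfg <- design$scenarios[[sc_i]]
      fcfg$years <- design$years
      fcfg$seed <- sub_seed(design$base_seed, 100 * sc_i + fr, PHASE[["forest"]])
      forest <- tryCatch(generate_forest(fcfg), error = function(e) e)
      if (inherits(forest, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          scenario = sc_name, forest_rep = fr, species_set = NA_integer_,
          error = conditionMessage(forest))
        warning(sprintf("forest generation failed for %s rep %d: %s",
                        sc_name, fr, conditionMessage(forest)), call. = FALSE)
        next
      }
      area_ha <- fcfg$plot_x * fcfg$plot_y / 1e4
      init_ps <- max(1L, round(design$init_density * area_ha / design$n_species))
      for (ss in seq_len(design$n_species_sets)) {
        run_seed <- sub_seed(design$base_seed, 10000 * sc_i + 100 * fr + ss,
                             PHASE[["init"]])
        res <- tryCatch({
          species <- design$species_sets[[ss]] %||%
            sample_species_set(design$trait_ranges, design$globals,
                               design$n_species, seed = run_seed)
          sim <- run_epiphyte_sim(forest = forest, species = species,
                                  globals = design$globals,
                                  init_per_species = init_ps,
                                  seed = run_seed, quiet = TRUE)
          cbind(scenario = sc_name, forest_rep = fr, species_set = ss,
                sim$summary,
                abundance_ha = sim$summary$abundance / sim$area_ha)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <- data.frame(
            scenario = sc_name, forest_rep = fr, species_set = ss,
            error = conditionMessage(res))
          warning(sprintf("run failed for %s rep %d set %d: %s",
                          sc_name, fr, ss, conditionMessage(res)),
                  call. = FALSE)
        } else {
          runs[[length(runs) + 1L]] <- res
          if (!quiet)
            cat(sprintf("done: %s forest %d set %d (final N = %d)\n",
                        sc_name, fr, ss, res$abundance[nrow(res)]))
        }
      }
    }
  }
  runs <- if (length(runs)) do.call(rbind, runs) else NULL
  aggregate_tab <- NULL
  if (!is.null(runs)) {
    aggregate_tab <- do.call(rbind, lapply(
      split(runs, list(runs$scenario, runs$year), drop = TRUE),
      function(d) data.frame(
        scenario = d$scenario[1], year = d$year[1], n_runs = nrow(d),
        saturation_mean = mean(d$saturation), saturation_sd = sd(d$saturation),
        abundance_ha_mean = mean(d$abundance_ha),
        abundance_ha_sd = sd(d$abundance_ha),
        richness_mean = mean(d$richness), richness_sd = sd(d$richness))))
    aggregate_tab <- aggregate_tab[order(aggregate_tab$scenario,
                                         aggregate_tab$year), ]
    rownames(aggregate_tab) <- NULL
  }
  if (length(failures) && !is.null(runs))
    warning("aggregate computed over completed runs only", call. = FALSE)
  structure(list(
    runs = runs, aggregate = aggregate_tab,
    failures = if (length(failures)) do.call(rbind, failures) else NULL,
    design = design
  ), class = "epx_experiment")
}

#' @export
print.epx_experiment <- function(x, ...) {
  nr <- if (is.null(x$runs)) 0L else
    nrow(unique(x$runs[, c("scenario", "forest_rep", "species_set")]))
  cat(sprintf("<epx_experiment> %d completed run(s), %d failure(s)\n",
              nr, if (is.null(x$failures)) 0L else nrow(x$failures)))
  invisible(x)
}
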