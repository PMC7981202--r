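#' Community saturation level
#'
#' Percentage of the total arboreal substrate area occupied by epiphytes:
#' `100 * sum_i g_S * M_i^p_A / sum_voxels S_B`. Because space competition
#' acts per voxel, values well below 100 can already represent effectively
#' saturated communities.
#'
#' @param state An `epx_community`.
#' @param habitat Current-year `epx_habitat`.
#' @param globals [global_params()] object (supplies `g_S`, `p_A`).
#' @return Saturation in percent.
#' @export
saturation_level <- function(state, habitat, globals = global_params()) {
  total <- sum(habitat$S_B)
  if (total <= 0) stopf("habitat has zero total substrate")
  100 * sum(globals$g_S * state$mass^globals$p_A) / total
}

#' Structural distributions of a simulated community
#'
#' Pools the per-year structural tallies of a simulation over a year window
#' and returns: the rank-abundance distribution (relative species
#' abundances, descending), the vertical distribution (relative abundance
#' per 1-m height bin), the size distribution (mass histogram over
#' quarter-decade log bins) and the per-species height stratification
#' (2.5/50/97.5 % height quantiles, sorted by median height).
#'
#' @param sim An `epx_sim` object, or a list of community data frames
#'   (as from [community_df()]) to pool directly.
#' @param window Integer vector of years to pool (default: all simulated).
#' @return List with data frames `rank_abundance`, `vertical`, `sizes`,
#'   `stratification`.
#' @export
structural_distributions <- function(sim, window = NULL) {
  if (inherits(sim, "epx_sim")) {
    window <- window %||% (seq_len(ncol(sim$species_counts)) - 1L)
    cols <- window + 1L
    sp_tot <- rowSums(sim$species_counts[, cols, drop = FALSE])
    spz <- sim$sp_z[sim$sp_z$year %in% window, , drop = FALSE]
    zn <- aggregate(list(n = spz$n), list(z = spz$z), sum)
    spzn <- aggregate(list(n = spz$n), list(sp = spz$sp, z = spz$z), sum)
    mh <- rowSums(sim$mass_hist[, cols, drop = FALSE])
    mass_breaks <- sim$mass_breaks
  } else {
    pool <- do.call(rbind, sim)
    if (!is.null(window)) pool <- pool[pool$year %in% window, , drop = FALSE]
    if (nrow(pool) == 0L) stopf("empty individual pool")
    sp_tot <- table(pool$ID_Sp)
    sp_tot <- setNames(as.numeric(sp_tot), names(sp_tot))
    zn <- aggregate(list(n = rep(1L, nrow(pool))), list(z = pool$E_Z), sum)
    spzn <- aggregate(list(n = rep(1L, nrow(pool))),
                      list(sp = pool$ID_Sp, z = pool$E_Z), sum)
    mass_breaks <- seq(floor(log10(min(pool$M)) * 4) / 4 - 0.125,
                       ceiling(log10(max(pool$M)) * 4) / 4 + 0.125, by = 0.25)
    mh <- tabulate(findInterval(log10(pool$M), mass_breaks,
                                all.inside = TRUE),
                   nbins = length(mass_breaks) - 1L)
  }
  total <- sum(sp_tot)
  if (total == 0) stopf("empty individual pool in window")

  present <- sp_tot[sp_tot > 0]
  ra <- data.frame(
    rank = seq_along(present),
    ID_Sp = as.integer(names(present)[order(-present)]),
    rel_abundance = as.numeric(sort(present, decreasing = TRUE)) / total
  )
  vert <- data.frame(z = zn$z, rel_abundance = zn$n / sum(zn$n))
  vert <- vert[order(vert$z), ]
  sizes <- data.frame(
    log10_mass_lo = mass_breaks[-length(mass_breaks)],
    log10_mass_hi = mass_breaks[-1], count = as.numeric(mh)
  )
  strat <- do.call(rbind, lapply(split(spzn, spzn$sp), function(d) {
    zrep <- rep(d$z + 0.5, d$n)  # voxel centres
    q <- quantile(zrep, c(0.025, 0.5, 0.975), names = FALSE, type = 1)
    data.frame(ID_Sp = d$sp[1], z_lo = q[1], z_med = q[2], z_hi = q[3],
               n = sum(d$n))
  }))
  strat <- strat[order(strat$z_med), ]
  rownames(strat) <- NULL
  list(rank_abundance = ra, vertical = vert, sizes = sizes,
       stratification = strat)
}

#' Per-cause mean annual mortality rates
#'
#' For each cause, the mean over the window of (deaths of that cause in the
#' year / standing abundance at the start of the year) x 100. Years with
#' zero standing abundance are excluded. `competition` is reported merged
#' with `oversize` (both express space limitation), with the split
#' retained.
#'
#' @param sim An `epx_sim` object.
#' @param window Integer vector of years (default all).
#' @return Data frame with `cause` and `rate` (percent per year), including
#'   a `total` row and the merged `competition_total`.
#' @export
mortality_decomposition <- function(sim, window = NULL) {
  s <- sim$summary
  if (!is.null(window)) s <- s[s$year %in% window, , drop = FALSE]
  s <- s[s$abundance_start > 0, , drop = FALSE]
  if (nrow(s) == 0L) stopf("no years with positive abundance in window")
  rate <- function(col) mean(100 * s[[col]] / s$abundance_start)
  causes <- c(light_niche = rate("deaths_light_niche"),
              competition = rate("deaths_competition"),
              oversize = rate("deaths_oversize"),
              dislodgement = rate("deaths_dislodgement"),
              metabolic = rate("deaths_metabolic"))
  data.frame(
    cause = c(names(causes), "competition_total", "total"),
    rate = as.numeric(c(causes, causes[["competition"]] + causes[["oversize"]],
                        sum(causes)))
  )
}

# ---- result file I/O ------------------------------------------------------

#' Write / read simulation outputs
#'
#' `write_outputs()` writes a directory of CSV files (`summary.csv`,
#' `mortality.csv`, `rank_abundance.csv`, `vertical.csv`, `sizes.csv`,
#' `stratification.csv`) plus a fully resolved `config.yaml` echo (seed
#' included). Column meanings and units are listed in the packaged data
#' dictionary (`inst/extdata/data_dictionary.md`). `read_outputs()` reads
#' the directory back; malformed tables are rejected with the location of
#' the first offending record.
#'
#' @param sim An `epx_sim` object.
#' @param dir Output directory (created if missing).
#' @param window Pooling window for the structural distributions.
#' @rdname outputs_io
#' @export
write_outputs <- function(sim, dir, window = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sim$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  write.csv(mortality_decomposition(sim, window),
            file.path(dir, "mortality.csv"), row.names = FALSE)
  sd <- structural_distributions(sim, window)
  write.csv(sd$rank_abundance, file.path(dir, "rank_abundance.csv"),
            row.names = FALSE)
  write.csv(sd$vertical, file.path(dir, "vertical.csv"), row.names = FALSE)
  write.csv(sd$sizes, file.path(dir, "sizes.csv"), row.names = FALSE)
  write.csv(sd$stratification, file.path(dir, "stratification.csv"),
            row.names = FALSE)
  cfg <- list(
    seed = sim$seed, area_ha = sim$area_ha,
    globals = unclass(sim$globals),
    forest = if (!is.null(sim$config)) {
      f <- unclass(sim$config)
      f$logging_dbh <- f$logging_dbh %||% "none"
      f
    } else "external habitat input"
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname outputs_io
#' @export
read_outputs <- function(dir) {
  read_table <- function(name, required) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stopf("missing output file '%s'", name)
    tab <- tryCatch(read.csv(path), warning = function(w)
      stopf("malformed %s: %s", name, conditionMessage(w)))
    miss <- setdiff(required, names(tab))
    if (length(miss)) stopf("%s lacks column(s): %s", name,
                            paste(miss, collapse = ", "))
    bad <- which(!stats::complete.cases(tab[required]))
    if (length(bad)) stopf("%s: malformed record at data line %d", name, bad[1])
    tab
  }
  list(
    summary = read_table("summary.csv", c("year", "abundance", "richness",
                                          "saturation")),
    mortality = read_table("mortality.csv", c("cause", "rate")),
    rank_abundance = read_table("rank_abundance.csv",
                                c("rank", "ID_Sp", "rel_abundance")),
    vertical = read_table("vertical.csv", c("z", "rel_abundance")),
    sizes = read_table("sizes.csv", c("log10_mass_lo", "log10_mass_hi",
                                      "count")),
    stratification = read_table("stratification.csv",
                                c("ID_Sp", "z_lo", "z_med", "z_hi")),
    config = yaml::read_yaml(file.path(dir, "config.yaml"))
  )
}
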