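#' Forest scenario configuration
#'
#' Describes one synthetic forest scenario: plot geometry, target mean stem
#' turnover, interannual turnover variation, optional selective-logging
#' target diameter, and a static (frozen) mode. The generator tunes its
#' background mortality so that the realized long-run mean stem turnover
#' matches `target_turnover`.
#'
#' @param plot_x,plot_y Plot edge lengths in m (default 50 x 50 m = 0.25 ha).
#' @param canopy_height Vertical extent of the model space in m (max 50).
#' @param target_turnover Target mean annual stem turnover in percent per
#'   year; tropical stands span roughly 1--4.
#' @param turnover_cv Coefficient of variation of the lognormal interannual
#'   multiplier on yearly mortality probability.
#' @param logging_dbh Optional target diameter (cm): each year every tree
#'   reaching this DBH is removed.
#' @param static If `TRUE` the stand is frozen: every yearly snapshot is
#'   identical to year 0 and no demographic events occur.
#' @param years Number of yearly snapshots to record.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param demography Named list overriding demographic constants:
#'   `recruit_dbh` (cm), `dbh_asym` (cm, asymptotic DBH of the saturating
#'   growth rule), `growth_max` (cm/a), `stem_density` (stems/ha at
#'   equilibrium), `u_dbh`, `u_pow` (U-shaped size effect on mortality so
#'   large trees occasionally fall), `m_base` (background mortality
#'   probability; tuned automatically when `NULL`), `recruitment` (logical),
#'   `mort_cap` (upper cap on per-tree death probability).
#' @param allometry Named list of allometry coefficients, see
#'   [default_allometry()].
#' @return An object of class `epx_forest_config`.
#' @export
forest_config <- function(plot_x = 50, plot_y = 50, canopy_height = 50,
                          target_turnover = 2.7, turnover_cv = 0.25,
                          logging_dbh = NULL, static = FALSE,
                          years = 600, seed = 1L,
                          demography = list(), allometry = list()) {
  check_number(plot_x, "plot_x", 5)
  check_number(plot_y, "plot_y", 5)
  check_number(canopy_height, "canopy_height", 5, 50)
  check_number(target_turnover, "target_turnover", 0, 10)
  check_number(turnover_cv, "turnover_cv", 0, 2)
  check_number(years, "years", 1)
  if (!is.null(logging_dbh)) check_number(logging_dbh, "logging_dbh", 1)
  dem <- list(
    recruit_dbh = 10, dbh_asym = 120, growth_max = 0.9,
    stem_density = 500, u_dbh = 90, u_pow = 2,
    m_base = NULL, recruitment = TRUE, mort_cap = 0.95
  )
  dem[names(demography)] <- demography
  allo <- default_allometry()
  allo[names(allometry)] <- allometry
  structure(list(
    plot_x = plot_x, plot_y = plot_y, canopy_height = canopy_height,
    target_turnover = target_turnover, turnover_cv = turnover_cv,
    logging_dbh = logging_dbh, static = isTRUE(static),
    years = as.integer(years), seed = as.integer(seed),
    demography = dem, allometry = allo
  ), class = "epx_forest_config")
}

# ---- internal stand demography -------------------------------------------

# initial stand: equilibrium count with a decaying size distribution
init_stand <- function(cfg) {
  dem <- cfg$demography
  n <- max(2L, round(dem$stem_density * cfg$plot_x * cfg$plot_y / 1e4))
  dbh <- pmin(dem$dbh_asym - 1, dem$recruit_dbh + stats::rexp(n, rate = 1 / 12))
  list(
    id = seq_len(n), x = runif(n, 0, cfg$plot_x), y = runif(n, 0, cfg$plot_y),
    dbh = dbh, next_id = n + 1L
  )
}

# one year of stand dynamics: mortality -> growth -> recruitment -> logging
advance_stand <- function(st, cfg, m_base, logging = TRUE) {
  dem <- cfg$demography
  n_start <- length(st$id)
  deaths <- 0L
  if (n_start > 0L) {
    sigma <- sqrt(log(1 + cfg$turnover_cv^2))
    mult <- rlnorm(1, meanlog = -sigma^2 / 2, sdlog = sigma)
    p <- pmin(dem$mort_cap, m_base * mult * (1 + (st$dbh / dem$u_dbh)^dem$u_pow))
    die <- runif(n_start) < p
    deaths <- sum(die)
    st$id <- st$id[!die]; st$x <- st$x[!die]; st$y <- st$y[!die]
    st$dbh <- st$dbh[!die]
  }
  st$dbh <- st$dbh + dem$growth_max * pmax(0, 1 - st$dbh / dem$dbh_asym)
  recruits <- 0L
  if (isTRUE(dem$recruitment)) {
    n_eq <- max(2L, round(dem$stem_density * cfg$plot_x * cfg$plot_y / 1e4))
    lam <- max(0, n_eq - length(st$id))
    recruits <- rpois(1, lam)
    if (recruits > 0L) {
      # gap-biased placement: pick, per recruit, the least crown-covered of
      # three uniform candidates
      cr <- cfg$allometry$cr_coef * st$dbh^cfg$allometry$cr_pow
      pos <- vapply(seq_len(recruits), function(i) {
        cx <- runif(3, 0, cfg$plot_x); cy <- runif(3, 0, cfg$plot_y)
        cover <- vapply(1:3, function(j) {
          if (length(st$x) == 0L) return(0)
          sum((st$x - cx[j])^2 + (st$y - cy[j])^2 <= cr^2)
        }, numeric(1))
        k <- which.min(cover)
        c(cx[k], cy[k])
      }, numeric(2))
      ids <- st$next_id + seq_len(recruits) - 1L
      st$id <- c(st$id, ids); st$next_id <- st$next_id + recruits
      st$x <- c(st$x, pos[1, ]); st$y <- c(st$y, pos[2, ])
      st$dbh <- c(st$dbh, rep(dem$recruit_dbh, recruits))
    }
  }
  if (logging && !is.null(cfg$logging_dbh)) {
    cut <- st$dbh >= cfg$logging_dbh
    if (any(cut)) {
      deaths <- deaths + sum(cut)
      st$id <- st$id[!cut]; st$x <- st$x[!cut]; st$y <- st$y[!cut]
      st$dbh <- st$dbh[!cut]
    }
  }
  list(stand = st, n_start = n_start, deaths = deaths, recruits = recruits)
}

# mean realized turnover (% / a) of a fresh stand run, used for tuning
trial_turnover <- function(cfg, m_base, burn = 100L, measure = 150L, seed = 1L) {
  set.seed(seed)
  st <- init_stand(cfg)
  for (i in seq_len(burn)) st <- advance_stand(st, cfg, m_base, logging = FALSE)$stand
  rates <- numeric(0)
  for (i in seq_len(measure)) {
    a <- advance_stand(st, cfg, m_base, logging = FALSE)
    st <- a$stand
    if (a$n_start > 0L)
      rates <- c(rates, 50 * (a$deaths + a$recruits) / a$n_start)
  }
  mean(rates)
}

tune_m_base <- function(cfg) {
  target <- cfg$target_turnover
  lo <- 1e-4; hi <- 0.25
  eval_seed <- sub_seed(cfg$seed, 0L, PHASE[["forest"]])
  f_lo <- trial_turnover(cfg, lo, seed = eval_seed) - target
  f_hi <- trial_turnover(cfg, hi, seed = eval_seed) - target
  if (f_lo > 0 || f_hi < 0)
    stopf("turnover target %.2f %%/a unreachable by mortality tuning", target)
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    f <- trial_turnover(cfg, mid, seed = eval_seed) - target
    if (abs(f) < 0.05) return(mid)
    if (f > 0) hi <- mid else lo <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(trial_turnover(cfg, mid, seed = eval_seed) - target) > 0.3)
    stopf("turnover target %.2f %%/a unreachable by mortality tuning", target)
  mid
}

stand_snapshot <- function(st, cfg) {
  al <- tree_allometry(st$dbh, cfg$allometry, cfg$canopy_height)
  data.frame(
    id = st$id, x = st$x, y = st$y, dbh = st$dbh,
    height = al$height, crown_radius = al$crown_radius,
    crown_depth = al$crown_depth, branch_area = al$branch_area,
    leaf_area = al$leaf_area
  )
}

#' Generate a synthetic forest time series
#'
#' Runs a minimal gap-model-style tree demographic simulation: recruitment
#' at the least crown-covered of candidate sites, saturating DBH growth, a
#' background mortality probability tuned by bisection so that the realized
#' long-run mean annual stem turnover matches the configured target, a
#' lognormal interannual multiplier on mortality, and a mildly U-shaped size
#' effect so big trees occasionally fall. The stand is burnt in to
#' quasi-equilibrium before year 0 of the recorded output. With
#' `static = TRUE` the burnt-in stand is frozen and every snapshot is
#' identical.
#'
#' @param config An [forest_config()] object.
#' @param burn_in Burn-in years before recording (default 200).
#' @return An object of class `epx_forest`: list with `snapshots` (one tree
#'   data frame per year: id, x, y, dbh, height, crown_radius, crown_depth,
#'   branch_area, leaf_area), `counts` (per transition year: n_start,
#'   deaths, recruits), `geometry` (nx, ny, nz in m/voxels), `config`, and
#'   the tuned `m_base`.
#' @export
generate_forest <- function(config, burn_in = 200L) {
  stopifnot(inherits(config, "epx_forest_config"))
  cfg <- config
  m_base <- cfg$demography$m_base %||% tune_m_base(cfg)
  set.seed(sub_seed(cfg$seed, 1L, PHASE[["forest"]]))
  st <- init_stand(cfg)
  for (i in seq_len(burn_in)) st <- advance_stand(st, cfg, m_base)$stand
  years <- cfg$years
  snapshots <- vector("list", years)
  if (cfg$static) {
    snap <- stand_snapshot(st, cfg)
    for (t in seq_len(years)) snapshots[[t]] <- snap
    counts <- data.frame(
      year = seq_len(max(years - 1L, 0L)) - 1L,
      n_start = nrow(snap), deaths = 0L, recruits = 0L
    )
  } else {
    counts <- data.frame(
      year = integer(0), n_start = integer(0),
      deaths = integer(0), recruits = integer(0)
    )
    for (t in seq_len(years)) {
      if (length(st$id) == 0L)
        stopf("forest collapsed to zero trees in recorded year %d", t - 1L)
      snapshots[[t]] <- stand_snapshot(st, cfg)
      if (t < years) {
        a <- advance_stand(st, cfg, m_base)
        st <- a$stand
        counts <- rbind(counts, data.frame(
          year = t - 1L, n_start = a$n_start,
          deaths = a$deaths, recruits = a$recruits
        ))
      }
    }
  }
  structure(list(
    snapshots = snapshots, counts = counts,
    geometry = c(nx = as.integer(ceiling(cfg$plot_x)),
                 ny = as.integer(ceiling(cfg$plot_y)),
                 nz = as.integer(ceiling(cfg$canopy_height))),
    config = cfg, m_base = m_base
  ), class = "epx_forest")
}

#' Remove all trees at or above a target diameter from a forest series
#'
#' Post-processing selective logging: in every year, trees whose DBH has
#' reached `target_dbh` are removed from the snapshot, and the per-year
#' demographic counts are recomputed from the resulting tree id sets so the
#' removals appear as stem mortality (their substrate disappears in the
#' following transition).
#'
#' @param series An `epx_forest` object.
#' @param target_dbh Target diameter at breast height (cm), > 0.
#' @return A logged `epx_forest`.
#' @export
apply_logging <- function(series, target_dbh) {
  stopifnot(inherits(series, "epx_forest"))
  check_number(target_dbh, "target_dbh", lower = 1e-9)
  series$snapshots <- lapply(series$snapshots, function(s) s[s$dbh < target_dbh, , drop = FALSE])
  series$counts <- recount_series(series)
  series$config$logging_dbh <- target_dbh
  series
}

# recompute transition counts from the id sets of consecutive snapshots
recount_series <- function(series) {
  ny <- length(series$snapshots)
  if (ny < 2L) {
    return(data.frame(year = integer(0), n_start = integer(0),
                      deaths = integer(0), recruits = integer(0)))
  }
  out <- vector("list", ny - 1L)
  for (t in seq_len(ny - 1L)) {
    a <- series$snapshots[[t]]$id
    b <- series$snapshots[[t + 1L]]$id
    out[[t]] <- data.frame(
      year = t - 1L, n_start = length(a),
      deaths = sum(!(a %in% b)), recruits = sum(!(b %in% a))
    )
  }
  do.call(rbind, out)
}

#' Realized mean annual stem turnover of a forest series
#'
#' The standard forest-census definition: per transition year the mean of
#' the annualized stem mortality rate and recruitment rate (both relative to
#' the stem count at the start of the year), averaged over the window, in
#' percent per year.
#'
#' @param series An `epx_forest` object.
#' @param window Integer vector of transition years (0-based, as in
#'   `series$counts$year`); default all.
#' @return Mean turnover in % per year.
#' @export
stem_turnover <- function(series, window = NULL) {
  stopifnot(inherits(series, "epx_forest"))
  cnt <- series$counts
  if (!is.null(window)) cnt <- cnt[cnt$year %in% window, , drop = FALSE]
  if (nrow(cnt) == 0L) stopf("empty turnover window")
  cnt <- cnt[cnt$n_start > 0L, , drop = FALSE]
  mean(50 * (cnt$deaths + cnt$recruits) / cnt$n_start)
}

#' @export
print.epx_forest <- function(x, ...) {
  ny <- length(x$snapshots)
  cat(sprintf(
    "<epx_forest> %d x %d x %d m, %d yearly snapshots, %d trees in year 0\n",
    x$geometry[["nx"]], x$geometry[["ny"]], x$geometry[["nz"]],
    ny, nrow(x$snapshots[[1]])
  ))
  if (nrow(x$counts) > 0L)
    cat(sprintf("  realized stem turnover: %.2f %%/a (target %.2f)\n",
                stem_turnover(x), x$config$target_turnover))
  if (x$config$static) cat("  static (frozen) stand\n")
  invisible(x)
}

#' Write / read a forest series as CSV
#'
#' One row per tree-year with columns `year`, `id`, `x`, `y`, `dbh_cm`,
#' `height_m`, `crown_radius_m`, `crown_depth_m`, `alive`. Only living trees
#' are stored (`alive` is always `TRUE`); structural allometry columns are
#' re-derived on read.
#'
#' @param series An `epx_forest` object.
#' @param path File path.
#' @rdname forest_csv
#' @export
write_forest_csv <- function(series, path) {
  rows <- do.call(rbind, lapply(seq_along(series$snapshots), function(t) {
    s <- series$snapshots[[t]]
    data.frame(year = t - 1L, id = s$id, x = s$x, y = s$y, dbh_cm = s$dbh,
               height_m = s$height, crown_radius_m = s$crown_radius,
               crown_depth_m = s$crown_depth, alive = TRUE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @param config The [forest_config()] describing plot geometry (the CSV
#'   stores tree lists only).
#' @rdname forest_csv
#' @export
read_forest_csv <- function(path, config) {
  rows <- read.csv(path)
  need <- c("year", "id", "x", "y", "dbh_cm")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stopf("forest CSV lacks column(s): %s", paste(miss, collapse = ", "))
  yrs <- sort(unique(rows$year))
  snaps <- lapply(yrs, function(t) {
    s <- rows[rows$year == t & (rows$alive %||% TRUE), , drop = FALSE]
    al <- tree_allometry(s$dbh_cm, config$allometry, config$canopy_height)
    data.frame(id = s$id, x = s$x, y = s$y, dbh = s$dbh_cm,
               height = al$height, crown_radius = al$crown_radius,
               crown_depth = al$crown_depth, branch_area = al$branch_area,
               leaf_area = al$leaf_area)
  })
  out <- structure(list(
    snapshots = snaps, counts = NULL,
    geometry = c(nx = as.integer(ceiling(config$plot_x)),
                 ny = as.integer(ceiling(config$plot_y)),
                 nz = as.integer(ceiling(config$canopy_height))),
    config = config, m_base = NA_real_
  ), class = "epx_forest")
  out$counts <- recount_series(out)
  out
}
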