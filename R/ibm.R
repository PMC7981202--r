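#' Parabolic light response
#'
#' `f(I) = max(0, I_A*I^2 + I_B*I + I_C)`, exactly 0 outside
#' `[I_Min, I_Max]`, maximum 1 at `I_Opt`. The multiplier scales both the
#' von Bertalanffy growth step and realized fecundity.
#'
#' @param I Light intensity (umol m-2 s-1), vectorized.
#' @param traits A single-species row (or list) with `I_A`, `I_B`, `I_C`,
#'   `I_Min`, `I_Max`.
#' @return Multiplier in \[0, 1\].
#' @export
light_response <- function(I, traits) {
  f <- pmax(0, traits$I_A * I^2 + traits$I_B * I + traits$I_C)
  f[I < traits$I_Min | I > traits$I_Max] <- 0
  f
}

# per-individual light multiplier, indexing species traits by sp id
light_response_at <- function(I, species, sp) {
  f <- pmax(0, species$I_A[sp] * I^2 + species$I_B[sp] * I + species$I_C[sp])
  f[I < species$I_Min[sp] | I > species$I_Max[sp]] <- 0
  f
}

#' One-year von Bertalanffy mass increment under a light multiplier
#'
#' `M' = M_Max * (1 - (1 - (M/M_Max)^(1/3)) * exp(-K * f))^3` with
#' `f = light_response(I, traits)`; the update is monotone, fixes `M_Max`,
#' and leaves mass unchanged when `f = 0`.
#'
#' @param M Current mass (g), `0 < M <= M_Max`.
#' @param I Light intensity in the individual's voxel.
#' @param traits Single-species row with `K`, `M_Max` and the parabola
#'   fields.
#' @return Updated mass (g).
#' @export
grow_mass <- function(M, I, traits) {
  f <- light_response(I, traits)
  vb_step(M, traits$M_Max, traits$K, f)
}

vb_step <- function(M, M_Max, K, f) {
  M_Max * (1 - (1 - pmin(1, M / M_Max)^(1 / 3)) * exp(-K * f))^3
}

# ---- community state ------------------------------------------------------

new_community <- function(n_species) {
  structure(list(
    id = integer(0), sp = integer(0), age = numeric(0), mass = numeric(0),
    x = integer(0), y = integer(0), z = integer(0),
    next_id = 1L, n_species = n_species
  ), class = "epx_community")
}

#' @export
print.epx_community <- function(x, ...) {
  cat(sprintf("<epx_community> %d individuals, %d species present\n",
              length(x$id), length(unique(x$sp))))
  invisible(x)
}

#' Community snapshot as a data frame
#'
#' @param state An `epx_community`.
#' @param year Optional year column.
#' @return Data frame with `ID_Ind`, `ID_Sp`, `A`, `M`, `E_X`, `E_Y`, `E_Z`
#'   (and `year` if given).
#' @export
community_df <- function(state, year = NULL) {
  out <- data.frame(ID_Ind = state$id, ID_Sp = state$sp, A = state$age,
                    M = state$mass, E_X = state$x, E_Y = state$y,
                    E_Z = state$z)
  if (!is.null(year)) out <- cbind(year = year, out)
  out
}

#' Initialize an unstructured epiphyte community
#'
#' For each species, `n_per_species` individuals are placed in voxels drawn
#' with probability proportional to substrate area, restricted to voxels
#' whose light lies within the species' niche. Initial mass is log-uniform
#' between seedling mass and the species' mass at maturity; initial age is
#' 0. Species without any admissible voxel contribute a reported placement
#' shortfall rather than an error.
#'
#' @param habitat Year-0 `epx_habitat`.
#' @param species An `epx_species` set.
#' @param n_per_species Individuals per species (100 individuals of 100
#'   species on 0.25 ha gives the reference density of 40,000 per ha).
#' @param globals [global_params()] object.
#' @param seed Integer seed.
#' @return An `epx_community`; attribute `shortfall` is a named count of
#'   unplaced individuals per species (only species with a shortfall).
#' @export
initialize_community <- function(habitat, species, n_per_species = 100,
                                 globals = global_params(), seed = 1L) {
  set.seed(sub_seed(seed, 0L, PHASE[["init"]]))
  dims <- habitat$geometry
  sb <- as.vector(habitat$S_B)
  Iv <- as.vector(habitat$I)
  state <- new_community(nrow(species))
  shortfall <- integer(0)
  acc <- vector("list", nrow(species))
  for (i in seq_len(nrow(species))) {
    adm <- which(sb > 0 & Iv >= species$I_Min[i] & Iv <= species$I_Max[i])
    if (!length(adm)) {
      shortfall[as.character(species$ID_Sp[i])] <- n_per_species
      next
    }
    pick <- if (length(adm) == 1L) rep(adm, n_per_species) else
      sample(adm, n_per_species, replace = TRUE, prob = sb[adm])
    mass <- exp(runif(n_per_species, log(globals$seedling_mass),
                      log(species$M_Mat[i])))
    acc[[i]] <- list(sp = rep(i, n_per_species), mass = mass, vi = pick)
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (length(acc)) {
    vi <- unlist(lapply(acc, `[[`, "vi")) - 1L
    n <- length(vi)
    state$id <- seq_len(n)
    state$next_id <- n + 1L
    state$sp <- unlist(lapply(acc, `[[`, "sp"))
    state$age <- rep(0, n)
    state$mass <- unlist(lapply(acc, `[[`, "mass"))
    state$x <- as.integer(vi %% dims[[1]])
    state$y <- as.integer((vi %/% dims[[1]]) %% dims[[2]])
    state$z <- as.integer(vi %/% (dims[[1]] * dims[[2]]))
  }
  attr(state, "shortfall") <- shortfall
  state
}

# ---- annual submodels -----------------------------------------------------

#' Dispersal and recruitment
#'
#' Every mature individual (age >= `A_Mat`) produces a Poisson number of
#' propagules with mean `n_RPot * f(I_parent)`; each propagule lands in a
#' voxel sampled from the truncated negative-exponential kernel
#' `S_B(v) * exp(-D_K d) * asym(dz)` (downward displacements weighted by
#' `D_KAs`), truncated where the kernel falls below `kernel_cut` of its
#' peak. Propagules landing in voxels whose light is outside the species
#' niche, or in voxels without enough free substrate beside the standing
#' occupants, are lost; survivors enter at seedling mass and age 0.
#'
#' @param state An `epx_community`.
#' @param habitat Current-year `epx_habitat`.
#' @param species,globals Trait set and global parameters.
#' @param seed Integer seed for this submodel draw.
#' @return List with the updated `state` and `recruits` (count added).
#' @export
disperse_and_recruit <- function(state, habitat, species,
                                 globals = global_params(), seed = 1L) {
  set.seed(seed)
  dims <- habitat$geometry
  mat <- which(state$age >= species$A_Mat[state$sp])
  if (!length(mat)) return(list(state = state, recruits = 0L))
  vi <- voxel_index(state$x[mat], state$y[mat], state$z[mat], dims)
  f <- light_response_at(habitat$I[vi], species, state$sp[mat])
  lambda0 <- species$n_RPot[state$sp[mat]] * f
  res <- recruit_kernel(
    state$x[mat], state$y[mat], state$z[mat], lambda0,
    species$D_K[state$sp[mat]], species$D_KAs[state$sp[mat]],
    habitat$S_B, as.integer(dims), globals$kernel_cut
  )
  if (!length(res$x)) return(list(state = state, recruits = 0L))
  rsp <- state$sp[mat][res$parent]
  rvi <- voxel_index(res$x, res$y, res$z, dims)
  ok <- habitat$I[rvi] >= species$I_Min[rsp] & habitat$I[rvi] <= species$I_Max[rsp]
  # establishment requires free substrate: a voxel admits only as many
  # seedlings as fit beside its standing occupants; surplus propagules are
  # lost rather than culled (and booked as competition deaths) later
  if (any(ok)) {
    a_seed <- globals$g_S * globals$seedling_mass^globals$p_A
    load <- numeric(prod(dims))
    if (length(state$id)) {
      svi <- voxel_index(state$x, state$y, state$z, dims)
      occ <- rowsum(globals$g_S * state$mass^globals$p_A, svi)
      load[as.integer(rownames(occ))] <- occ[, 1]
    }
    est_f <- globals$est_area_factor %||% 1
    cap_n <- floor((habitat$S_B[rvi] - load[rvi]) / (est_f * a_seed) + 1e-9)
    okw <- which(ok)
    arrival <- stats::ave(seq_along(okw), rvi[okw], FUN = seq_along)
    ok[okw] <- arrival <= cap_n[okw]
  }
  n <- sum(ok)
  if (n == 0L) return(list(state = state, recruits = 0L))
  state$id <- c(state$id, state$next_id + seq_len(n) - 1L)
  state$next_id <- state$next_id + n
  state$sp <- c(state$sp, rsp[ok])
  state$age <- c(state$age, rep(0, n))
  state$mass <- c(state$mass, rep(globals$seedling_mass, n))
  state$x <- c(state$x, res$x[ok]); state$y <- c(state$y, res$y[ok])
  state$z <- c(state$z, res$z[ok])
  list(state = state, recruits = n)
}

# drop individuals by logical index, tallying deaths by cause and species
drop_individuals <- function(state, die) {
  keep <- !die
  state$id <- state$id[keep]; state$sp <- state$sp[keep]
  state$age <- state$age[keep]; state$mass <- state$mass[keep]
  state$x <- state$x[keep]; state$y <- state$y[keep]; state$z <- state$z[keep]
  state
}

MORT_CAUSES <- c("light_niche", "competition", "oversize", "dislodgement",
                 "metabolic")

#' Apply the four annual mortality channels
#'
#' Fixed sub-order: (1) light niche -- die iff the voxel light is outside
#' `[I_Min, I_Max]`; (2) space -- per voxel, individual areas
#' `a = g_S * M^p_A` are summed and, where the sum exceeds the voxel's
#' substrate area, individuals are removed smallest-mass-first (mass ties
#' broken by keeping the lower `ID_Ind`) until the rest fit; a lone
#' over-large individual dies with cause `oversize`, removals with
#' neighbors present with cause `competition`; (3) dislodgement --
#' Bernoulli(`S_Loss`/100); (4) metabolic -- Bernoulli(min(1,
#' `k_M * M^(-1/4)`)). Ages are not touched here; the scheduler increments
#' them afterwards.
#'
#' @inheritParams disperse_and_recruit
#' @param seeds Integer seeds for the two stochastic channels
#'   (dislodgement, metabolic).
#' @return List with updated `state` and `deaths`, a named count by cause,
#'   plus `deaths_by_sp` (data frame cause, ID_Sp, count).
#' @export
apply_mortality <- function(state, habitat, species,
                            globals = global_params(),
                            seeds = c(fall = 1L, metab = 2L)) {
  dims <- habitat$geometry
  deaths <- setNames(integer(length(MORT_CAUSES)), MORT_CAUSES)
  by_sp <- list()
  note <- function(cause, sp_rows) {
    sp_dead <- species$ID_Sp[sp_rows]
    deaths[[cause]] <<- deaths[[cause]] + length(sp_dead)
    if (length(sp_dead))
      by_sp[[length(by_sp) + 1L]] <<- data.frame(
        cause = cause, ID_Sp = as.integer(names(table(sp_dead))),
        count = as.integer(table(sp_dead)))
  }

  # 1. light niche (deterministic environmental filter)
  if (length(state$id)) {
    vi <- voxel_index(state$x, state$y, state$z, dims)
    Iv <- habitat$I[vi]
    die <- Iv < species$I_Min[state$sp] | Iv > species$I_Max[state$sp]
    note("light_niche", state$sp[die])
    state <- drop_individuals(state, die)
  }

  # 2. space competition / oversize (deterministic)
  if (length(state$id)) {
    vi <- voxel_index(state$x, state$y, state$z, dims)
    a <- globals$g_S * state$mass^globals$p_A
    o <- order(vi, -state$mass, state$id)
    grp <- vi[o]
    firsts <- !duplicated(grp)
    gid <- cumsum(firsts)
    cs <- cumsum(a[o])
    cso <- cs - (cs - a[o])[firsts][gid]
    keep_o <- cso <= habitat$S_B[grp] + 1e-9
    nres <- tabulate(gid)
    lone <- nres[gid] == 1L
    die <- logical(length(state$id))
    die[o] <- !keep_o
    cause_oversize <- logical(length(state$id))
    cause_oversize[o] <- !keep_o & lone
    note("oversize", state$sp[die & cause_oversize])
    note("competition", state$sp[die & !cause_oversize])
    state <- drop_individuals(state, die)
  }

  # 3. dislodgement (branch / tree fall)
  if (length(state$id)) {
    set.seed(seeds[["fall"]])
    vi <- voxel_index(state$x, state$y, state$z, dims)
    die <- runif(length(state$id)) < habitat$S_Loss[vi] / 100
    note("dislodgement", state$sp[die])
    state <- drop_individuals(state, die)
  }

  # 4. quarter-power metabolic mortality
  if (length(state$id)) {
    set.seed(seeds[["metab"]])
    p <- pmin(1, globals$k_M * state$mass^(-1 / 4))
    die <- runif(length(state$id)) < p
    note("metabolic", state$sp[die])
    state <- drop_individuals(state, die)
  }

  by_sp <- if (length(by_sp)) do.call(rbind, by_sp) else
    data.frame(cause = character(0), ID_Sp = integer(0), count = integer(0))
  list(state = state, deaths = deaths, deaths_by_sp = by_sp)
}

#' One annual scheduling step
#'
#' Executes recruitment, growth, mortality and the age increment exactly
#' once each, in that order, and emits the per-year summary record.
#'
#' @inheritParams disperse_and_recruit
#' @param year Simulation year (drives the RNG substreams).
#' @param base_seed Simulation seed from which submodel seeds derive.
#' @return List: `state` (year t+1), `record` (one-row summary data frame),
#'   `ledger` (deaths by cause and species for the year).
#' @export
step_year <- function(state, habitat, species, globals = global_params(),
                      year = 0L, base_seed = 1L) {
  n_start <- length(state$id)

  rec <- disperse_and_recruit(
    state, habitat, species, globals,
    seed = sub_seed(base_seed, year, PHASE[["recruit"]])
  )
  state <- rec$state

  if (length(state$id)) {
    vi <- voxel_index(state$x, state$y, state$z, habitat$geometry)
    f <- light_response_at(habitat$I[vi], species, state$sp)
    state$mass <- vb_step(state$mass, species$M_Max[state$sp],
                          species$K[state$sp], f)
  }

  mor <- apply_mortality(
    state, habitat, species, globals,
    seeds = c(fall = sub_seed(base_seed, year, PHASE[["mort_fall"]]),
              metab = sub_seed(base_seed, year, PHASE[["mort_metab"]]))
  )
  state <- mor$state
  state$age <- state$age + 1

  total_sb <- sum(habitat$S_B)
  sat <- if (total_sb > 0)
    100 * sum(globals$g_S * state$mass^globals$p_A) / total_sb else NA_real_
  record <- data.frame(
    year = year, abundance_start = n_start, recruits = rec$recruits,
    deaths_light_niche = mor$deaths[["light_niche"]],
    deaths_competition = mor$deaths[["competition"]],
    deaths_oversize = mor$deaths[["oversize"]],
    deaths_dislodgement = mor$deaths[["dislodgement"]],
    deaths_metabolic = mor$deaths[["metabolic"]],
    abundance = length(state$id),
    richness = length(unique(state$sp)),
    saturation = sat,
    growth_rate = if (n_start > 0) length(state$id) / n_start else NA_real_
  )
  ledger <- mor$deaths_by_sp
  if (nrow(ledger)) ledger <- cbind(year = year, ledger)
  else ledger <- data.frame(year = integer(0), cause = character(0),
                            ID_Sp = integer(0), count = integer(0))
  list(state = state, record = record, ledger = ledger)
}

# ---- full simulation ------------------------------------------------------

#' Simulate an epiphyte community on a forest
#'
#' Runs the annual update over a forest time series (microhabitat matrices
#' are streamed year by year from consecutive snapshots) or over
#' pre-computed habitat matrices. The community is closed: no propagules
#' arrive from outside, so richness is non-increasing after initialization.
#'
#' @param forest An `epx_forest` series (used unless `habitats` is given).
#' @param habitats Optional list of `epx_habitat` matrices.
#' @param species An `epx_species` trait set.
#' @param globals [global_params()] object.
#' @param init_per_species Individuals per species at initialization.
#' @param seed Integer simulation seed.
#' @param years Number of years (default: all available).
#' @param record_states Integer vector of years whose full community
#'   snapshots should be kept (pooled structural tallies are always kept).
#' @param tallies Keep per-year structural tallies (disable for cheap
#'   throwaway runs such as the viability screen).
#' @param quiet Suppress the per-decade run log.
#' @return Object of class `epx_sim`: `summary` (per-year records),
#'   `ledger` (year x cause x species death counts), structural tallies
#'   (`species_counts`, `sp_z`, `mass_hist` with `mass_breaks`),
#'   `final_state`, `states` (requested snapshots), `species`, `globals`,
#'   `config` echo and the area in ha.
#' @export
run_epiphyte_sim <- function(forest = NULL, habitats = NULL, species,
                             globals = global_params(),
                             init_per_species = 100, seed = 1L,
                             years = NULL, record_states = integer(0),
                             tallies = TRUE, quiet = FALSE) {
  if (is.null(forest) && is.null(habitats))
    stopf("provide a forest series or habitat matrices")
  streamed <- is.null(habitats)
  n_avail <- if (streamed) length(forest$snapshots) else length(habitats)
  years <- as.integer(years %||% n_avail)
  if (years > n_avail) stopf("requested %d years but only %d available",
                             years, n_avail)
  geom <- if (streamed) forest$geometry else habitats[[1]]$geometry
  area_ha <- geom[[1]] * geom[[2]] / 1e4

  hab_for_year <- function(t, ras_now, ras_next) {
    sl <- if (!is.null(ras_next)) substrate_loss(ras_now$S_B, ras_next$S_B)
    else array(0, dim = dim(ras_now$S_B))
    new_habitat(t - 1L,
                light_from_lad(ras_now$LAD, globals$I_top, globals$k_ext,
                               globals$edge_margin),
                ras_now$S_B, sl, geom)
  }

  n_snap <- if (streamed) length(forest$snapshots) else 0L
  if (streamed) {
    ras_now <- rasterize_snapshot(forest$snapshots[[1]], geom)
    ras_next <- if (n_snap >= 2L) rasterize_snapshot(forest$snapshots[[2]], geom)
    hab <- hab_for_year(1L, ras_now, ras_next)
  } else {
    hab <- habitats[[1]]
  }

  state <- initialize_community(hab, species, init_per_species, globals, seed)
  shortfall <- attr(state, "shortfall")

  mass_breaks <- seq(log10(globals$seedling_mass) - 0.125,
                     log10(max(species$M_Max)) + 0.375, by = 0.25)
  records <- vector("list", years)
  ledgers <- vector("list", years)
  sp_counts <- matrix(0L, nrow(species), years,
                      dimnames = list(species$ID_Sp, NULL))
  sp_z <- vector("list", years)
  mass_hist <- matrix(0L, length(mass_breaks) - 1L, years)
  states <- list()

  stopped_at <- 0L
  for (t in seq_len(years)) {
    st <- step_year(state, hab, species, globals, year = t - 1L,
                    base_seed = seed)
    state <- st$state
    records[[t]] <- st$record
    ledgers[[t]] <- st$ledger
    if (tallies && length(state$id)) {
      sp_counts[, t] <- tabulate(state$sp, nbins = nrow(species))
      tz <- aggregate(list(n = rep(1L, length(state$sp))),
                      list(sp = state$sp, z = state$z), sum)
      tz$sp <- species$ID_Sp[tz$sp]
      sp_z[[t]] <- cbind(year = t - 1L, tz)
      mass_hist[, t] <- tabulate(
        findInterval(log10(state$mass), mass_breaks, all.inside = TRUE),
        nbins = length(mass_breaks) - 1L)
    }
    if ((t - 1L) %in% record_states) {
      df <- community_df(state, year = t - 1L)
      df$ID_Sp <- species$ID_Sp[df$ID_Sp]
      states[[as.character(t - 1L)]] <- df
    }
    if (!quiet && (t %% 10L == 0L || t == years))
      cat(sprintf("year %4d: N = %6d, S = %3d\n", t - 1L,
                  length(state$id), length(unique(state$sp))))
    if (length(state$id) == 0L && st$record$abundance_start == 0L &&
        st$record$recruits == 0L) {
      # community extinct: remaining years are all-zero records
      stopped_at <- t
      break
    }
    if (t < years) {
      if (streamed) {
        ras_now <- ras_next
        ras_next <- if (t + 2L <= n_snap)
          rasterize_snapshot(forest$snapshots[[t + 2L]], geom) else NULL
        hab <- hab_for_year(t + 1L, ras_now, ras_next)
      } else {
        hab <- habitats[[t + 1L]]
      }
    }
  }

  if (stopped_at > 0L && stopped_at < years) {
    for (t in (stopped_at + 1L):years) {
      rec <- records[[stopped_at]]
      rec$year <- t - 1L
      records[[t]] <- rec
      ledgers[[t]] <- ledgers[[stopped_at]][0, , drop = FALSE]
    }
  }
  structure(list(
    summary = do.call(rbind, records),
    ledger = do.call(rbind, ledgers),
    species_counts = sp_counts,
    sp_z = do.call(rbind, sp_z[!vapply(sp_z, is.null, logical(1))]),
    mass_hist = mass_hist, mass_breaks = mass_breaks,
    final_state = state, states = states,
    species = species, globals = globals, seed = as.integer(seed),
    area_ha = area_ha, shortfall = shortfall,
    config = if (streamed) forest$config else NULL
  ), class = "epx_sim")
}

#' @export
print.epx_sim <- function(x, ...) {
  ny <- nrow(x$summary)
  last <- x$summary[ny, ]
  cat(sprintf("<epx_sim> %d years on %.2f ha\n", ny, x$area_ha))
  cat(sprintf("  final: %d individuals (%.0f /ha), %d species, saturation %.1f %%\n",
              last$abundance, last$abundance / x$area_ha, last$richness,
              last$saturation))
  invisible(x)
}

#' @export
summary.epx_sim <- function(object, window = NULL, ...) {
  s <- object$summary
  if (!is.null(window)) s <- s[s$year %in% window, , drop = FALSE]
  data.frame(
    years = nrow(s),
    mean_abundance_ha = mean(s$abundance) / object$area_ha,
    mean_richness = mean(s$richness),
    mean_saturation = mean(s$saturation),
    mortality_rate = mean(ifelse(
      s$abundance_start > 0,
      100 * (s$deaths_light_niche + s$deaths_competition + s$deaths_oversize +
               s$deaths_dislodgement + s$deaths_metabolic) /
        s$abundance_start, NA), na.rm = TRUE)
  )
}
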