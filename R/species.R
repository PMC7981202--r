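#' Community-wide global parameters
#'
#' Constants shared by every species of a community.
#'
#' @param k_M Intercept of the quarter-power metabolic mortality
#'   probability, `p = min(1, k_M * M^(-1/4))` (a-1 g^(1/4)).
#' @param g_S Scaling factor relating epiphyte biomass to occupied substrate
#'   area, `a = g_S * M^p_A` (m2 g^(-p_A)).
#' @param p_A Area exponent (default 2/3, geometric surface-to-mass
#'   scaling).
#' @param k_Mat Intercept of the power-law relationship between age at
#'   maturity and maximum mass, `A_Mat = k_Mat * M_Max^q_Mat`.
#' @param q_Mat Exponent of that relationship (default 0.25).
#' @param I_top Above-canopy irradiance (umol m-2 s-1).
#' @param k_ext Canopy light extinction coefficient.
#' @param edge_margin Lateral edge-brightening margin (m).
#' @param seedling_mass Mass of a newly established recruit (g).
#' @param est_area_factor Establishment space requirement as a multiple of
#'   the seedling's own occupied area: a voxel admits a recruit only if
#'   this much substrate is free beside the standing occupants
#'   (germination and anchoring need more room than the plantlet body).
#' @param kernel_cut Dispersal neighborhood truncation: voxels where the
#'   kernel falls below this fraction of its peak are ignored.
#' @return Object of class `epx_globals` (named list).
#' @export
global_params <- function(k_M = 0.1, g_S = 0.004, p_A = 2 / 3,
                          k_Mat = 2.0, q_Mat = 0.25,
                          I_top = 1000, k_ext = 0.35, edge_margin = 3,
                          seedling_mass = 0.5, est_area_factor = 6,
                          kernel_cut = 1e-3) {
  check_number(k_M, "k_M", 0)
  check_number(g_S, "g_S", 1e-12)
  check_number(p_A, "p_A", 1e-6, 1)
  check_number(k_Mat, "k_Mat", 1e-12)
  check_number(seedling_mass, "seedling_mass", 1e-9)
  structure(list(
    k_M = k_M, g_S = g_S, p_A = p_A, k_Mat = k_Mat, q_Mat = q_Mat,
    I_top = I_top, k_ext = k_ext, edge_margin = edge_margin,
    seedling_mass = seedling_mass, est_area_factor = est_area_factor,
    kernel_cut = kernel_cut
  ), class = "epx_globals")
}

#' Default species trait ranges
#'
#' Surrogate sampling ranges for the 13 species-specific traits, shipped as
#' a YAML fixtures file in `inst/extdata/trait_ranges.yaml` and calibrated
#' so that sampled communities on the reference forest persist in a dynamic
#' equilibrium (see the methods vignette).
#'
#' @param path Optional alternative YAML file with the same keys.
#' @return Named list of ranges: each entry `c(min, max)`.
#' @export
default_trait_ranges <- function(path = NULL) {
  path <- path %||% system.file("extdata", "trait_ranges.yaml", package = "epivox")
  r <- yaml::read_yaml(path)
  lapply(r, function(v) as.numeric(v))
}

#' Von Bertalanffy growth constant from three life-history traits
#'
#' Under the cubic (length-to-mass) von Bertalanffy trajectory from mass 0,
#' `M(t) = M_Max * (1 - exp(-K t))^3`, the single growth constant follows
#' from age at maturity, mass at maturity and maximum mass:
#' `K = -log(1 - (M_Mat/M_Max)^(1/3)) / A_Mat`, so that
#' `M(A_Mat) = M_Mat` exactly under optimal light.
#'
#' @param A_Mat Age at maturity (years), > 0.
#' @param M_Mat Mass at maturity (g), 0 < M_Mat < M_Max.
#' @param M_Max Maximum mass (g).
#' @return Growth constant K (a-1). Vectorized.
#' @export
derive_growth_rate <- function(A_Mat, M_Mat, M_Max) {
  if (any(A_Mat <= 0)) stopf("A_Mat must be positive")
  ratio <- M_Mat / M_Max
  if (any(ratio >= 1 | ratio <= 0)) stopf("require 0 < M_Mat < M_Max")
  -log(1 - ratio^(1 / 3)) / A_Mat
}

#' Parabolic light response from the niche limits
#'
#' Constructs `f(I) = I_A*I^2 + I_B*I + I_C` with roots at `I_Min` and
#' `I_Max` and maximum value 1 at the niche midpoint
#' `I_Opt = (I_Min + I_Max)/2`.
#'
#' @param I_Min,I_Max Lower / upper light niche limit (umol m-2 s-1).
#' @return List with `I_A`, `I_B`, `I_C`, `I_Opt` (vectorized).
#' @export
derive_light_parabola <- function(I_Min, I_Max) {
  if (any(I_Min >= I_Max)) stopf("require I_Min < I_Max")
  I_Opt <- (I_Min + I_Max) / 2
  h <- (I_Max - I_Min) / 2
  list(I_A = -1 / h^2, I_B = 2 * I_Opt / h^2, I_C = 1 - (I_Opt / h)^2,
       I_Opt = I_Opt)
}

#' Sample a correlated species trait set
#'
#' Draws `n_species` trait vectors from the given ranges: masses and the
#' lower light niche limit log-uniform (both span decades), other traits
#' uniform. Mass at maturity is a uniform
#' fraction of maximum mass; age at maturity follows the trait correlation
#' `A_Mat = k_Mat * M_Max^q_Mat`, jittered multiplicatively and clamped to
#' its range; the growth constant and the light parabola are then derived
#' from the sampled traits.
#'
#' @param ranges Named list of trait ranges, see [default_trait_ranges()].
#'   Keys: `M_Max`, `M_Mat_frac`, `n_RPot`, `D_K`, `D_KAs`, `I_Min`,
#'   `I_width`, `A_Mat_jitter`, `A_Mat`.
#' @param globals [global_params()] object (supplies `k_Mat`, `q_Mat`).
#' @param n_species Number of species, >= 1.
#' @param seed Integer seed.
#' @return Object of class `epx_species`: data frame with one row per
#'   species and columns `ID_Sp`, `A_Mat`, `M_Mat`, `M_Max`, `K`, `n_RPot`,
#'   `D_K`, `D_KAs`, `I_Min`, `I_Opt`, `I_Max`, `I_A`, `I_B`, `I_C`.
#' @export
sample_species_set <- function(ranges = default_trait_ranges(),
                               globals = global_params(),
                               n_species = 100, seed = 1L) {
  if (n_species < 1) stopf("n_species must be >= 1")
  for (nm in c("M_Max", "M_Mat_frac", "n_RPot", "D_K", "D_KAs",
               "I_Min", "I_width", "A_Mat_jitter", "A_Mat")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2] || !all(is.finite(r)))
      stopf("trait range '%s' missing or inverted", nm)
  }
  set.seed(sub_seed(seed, 0L, PHASE[["traits"]]))
  lu <- function(r, n) exp(runif(n, log(r[1]), log(r[2])))
  un <- function(r, n) runif(n, r[1], r[2])
  n <- n_species
  M_Max <- lu(ranges$M_Max, n)
  M_Mat <- un(ranges$M_Mat_frac, n) * M_Max
  A_Mat <- globals$k_Mat * M_Max^globals$q_Mat * un(ranges$A_Mat_jitter, n)
  A_Mat <- pmin(ranges$A_Mat[2], pmax(ranges$A_Mat[1], A_Mat))
  I_Min <- lu(ranges$I_Min, n)  # light thresholds span decades
  I_Max <- pmin(globals$I_top, I_Min + un(ranges$I_width, n))
  par <- derive_light_parabola(I_Min, I_Max)
  out <- data.frame(
    ID_Sp = seq_len(n), A_Mat = A_Mat, M_Mat = M_Mat, M_Max = M_Max,
    K = derive_growth_rate(A_Mat, M_Mat, M_Max),
    n_RPot = un(ranges$n_RPot, n),
    D_K = un(ranges$D_K, n), D_KAs = un(ranges$D_KAs, n),
    I_Min = I_Min, I_Opt = par$I_Opt, I_Max = I_Max,
    I_A = par$I_A, I_B = par$I_B, I_C = par$I_C
  )
  class(out) <- c("epx_species", "data.frame")
  out
}

#' Write / read a species set as CSV
#'
#' One row per species, columns named after the trait symbols.
#'
#' @param species An `epx_species` data frame.
#' @param path File path.
#' @rdname species_csv
#' @export
write_species_csv <- function(species, path) {
  write.csv(as.data.frame(species), path, row.names = FALSE)
  invisible(path)
}

#' @rdname species_csv
#' @export
read_species_csv <- function(path) {
  out <- read.csv(path)
  need <- c("ID_Sp", "A_Mat", "M_Mat", "M_Max", "K", "n_RPot", "D_K",
            "D_KAs", "I_Min", "I_Opt", "I_Max", "I_A", "I_B", "I_C")
  miss <- setdiff(need, names(out))
  if (length(miss)) stopf("species CSV lacks column(s): %s",
                          paste(miss, collapse = ", "))
  class(out) <- c("epx_species", "data.frame")
  out
}

#' Screen species for demographic viability
#'
#' Runs a single-species simulation for each species on the supplied
#' reference microhabitat matrices and computes the geometric mean of the
#' annual population growth rate `N(t+1)/N(t)` over the first century (or
#' the supplied number of years). A species passes iff that rate lies in
#' \[1.00, 1.01\]: it persists without quickly outcompeting the rest of the
#' community. Extinction before year 10 records a rate of 0.
#'
#' @param species An `epx_species` data frame.
#' @param habitats List of `epx_habitat` matrices covering at least `years`
#'   years (recycled periodically if shorter is not allowed).
#' @param globals [global_params()] object.
#' @param years Screening horizon (default 100).
#' @param n0 Founding individuals per species (default 100).
#' @param seed Integer seed; screening is deterministic given the seed.
#' @return Data frame with `ID_Sp`, `rate`, `viable`; attribute
#'   `viable_set` holds the passing subset of `species`.
#' @export
viability_screen <- function(species, habitats, globals = global_params(),
                             years = 100, n0 = 100, seed = 1L) {
  if (length(habitats) < years)
    stopf("habitat matrices cover %d years, need >= %d", length(habitats), years)
  rates <- numeric(nrow(species))
  for (i in seq_len(nrow(species))) {
    sp <- species[i, , drop = FALSE]
    class(sp) <- c("epx_species", "data.frame")
    sim <- run_epiphyte_sim(
      habitats = habitats[seq_len(years)], species = sp, globals = globals,
      init_per_species = n0, seed = sub_seed(seed, i, PHASE[["screen"]]),
      tallies = FALSE, quiet = TRUE
    )
    N0 <- sim$summary$abundance_start
    N1 <- sim$summary$abundance
    if (any(N1 == 0) || any(N0 == 0)) {
      # extinction: geometric mean growth is 0 whenever the population hits 0
      rates[i] <- 0
    } else {
      rates[i] <- exp(mean(log(N1 / N0)))
    }
  }
  res <- data.frame(ID_Sp = species$ID_Sp, rate = rates,
                    viable = rates >= 1.00 & rates <= 1.01)
  keep <- species[res$viable, , drop = FALSE]
  class(keep) <- c("epx_species", "data.frame")
  attr(res, "viable_set") <- keep
  res
}

#' Enumerate the calibration grid over the four sensitive parameters
#'
#' Crosses the levels of the two sensitive global parameters (`k_M`, `g_S`)
#' with the levels of the two species-set generators (the `n_RPot` trait
#' range and the maturity-correlation intercept `k_Mat`). With five levels
#' each this yields the full 25 x 25 = 625 combinations; each row carries a
#' deterministically derived seed.
#'
#' @param k_M_levels,g_S_levels,k_Mat_levels Numeric vectors of levels.
#' @param n_RPot_ranges List of `c(min, max)` trait ranges.
#' @param base_seed Integer seed from which per-combination seeds derive.
#' @return Data frame with one row per combination: `k_M`, `g_S`,
#'   `n_RPot_min`, `n_RPot_max`, `k_Mat`, `seed`.
#' @export
build_calibration_grid <- function(k_M_levels, g_S_levels, n_RPot_ranges,
                                   k_Mat_levels, base_seed = 1L) {
  if (!length(k_M_levels) || !length(g_S_levels) || !length(n_RPot_ranges) ||
      !length(k_Mat_levels))
    stopf("each calibration parameter needs at least one level")
  if (!all(vapply(n_RPot_ranges, length, integer(1)) == 2L))
    stopf("n_RPot_ranges must be a list of c(min, max) pairs")
  grid <- expand.grid(
    k_M = k_M_levels, g_S = g_S_levels,
    n_RPot_i = seq_along(n_RPot_ranges), k_Mat = k_Mat_levels,
    KEEP.OUT.ATTRS = FALSE
  )
  grid$n_RPot_min <- vapply(n_RPot_ranges, `[`, numeric(1), 1)[grid$n_RPot_i]
  grid$n_RPot_max <- vapply(n_RPot_ranges, `[`, numeric(1), 2)[grid$n_RPot_i]
  grid$n_RPot_i <- NULL
  grid$seed <- vapply(seq_len(nrow(grid)), function(i)
    sub_seed(base_seed, i, PHASE[["traits"]]), integer(1))
  grid[, c("k_M", "g_S", "n_RPot_min", "n_RPot_max", "k_Mat", "seed")]
}

#' Build a pool of viable species by repeated sampling and screening
#'
#' Repeats the sample-then-screen procedure until at least `n_pool` viable
#' species are collected (or `max_batches` candidate batches have been
#' screened): candidate species are drawn from the trait ranges, screened
#' in single-species runs on the reference habitat matrices, and passers
#' accumulate in the pool. Replicate community sets for experiments are
#' then subsampled from the pool with [draw_species_set()].
#'
#' @param forest Reference `epx_forest` series (first `years` + 1 snapshots
#'   are used to build the screening habitats), or a list of `epx_habitat`
#'   matrices via `habitats`.
#' @param habitats Optional pre-built habitat matrices.
#' @param ranges,globals Trait ranges and global parameters.
#' @param n_pool Target number of viable species.
#' @param batch Candidate species per screening batch.
#' @param max_batches Upper bound on screened batches.
#' @param years,n0 Screening horizon and founding population size.
#' @param seed Integer seed.
#' @param quiet Suppress progress lines.
#' @return An `epx_species` pool (with re-numbered `ID_Sp` and a
#'   `screen_rate` column of realized growth rates).
#' @export
viable_species_pool <- function(forest = NULL, habitats = NULL,
                                ranges = default_trait_ranges(),
                                globals = global_params(),
                                n_pool = 100, batch = 100, max_batches = 20,
                                years = 100, n0 = 100, seed = 1L,
                                quiet = FALSE) {
  if (is.null(habitats)) {
    if (is.null(forest)) stopf("provide a reference forest or habitats")
    n_take <- min(length(forest$snapshots), years + 1L)
    sub <- forest
    sub$snapshots <- forest$snapshots[seq_len(n_take)]
    habitats <- build_microhabitat(sub, I_top = globals$I_top,
                                   k_ext = globals$k_ext,
                                   edge_margin = globals$edge_margin)
  }
  if (length(habitats) < years)
    stopf("habitats cover %d years, need >= %d", length(habitats), years)
  pool <- list()
  n_found <- 0L
  for (b in seq_len(max_batches)) {
    cand <- sample_species_set(ranges, globals, batch,
                               seed = sub_seed(seed, b, PHASE[["traits"]]))
    scr <- viability_screen(cand, habitats, globals, years = years, n0 = n0,
                            seed = sub_seed(seed, b, PHASE[["screen"]]))
    keep <- attr(scr, "viable_set")
    if (nrow(keep)) {
      keep$screen_rate <- scr$rate[scr$viable]
      pool[[length(pool) + 1L]] <- keep
      n_found <- n_found + nrow(keep)
    }
    if (!quiet)
      cat(sprintf("screen batch %d: %d viable (total %d / %d)\n",
                  b, nrow(keep), n_found, n_pool))
    if (n_found >= n_pool) break
  }
  if (n_found == 0L) stopf("no viable species found in %d batches", max_batches)
  out <- do.call(rbind, pool)
  out$ID_Sp <- seq_len(nrow(out))
  class(out) <- c("epx_species", "data.frame")
  out
}

#' Draw a replicate species set from a viable pool
#'
#' @param pool An `epx_species` pool from [viable_species_pool()].
#' @param n_species Set size (sampled without replacement when the pool is
#'   large enough, with replacement otherwise).
#' @param seed Integer seed.
#' @return An `epx_species` set with re-numbered `ID_Sp`.
#' @export
draw_species_set <- function(pool, n_species = 100, seed = 1L) {
  set.seed(sub_seed(seed, 1L, PHASE[["traits"]]))
  idx <- sample(nrow(pool), n_species, replace = nrow(pool) < n_species)
  out <- pool[idx, , drop = FALSE]
  out$ID_Sp <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("epx_species", "data.frame")
  out
}
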