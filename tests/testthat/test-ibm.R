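test_that("light response matches the parabola inside the niche, 0 outside", {
  sp <- toy_species(I_Min = 10, I_Max = 90)
  expect_equal(light_response(50, sp), 1)
  expect_equal(light_response(10, sp), 0, tolerance = 1e-12)
  expect_equal(light_response(30, sp), 0.75)
  expect_equal(light_response(c(5, 95, 1000), sp), c(0, 0, 0))
})

test_that("growth fixes M_Max, halts in the dark, and hits M_Mat on time", {
  sp <- toy_species(A_Mat = 10, M_Mat = 50, M_Max = 100)
  expect_equal(grow_mass(100, sp$I_Opt, sp), 100)
  expect_equal(grow_mass(25, sp$I_Min, sp), 25)  # f = 0 at the niche edge
  M <- 0
  for (i in 1:10) M <- grow_mass(M, sp$I_Opt, sp)
  expect_equal(M, 50, tolerance = 1e-7)
  # mass never decreases and never exceeds M_Max
  expect_true(all(diff(c(25, grow_mass(25, 300, sp))) >= 0))
})

test_that("initialization places the requested density or reports shortfall", {
  hab <- flat_habitat(nx = 10, ny = 10, nz = 10, I = 500, sb = 2)
  sp <- rbind(toy_species(ID_Sp = 1L), toy_species(ID_Sp = 2L))
  class(sp) <- c("epx_species", "data.frame")
  st <- initialize_community(hab, sp, n_per_species = 50, seed = 1)
  expect_equal(length(st$id), 100L)
  expect_equal(anyDuplicated(st$id), 0L)
  expect_true(all(st$age == 0))
  expect_true(all(st$mass >= 0.1 & st$mass <= sp$M_Mat[st$sp]))
  # all-dark forest: niches exclude 0, so no placement, full shortfall
  dark <- flat_habitat(nx = 10, ny = 10, nz = 10, I = 0, sb = 2)
  st0 <- initialize_community(dark, sp, n_per_species = 50, seed = 1)
  expect_equal(length(st0$id), 0L)
  expect_equal(sum(attr(st0, "shortfall")), 100)
})

test_that("initial placement follows the substrate-proportional law", {
  nx <- 6
  geom <- c(nx = nx, ny = nx, nz = nx)
  sb <- array(rep_len(c(0.5, 1, 2, 4), nx^3), dim = geom)
  hab <- epivox:::new_habitat(0L, array(500, geom), sb, array(0, geom), geom)
  sp <- toy_species()
  st <- initialize_community(hab, sp, n_per_species = 100000, seed = 7)
  obs <- tabulate(epivox:::voxel_index(st$x, st$y, st$z, geom), nbins = nx^3)
  expected <- as.vector(sb) / sum(sb) * length(st$id)
  X2 <- sum((obs - expected)^2 / expected)
  expect_lt(X2, stats::qchisq(0.999, df = nx^3 - 1))
})

test_that("recruitment conserves the Poisson expectation under uniform substrate", {
  hab <- flat_habitat(nx = 17, ny = 17, nz = 17, I = 500, sb = 1)
  sp <- toy_species(I_Min = 10, I_Max = 990, A_Mat = 1, n_RPot = 2,
                    D_K = 1, D_KAs = 1)
  lam <- sp$n_RPot * light_response(500, sp)
  st <- toy_community(mass = 60, x = 8, y = 8, z = 8, age = 5)
  set.seed(99)
  seeds <- sample.int(1e6, 2000)
  counts <- vapply(seeds, function(s)
    disperse_and_recruit(st, hab, sp, global_params(), seed = s)$recruits,
    integer(1))
  se <- sqrt(lam / length(counts))
  expect_lt(abs(mean(counts) - lam), 3 * se)
  # no fecundity, no recruits
  sp0 <- toy_species(n_RPot = 0, A_Mat = 1)
  expect_equal(disperse_and_recruit(st, hab, sp0, global_params(),
                                    seed = 1)$recruits, 0L)
})

test_that("kernel asymmetry biases recruits downward by the stated factor", {
  hab <- flat_habitat(nx = 17, ny = 17, nz = 17, I = 500, sb = 1)
  sp <- toy_species(I_Min = 10, I_Max = 990, A_Mat = 1, n_RPot = 4,
                    D_K = 1, D_KAs = 3)
  st <- toy_community(mass = 60, x = 8, y = 8, z = 8, age = 5)
  down <- 0; up <- 0
  for (s in 1:800) {
    r <- disperse_and_recruit(st, hab, sp, global_params(), seed = s)$state
    if (length(r$id) > 1) {
      dz <- r$z[-1] - 8L
      down <- down + sum(dz < 0); up <- up + sum(dz > 0)
    }
  }
  p_hat <- down / (down + up)  # expected 3 / (3 + 1)
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / (down + up)))
})

test_that("space competition removes smallest first with deterministic ties", {
  geom <- c(nx = 3, ny = 3, nz = 3)
  sb <- array(0.5, geom)
  hab <- epivox:::new_habitat(0L, array(500, geom), sb, array(0, geom), geom)
  glob <- global_params(k_M = 0, g_S = 1, p_A = 1)
  sp <- toy_species(I_Min = 1, I_Max = 999)
  st <- toy_community(mass = c(0.4, 0.1, 0.1), x = 1, y = 1, z = 1, age = 0)
  out <- apply_mortality(st, hab, sp, glob)
  expect_equal(out$deaths[["competition"]], 1L)
  expect_equal(sum(out$deaths), 1L)
  expect_equal(out$state$id, c(1L, 2L))  # the higher-id tie loses
  # a lone oversized individual dies of oversize, not competition
  st2 <- toy_community(mass = 0.9, x = 1, y = 1, z = 1)
  out2 <- apply_mortality(st2, hab, sp, glob)
  expect_equal(out2$deaths[["oversize"]], 1L)
  expect_equal(length(out2$state$id), 0L)
})

test_that("total substrate loss kills every resident with certainty", {
  geom <- c(nx = 3, ny = 3, nz = 3)
  hab <- epivox:::new_habitat(0L, array(500, geom), array(10, geom),
                              array(100, geom), geom)
  glob <- global_params(k_M = 0)
  sp <- toy_species(I_Min = 1, I_Max = 999)
  st <- toy_community(mass = rep(1, 7), x = c(0:2, 0:2, 1), y = 1, z = 1)
  out <- apply_mortality(st, hab, sp, glob)
  expect_equal(out$deaths[["dislodgement"]], 7L)
  expect_equal(length(out$state$id), 0L)
})

test_that("metabolic survivorship follows the closed-form expectation", {
  # constant mass 16 g and k_M = 0.1 give a death probability of exactly
  # 0.05 per year; light pinned to the niche edge freezes growth
  sp <- toy_species(I_Min = 100, I_Max = 900, n_RPot = 0)
  geom <- c(nx = 20, ny = 20, nz = 5)
  hab <- epivox:::new_habitat(0L, array(100, geom), array(1e6, geom),
                              array(0, geom), geom)
  glob <- global_params(k_M = 0.1)
  n0 <- 2000
  st <- toy_community(mass = rep(16, n0), x = rep(0:19, 100),
                      y = rep(0:19, each = 100), z = 1)
  for (yr in 0:9)
    st <- step_year(st, hab, sp, glob, year = yr, base_seed = 21)$state
  expected <- n0 * (1 - 0.05)^10
  se <- sqrt(n0 * (0.95^10) * (1 - 0.95^10))
  expect_lt(abs(length(st$id) - expected), 3 * se)
})

test_that("an empty community without mature plants stays empty", {
  hab <- flat_habitat(nx = 5, ny = 5, nz = 5)
  sp <- toy_species()
  st <- epivox:::new_community(1L)
  out <- step_year(st, hab, sp, global_params(), year = 0, base_seed = 1)
  expect_equal(length(out$state$id), 0L)
  expect_equal(out$record$abundance, 0L)
})

test_that("one annual step matches the brute-force oracle exactly", {
  geom <- c(nx = 3, ny = 3, nz = 3)
  set.seed(42)
  sb <- array(runif(27, 0, 0.3), dim = geom)
  sb[sample(27, 5)] <- 0
  I <- array(runif(27, 5, 900), dim = geom)
  sl <- array(runif(27, 0, 30), dim = geom)
  hab <- epivox:::new_habitat(0L, I, sb, sl, geom)
  sp <- rbind(toy_species(ID_Sp = 1L, I_Min = 5, I_Max = 950, A_Mat = 2,
                          n_RPot = 3, D_K = 1, D_KAs = 2),
              toy_species(ID_Sp = 2L, I_Min = 20, I_Max = 700, A_Mat = 3,
                          n_RPot = 5, D_K = 0.8, D_KAs = 1.5))
  class(sp) <- c("epx_species", "data.frame")
  glob <- global_params(k_M = 0.1, g_S = 0.05, p_A = 2 / 3)
  occ <- which(as.vector(sb) > 0)
  set.seed(1)
  vi <- sample(occ, 10, replace = TRUE) - 1L
  st <- toy_community(mass = runif(10, 0.1, 20),
                      x = vi %% 3L, y = (vi %/% 3L) %% 3L, z = vi %/% 9L,
                      sp = rep(1:2, 5), age = sample(0:6, 10, TRUE))
  st_pkg <- st; st_ora <- st
  for (yr in 0:2) {
    st_pkg <- step_year(st_pkg, hab, sp, glob, year = yr, base_seed = 77)$state
    st_ora <- oracle_step(st_ora, hab, sp, glob, year = yr, base_seed = 77)
    for (nm in c("id", "sp", "x", "y", "z"))
      expect_equal(unname(st_pkg[[nm]]), unname(st_ora[[nm]]),
                   info = sprintf("field %s, year %d", nm, yr))
    expect_equal(st_pkg$mass, st_ora$mass, tolerance = 1e-12)
    expect_equal(st_pkg$age, st_ora$age)
  }
})

test_that("trajectories conserve individuals and never break the invariants", {
  cfg <- forest_config(plot_x = 20, plot_y = 20, years = 40, seed = 13,
                       demography = list(m_base = 0.025))
  f <- generate_forest(cfg, burn_in = 60)
  habs <- build_microhabitat(f)
  sp <- sample_species_set(n_species = 10, seed = 5)
  glob <- global_params()
  st <- initialize_community(habs[[1]], sp, n_per_species = 30,
                             globals = glob, seed = 2)
  richness_prev <- Inf
  for (t in seq_len(40)) {
    out <- step_year(st, habs[[t]], sp, glob, year = t - 1, base_seed = 9)
    rec <- out$record
    # conservation: N(t+1) = N(t) + recruits - sum(deaths by cause)
    deaths <- rec$deaths_light_niche + rec$deaths_competition +
      rec$deaths_oversize + rec$deaths_dislodgement + rec$deaths_metabolic
    expect_equal(rec$abundance, rec$abundance_start + rec$recruits - deaths)
    # ledger partition matches the per-species ledger
    expect_equal(sum(out$ledger$count), deaths)
    st <- out$state
    # closed system: richness never increases
    expect_lte(rec$richness, richness_prev)
    richness_prev <- rec$richness
    # no one sits on bare voxels, exceeds M_Max, or overfills a voxel
    if (length(st$id)) {
      vi <- epivox:::voxel_index(st$x, st$y, st$z, f$geometry)
      expect_true(all(habs[[t]]$S_B[vi] > 0))
      expect_true(all(st$mass <= sp$M_Max[st$sp] + 1e-9))
      a <- glob$g_S * st$mass^glob$p_A
      load <- rowsum(a, vi)
      expect_true(all(load[, 1] <= habs[[t]]$S_B[as.integer(rownames(load))] + 1e-6))
    }
  }
})

test_that("identical seed and config reproduce the trajectory bit for bit", {
  cfg <- forest_config(plot_x = 20, plot_y = 20, years = 15, seed = 13,
                       demography = list(m_base = 0.025))
  f <- generate_forest(cfg, burn_in = 40)
  sp <- sample_species_set(n_species = 8, seed = 5)
  s1 <- run_epiphyte_sim(forest = f, species = sp, init_per_species = 20,
                         seed = 4, quiet = TRUE)
  s2 <- run_epiphyte_sim(forest = f, species = sp, init_per_species = 20,
                         seed = 4, quiet = TRUE)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$final_state, s2$final_state)
})
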