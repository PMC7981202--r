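# Straight-line, loop-based re-implementation of one annual step, kept
# deliberately free of the package's vectorized/compiled code paths. Used
# to pin down the exact semantics (and RNG draw order) of step_year().

oracle_step <- function(state, hab, species, globals, year, base_seed) {
  dims <- hab$geometry
  nx <- dims[[1]]; ny <- dims[[2]]; nz <- dims[[3]]
  getI <- function(x, y, z) hab$I[x + 1, y + 1, z + 1]
  getSB <- function(x, y, z) hab$S_B[x + 1, y + 1, z + 1]
  getSL <- function(x, y, z) hab$S_Loss[x + 1, y + 1, z + 1]
  fresp <- function(I, s) {
    if (I < species$I_Min[s] || I > species$I_Max[s]) return(0)
    max(0, species$I_A[s] * I^2 + species$I_B[s] * I + species$I_C[s])
  }
  n_start <- length(state$id)

  # --- recruitment ---------------------------------------------------------
  set.seed(epivox:::sub_seed(base_seed, year, epivox:::PHASE[["recruit"]]))
  mat <- which(state$age >= species$A_Mat[state$sp])
  cand <- list()
  for (k in mat) {
    s <- state$sp[k]
    lam <- species$n_RPot[s] * fresp(getI(state$x[k], state$y[k], state$z[k]), s)
    if (lam <= 0) next
    n <- rpois(1, lam)
    if (n < 1) next
    dk <- species$D_K[s]; as_ <- species$D_KAs[s]
    Rr <- ceiling(log(1 / globals$kernel_cut) / dk)
    maxd2 <- (log(1 / globals$kernel_cut) / dk)^2
    w <- numeric(0); vx <- integer(0); vy <- integer(0); vz <- integer(0)
    for (dx in -Rr:Rr) {
      x <- state$x[k] + dx
      if (x < 0 || x >= nx) next
      for (dy in -Rr:Rr) {
        y <- state$y[k] + dy
        if (y < 0 || y >= ny) next
        if (dx^2 + dy^2 > maxd2) next
        for (dz in -Rr:Rr) {
          z <- state$z[k] + dz
          if (z < 0 || z >= nz) next
          d2 <- dx^2 + dy^2 + dz^2
          if (d2 > maxd2) next
          sb <- getSB(x, y, z)
          if (sb <= 0) next
          wk <- sb * exp(-dk * sqrt(d2))
          if (dz < 0) wk <- wk * as_
          w <- c(w, wk); vx <- c(vx, x); vy <- c(vy, y); vz <- c(vz, z)
        }
      }
    }
    if (sum(w) <= 0) next
    cw <- cumsum(w)
    for (j in seq_len(n)) {
      u <- runif(1) * sum(w)
      pick <- which(u <= cw)[1]
      if (is.na(pick)) pick <- length(w)
      cand[[length(cand) + 1L]] <- c(vx[pick], vy[pick], vz[pick], s)
    }
  }
  # free-substrate capacity per voxel before any recruit establishes
  a_seed <- globals$g_S * globals$seedling_mass^globals$p_A
  standing <- numeric(nx * ny * nz)
  for (i in seq_along(state$id)) {
    v <- state$x[i] + nx * (state$y[i] + ny * state$z[i]) + 1
    standing[v] <- standing[v] + globals$g_S * state$mass[i]^globals$p_A
  }
  placed <- integer(nx * ny * nz)
  recruits <- 0L
  for (cc in cand) {
    I <- getI(cc[1], cc[2], cc[3])
    if (I < species$I_Min[cc[4]] || I > species$I_Max[cc[4]]) next
    v <- cc[1] + nx * (cc[2] + ny * cc[3]) + 1
    est_f <- if (is.null(globals$est_area_factor)) 1 else globals$est_area_factor
    cap <- floor((getSB(cc[1], cc[2], cc[3]) - standing[v]) / (est_f * a_seed) + 1e-9)
    if (placed[v] + 1 > cap) next
    placed[v] <- placed[v] + 1L
    state$id <- c(state$id, state$next_id)
    state$next_id <- state$next_id + 1L
    state$sp <- c(state$sp, cc[4])
    state$age <- c(state$age, 0)
    state$mass <- c(state$mass, globals$seedling_mass)
    state$x <- c(state$x, cc[1]); state$y <- c(state$y, cc[2])
    state$z <- c(state$z, cc[3])
    recruits <- recruits + 1L
  }

  # --- growth --------------------------------------------------------------
  for (i in seq_along(state$id)) {
    s <- state$sp[i]
    f <- fresp(getI(state$x[i], state$y[i], state$z[i]), s)
    mm <- species$M_Max[s]
    state$mass[i] <- mm * (1 - (1 - min(1, state$mass[i] / mm)^(1 / 3)) *
                             exp(-species$K[s] * f))^3
  }

  # --- mortality -----------------------------------------------------------
  kill <- function(state, die) {
    for (nm in c("id", "sp", "age", "mass", "x", "y", "z"))
      state[[nm]] <- state[[nm]][!die]
    state
  }
  # light niche
  die <- vapply(seq_along(state$id), function(i) {
    I <- getI(state$x[i], state$y[i], state$z[i])
    I < species$I_Min[state$sp[i]] || I > species$I_Max[state$sp[i]]
  }, logical(1))
  if (length(die)) state <- kill(state, die)
  # space: per voxel remove smallest first (mass ties: keep lower id)
  if (length(state$id)) {
    vi <- state$x + nx * (state$y + ny * state$z)
    die <- rep(FALSE, length(state$id))
    for (v in unique(vi)) {
      res <- which(vi == v)
      res <- res[order(-state$mass[res], state$id[res])]
      cap <- getSB(state$x[res[1]], state$y[res[1]], state$z[res[1]])
      tot <- 0
      for (i in res) {
        tot <- tot + globals$g_S * state$mass[i]^globals$p_A
        if (tot > cap + 1e-9) die[i] <- TRUE
      }
    }
    state <- kill(state, die)
  }
  # dislodgement
  if (length(state$id)) {
    set.seed(epivox:::sub_seed(base_seed, year, epivox:::PHASE[["mort_fall"]]))
    die <- rep(FALSE, length(state$id))
    for (i in seq_along(state$id))
      die[i] <- runif(1) < getSL(state$x[i], state$y[i], state$z[i]) / 100
    state <- kill(state, die)
  }
  # metabolic
  if (length(state$id)) {
    set.seed(epivox:::sub_seed(base_seed, year, epivox:::PHASE[["mort_metab"]]))
    die <- rep(FALSE, length(state$id))
    for (i in seq_along(state$id))
      die[i] <- runif(1) < min(1, globals$k_M * state$mass[i]^(-1 / 4))
    state <- kill(state, die)
  }
  state$age <- state$age + 1
  state
}
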