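# Small in-code fixtures shared across test files.

# a bare habitat with constant light and substrate (no edge effects)
flat_habitat <- function(nx = 17, ny = 17, nz = 17, I = 500, sb = 1,
                         s_loss = 0) {
  geom <- c(nx = nx, ny = ny, nz = nz)
  epivox:::new_habitat(
    0L,
    array(I, dim = geom), array(sb, dim = geom), array(s_loss, dim = geom),
    geom
  )
}

# hand-built forest series from a list of tree data frames
make_series <- function(snapshots, nx = 20, ny = 20, nz = 50,
                        config = forest_config(plot_x = nx, plot_y = ny,
                                               years = length(snapshots))) {
  snaps <- lapply(snapshots, function(s) {
    if (is.null(s$height)) {
      al <- epivox:::tree_allometry(s$dbh)
      s <- cbind(s, al)
    }
    s
  })
  out <- structure(list(
    snapshots = snaps, counts = NULL,
    geometry = c(nx = nx, ny = ny, nz = nz),
    config = config, m_base = NA_real_
  ), class = "epx_forest")
  out$counts <- epivox:::recount_series(out)
  out
}

# a tree row without crown (trunk only)
bare_trunk <- function(x, y, dbh, height, id = 1L) {
  data.frame(x = x, y = y, id = id, dbh = dbh, height = height,
             crown_radius = 0, crown_depth = 0, branch_area = 0,
             leaf_area = 0)
}

# single-species trait table built from explicit values
toy_species <- function(I_Min = 10, I_Max = 990, A_Mat = 5, M_Mat = 50,
                        M_Max = 100, n_RPot = 1, D_K = 1, D_KAs = 1,
                        ID_Sp = 1L) {
  par <- derive_light_parabola(I_Min, I_Max)
  out <- data.frame(
    ID_Sp = ID_Sp, A_Mat = A_Mat, M_Mat = M_Mat, M_Max = M_Max,
    K = derive_growth_rate(A_Mat, M_Mat, M_Max), n_RPot = n_RPot,
    D_K = D_K, D_KAs = D_KAs, I_Min = I_Min, I_Opt = par$I_Opt,
    I_Max = I_Max, I_A = par$I_A, I_B = par$I_B, I_C = par$I_C
  )
  class(out) <- c("epx_species", "data.frame")
  out
}

# a community of given masses in given voxels (single species by default)
toy_community <- function(mass, x, y, z, sp = 1L, age = 0) {
  n <- length(mass)
  st <- epivox:::new_community(max(sp))
  st$id <- seq_len(n); st$sp <- rep_len(sp, n)
  st$age <- rep_len(age, n); st$mass <- mass
  st$x <- as.integer(rep_len(x, n)); st$y <- as.integer(rep_len(y, n))
  st$z <- as.integer(rep_len(z, n)); st$next_id <- n + 1L
  st
}
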