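#' Voxel substrate area from a tree snapshot
#'
#' Rasterizes a tree list onto the 1-m voxel lattice. Each trunk contributes
#' its cylindrical lateral area, `pi * DBH/100 * intersected length`, to the
#' voxels it crosses (the partial top metre contributes proportionally).
#' Each tree's total branch surface area is distributed uniformly over its
#' crown voxels (a cylinder of the crown radius spanning
#' `[height - crown_depth, height]`). Voxel coordinates are 0-based with
#' half-open `[i, i+1)` metre bins on every axis.
#'
#' @param trees Tree data frame with columns `x`, `y`, `dbh`, `height`,
#'   `crown_radius`, `crown_depth`, `branch_area` (as in `epx_forest`
#'   snapshots).
#' @param geometry Integer vector `c(nx, ny, nz)` of plot dimensions in m.
#' @return 3-D array `[nx, ny, nz]` of substrate area (m2) per voxel.
#' @export
substrate_area <- function(trees, geometry) {
  rasterize_snapshot(trees, geometry)$S_B
}

# Shared rasterizer: substrate area and leaf area density in one pass.
rasterize_snapshot <- function(trees, geometry) {
  nx <- geometry[[1]]; ny <- geometry[[2]]; nz <- geometry[[3]]
  S_B <- array(0, dim = c(nx, ny, nz))
  LAD <- array(0, dim = c(nx, ny, nz))
  if (is.null(trees) || nrow(trees) == 0L) return(list(S_B = S_B, LAD = LAD))
  xi <- pmin(nx - 1L, pmax(0L, floor(trees$x)))
  yi <- pmin(ny - 1L, pmax(0L, floor(trees$y)))
  ht <- pmin(trees$height, nz)
  # trunks
  idx_acc <- vector("list", nrow(trees) + 1L)
  val_acc <- vector("list", nrow(trees) + 1L)
  for (i in seq_len(nrow(trees))) {
    h <- ht[i]
    if (h <= 0) next
    ztop <- ceiling(h) - 1L
    zz <- 0:ztop
    len <- pmin(1, h - zz)
    idx_acc[[i]] <- voxel_index(xi[i], yi[i], zz, c(nx, ny, nz))
    val_acc[[i]] <- pi * trees$dbh[i] / 100 * len
  }
  # crowns: leaf area spread uniformly over crown voxels; branch surface
  # concentrated branch-like, inner-crown-first, at a fixed density of
  # `branch_voxel_area` m2 per filled voxel, so a growing tree only adds
  # substrate voxels (existing ones never shrink while the tree lives)
  s0 <- attr(trees, "branch_voxel_area") %||% 0.5
  cidx <- vector("list", nrow(trees))
  cval <- vector("list", nrow(trees))
  lval <- vector("list", nrow(trees))
  for (i in seq_len(nrow(trees))) {
    if (trees$branch_area[i] <= 0 && (is.null(trees$leaf_area) || trees$leaf_area[i] <= 0)) next
    cv <- crown_voxels(xi[i], yi[i], ht[i], trees$crown_radius[i],
                       trees$crown_depth[i], nx, ny, nz)
    if (length(cv) == 0L) next
    ba <- trees$branch_area[i]
    bval <- numeric(length(cv))
    if (ba >= s0 * length(cv)) {
      bval[] <- ba / length(cv)  # crown smaller than the branch area demands
    } else if (ba > 0) {
      nfill <- ceiling(ba / s0)
      bval[seq_len(nfill)] <- s0
      bval[nfill] <- ba - s0 * (nfill - 1L)
    }
    cidx[[i]] <- cv
    cval[[i]] <- bval
    la <- if (is.null(trees$leaf_area)) 0 else trees$leaf_area[i]
    lval[[i]] <- rep(la / length(cv), length(cv))
  }
  ti <- unlist(idx_acc); tv <- unlist(val_acc)
  if (length(ti)) {
    agg <- rowsum(tv, ti)
    S_B[as.integer(rownames(agg))] <- S_B[as.integer(rownames(agg))] + agg[, 1]
  }
  ci <- unlist(cidx)
  if (length(ci)) {
    agg <- rowsum(unlist(cval), ci)
    S_B[as.integer(rownames(agg))] <- S_B[as.integer(rownames(agg))] + agg[, 1]
    agg <- rowsum(unlist(lval), ci)
    LAD[as.integer(rownames(agg))] <- LAD[as.integer(rownames(agg))] + agg[, 1]
  }
  list(S_B = S_B, LAD = LAD)
}

# voxel indices of a crown cylinder, clipped to the plot, ordered
# inner-crown-first (radial distance from the stem axis ascending, upper
# layers first within a column) so branch substrate concentrates where
# epiphyte loads are highest in real canopies
crown_voxels <- function(xi, yi, height, radius, depth, nx, ny, nz) {
  if (height <= 0 || depth <= 0) return(integer(0))
  z0 <- max(0L, floor(height - depth))
  z1 <- min(nz - 1L, ceiling(height) - 1L)
  if (z1 < z0) z1 <- z0
  r <- max(0L, floor(radius))
  dx <- -r:r
  off <- expand.grid(dx = dx, dy = dx)
  off <- off[off$dx^2 + off$dy^2 <= radius^2 | (off$dx == 0 & off$dy == 0), , drop = FALSE]
  off <- off[order(off$dx^2 + off$dy^2, off$dx, off$dy), , drop = FALSE]
  cx <- xi + off$dx; cy <- yi + off$dy
  ok <- cx >= 0 & cx < nx & cy >= 0 & cy < ny
  cx <- cx[ok]; cy <- cy[ok]
  if (!length(cx)) return(integer(0))
  zz <- z1:z0
  voxel_index(rep(cx, each = length(zz)), rep(cy, each = length(zz)),
              rep(zz, times = length(cx)), c(nx, ny, nz))
}

#' Voxel light field from a tree snapshot
#'
#' Beer--Lambert extinction down each 1-m column:
#' `I(z) = I_top * exp(-k_ext * LAI_above(z))`, where `LAI_above(z)` is the
#' cumulative leaf area (per m2 of column) strictly above voxel layer `z`.
#' Within `edge_margin` m of a lateral plot boundary the field is blended
#' linearly toward `I_top`, so light increases toward the forest edge.
#'
#' @inheritParams substrate_area
#' @param I_top Above-canopy irradiance (umol m-2 s-1), > 0.
#' @param k_ext Extinction coefficient (default 0.35).
#' @param edge_margin Lateral edge-brightening margin in m (default 3).
#' @return 3-D array `[nx, ny, nz]` of light intensity.
#' @export
light_field <- function(trees, geometry, I_top = 1000, k_ext = 0.35,
                        edge_margin = 3) {
  check_number(I_top, "I_top", lower = 1e-12)
  LAD <- rasterize_snapshot(trees, geometry)$LAD
  light_from_lad(LAD, I_top, k_ext, edge_margin)
}

light_from_lad <- function(LAD, I_top, k_ext = 0.5, edge_margin = 3) {
  d <- dim(LAD)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  A <- matrix(LAD, nx * ny, nz)
  above <- matrix(0, nx * ny, nz)
  if (nz > 1L) {
    for (z in (nz - 1L):1L) above[, z] <- above[, z + 1L] + A[, z + 1L]
  }
  I <- I_top * exp(-k_ext * above)
  if (edge_margin > 0) {
    xs <- (seq_len(nx) - 0.5); ys <- (seq_len(ny) - 0.5)
    dx <- pmin(xs, nx - xs); dy <- pmin(ys, ny - ys)
    dmat <- outer(dx, dy, pmin)
    w <- pmax(0, (edge_margin - as.vector(dmat)) / edge_margin)
    I <- I + w * (I_top - I)
  }
  array(I, dim = d)
}

#' Relative annual substrate loss between consecutive years
#'
#' `S_Loss = 100 * max(0, S_B_now - S_B_next) / S_B_now` where
#' `S_B_now > 0`, else 0; clamped to \[0, 100\]. Gains are not losses:
#' the quantity is used as a dislodgement (fall) mortality probability.
#'
#' @param S_B_now,S_B_next Substrate-area arrays of equal shape for years
#'   t and t+1.
#' @return Array of percentage annual surface-area loss.
#' @export
substrate_loss <- function(S_B_now, S_B_next) {
  if (!identical(dim(S_B_now), dim(S_B_next)))
    stopf("substrate arrays have mismatched shapes")
  out <- array(0, dim = dim(S_B_now))
  pos <- S_B_now > 0
  out[pos] <- 100 * pmax(0, S_B_now[pos] - S_B_next[pos]) / S_B_now[pos]
  pmin(out, 100)
}

# habitat object for one year (dim attributes normalized to unnamed)
new_habitat <- function(year, I, S_B, S_Loss, geometry) {
  strip <- function(a) { dim(a) <- unname(dim(a)); a }
  structure(list(year = year, I = strip(I), S_B = strip(S_B),
                 S_Loss = strip(S_Loss), geometry = geometry),
            class = "epx_habitat")
}

#' @export
print.epx_habitat <- function(x, ...) {
  cat(sprintf(
    "<epx_habitat> year %d, %d x %d x %d voxels, total substrate %.1f m2\n",
    x$year, x$geometry[[1]], x$geometry[[2]], x$geometry[[3]], sum(x$S_B)))
  invisible(x)
}

#' Build the yearly microhabitat matrices for a forest series
#'
#' For each year t the light field and substrate area are computed from the
#' year-t snapshot and the relative substrate loss from the (t, t+1) pair;
#' the final year's loss is 0 by convention. Note that the full sequence for
#' long runs is large (`nx*ny*nz*3` doubles per year); the simulation loop
#' streams these matrices internally instead of materializing them.
#'
#' @param series An `epx_forest` object (>= 1 snapshot).
#' @param I_top,k_ext,edge_margin See [light_field()].
#' @return List of `epx_habitat` objects, one per year.
#' @export
build_microhabitat <- function(series, I_top = 1000, k_ext = 0.35,
                               edge_margin = 3) {
  stopifnot(inherits(series, "epx_forest"))
  ny <- length(series$snapshots)
  geom <- series$geometry
  out <- vector("list", ny)
  ras_next <- rasterize_snapshot(series$snapshots[[1]], geom)
  for (t in seq_len(ny)) {
    ras <- ras_next
    I <- light_from_lad(ras$LAD, I_top, k_ext, edge_margin)
    if (t < ny) {
      ras_next <- rasterize_snapshot(series$snapshots[[t + 1L]], geom)
      sl <- substrate_loss(ras$S_B, ras_next$S_B)
    } else {
      sl <- array(0, dim = dim(ras$S_B))
    }
    out[[t]] <- new_habitat(t - 1L, I, ras$S_B, sl, geom)
  }
  out
}

# ---- gridded serialization ------------------------------------------------

#' Write / read microhabitat matrices
#'
#' Two formats are supported. `write_microhabitat_nc()` stores the yearly
#' grids in a NetCDF file with dimensions `x`, `y`, `z`, `year` and
#' variables `I` (umol m-2 s-1), `S_B` (m2) and `S_Loss` (percent); it
#' requires the ncdf4 package. `write_microhabitat_csv()` writes the same
#' content as a plain long-format CSV (`year,x,y,z,I,S_B,S_Loss`; zero-only
#' voxels included so the round trip is exact). Externally produced files
#' with either layout are accepted in place of generator output.
#'
#' @param habitats List of `epx_habitat` objects.
#' @param path File path.
#' @rdname microhabitat_io
#' @export
write_microhabitat_nc <- function(habitats, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stopf("the ncdf4 package is required for NetCDF output")
  geom <- habitats[[1]]$geometry
  dx <- ncdf4::ncdim_def("x", "m", 0:(geom[[1]] - 1L))
  dy <- ncdf4::ncdim_def("y", "m", 0:(geom[[2]] - 1L))
  dz <- ncdf4::ncdim_def("z", "m", 0:(geom[[3]] - 1L))
  dt <- ncdf4::ncdim_def("year", "a", vapply(habitats, `[[`, integer(1), "year"))
  vI <- ncdf4::ncvar_def("I", "umol m-2 s-1", list(dx, dy, dz, dt), prec = "double")
  vS <- ncdf4::ncvar_def("S_B", "m2", list(dx, dy, dz, dt), prec = "double")
  vL <- ncdf4::ncvar_def("S_Loss", "percent", list(dx, dy, dz, dt), prec = "double")
  nc <- ncdf4::nc_create(path, list(vI, vS, vL))
  on.exit(ncdf4::nc_close(nc))
  for (k in seq_along(habitats)) {
    st <- c(1, 1, 1, k); ct <- c(geom[[1]], geom[[2]], geom[[3]], 1)
    ncdf4::ncvar_put(nc, vI, habitats[[k]]$I, start = st, count = ct)
    ncdf4::ncvar_put(nc, vS, habitats[[k]]$S_B, start = st, count = ct)
    ncdf4::ncvar_put(nc, vL, habitats[[k]]$S_Loss, start = st, count = ct)
  }
  invisible(path)
}

#' @rdname microhabitat_io
#' @export
read_microhabitat_nc <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stopf("the ncdf4 package is required for NetCDF input")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  years <- as.integer(nc$dim$year$vals)
  geom <- c(nx = nc$dim$x$len, ny = nc$dim$y$len, nz = nc$dim$z$len)
  lapply(seq_along(years), function(k) {
    st <- c(1, 1, 1, k); ct <- c(geom[[1]], geom[[2]], geom[[3]], 1)
    new_habitat(
      years[k],
      array(ncdf4::ncvar_get(nc, "I", start = st, count = ct), dim = geom),
      array(ncdf4::ncvar_get(nc, "S_B", start = st, count = ct), dim = geom),
      array(ncdf4::ncvar_get(nc, "S_Loss", start = st, count = ct), dim = geom),
      geom
    )
  })
}

#' @rdname microhabitat_io
#' @export
write_microhabitat_csv <- function(habitats, path) {
  geom <- habitats[[1]]$geometry
  grid <- expand.grid(x = 0:(geom[[1]] - 1L), y = 0:(geom[[2]] - 1L),
                      z = 0:(geom[[3]] - 1L))
  rows <- do.call(rbind, lapply(habitats, function(h) {
    data.frame(year = h$year, grid, I = as.vector(h$I),
               S_B = as.vector(h$S_B), S_Loss = as.vector(h$S_Loss))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname microhabitat_io
#' @export
read_microhabitat_csv <- function(path) {
  rows <- read.csv(path)
  need <- c("year", "x", "y", "z", "I", "S_B", "S_Loss")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stopf("microhabitat CSV lacks column(s): %s",
                          paste(miss, collapse = ", "))
  geom <- c(nx = max(rows$x) + 1L, ny = max(rows$y) + 1L, nz = max(rows$z) + 1L)
  lapply(sort(unique(rows$year)), function(yr) {
    r <- rows[rows$year == yr, , drop = FALSE]
    if (nrow(r) != prod(geom))
      stopf("microhabitat CSV year %d has %d voxels, expected %d",
            yr, nrow(r), prod(geom))
    o <- order(r$z, r$y, r$x)
    new_habitat(yr,
                array(r$I[o], dim = geom),
                array(r$S_B[o], dim = geom),
                array(r$S_Loss[o], dim = geom), geom)
  })
}
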