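geom20 <- c(nx = 20, ny = 20, nz = 50)

test_that("an empty plot rasterizes to all-zero substrate", {
  expect_true(all(substrate_area(data.frame(), geom20) == 0))
})

test_that("a bare trunk contributes its cylindrical lateral area per voxel", {
  tr <- bare_trunk(10.5, 10.5, dbh = 31.83, height = 10)
  sb <- substrate_area(tr, geom20)
  col <- sb[11, 11, ]
  expect_equal(col[1:10], rep(pi * 0.3183, 10), tolerance = 1e-12)
  expect_true(all(col[11:50] == 0))
  expect_equal(sum(sb), pi * 0.3183 * 10, tolerance = 1e-12)
})

test_that("substrate of disjoint trees is additive", {
  t1 <- bare_trunk(3.5, 3.5, 20, 8)
  t2 <- bare_trunk(15.5, 15.5, 30, 12)
  both <- rbind(t1, t2)
  expect_equal(substrate_area(both, geom20),
               substrate_area(t1, geom20) + substrate_area(t2, geom20))
})

test_that("total substrate is conserved through rasterization", {
  cfg <- forest_config(plot_x = 20, plot_y = 20, years = 3, seed = 9,
                       demography = list(m_base = 0.02))
  f <- generate_forest(cfg, burn_in = 40)
  s <- f$snapshots[[1]]
  analytic <- sum(pi * s$dbh / 100 * pmin(s$height, 50)) + sum(s$branch_area)
  expect_equal(sum(substrate_area(s, f$geometry)), analytic,
               tolerance = 1e-9)
})

test_that("a leafless plot is uniformly lit at the top irradiance", {
  tr <- bare_trunk(10.5, 10.5, 30, 10)
  I <- light_field(tr, geom20, I_top = 800)
  expect_true(all(abs(I - 800) < 1e-9))
})

test_that("light follows Beer-Lambert through a known leaf layer", {
  # one crown voxel holding leaf area 2 directly above the probe voxel
  tr <- data.frame(x = 10.5, y = 10.5, id = 1L, dbh = 20, height = 30,
                   crown_radius = 0.4, crown_depth = 1, branch_area = 0,
                   leaf_area = 2)
  I <- light_field(tr, geom20, I_top = 1000, k_ext = 0.5)
  # layers below the leaf voxel (z index 29) see LAI 2 above
  expect_equal(I[11, 11, 29], 1000 * exp(-1), tolerance = 1e-9)
  expect_equal(I[11, 11, 31], 1000, tolerance = 1e-9)
})

test_that("light is monotonically non-increasing downward in interior columns", {
  cfg <- forest_config(plot_x = 20, plot_y = 20, years = 3, seed = 10,
                       demography = list(m_base = 0.02))
  f <- generate_forest(cfg, burn_in = 40)
  I <- light_field(f$snapshots[[1]], f$geometry)
  interior <- I[5:16, 5:16, ]
  diffs <- interior[, , 2:50] - interior[, , 1:49]
  expect_true(all(diffs >= -1e-9))
})

test_that("the light field ignores tree identity labels", {
  cfg <- forest_config(plot_x = 20, plot_y = 20, years = 3, seed = 12,
                       demography = list(m_base = 0.02))
  f <- generate_forest(cfg, burn_in = 40)
  s <- f$snapshots[[1]]
  shuffled <- s[rev(seq_len(nrow(s))), ]
  shuffled$id <- seq_len(nrow(s))
  expect_equal(light_field(s, f$geometry), light_field(shuffled, f$geometry))
})

test_that("substrate loss handles decline, growth and zero substrate", {
  a <- array(c(2, 1, 0, 1), dim = c(2, 2, 1))
  b <- array(c(1, 1.4, 0, 0), dim = c(2, 2, 1))
  sl <- substrate_loss(a, b)
  expect_equal(sl[1, 1, 1], 50)   # 2 -> 1
  expect_equal(sl[2, 1, 1], 0)    # growth is not loss
  expect_equal(sl[1, 2, 1], 0)    # no substrate, no loss
  expect_equal(sl[2, 2, 1], 100)  # total loss
  expect_true(all(sl >= 0 & sl <= 100))
  expect_error(substrate_loss(a, array(0, dim = c(1, 2, 1))), "shape")
})

test_that("static forests give constant matrices with zero loss", {
  cfg <- forest_config(plot_x = 20, plot_y = 20, years = 3, seed = 3,
                       static = TRUE, demography = list(m_base = 0.02))
  f <- generate_forest(cfg, burn_in = 30)
  habs <- build_microhabitat(f)
  expect_equal(habs[[1]]$S_B, habs[[3]]$S_B)
  expect_equal(habs[[1]]$I, habs[[2]]$I)
  for (h in habs) expect_true(all(h$S_Loss == 0))
})

test_that("voxels solely occupied by a logged tree lose all substrate", {
  lone <- bare_trunk(5.5, 5.5, 45, 12, id = 1L)
  other <- bare_trunk(15.5, 15.5, 20, 8, id = 2L)
  f <- make_series(list(rbind(lone, other), other))
  habs <- build_microhabitat(f)
  expect_true(all(habs[[1]]$S_Loss[6, 6, 1:12] == 100))
  expect_true(all(habs[[1]]$S_Loss[16, 16, ] == 0))
  expect_true(all(habs[[2]]$S_Loss == 0))  # final year convention
})

test_that("microhabitat matrices round-trip through CSV and NetCDF", {
  f <- make_series(list(bare_trunk(3.5, 3.5, 25, 9),
                        bare_trunk(3.5, 3.5, 26, 9.3)),
                   nx = 8, ny = 8, nz = 12)
  habs <- build_microhabitat(f)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_microhabitat_csv(habs, csv)
  back <- read_microhabitat_csv(csv)
  expect_equal(length(back), 2L)
  for (t in 1:2) {
    expect_equal(back[[t]]$I, habs[[t]]$I)
    expect_equal(back[[t]]$S_B, habs[[t]]$S_B)
    expect_equal(back[[t]]$S_Loss, habs[[t]]$S_Loss)
  }
  nc <- withr::local_tempfile(fileext = ".nc")
  write_microhabitat_nc(habs, nc)
  back2 <- read_microhabitat_nc(nc)
  for (t in 1:2) {
    expect_identical(back2[[t]]$S_B, habs[[t]]$S_B)
    expect_identical(back2[[t]]$I, habs[[t]]$I)
    expect_identical(back2[[t]]$S_Loss, habs[[t]]$S_Loss)
  }
})
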