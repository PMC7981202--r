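test_that("static scenario freezes the stand: every snapshot equals year 0", {
  cfg <- forest_config(plot_x = 20, plot_y = 20, years = 5, seed = 3,
                       static = TRUE, demography = list(m_base = 0.02))
  f <- generate_forest(cfg, burn_in = 30)
  for (t in 2:5) expect_identical(f$snapshots[[t]], f$snapshots[[1]])
  expect_equal(stem_turnover(f), 0)
})

test_that("no demographic events means zero turnover", {
  cfg <- forest_config(plot_x = 20, plot_y = 20, years = 10, seed = 3,
                       demography = list(m_base = 0, recruitment = FALSE))
  f <- generate_forest(cfg, burn_in = 10)
  expect_equal(stem_turnover(f), 0)
  expect_equal(sum(f$counts$deaths), 0L)
  expect_equal(sum(f$counts$recruits), 0L)
})

test_that("turnover is the mean of mortality and recruitment rates", {
  # constant pool of 100 stems, exactly 2 deaths and 2 recruits per year
  f <- structure(list(
    snapshots = list(), geometry = c(nx = 20, ny = 20, nz = 50),
    counts = data.frame(year = 0:9, n_start = 100L, deaths = 2L,
                        recruits = 2L),
    config = forest_config(plot_x = 20, plot_y = 20, years = 11),
    m_base = NA_real_
  ), class = "epx_forest")
  expect_equal(stem_turnover(f), 2.0)
  expect_error(stem_turnover(f, window = 99), "empty")
})

test_that("bookkept event counts match a recount from snapshot id sets", {
  cfg <- forest_config(plot_x = 25, plot_y = 25, years = 40, seed = 11,
                       demography = list(m_base = 0.02))
  f <- generate_forest(cfg, burn_in = 60)
  expect_equal(f$counts, epivox:::recount_series(f))
})

test_that("realized turnover tracks the configured target", {
  cfg <- forest_config(years = 300, seed = 5)
  f <- generate_forest(cfg)
  expect_lt(abs(stem_turnover(f) - 2.7), 0.3)
})

test_that("identical config and seed reproduce the series exactly", {
  cfg <- forest_config(plot_x = 20, plot_y = 20, years = 15, seed = 8,
                       demography = list(m_base = 0.02))
  f1 <- generate_forest(cfg, burn_in = 25)
  f2 <- generate_forest(cfg, burn_in = 25)
  expect_identical(f1$snapshots, f2$snapshots)
  expect_identical(f1$counts, f2$counts)
})

test_that("logging removes exactly the trees at or above the target", {
  snap <- data.frame(id = 1:3, x = c(2, 8, 14), y = c(5, 5, 5),
                     dbh = c(35, 40, 52))
  f <- make_series(list(snap, snap))
  logged <- apply_logging(f, 40)
  expect_equal(logged$snapshots[[1]]$id, 1L)
  expect_equal(logged$snapshots[[2]]$id, 1L)
  # vacuous threshold leaves the series unchanged
  untouched <- apply_logging(f, 60)
  expect_identical(untouched$snapshots, f$snapshots)
})

test_that("no living tree reaches the target diameter in logged scenarios", {
  cfg <- forest_config(plot_x = 25, plot_y = 25, years = 60, seed = 4,
                       logging_dbh = 40, demography = list(m_base = 0.02))
  f <- generate_forest(cfg, burn_in = 80)
  max_dbh <- vapply(f$snapshots, function(s) max(c(0, s$dbh)), numeric(1))
  expect_true(all(max_dbh < 40))
})

test_that("a laxer logging target retains at least as much basal area", {
  cfg <- forest_config(plot_x = 25, plot_y = 25, years = 60, seed = 4,
                       demography = list(m_base = 0.02))
  f <- generate_forest(cfg, burn_in = 80)
  ba <- function(series) sum(vapply(series$snapshots,
                                    function(s) sum(s$dbh^2), numeric(1)))
  expect_gte(ba(apply_logging(f, 50)), ba(apply_logging(f, 40)))
})

test_that("tree counts stay positive and basal area finite", {
  cfg <- forest_config(plot_x = 20, plot_y = 20, years = 50, seed = 2,
                       demography = list(m_base = 0.02))
  f <- generate_forest(cfg, burn_in = 50)
  n <- vapply(f$snapshots, nrow, integer(1))
  expect_true(all(n > 0))
  expect_true(all(is.finite(vapply(f$snapshots,
                                   function(s) sum(s$dbh^2), numeric(1)))))
})

test_that("an unreachable turnover target fails loudly", {
  cfg <- forest_config(plot_x = 20, plot_y = 20, years = 5, seed = 1,
                       target_turnover = 3,
                       demography = list(mort_cap = 0.002))
  expect_error(generate_forest(cfg), "unreachable")
})

test_that("forest series round-trips through CSV", {
  cfg <- forest_config(plot_x = 20, plot_y = 20, years = 5, seed = 6,
                       demography = list(m_base = 0.02))
  f <- generate_forest(cfg, burn_in = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_forest_csv(f, path)
  g <- read_forest_csv(path, cfg)
  for (t in seq_along(f$snapshots)) {
    a <- f$snapshots[[t]][order(f$snapshots[[t]]$id), ]
    b <- g$snapshots[[t]][order(g$snapshots[[t]]$id), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, tolerance = 1e-6)
  }
})
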