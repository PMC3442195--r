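test_that("slice_profile extracts grid lines exactly", {
  fl <- flow2d()
  src <- ctc_sources(10, 5)
  g <- field_grid(src, fl, t = 1, x = seq(0, 20, by = 1), y = c(0, 2, 4, 8))
  p <- slice_profile(g, "y", 2)
  expect_identical(p$conc, g$conc[g$y == 2])
  # symmetric about the source's x for a single source
  expect_equal(p$conc[p$x == 10 - 3], p$conc[p$x == 10 + 3])
  # nearest line + recorded actual offset when not representable
  p2 <- slice_profile(g, "y", 2.4)
  expect_equal(unique(p2$offset), 2)
  expect_equal(unique(p2$offset_requested), 2.4)
  expect_equal(attr(p2, "offset_actual"), 2)
  expect_error(slice_profile(g, "y", 50), "outside")
})

test_that("peak_series maxima agree with a dense brute-force rescan", {
  fl <- flow2d()
  src <- random_sources_2d(8, seed = 21, box = list(x = c(0, 60), y = c(0, 20)))
  pk <- peak_series(src, fl, times = c(1, 5), offsets = c(0, 10),
                    xlim = c(0, 60), n = 601, refine = 2)
  f <- field_evaluator(src, fl)
  for (i in seq_len(nrow(pk))) {
    xs <- seq(0, 60, length.out = 24001)
    brute <- max(f(xs, pk$offset[i], t = pk$t[i]))
    expect_equal(pk$peak[i], brute, tolerance = 1e-6)
    expect_gte(pk$peak[i], brute * (1 - 1e-8))  # refinement never undershoots
  }
  expect_equal(attr(pk, "sampling")$n, 601)
})

test_that("regime_split recovers an exact piecewise power law", {
  tt <- exp(seq(log(0.3), log(300), length.out = 30))
  tb <- tt[which.min(abs(tt - 3))]
  cc <- ifelse(tt <= tb, tb^(-1) * (tt / tb)^(-1.2), tb^(-1) * (tt / tb)^(-0.4))
  rs <- regime_split(tibble::tibble(t = tt, peak = cc))
  expect_equal(rs$t_split, tb)
  expect_equal(rs$early_slope, -1.2, tolerance = 1e-8)
  expect_equal(rs$late_slope, -0.4, tolerance = 1e-8)
  td <- tidy(rs)
  expect_equal(td$estimate, c(-1.2, -0.4), tolerance = 1e-8)
  gl <- glance(rs)
  expect_equal(gl$t_split, tb)
  expect_gt(gl$r.squared, 0.999)
})

test_that("regime_split on a pure power law finds equal slopes", {
  tt <- exp(seq(log(0.5), log(100), length.out = 25))
  rs <- regime_split(tibble::tibble(t = tt, peak = 2 * tt^(-0.8)))
  expect_equal(rs$early_slope, -0.8, tolerance = 1e-8)
  expect_equal(rs$late_slope, -0.8, tolerance = 1e-8)
  expect_error(regime_split(tibble::tibble(t = 1:5, peak = 1 / (1:5))), "short")
})

test_that("the mean field scales exactly linearly in co-located count", {
  fl <- flow2d()
  one <- ctc_sources(5, 3)
  sets <- list(one[0, ], one[rep(1, 4), ], one[rep(1, 100), ])
  ns <- n_scaling_summary(sets, fl, t = 2, x = seq(0, 10, by = 1),
                          y = seq(0, 6, by = 1))
  tab <- tidy(ns)
  expect_equal(tab$n, c(0L, 4L, 100L))
  expect_identical(tab$mean_conc[1], 0)
  expect_equal(tab$mean_conc[3] / tab$mean_conc[2], 25, tolerance = 1e-12)
  gl <- glance(ns)
  expect_equal(gl$intercept, 0, tolerance = 1e-15)
  expect_equal(gl$slope, tab$mean_conc[2] / 4, tolerance = 1e-12)
  # sets differing beyond count are refused
  bad <- dplyr::mutate(one, alpha = 2)
  expect_error(n_scaling_summary(list(one, bad), fl, t = 1,
                                 x = 0:1, y = 0:1), "beyond count")
})

test_that("run_simulation is deterministic and covers requested outputs", {
  cfg <- tiny_config_2d()
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$fields, r2$fields)
  expect_identical(r1$sources, r2$sources)
  expect_identical(as.data.frame(r1$peaks), as.data.frame(r2$peaks))
  expect_setequal(unique(r1$fields$t), cfg$times)
  expect_setequal(unique(r1$peaks$offset), c(0, 5, 20))
  expect_true(all(is.finite(r1$fields$conc)) && all(r1$fields$conc >= 0))
  gl <- glance(r1)
  expect_equal(gl$n_sources, 12L)
})

test_that("whole-run linearity: doubling strengths doubles every field value", {
  cfg <- tiny_config_2d()
  base <- run_simulation(cfg)
  cfg2 <- validate_run_config(
    modifyList(unclass(cfg),
               list(sources = list(recipe = modifyList(
                 cfg$sources$recipe, list(strength = 2)))))
  )
  doubled <- run_simulation(cfg2)
  expect_identical(doubled$sources[c("x0", "y0")], base$sources[c("x0", "y0")])
  expect_equal(doubled$fields$conc, 2 * base$fields$conc, tolerance = 1e-14)
  expect_equal(doubled$peaks$peak, 2 * base$peaks$peak, tolerance = 1e-14)
})

test_that("in-plane translation leaves all field values unchanged", {
  fl <- flow2d()
  src <- random_sources_2d(6, seed = 33)
  shift <- 123.5
  src_s <- dplyr::mutate(src, x0 = x0 + shift)
  x <- seq(-10, 10, by = 2.5); y <- c(0, 1, 4)
  g <- field_grid(src, fl, t = 3, x = x, y = y)
  gs <- field_grid(src_s, fl, t = 3, x = x + shift, y = y)
  expect_equal(g$conc, gs$conc, tolerance = 1e-14)
})

test_that("peak location is grid-robust for a single source", {
  fl <- flow2d()
  src <- ctc_sources(7.3, 4)
  pk_lo <- peak_series(src, fl, times = 2, offsets = 4, xlim = c(0, 20),
                       n = 101, refine = 0)
  pk_hi <- peak_series(src, fl, times = 2, offsets = 4, xlim = c(0, 20),
                       n = 401, refine = 0)
  cell_lo <- 20 / 100
  expect_lte(abs(pk_lo$at_x - pk_hi$at_x), cell_lo)
  # with refinement both land on the analytic maximum
  pk_r <- peak_series(src, fl, times = 2, offsets = 4, xlim = c(0, 20),
                      n = 101, refine = 3)
  expect_equal(pk_r$at_x, 7.3, tolerance = 1e-2)
})

test_that("the packaged 3D four-cell run produces finite wall-dominant slices", {
  cfgs <- fixture_configs()
  cfg <- read_run_config(cfgs$path[cfgs$name == "3d_4ctc"])
  cfg <- apply_overrides(cfg, c("grid.nx=64", "grid.ny=64"))
  run <- run_simulation(cfg)
  expect_true(all(is.finite(run$fields$conc)) && all(run$fields$conc >= 0))
  expect_setequal(unique(run$fields$z), c(0, 45, 90))
  expect_setequal(unique(run$fields$t), c(1, 10, 40, 75))
  # every (t, z) slice attains its max on a finite set
  mx <- dplyr::summarise(dplyr::group_by(run$fields, t, z),
                         m = max(conc), .groups = "drop")
  expect_true(all(is.finite(mx$m)))
})
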