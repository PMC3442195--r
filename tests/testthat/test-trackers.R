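test_that("polling a uniform field yields all-zero differences", {
  flat <- function(x, y, z = NULL, t) rep(3.14, max(length(x), length(y)))
  d <- poll_neighbors(1, 2, t = 1, field = flat, eps = 0.5)
  expect_named(d, c("+x", "-x", "+y", "-y"))
  expect_identical(unname(d), rep(0, 4))
  d3 <- poll_neighbors(1, 2, z = 3, t = 1, field = flat, eps = 0.5)
  expect_named(d3, c("+x", "-x", "+y", "-y", "+z", "-z"))
  # a tracker in a uniform field never moves
  tr <- tibble::tibble(id = 1L, polarity = "high", x = 1, y = 2, z = NA_real_,
                       eps = 0.5)
  expect_identical(step_trackers(tr, flat, t = 1)[c("x", "y")], tr[c("x", "y")])
})

test_that("differences point down-gradient toward a source", {
  fl <- flow2d()
  src <- ctc_sources(0, 10)  # directly "north" of the tracker
  f <- field_evaluator(src, fl)
  d <- poll_neighbors(0, 4, t = 1, field = f, eps = 0.5)
  # moving +y gains the most: c(p) - c(p+eps*ey) is the most negative
  expect_identical(names(which.min(d)), "+y")
  expect_lt(d[["+y"]], 0)
})

test_that("shrinking eps recovers the analytic gradient", {
  src <- ctc_sources(1, 6, strength = 2, alpha = 1.5)
  f <- field_evaluator(src, flow2d())
  # closed-form partials of the direct+image kernel
  grad <- function(x, y, t) {
    a <- 1.5; denom <- 4 * a * t
    g1 <- exp(-((x - 1)^2 + (y - 6)^2) / denom)
    g2 <- exp(-((x - 1)^2 + (y + 6)^2) / denom)
    pref <- 2 / (pi * denom)
    c(
      dx = pref * (-2 * (x - 1) / denom) * (g1 + g2),
      dy = pref * (-2 * (y - 6) / denom * g1 - 2 * (y + 6) / denom * g2)
    )
  }
  px <- 2.3; py <- 3.1; t <- 2
  g <- grad(px, py, t)
  for (eps in c(1e-2, 1e-3)) {
    d <- poll_neighbors(px, py, t = t, field = f, eps = eps)
    # c(p) - c(p + eps e) ~ -eps * dc/de
    expect_equal(d[["+x"]] / eps, -g[["dx"]], tolerance = 50 * eps)
    expect_equal(d[["-x"]] / eps, g[["dx"]], tolerance = 50 * eps)
    expect_equal(d[["+y"]] / eps, -g[["dy"]], tolerance = 50 * eps)
  }
})

test_that("steps follow polarity and brute-force six-way choice", {
  fl <- flow2d()
  src <- ctc_sources(0, 10)
  f <- field_evaluator(src, fl)
  tr <- tibble::tibble(id = 1:2, polarity = c("high", "low"),
                       x = c(0, 0), y = c(4, 4), z = NA_real_, eps = 0.5)
  st <- step_trackers(tr, f, t = 1)
  expect_equal(st$y, c(4.5, 3.5))  # high climbs toward, low flees
  # high-seeker at a strict local maximum stays put
  at_max <- tibble::tibble(id = 1L, polarity = "high", x = 0, y = 10,
                           z = NA_real_, eps = 0.3)
  expect_equal(step_trackers(at_max, f, t = 0.5)[c("x", "y")],
               at_max[c("x", "y")])
  # low-seeker between two sources agrees with exhaustive evaluation
  two <- ctc_sources(c(-8, 8), c(5, 5))
  f2 <- field_evaluator(two, fl)
  lo <- tibble::tibble(id = 1L, polarity = "low", x = 1.3, y = 5.2,
                       z = NA_real_, eps = 0.4)
  stepped <- step_trackers(lo, f2, t = 1)
  cands <- tibble::tibble(
    x = lo$x + 0.4 * c(1, -1, 0, 0), y = pmax(lo$y + 0.4 * c(0, 0, 1, -1), 0))
  vals <- f2(cands$x, cands$y, t = 1)
  best <- cands[which.min(vals), ]
  expect_equal(c(stepped$x, stepped$y), c(best$x, best$y))
})

test_that("trackers respect the wall and the lattice step structure", {
  fl <- flow2d()
  src <- ctc_sources(0, 0.2)  # source hugging the wall pulls trackers down
  tr <- tibble::tibble(id = 1L, polarity = "high", x = 0, y = 0.3,
                       z = NA_real_, eps = 0.5)
  traj <- evolve_trackers(tr, src, fl, t0 = 1, t1 = 5, dt = 1)
  expect_true(all(traj$y >= 0))
  # consecutive positions differ by exactly eps along one axis, or not at all
  steps <- dplyr::mutate(dplyr::group_by(traj, id),
                         dx = abs(x - dplyr::lag(x)),
                         dy = abs(y - dplyr::lag(y)))
  moves <- dplyr::filter(steps, !is.na(dx))
  ok <- (moves$dx == 0 & moves$dy == 0) |
    (moves$dx == 0.5 & moves$dy == 0) | (moves$dx == 0 & moves$dy == 0.5) |
    # a wall-clamped move may be shorter than eps in y
    (moves$dx == 0 & moves$dy < 0.5)
  expect_true(all(ok))
})

test_that("with no sources trackers are stationary forever", {
  fl <- flow2d()
  empty <- ctc_sources(0, 1)[0, ]
  tr <- make_trackers(3, 3, box = list(x = c(0, 10), y = c(0, 10)),
                      eps = 1, seed = 4)
  traj <- evolve_trackers(tr, empty, fl, t0 = 1, t1 = 6, dt = 1)
  spans <- dplyr::summarise(dplyr::group_by(traj, id),
                            sx = diff(range(x)), sy = diff(range(y)))
  expect_true(all(spans$sx == 0 & spans$sy == 0))
})

test_that("a high-seeking tracker converges onto a single static source", {
  fl <- flow2d()
  src <- ctc_sources(0, 50)  # far from the wall so the source stays the max
  eps <- 0.5
  tr <- tibble::tibble(id = 1L, polarity = "high", x = 6.2, y = 43.9,
                       z = NA_real_, eps = eps)
  traj <- evolve_trackers(tr, src, fl, t0 = 1, t1 = 40, dt = 1)
  d <- sqrt((traj$x - 0)^2 + (traj$y - 50)^2)
  expect_lte(tail(d, 1), eps * sqrt(2))
  # distance is eventually non-increasing (after the approach phase)
  late <- tail(d, 15)
  expect_true(all(diff(late) <= 1e-12))
  # per-step approach speed never exceeds the step length
  expect_true(all(abs(diff(d)) <= eps + 1e-12))
})

test_that("trackers are passive: the field never sees them", {
  fl <- flow2d()
  src <- random_sources_2d(4, seed = 12)
  pts <- tibble::tibble(x = c(0, 5), y = c(1, 2), t = 3)
  before <- field_at(pts, src, fl)$conc
  tr <- make_trackers(5, 5, box = list(x = c(0, 10), y = c(0, 10)),
                      eps = 0.5, seed = 2)
  invisible(evolve_trackers(tr, src, fl, t0 = 1, t1 = 3, dt = 1))
  expect_identical(field_at(pts, src, fl)$conc, before)
})
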