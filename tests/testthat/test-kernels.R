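test_that("2D kernel matches its closed form at hand-checked points", {
  # at the source centre the direct exponent is 0 and the image exponent
  # is -(2 y0)^2 / (4 alpha t)
  expect_equal(kernel_2d(0, 2, t = 1, x0 = 0, y0 = 2, strength = 1, alpha = 1),
               1 / (4 * pi) * (1 + exp(-4)))
  # strength and alpha scale the prefactor
  expect_equal(kernel_2d(3, 1, t = 2, x0 = 3, y0 = 1, strength = 7, alpha = 0.5),
               7 / (4 * pi * 0.5 * 2) * (1 + exp(-4 * 1 / (4 * 0.5 * 2))))
  # even in x - x0
  for (d in c(0.3, 2, 17)) {
    expect_identical(kernel_2d(5 + d, 4, t = 3, x0 = 5, y0 = 2),
                     kernel_2d(5 - d, 4, t = 3, x0 = 5, y0 = 2))
  }
})

test_that("2D kernel rejects out-of-domain input", {
  expect_error(kernel_2d(0, 1, t = 0, y0 = 1), "t = 0")
  expect_error(kernel_2d(0, -1, t = 1, y0 = 1), "half-plane")
  expect_error(kernel_2d(0, 1, t = 1, y0 = -1), "half-plane")
  expect_error(kernel_2d(0, 1, t = 1, y0 = 1, alpha = 0), "alpha")
  # the mirror extension is available on request (no-flux evenness)
  expect_identical(kernel_2d(0, -1, t = 1, y0 = 1, check_wall = FALSE),
                   kernel_2d(0, 1, t = 1, y0 = 1))
})

test_that("half-plane mass of a single 2D source equals its strength", {
  src <- ctc_sources(2, 3, strength = 2.5, alpha = 1.5)
  expect_equal(half_plane_mass(src, 1), 2.5, tolerance = 1e-8)
  expect_equal(half_plane_mass(src, 10), 2.5, tolerance = 1e-8)
})

test_that("3D kernel matches its closed form and conventions", {
  # r = 1; all in-plane Gaussian arguments vanish; bracket = 1 + exp(-1)
  expect_equal(kernel_3d(1, 0, 1, t = 1, x0 = 0, y0 = 0, z0 = 1, u = 1,
                         strength = 1, alpha = 1),
               1 / (8 * pi) * (1 + exp(-1)))
  # wall value is exactly twice the single (z - H) term
  v <- kernel_3d(4, 2, 0, t = 2, x0 = 1, y0 = 3, z0 = 1.5, u = 0.8,
                 strength = 2, alpha = 1.2)
  expect_equal(v, 2 * puff_term_3d(4, 2, 0, 2, 1, 3, 1.5, 0.8, 2, 1.2))
  # upstream convention: s <= 0 gives 0
  expect_identical(kernel_3d(-1, 0, 1, t = 1, z0 = 1, u = 1), 0)
  expect_identical(kernel_3d(0, 0, 1, t = 1, x0 = 0, z0 = 1, u = 1), 0)
  expect_error(kernel_3d(1, 0, 1, t = 1, z0 = 1, u = 0), "u")
  expect_error(kernel_3d(1, 0, 1, t = 1, z0 = 1), "u")
  expect_error(kernel_3d(1, 0, -1, t = 1, z0 = 1, u = 1), "half-space")
})

test_that("textbook puff normalization is the exact travelling Green's function", {
  # closed-form mass: the direct + image pair restores exactly `strength`
  # over the half-space; check by separable 1D quadratures
  alpha <- 0.7; u <- 0.9; t <- 1.3; H <- 1.1; Q <- 2
  fx <- stats::integrate(function(x) {
    exp(-((x - u * t)^2) / (4 * alpha * t)) / sqrt(4 * pi * alpha * t)
  }, -Inf, Inf)$value
  fz <- stats::integrate(function(z) {
    (exp(-(z - H)^2 / (4 * alpha * t)) + exp(-(z + H)^2 / (4 * alpha * t))) /
      sqrt(4 * pi * alpha * t)
  }, 0, Inf)$value
  got <- stats::integrate(Vectorize(function(y) {
    stats::integrate(Vectorize(function(z) {
      stats::integrate(function(x) {
        kernel_3d(x, y, z, t, z0 = H, u = u, strength = Q, alpha = alpha,
                  normalization = "textbook_puff")
      }, u * t - 15, u * t + 15)$value
    }), 0, 15)$value
  }), -15, 15)$value
  expect_equal(fx, 1, tolerance = 1e-9)
  expect_equal(fz, 1, tolerance = 1e-9)
  expect_equal(got, Q, tolerance = 1e-6)
  # defined upstream (true puff), positive everywhere
  expect_gt(kernel_3d(-3, 0, 1, t = 1, z0 = 1, u = 1,
                      normalization = "textbook_puff"), 0)
})

test_that("wall-normal derivative of both kernels vanishes at the wall", {
  set.seed(42)
  for (i in 1:20) {
    x0 <- runif(1, -5, 5); y0 <- runif(1, 0, 5); t <- runif(1, 0.2, 5)
    x <- runif(1, -5, 5)
    for (h in c(1e-2, 1e-4)) {
      up <- kernel_2d(x, h, t, x0 = x0, y0 = y0, check_wall = FALSE)
      dn <- kernel_2d(x, -h, t, x0 = x0, y0 = y0, check_wall = FALSE)
      mid <- kernel_2d(x, 0, t, x0 = x0, y0 = y0)
      expect_lte(abs(up - dn) / (2 * h), 1e-10 * mid)
    }
    H <- runif(1, 0, 3); u <- runif(1, 0.3, 2)
    for (h in c(1e-2, 1e-4)) {
      up <- kernel_3d(x + 6, y0, h, t, z0 = H, u = u, check_wall = FALSE)
      dn <- kernel_3d(x + 6, y0, -h, t, z0 = H, u = u, check_wall = FALSE)
      mid <- kernel_3d(x + 6, y0, 0, t, z0 = H, u = u)
      expect_lte(abs(up - dn) / (2 * h), 1e-10 * max(mid, 1e-300))
    }
  }
})

test_that("image contribution decays as the source recedes from the wall", {
  # relative image weight at (x0, y) is exp(-y0*y/(alpha*t))
  alpha <- 1.5; t <- 2; y <- 1
  for (y0 in c(2, 5, 10)) {
    full <- kernel_2d(0, y, t, y0 = y0, alpha = alpha)
    free <- 1 / (4 * pi * alpha * t) * exp(-(y - y0)^2 / (4 * alpha * t))
    expect_equal(full / free - 1, exp(-y0 * y / (alpha * t)), tolerance = 1e-12)
  }
  # free-space limit
  expect_equal(kernel_2d(0, 30, t, y0 = 30, alpha = alpha),
               1 / (4 * pi * alpha * t), tolerance = 1e-10)
})

test_that("superposition is exactly additive and homogeneous", {
  fl <- flow2d()
  A <- random_sources_2d(6, seed = 1)
  B <- random_sources_2d(9, seed = 2)
  pts <- tibble::tibble(x = runif(10, -40, 40), y = runif(10, 0, 30), t = 2)
  cA <- field_at(pts, A, fl)$conc
  cB <- field_at(pts, B, fl)$conc
  cAB <- field_at(pts, dplyr::bind_rows(A, B), fl)$conc
  expect_equal(cAB, cA + cB, tolerance = 1e-14)
  # homogeneity in strength
  A3 <- dplyr::mutate(A, strength = strength * 3.7)
  expect_equal(field_at(pts, A3, fl)$conc, 3.7 * cA, tolerance = 1e-14)
  # term-by-term summation oracle
  manual <- rowSums(sapply(seq_len(nrow(A)), function(i) {
    kernel_2d(pts$x, pts$y, pts$t, x0 = A$x0[i], y0 = A$y0[i],
              strength = A$strength[i], alpha = A$alpha[i])
  }))
  expect_equal(cA, manual, tolerance = 1e-14)
  # empty source set gives a zero field, not an error
  empty <- A[0, ]
  expect_identical(field_at(pts, empty, fl)$conc, rep(0, nrow(pts)))
})

test_that("co-located source count scales the field exactly linearly", {
  fl <- flow3d(u = 0.8)
  one <- ctc_sources(0, 0, 5, strength = 1, alpha = 1.5)
  n4 <- one[rep(1, 4), ]
  n100 <- one[rep(1, 100), ]
  pts <- tibble::tibble(x = c(2, 10, 30), y = c(0, 1, -2), z = c(0, 3, 7), t = 4)
  c4 <- field_at(pts, n4, fl)$conc
  c100 <- field_at(pts, n100, fl)$conc
  expect_equal(c100 / c4, rep(25, 3), tolerance = 1e-12)
})

test_that("field_grid equals pointwise superposition and respects the wall", {
  fl <- flow2d()
  src <- random_sources_2d(5, seed = 3)
  g <- field_grid(src, fl, t = c(1, 2), x = c(-5, 0, 5), y = c(0, 2))
  expect_equal(nrow(g), 12L)
  # bit-identical to a pointwise loop
  loop <- purrr::pmap_dbl(g[c("x", "y", "t")], function(x, y, t) {
    field_at(tibble::tibble(x = x, y = y, t = t), src, fl)$conc
  })
  expect_identical(g$conc, loop)
  # degenerate 1x1 grid
  g1 <- field_grid(src, fl, t = 1, x = 2, y = 3)
  expect_identical(g1$conc,
                   field_at(tibble::tibble(x = 2, y = 3, t = 1), src, fl)$conc)
  expect_error(field_grid(src, fl, t = 1, x = 0, y = c(-1, 1)), "wall")

  # 3D wall slice is exactly twice the image-free field
  fl3 <- flow3d(u = 1)
  src3 <- ctc_sources(0, 0, 2, strength = 1.3, alpha = 1.1)
  gw <- field_grid(src3, fl3, t = 2, x = c(1, 3, 6), y = c(-1, 0, 2), z = 0)
  noimg <- puff_term_3d(gw$x, gw$y, gw$z, gw$t, 0, 0, 2, 1, 1.3, 1.1)
  expect_equal(gw$conc, 2 * noimg, tolerance = 1e-14)
})
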