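#' Background flow specification
#'
#' The model supports two flow regimes: a quiescent 2D half-plane
#' (`"no_flow_2d"`, wall at y = 0, u = 0) and a 3D half-space with a constant
#' unidirectional flow along +x (`"constant_flow_3d"`, wall at z = 0, u > 0).
#' The constant-flow kernel uses the scaled variable r = alpha * s / u, which
#' is undefined at u = 0, so a strictly positive speed is required in 3D mode.
#'
#' @param mode `"no_flow_2d"` or `"constant_flow_3d"`.
#' @param u Dimensionless flow speed along +x. Defaults to 0 in 2D mode and
#'   1 in 3D mode.
#' @return A `flow_spec` object (list with `mode` and `u`).
#' @examples
#' flow_spec("no_flow_2d")
#' flow_spec("constant_flow_3d", u = 0.5)
#' @export
flow_spec <- function(mode = c("no_flow_2d", "constant_flow_3d"), u = NULL) {
  mode <- match.arg(mode)
  if (is.null(u)) u <- if (mode == "no_flow_2d") 0 else 1
  check_scalar_number(u, "u", lower = 0)
  if (mode == "no_flow_2d" && u != 0) {
    stopf("2D mode is quiescent: u must be 0 (got %g)", u)
  }
  if (mode == "constant_flow_3d" && u <= 0) {
    stopf("constant-flow 3D mode requires u > 0: the scaled variable r = alpha*x/u is undefined at u = 0")
  }
  structure(list(mode = mode, u = u), class = "flow_spec")
}

#' @export
print.flow_spec <- function(x, ...) {
  cat(sprintf("<flow_spec> mode = %s, u = %g\n", x$mode, x$u))
  invisible(x)
}

is_3d <- function(flow) {
  if (!inherits(flow, "flow_spec")) stopf("`flow` must be created with flow_spec()")
  flow$mode == "constant_flow_3d"
}

#' Single-source diffusion kernel in the half-plane (2D, no flow)
#'
#' Concentration at `(x, y)` and time `t` due to a point release of total
#' strength `strength` at `(x0, y0)` in the upper half-plane, diffusing with
#' coefficient `alpha` above a no-flux wall at y = 0. The wall condition is
#' enforced by an image source at `(x0, -y0)`:
#'
#' c = strength / (4 pi alpha t) \* \[ exp(-((x-x0)^2 + (y-y0)^2) / (4 alpha t))
#'   + exp(-((x-x0)^2 + (y+y0)^2) / (4 alpha t)) \]
#'
#' The direct + image pair integrates to exactly `strength` over the
#' half-plane for every t > 0 and has identically zero wall-normal derivative
#' at y = 0.
#'
#' @param x,y Evaluation coordinates (vectorised; y >= 0 unless
#'   `check_wall = FALSE`).
#' @param t Time since release, > 0 (vectorised).
#' @param x0,y0 Source position (y0 >= 0).
#' @param strength Total released amount, > 0.
#' @param alpha Dimensionless diffusion coefficient, > 0.
#' @param check_wall If `TRUE` (default), reject evaluation points or sources
#'   below the wall. The closed form extends evenly across y = 0 (that
#'   evenness *is* the no-flux condition), so derivative checks may disable
#'   the guard.
#' @return Numeric vector of concentrations (strictly positive, finite).
#' @examples
#' kernel_2d(0, 2, t = 1, x0 = 0, y0 = 2, strength = 1, alpha = 1)
#' # = 1/(4*pi) * (1 + exp(-4))
#' @export
kernel_2d <- function(x, y, t, x0 = 0, y0 = 0, strength = 1, alpha = 1.5,
                      check_wall = TRUE) {
  check_times_positive(t)
  if (any(alpha <= 0)) stopf("`alpha` must be > 0")
  if (any(strength <= 0)) stopf("`strength` must be > 0")
  if (check_wall && (any(y < 0) || any(y0 < 0))) {
    stopf("2D evaluation points and sources must lie in the closed half-plane y >= 0")
  }
  a <- recycle_common(x = x, y = y, t = t, x0 = x0, y0 = y0,
                      strength = strength, alpha = alpha)
  denom <- 4 * a$alpha * a$t
  dx2 <- (a$x - a$x0)^2
  a$strength / (pi * denom) *
    (exp(-(dx2 + (a$y - a$y0)^2) / denom) +
       exp(-(dx2 + (a$y + a$y0)^2) / denom))
}

#' Single-source advected kernel in the half-space (3D, constant flow)
#'
#' Concentration at `(x, y, z)` and time `t` due to a point source of strength
#' `strength` released at `(x0, y0, z0)` (release height H = z0 above the
#' wall at z = 0), carried by a constant flow `u` along +x and diffusing with
#' coefficient `alpha`. The wall is handled by an image source at height -H.
#'
#' Two normalizations are available:
#'
#' * `"as_printed"` (default): the published closed form. With downstream
#'   distance s = x - x0 and the plume-like scaled variable r = alpha * s / u,
#'
#'   c = strength / (8 pi r^(3/2)) \* exp(-((s - u t)^2 + (y - y0)^2) / (4 r))
#'     \* \[ exp(-(z-H)^2 / (4 r)) + exp(-(z+H)^2 / (4 r)) \]
#'
#'   r is undefined for s <= 0, so upstream points return 0 (the standard
#'   plume/puff convention). Note this form mixes plume scaling (r
#'   proportional to downstream distance) with a travelling puff term
#'   (s - u t)^2, and its prefactor differs from the textbook puff by a
#'   factor of sqrt(pi); it is kept verbatim as the reference formulation.
#'
#' * `"textbook_puff"`: the exact Green's function of
#'   dc/dt + u dc/dx = alpha Laplacian(c) for an instantaneous point release,
#'   i.e. r = alpha * t, prefactor (4 pi r)^(3/2), centre advected to
#'   x0 + u t, defined for all x. This mode is the one validated against the
#'   finite-difference oracle (see [fd_solve_3d()]).
#'
#' Both modes satisfy the no-flux wall condition exactly.
#'
#' @param x,y,z Evaluation coordinates (vectorised; z >= 0 unless
#'   `check_wall = FALSE`).
#' @param t Time since release, > 0.
#' @param x0,y0,z0 Source release position; z0 = H >= 0.
#' @param u Constant flow speed, > 0 (scalar).
#' @param strength Lumped emission magnitude (total amount of tissue factor
#'   expressed by the cell), > 0.
#' @param alpha Dimensionless diffusion coefficient, > 0.
#' @param normalization `"as_printed"` or `"textbook_puff"`.
#' @inheritParams kernel_2d
#' @return Numeric vector of concentrations (>= 0, finite).
#' @examples
#' # all Gaussian arguments 0, 0 and -(2H)^2/4: 1/(8*pi) * (1 + exp(-1))
#' kernel_3d(1, 0, 1, t = 1, x0 = 0, y0 = 0, z0 = 1, u = 1, alpha = 1)
#' @export
kernel_3d <- function(x, y, z, t, x0 = 0, y0 = 0, z0 = 0, u, strength = 1,
                      alpha = 1.5,
                      normalization = c("as_printed", "textbook_puff"),
                      check_wall = TRUE) {
  normalization <- match.arg(normalization)
  if (missing(u)) stopf("`u` is required: the 3D kernel is defined for constant flow u > 0")
  check_scalar_number(u, "u", lower = 0, strict = TRUE)
  check_times_positive(t)
  if (any(alpha <= 0)) stopf("`alpha` must be > 0")
  if (any(strength <= 0)) stopf("`strength` must be > 0")
  if (check_wall && (any(z < 0) || any(z0 < 0))) {
    stopf("3D evaluation points and sources must lie in the closed half-space z >= 0")
  }
  a <- recycle_common(x = x, y = y, z = z, t = t, x0 = x0, y0 = y0, z0 = z0,
                      strength = strength, alpha = alpha)
  s <- a$x - a$x0
  if (normalization == "as_printed") {
    down <- s > 0
    r <- ifelse(down, a$alpha * s / u, 1)  # placeholder where masked
    core <- a$strength / (8 * pi * r^1.5) *
      exp(-((s - u * a$t)^2 + (a$y - a$y0)^2) / (4 * r)) *
      (exp(-(a$z - a$z0)^2 / (4 * r)) + exp(-(a$z + a$z0)^2 / (4 * r)))
    ifelse(down, core, 0)
  } else {
    r <- a$alpha * a$t
    a$strength / (4 * pi * r)^1.5 *
      exp(-((s - u * a$t)^2 + (a$y - a$y0)^2) / (4 * r)) *
      (exp(-(a$z - a$z0)^2 / (4 * r)) + exp(-(a$z + a$z0)^2 / (4 * r)))
  }
}

# vectorised superposed concentration at arbitrary coordinates (internal core)
conc_at <- function(x, y, z = NULL, t, sources, flow,
                    normalization = "as_printed", check_wall = TRUE) {
  n <- max(length(x), length(y), length(t), length(z %||% numeric(1)))
  out <- numeric(n)
  if (is.null(sources) || nrow(sources) == 0L) {
    check_times_positive(t)
    return(out)
  }
  sources <- validate_sources(sources, flow)
  if (is_3d(flow)) {
    if (is.null(z)) stopf("3D mode needs z coordinates")
    for (i in seq_len(nrow(sources))) {
      out <- out + kernel_3d(x, y, z, t,
                             x0 = sources$x0[i], y0 = sources$y0[i],
                             z0 = sources$z0[i], u = flow$u,
                             strength = sources$strength[i],
                             alpha = sources$alpha[i],
                             normalization = normalization,
                             check_wall = check_wall)
    }
  } else {
    for (i in seq_len(nrow(sources))) {
      out <- out + kernel_2d(x, y, t,
                             x0 = sources$x0[i], y0 = sources$y0[i],
                             strength = sources$strength[i],
                             alpha = sources$alpha[i],
                             check_wall = check_wall)
    }
  }
  out
}

#' Superposed concentration field at arbitrary points
#'
#' Evaluates the linear superposition of single-source kernels over a source
#' set at each row of `points`. The field equations are linear, so the
#' multi-cell field is exactly the sum of per-cell kernels; an empty source
#' set gives a zero field (documented behaviour, not an error).
#'
#' @param points A data frame with columns `x`, `y`, `t` (and `z` in 3D mode).
#' @param sources A source table, see [ctc_sources()]. May have zero rows.
#' @param flow A [flow_spec()].
#' @param normalization Passed to [kernel_3d()]; ignored in 2D mode.
#' @param check_wall Passed to the kernels.
#' @return `points` as a tibble with an added `conc` column.
#' @export
field_at <- function(points, sources, flow, normalization = "as_printed",
                     check_wall = TRUE) {
  if (!is.data.frame(points)) stopf("`points` must be a data frame")
  need <- c("x", "y", "t", if (is_3d(flow)) "z")
  miss <- setdiff(need, names(points))
  if (length(miss)) stopf("`points` is missing column(s): %s", paste(miss, collapse = ", "))
  pts <- as_tibble(points)
  pts$conc <- conc_at(pts$x, pts$y, z = if (is_3d(flow)) pts$z, t = pts$t,
                      sources = sources, flow = flow,
                      normalization = normalization, check_wall = check_wall)
  pts
}

# returns an evaluator f(x, y, z, t) -> conc for trackers / oracles
field_evaluator <- function(sources, flow, normalization = "as_printed") {
  force(sources); force(flow); force(normalization)
  function(x, y, z = NULL, t) {
    conc_at(x, y, z = z, t = t, sources = sources, flow = flow,
            normalization = normalization)
  }
}

#' Concentration field on a rectilinear grid or slice
#'
#' Evaluates the superposed field on the tensor grid of the supplied
#' coordinate vectors at each time in `t`, returning a long tibble. A planar
#' slice is just a grid with one coordinate vector of length 1 (e.g. `z = 0`
#' for the wall slice of a 3D run). Every cell equals [field_at()] at that
#' cell's coordinates.
#'
#' @param sources Source table.
#' @param flow A [flow_spec()].
#' @param t Output time(s), > 0.
#' @param x,y Coordinate vectors.
#' @param z Coordinate vector (3D mode only), all >= 0.
#' @inheritParams field_at
#' @return Long tibble with columns `t`, (`z`,) `y`, `x`, `conc`; `x` varies
#'   fastest.
#' @export
field_grid <- function(sources, flow, t, x, y, z = NULL,
                       normalization = "as_printed") {
  check_times_positive(t)
  if (is_3d(flow)) {
    if (is.null(z)) stopf("3D mode needs a z coordinate vector")
    if (any(z < 0)) stopf("grid crosses the wall: all z must be >= 0")
    pts <- tidyr::expand_grid(t = t, z = z, y = y, x = x)
  } else {
    if (!is.null(z)) stopf("2D mode takes no z coordinates")
    if (any(y < 0)) stopf("grid crosses the wall: all y must be >= 0")
    pts <- tidyr::expand_grid(t = t, y = y, x = x)
  }
  field_at(pts, sources, flow, normalization = normalization)
}

#' Half-plane mass of a single 2D source field
#'
#' Numerically integrates a single-source 2D field over the upper half-plane
#' by nested adaptive quadrature (inner over x, outer over y) on a generous
#' truncated support (the integrand decays like a Gaussian, so truncation
#' error is negligible at the chosen extent). For the image-corrected kernel
#' the result equals the source strength exactly, for every t > 0: the wall
#' reflects, it does not absorb.
#'
#' @param source One-row source table.
#' @param t Time, > 0 (scalar).
#' @param nsig Half-width of the integration support in units of the Gaussian
#'   scale sqrt(4 alpha t).
#' @param rel.tol Relative tolerance for both quadrature levels.
#' @return Scalar mass estimate.
#' @export
half_plane_mass <- function(source, t, nsig = 14, rel.tol = 1e-10) {
  stopifnot(nrow(source) == 1L)
  check_scalar_number(t, "t", lower = 0, strict = TRUE)
  sig <- sqrt(4 * source$alpha * t)
  inner <- function(y) {
    stats::integrate(function(x) {
      kernel_2d(x, y, t, x0 = source$x0, y0 = source$y0,
                strength = source$strength, alpha = source$alpha)
    }, lower = source$x0 - nsig * sig, upper = source$x0 + nsig * sig,
    rel.tol = rel.tol, subdivisions = 500L)$value
  }
  stats::integrate(Vectorize(inner), lower = 0,
                   upper = source$y0 + nsig * sig,
                   rel.tol = rel.tol, subdivisions = 500L)$value
}
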