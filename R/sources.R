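#' Build a table of CTC point sources
#'
#' A source is one circulating tumor cell, reduced to a point release: its
#' position, a lumped emission strength (total tissue factor expressed by the
#' cell) and a per-cell diffusion coefficient. In 2D mode the wall-normal
#' coordinate is `y0` and `z0` is unused (`NA`); in 3D mode `z0` is the
#' release height H above the wall.
#'
#' @param x0,y0 In-plane position components (vectorised).
#' @param z0 Release height above the wall (3D mode); `NA` for 2D sources.
#' @param strength Emission magnitude, > 0.
#' @param alpha Diffusion coefficient, > 0. The published runs all use 1.5.
#' @return A tibble with columns `x0, y0, z0, strength, alpha`.
#' @examples
#' ctc_sources(x0 = c(0, 10), y0 = c(2, 5))
#' @export
ctc_sources <- function(x0, y0, z0 = NA_real_, strength = 1, alpha = 1.5) {
  a <- recycle_common(x0 = x0, y0 = y0, z0 = z0, strength = strength,
                      alpha = alpha)
  out <- tibble(x0 = as.numeric(a$x0), y0 = as.numeric(a$y0),
                z0 = as.numeric(a$z0), strength = as.numeric(a$strength),
                alpha = as.numeric(a$alpha))
  if (any(out$strength <= 0)) stopf("source `strength` must be > 0")
  if (any(out$alpha <= 0)) stopf("source `alpha` must be > 0")
  if (any(!is.na(out$z0) & out$z0 < 0)) stopf("release heights z0 must be >= 0")
  out
}

# check a source table against a flow mode's wall constraint
validate_sources <- function(sources, flow) {
  if (!is.data.frame(sources)) stopf("`sources` must be a data frame")
  need <- c("x0", "y0", "strength", "alpha")
  miss <- setdiff(need, names(sources))
  if (length(miss)) stopf("source table is missing column(s): %s", paste(miss, collapse = ", "))
  if (!"z0" %in% names(sources)) sources$z0 <- NA_real_
  if (any(sources$strength <= 0)) stopf("source `strength` must be > 0")
  if (any(sources$alpha <= 0)) stopf("source `alpha` must be > 0")
  if (is_3d(flow)) {
    if (any(is.na(sources$z0)) || any(sources$z0 < 0)) {
      stopf("3D sources need release heights z0 >= 0")
    }
  } else if (any(sources$y0 < 0)) {
    stopf("2D sources must lie in the closed half-plane y0 >= 0")
  }
  as_tibble(sources)
}

#' Seeded uniform random placement of CTC sources
#'
#' Draws `n` sources i.i.d. uniform over an axis-aligned box, reproducibly:
#' the same `(box, n, seed, rng_kind)` always yields the same table, and the
#' caller's RNG state is left untouched. The generator algorithm is pinned by
#' name so seeds are portable across sessions and platforms.
#'
#' @param n Number of sources, >= 1.
#' @param box Named list of 2-vectors `list(x = c(lo, hi), y = c(lo, hi))`,
#'   plus `z = c(lo, hi)` for 3D placement. The wall-normal lower bound
#'   (`y` in 2D, `z` in 3D) must be >= 0.
#' @param seed Integer seed.
#' @param strength,alpha Shared source parameters.
#' @param rng_kind RNG algorithm name, see [set.seed()].
#' @return A source tibble (see [ctc_sources()]).
#' @export
place_sources <- function(n, box, seed, strength = 1, alpha = 1.5,
                          rng_kind = "Mersenne-Twister") {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stopf("`n` must be a positive integer")
  }
  box <- validate_box(box)
  wall_ax <- if (!is.null(box$z)) "z" else "y"
  if (box[[wall_ax]][1] < 0) {
    stopf("placement box violates the wall: lower %s bound must be >= 0", wall_ax)
  }
  coords <- with_local_seed(seed, rng_kind, {
    out <- list(
      x0 = runif(n, box$x[1], box$x[2]),
      y0 = runif(n, box$y[1], box$y[2])
    )
    if (!is.null(box$z)) out$z0 <- runif(n, box$z[1], box$z[2])
    out
  })
  ctc_sources(x0 = coords$x0, y0 = coords$y0,
              z0 = coords$z0 %||% NA_real_,
              strength = strength, alpha = alpha)
}

validate_box <- function(box) {
  if (!is.list(box) || is.null(box$x) || is.null(box$y)) {
    stopf("`box` must be a named list with 2-vectors `x`, `y` (and `z` in 3D)")
  }
  for (ax in intersect(c("x", "y", "z"), names(box))) {
    b <- box[[ax]]
    if (!is.numeric(b) || length(b) != 2L || any(!is.finite(b)) || b[2] <= b[1]) {
      stopf("box `%s` must be a nondegenerate finite interval c(lo, hi)", ax)
    }
  }
  box[intersect(c("x", "y", "z"), names(box))]
}

#' The four-cell reference configuration of the 3D runs
#'
#' The explicit four-CTC arrangement used by the published 3D simulations:
#' positions (300, 300, 45), (180, 400, 30), (300, 100, 30), (275, 200, 60),
#' all with diffusion coefficient 1.5 and unit strength.
#'
#' @return A 4-row source tibble.
#' @export
reference_sources_3d <- function() {
  ctc_sources(
    x0 = c(300, 180, 300, 275),
    y0 = c(300, 400, 100, 200),
    z0 = c(45, 30, 30, 60),
    strength = 1,
    alpha = 1.5
  )
}

#' Advect source release positions downstream
#'
#' Shifts every source's `x0` by `u * dt`; cross-stream and wall-normal
#' coordinates are untouched, and 2D (no-flow) mode is the identity.
#'
#' Note for field evaluation: the constant-flow kernel already carries its own
#' advection through the travelling term `(x - x0 - u t)`, with `x0` the
#' *release* position. Fields must therefore be evaluated with release
#' positions, never with advected ones — applying both would double-count the
#' downstream displacement. `advect_sources()` exists for trajectory output
#' and for co-plotting current cell positions with trackers.
#'
#' @param sources Source table.
#' @param flow A [flow_spec()].
#' @param dt Time increment, >= 0.
#' @return The advected source tibble.
#' @export
advect_sources <- function(sources, flow, dt) {
  check_scalar_number(dt, "dt", lower = 0)
  sources <- validate_sources(sources, flow)
  sources$x0 <- sources$x0 + flow$u * dt
  sources
}

#' Read/write a source table as CSV
#'
#' One row per source with an `id` column: `id, x0, y0, z0, strength, alpha`.
#' `read_sources(write_sources(s, path))` round-trips exactly (full double
#' precision).
#'
#' @param sources Source table.
#' @param path File path.
#' @return `write_sources()` returns `path` invisibly; `read_sources()`
#'   returns the source tibble (without the `id` column).
#' @export
write_sources <- function(sources, path) {
  out <- as_tibble(sources)
  if (!"z0" %in% names(out)) out$z0 <- NA_real_
  out <- dplyr::mutate(out, id = row_number(), .before = 1)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_sources
#' @export
read_sources <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  ctc_sources(x0 = out$x0, y0 = out$y0, z0 = out$z0,
              strength = out$strength, alpha = out$alpha)
}
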