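#' Create passive gradient trackers
#'
#' Trackers are diagnostic particles that poll the concentration at six
#' axis-aligned neighbours (four in 2D) a distance `eps` away and hop `eps`
#' toward the largest concentration increase ("high-seeking", drawn red) or
#' decrease ("low-seeking", blue). They never perturb the field. Initial
#' positions are drawn uniformly over `box` with a pinned, seeded RNG.
#'
#' @param n_high,n_low Number of high-/low-seeking trackers.
#' @param box Placement box as in [place_sources()]; include `z` for 3D runs.
#' @param eps Probe and step distance, > 0 and small relative to the domain.
#' @param seed Integer seed.
#' @param rng_kind RNG algorithm name.
#' @return Tibble with columns `id, polarity, x, y, z, eps`.
#' @export
make_trackers <- function(n_high, n_low, box, eps, seed,
                          rng_kind = "Mersenne-Twister") {
  check_scalar_number(eps, "eps", lower = 0, strict = TRUE)
  box <- validate_box(box)
  n <- n_high + n_low
  if (n < 1) stopf("need at least one tracker")
  wall_ax <- if (!is.null(box$z)) "z" else "y"
  if (box[[wall_ax]][1] < 0) stopf("tracker box violates the wall")
  coords <- with_local_seed(seed, rng_kind, {
    out <- list(x = runif(n, box$x[1], box$x[2]),
                y = runif(n, box$y[1], box$y[2]))
    out$z <- if (!is.null(box$z)) runif(n, box$z[1], box$z[2]) else rep(NA_real_, n)
    out
  })
  tibble(
    id = seq_len(n),
    polarity = rep(c("high", "low"), c(n_high, n_low)),
    x = coords$x, y = coords$y, z = coords$z,
    eps = eps
  )
}

# direction table: fixed polling (and tie-break) order +x, -x, +y, -y, +z, -z
tracker_directions <- function(three_d) {
  d <- tibble(
    axis = c("x", "x", "y", "y", "z", "z"),
    sign = c(1, -1, 1, -1, 1, -1)
  )
  if (!three_d) d <- d[d$axis != "z", ]
  d
}

#' Poll the six axis neighbours of a tracker position
#'
#' Returns the signed differences `c(p) - c(p +- eps * e_k)` in the fixed
#' order `+x, -x, +y, -y, +z, -z` (the z pair is omitted in 2D). Probe points
#' that would cross the wall are clamped to the wall plane, where the field is
#' still defined.
#'
#' @param x,y,z Tracker position (scalars; `z = NULL` in 2D).
#' @param t Evaluation time, > 0.
#' @param field Evaluator `function(x, y, z, t) -> conc`, e.g. from a source
#'   set via `field_at()`; any function works (trackers are field-agnostic).
#' @param eps Probe distance.
#' @param wall_axis Which coordinate the wall bounds: `"y"` (2D) or `"z"` (3D).
#' @return Named numeric vector of differences (length 4 or 6).
#' @export
poll_neighbors <- function(x, y, z = NULL, t, field, eps,
                           wall_axis = if (is.null(z)) "y" else "z") {
  check_times_positive(t)
  three_d <- !is.null(z)
  dirs <- tracker_directions(three_d)
  px <- x + eps * dirs$sign * (dirs$axis == "x")
  py <- y + eps * dirs$sign * (dirs$axis == "y")
  pz <- if (three_d) z + eps * dirs$sign * (dirs$axis == "z") else NULL
  if (wall_axis == "y") py <- pmax(py, 0) else pz <- pmax(pz, 0)
  c0 <- field(x, y, z = z, t = t)
  cn <- field(px, py, z = pz, t = t)
  setNames(c0 - cn, paste0(ifelse(dirs$sign > 0, "+", "-"), dirs$axis))
}

# vectorised single step for a whole tracker table; internal workhorse
step_trackers_impl <- function(trackers, field, t, tol) {
  n <- nrow(trackers)
  three_d <- !all(is.na(trackers$z))
  dirs <- tracker_directions(three_d)
  k <- nrow(dirs)
  eps <- trackers$eps
  # probe coordinates: n x k matrices
  px <- trackers$x + t(t(matrix(eps, n, k)) * (dirs$sign * (dirs$axis == "x")))
  py <- trackers$y + t(t(matrix(eps, n, k)) * (dirs$sign * (dirs$axis == "y")))
  pz <- if (three_d) {
    trackers$z + t(t(matrix(eps, n, k)) * (dirs$sign * (dirs$axis == "z")))
  } else NULL
  # clamp probes at the wall
  if (three_d) pz <- pmax(pz, 0) else py <- pmax(py, 0)
  c0 <- field(trackers$x, trackers$y, z = if (three_d) trackers$z, t = t)
  cn <- matrix(
    field(as.vector(px), as.vector(py), z = if (three_d) as.vector(pz), t = t),
    n, k
  )
  gain <- cn - c0  # concentration change offered by each neighbour
  # low-seekers maximise the *decrease*
  score <- gain * ifelse(trackers$polarity == "high", 1, -1)
  best <- max.col(score, ties.method = "first")
  idx <- cbind(seq_len(n), best)
  move <- score[idx] > tol
  ax <- dirs$axis[best]
  sg <- dirs$sign[best]
  out <- trackers
  out$x <- out$x + ifelse(move & ax == "x", sg * eps, 0)
  out$y <- out$y + ifelse(move & ax == "y", sg * eps, 0)
  if (three_d) out$z <- out$z + ifelse(move & ax == "z", sg * eps, 0)
  # moves may not cross the wall
  if (three_d) out$z <- pmax(out$z, 0) else out$y <- pmax(out$y, 0)
  out
}

#' Advance trackers by one polling step
#'
#' Each tracker polls its axis neighbours at distance `eps` and hops `eps`
#' toward the neighbour offering the largest concentration increase
#' (high-seeking) or decrease (low-seeking). Ties are broken by the fixed
#' polling order `+x, -x, +y, -y, +z, -z` (first maximum wins); differences
#' not exceeding `tol` count as no improvement and the tracker stays. Moves
#' that would cross the wall are clamped to the wall plane.
#'
#' @param trackers Tracker tibble from [make_trackers()].
#' @param field Evaluator `function(x, y, z, t)`.
#' @param t Time at which the field is polled, > 0.
#' @param tol Absolute no-improvement tolerance (dimensionless); avoids
#'   noise-driven jitter in flat far fields.
#' @return The stepped tracker tibble.
#' @export
step_trackers <- function(trackers, field, t, tol = 1e-15) {
  check_times_positive(t)
  step_trackers_impl(trackers, field, t, tol)
}

#' Evolve trackers through a time-dependent field
#'
#' Steps every tracker once per cadence tick against the evolving superposed
#' field of `sources` under `flow`. Trackers are passive (the field never sees
#' them) and, by default, are not advected by the flow — they move only by
#' gradient polling. The first record is the initial state at `t0`; each
#' subsequent record at time t is the position after polling the field at t.
#'
#' @param trackers Tracker tibble.
#' @param sources Source table (release positions).
#' @param flow A [flow_spec()].
#' @param t0,t1 Start and end times, 0 < t0 < t1.
#' @param dt Cadence (time between tracker steps), > 0.
#' @param tol No-improvement tolerance, see [step_trackers()].
#' @param normalization 3D kernel normalization.
#' @param advect Logical; if `TRUE`, trackers are additionally carried
#'   downstream by `u * dt` each tick (off by default).
#' @return Long trajectory tibble: `id, polarity, t, x, y, z`.
#' @export
evolve_trackers <- function(trackers, sources, flow, t0, t1, dt,
                            tol = 1e-15, normalization = "as_printed",
                            advect = FALSE) {
  check_scalar_number(t0, "t0", lower = 0, strict = TRUE)
  check_scalar_number(dt, "dt", lower = 0, strict = TRUE)
  if (t1 <= t0) stopf("`t1` must exceed `t0`")
  field <- field_evaluator(sources, flow, normalization)
  times <- seq(t0, t1, by = dt)
  cur <- trackers
  snap <- function(tr, t) {
    tibble(id = tr$id, polarity = tr$polarity, t = t,
           x = tr$x, y = tr$y, z = tr$z)
  }
  out <- vector("list", length(times))
  out[[1]] <- snap(cur, times[1])
  for (i in seq_along(times)[-1]) {
    cur <- step_trackers_impl(cur, field, times[i], tol)
    if (advect) cur$x <- cur$x + flow$u * dt
    out[[i]] <- snap(cur, times[i])
  }
  bind_rows(out)
}
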