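# shared builders for tests; everything is generated in code

flow2d <- function() flow_spec("no_flow_2d")
flow3d <- function(u = 1) flow_spec("constant_flow_3d", u = u)

random_sources_2d <- function(n, seed, box = list(x = c(-50, 50), y = c(0, 40))) {
  place_sources(n, box = box, seed = seed)
}

random_sources_3d <- function(n, seed,
                              box = list(x = c(-50, 50), y = c(-40, 40), z = c(0, 30))) {
  place_sources(n, box = box, seed = seed)
}

# small validated 2D run config used by engine/config tests
tiny_config_2d <- function(seed = 11L, n = 12L) {
  run_config(
    mode = "no_flow_2d",
    sources = list(count = n, box = list(x = c(0, 60), y = c(0, 10)),
                   strength = 1, alpha = 1.5),
    times = c(1, 5),
    peak_times = exp(seq(log(0.5), log(50), length.out = 12)),
    slices = c(0, 5, 20),
    grid = list(x = c(0, 60), y = c(0, 30), nx = 48, ny = 32),
    profile_points = 101,
    seed = seed,
    name = "tiny2d"
  )
}

# hand-written single (direct or image) 3D term, used as an oracle for
# image-symmetry identities
puff_term_3d <- function(x, y, z, t, x0, y0, H, u, strength, alpha) {
  s <- x - x0
  r <- alpha * s / u
  strength / (8 * pi * r^1.5) *
    exp(-((s - u * t)^2 + (y - y0)^2) / (4 * r)) *
    exp(-(z - H)^2 / (4 * r))
}
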