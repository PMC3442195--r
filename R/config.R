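# cli_io: structured run configurations, validation, archives and manifests.
# Configs are YAML; unknown keys are a hard error (silent ignoring hides
# typos that would otherwise change the physics).

config_keys <- list(
  top = c("name", "mode", "u", "normalization", "seed", "rng_kind", "sources",
          "times", "peak_times", "slices", "grid", "profile_points",
          "trackers"),
  recipe = c("count", "box", "strength", "alpha", "seed"),
  trackers = c("n_high", "n_low", "box", "eps", "seed", "t0", "t1", "dt",
               "tol", "advect")
)

check_known_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stopf("unknown config key(s) in %s: %s", where,
          paste(unknown, collapse = ", "))
  }
}

#' Construct a run configuration
#'
#' Assembles and validates the full description of a simulation: flow mode and
#' speed, sources (an explicit table or a seeded placement recipe), output
#' times, wall-normal slice offsets, grid resolution, optional tracker block,
#' seed and RNG algorithm. The same structure round-trips through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param mode `"no_flow_2d"` or `"constant_flow_3d"`.
#' @param u Flow speed (0 in 2D mode, > 0 in 3D mode).
#' @param sources Either a source table (see [ctc_sources()]) or a recipe list
#'   `list(count =, box =, strength =, alpha =, seed =)` for
#'   [place_sources()].
#' @param times Strictly increasing field output times, all > 0.
#' @param slices Numeric vector of wall-normal slice offsets (>= 0), or a list
#'   of `list(axis =, offset =)` entries.
#' @param grid List `list(x = c(lo, hi), y = c(lo, hi), nx =, ny =)`.
#' @param peak_times Times for the peak-vs-time diagnostic (defaults to
#'   `times`).
#' @param profile_points Sample count for 1D slice profiles (2D mode).
#' @param trackers Optional tracker block:
#'   `list(n_high =, n_low =, box =, eps =, t0 =, t1 =, dt =, seed =, tol =,
#'   advect =)`.
#' @param seed Integer master seed.
#' @param normalization 3D kernel normalization.
#' @param rng_kind Pinned RNG algorithm name.
#' @param name Optional run label.
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode, u = NULL, sources, times, slices, grid,
                       peak_times = NULL, profile_points = 1201,
                       trackers = NULL, seed = 1L,
                       normalization = "as_printed",
                       rng_kind = "Mersenne-Twister", name = NULL) {
  if (is.data.frame(sources)) {
    src <- list(explicit = purrr::transpose(as.list(as_tibble(sources))))
  } else if (is.list(sources) && !is.null(sources$count)) {
    src <- list(recipe = sources)
  } else if (is.list(sources) && (!is.null(sources$explicit) || !is.null(sources$recipe))) {
    src <- sources
  } else {
    stopf("`sources` must be a source table or a placement recipe list")
  }
  if (is.numeric(slices)) {
    ax <- if (identical(mode, "constant_flow_3d")) "z" else "y"
    slices <- purrr::map(slices, ~list(axis = ax, offset = .x))
  }
  cfg <- list(
    name = name, mode = mode, u = u, normalization = normalization,
    seed = seed, rng_kind = rng_kind, sources = src, times = times,
    peak_times = peak_times, slices = slices, grid = grid,
    profile_points = profile_points, trackers = trackers
  )
  validate_run_config(cfg)
}

#' Validate (and normalise) a run configuration
#'
#' Checks every invariant the engine relies on before any compute: known keys
#' only, t > 0 and strictly increasing output times, wall-compatible slice
#' axes and offsets, in-half-space grids and boxes, tracker block sanity.
#' Numeric fields are normalised to doubles (seeds and counts to integers) so
#' that validated configs compare `identical()` across YAML round trips.
#'
#' @param config A run configuration list.
#' @return The normalised `run_config`.
#' @export
validate_run_config <- function(config) {
  if (inherits(config, "run_config")) config <- unclass(config)
  check_known_keys(config, config_keys$top, "run config")
  for (key in c("mode", "sources", "times", "slices", "grid", "seed")) {
    if (is.null(config[[key]])) stopf("config is missing required key `%s`", key)
  }
  if (!config$mode %in% c("no_flow_2d", "constant_flow_3d")) {
    stopf("`mode` must be no_flow_2d or constant_flow_3d")
  }
  three_d <- config$mode == "constant_flow_3d"
  config$u <- as.numeric(config$u %||% if (three_d) 1 else 0)
  flow <- flow_spec(config$mode, u = config$u)  # validates u/mode pairing
  config$normalization <- config$normalization %||% "as_printed"
  if (!config$normalization %in% c("as_printed", "textbook_puff")) {
    stopf("`normalization` must be as_printed or textbook_puff")
  }
  config$seed <- as.integer(config$seed)
  config$rng_kind <- config$rng_kind %||% "Mersenne-Twister"

  config$times <- as.numeric(unlist(config$times))
  check_times_positive(config$times, "times")
  if (is.unsorted(config$times, strictly = TRUE)) {
    stopf("`times` must be strictly increasing")
  }
  pt <- config$peak_times
  if (is.null(pt)) {
    config$peak_times <- config$times
  } else if (is.list(pt) && !is.null(pt$log_range)) {
    check_known_keys(pt, c("log_range", "n_points"), "peak_times")
    lr <- as.numeric(unlist(pt$log_range))
    config$peak_times <- exp(seq(log(lr[1]), log(lr[2]), length.out = pt$n_points))
  } else {
    config$peak_times <- as.numeric(unlist(pt))
  }
  check_times_positive(config$peak_times, "peak_times")

  wall_ax <- if (three_d) "z" else "y"
  config$slices <- purrr::map(config$slices, function(s) {
    check_known_keys(s, c("axis", "offset"), "slice")
    # YAML 1.1 reads a bare `y` as TRUE; tolerate hand-written configs
    if (isTRUE(s$axis)) s$axis <- "y"
    s$offset <- as.numeric(s$offset)
    if (!identical(s$axis, wall_ax)) {
      stopf("invalid slice/wall combination: %s mode slices along `%s`, got `%s`",
            config$mode, wall_ax, s$axis)
    }
    if (s$offset < 0) stopf("slice offsets on the wall-normal axis must be >= 0")
    list(axis = s$axis, offset = s$offset)
  })

  g <- config$grid
  check_known_keys(g, c("x", "y", "nx", "ny"), "grid")
  g$x <- as.numeric(unlist(g$x)); g$y <- as.numeric(unlist(g$y))
  g$nx <- as.integer(g$nx %||% 256L); g$ny <- as.integer(g$ny %||% 256L)
  if (length(g$x) != 2 || length(g$y) != 2 || g$x[2] <= g$x[1] || g$y[2] <= g$y[1]) {
    stopf("grid `x` and `y` must be nondegenerate intervals")
  }
  if (!three_d && g$y[1] < 0) stopf("2D grid crosses the wall: y range must start >= 0")
  config$grid <- g
  config$profile_points <- as.integer(config$profile_points %||% 1201L)

  src <- config$sources
  if (!is.null(src$recipe)) {
    check_known_keys(src$recipe, config_keys$recipe, "sources recipe")
    r <- src$recipe
    r$count <- as.integer(r$count)
    r$box <- purrr::map(validate_box(purrr::map(r$box, ~as.numeric(unlist(.x)))), identity)
    r$strength <- as.numeric(r$strength %||% 1)
    r$alpha <- as.numeric(r$alpha %||% 1.5)
    if (!is.null(r$seed)) r$seed <- as.integer(r$seed)
    if (three_d && is.null(r$box$z)) stopf("3D placement recipe needs a z box")
    wall_box <- if (three_d) r$box$z else r$box$y
    if (wall_box[1] < 0) stopf("placement box violates the wall")
    config$sources <- list(recipe = r)
  } else if (!is.null(src$explicit)) {
    rows <- purrr::map(src$explicit, function(s) {
      check_known_keys(s, c("x0", "y0", "z0", "strength", "alpha"), "explicit source")
      list(x0 = as.numeric(s$x0), y0 = as.numeric(s$y0),
           z0 = as.numeric(s$z0 %||% NA_real_),
           strength = as.numeric(s$strength %||% 1),
           alpha = as.numeric(s$alpha %||% 1.5))
    })
    tab <- bind_rows(purrr::map(rows, as_tibble))
    validate_sources(tab, flow)
    config$sources <- list(explicit = rows)
  } else {
    stopf("`sources` must contain either `explicit` or `recipe`")
  }

  if (!is.null(config$trackers)) {
    tc <- config$trackers
    check_known_keys(tc, config_keys$trackers, "trackers")
    for (key in c("n_high", "n_low", "box", "eps", "t0", "t1", "dt")) {
      if (is.null(tc[[key]])) stopf("tracker block is missing `%s`", key)
    }
    tc$n_high <- as.integer(tc$n_high); tc$n_low <- as.integer(tc$n_low)
    tc$box <- purrr::map(validate_box(purrr::map(tc$box, ~as.numeric(unlist(.x)))), identity)
    tc$eps <- as.numeric(tc$eps)
    tc$t0 <- as.numeric(tc$t0); tc$t1 <- as.numeric(tc$t1); tc$dt <- as.numeric(tc$dt)
    check_times_positive(tc$t0, "trackers$t0")
    if (tc$t1 <= tc$t0 || tc$dt <= 0) stopf("tracker block needs t1 > t0 and dt > 0")
    if (!is.null(tc$seed)) tc$seed <- as.integer(tc$seed)
    if (!is.null(tc$tol)) tc$tol <- as.numeric(tc$tol)
    tc$advect <- isTRUE(tc$advect)
    config$trackers <- tc
  }
  structure(config, class = "run_config")
}

resolve_sources <- function(config, flow) {
  src <- config$sources
  if (!is.null(src$explicit)) {
    tab <- bind_rows(purrr::map(src$explicit, as_tibble))
    return(validate_sources(tab, flow))
  }
  r <- src$recipe
  place_sources(r$count, box = r$box, seed = r$seed %||% config$seed,
                strength = r$strength, alpha = r$alpha,
                rng_kind = config$rng_kind)
}

#' Read / write run configurations as YAML
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  validate_run_config(fix_yaml_bool_keys(yaml::read_yaml(path)))
}

# YAML 1.1 turns a bare `y` key into TRUE; map it back for hand-written files
fix_yaml_bool_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) names(x) <- ifelse(nm == "TRUE", "y", nm)
  purrr::map(x, fix_yaml_bool_keys)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  config <- validate_run_config(config)
  yaml::write_yaml(drop_nulls(unclass(config)), path, precision = 17)
  invisible(path)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- purrr::compact(x)
  purrr::map(x, drop_nulls)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(drop_nulls(unclass(validate_run_config(config))), tf,
                   precision = 17)
  unname(tools::md5sum(tf))
}

#' Apply command-line style overrides to a config
#'
#' Overrides are `key=value` strings with dots for nesting, e.g.
#' `"seed=7"`, `"sources.recipe.count=4"`, `"grid.nx=128"`. Values are parsed
#' as YAML. Overriding an unknown key fails validation downstream.
#'
#' @param config A `run_config` (or raw config list).
#' @param overrides Character vector of `key=value` strings.
#' @return The re-validated `run_config`.
#' @export
apply_overrides <- function(config, overrides) {
  config <- unclass(config)
  for (ov in overrides) {
    m <- regmatches(ov, regexpr("=", ov), invert = TRUE)[[1]]
    if (length(m) != 2) stopf("override must look like key=value: %s", ov)
    keys <- strsplit(m[1], ".", fixed = TRUE)[[1]]
    value <- yaml::yaml.load(m[2])
    config <- assign_nested(config, keys, value)
  }
  validate_run_config(config)
}

assign_nested <- function(x, keys, value) {
  if (length(keys) == 1) {
    x[[keys]] <- value
    return(x)
  }
  x[[keys[1]]] <- assign_nested(x[[keys[1]]] %||% list(), keys[-1], value)
  x
}

#' Packaged fixture configurations
#'
#' Lists the run configurations shipped with the package, one per published
#' simulation: the 2D 100-cell quiescent run, the 3D four-cell and 100-cell
#' constant-flow runs, and the 3D gradient-tracker run.
#'
#' @return Tibble with columns `name`, `path`.
#' @export
fixture_configs <- function() {
  dir <- system.file("extdata", "configs", package = "ctcfields")
  paths <- sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))
  tibble(name = sub("\\.yaml$", "", basename(paths)), path = paths)
}

#' Run a configuration and write a checksummed archive
#'
#' Reads and validates a config, applies overrides, executes
#' [run_simulation()] and writes the archive: delimited tables for sources,
#' fields, profiles, peak series and tracker trajectories, a self-describing
#' `archive.json` (coordinate vectors, config, tool version) and a
#' `manifest.json` listing every emitted file with its MD5 checksum, the
#' config hash, seeds and wall times. Deterministic artifacts reproduce their
#' checksums on re-runs.
#'
#' @param config_path Path to a YAML run config.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed override (recorded in the manifest).
#' @param overrides Character vector of `key=value` overrides.
#' @param quiet Suppress the progress line.
#' @return The manifest (invisibly), as a list.
#' @export
cli_run <- function(config_path, out_dir, seed = NULL,
                    overrides = character(), quiet = TRUE) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  config <- read_run_config(config_path)
  if (!is.null(seed)) overrides <- c(overrides, sprintf("seed=%d", as.integer(seed)))
  if (length(overrides)) config <- apply_overrides(config, overrides)
  if (!quiet) {
    message(sprintf("event=run config=%s seed=%d rng=%s hash=%s",
                    config_path, config$seed, config$rng_kind,
                    config_hash(config)))
  }
  run <- run_simulation(config)
  manifest <- write_run_archive(run, out_dir, started = started,
                                overrides = overrides)
  if (!quiet) {
    message(sprintf("event=done artifacts=%d out=%s",
                    nrow(manifest$artifacts), out_dir))
  }
  invisible(manifest)
}

#' Write a run archive to disk
#'
#' @param run A `ctc_run` from [run_simulation()].
#' @param dir Output directory.
#' @param started Optional ISO start timestamp (defaults to now).
#' @param overrides Overrides applied to the config, recorded verbatim.
#' @return The manifest list (also written as `manifest.json`).
#' @export
write_run_archive <- function(run, dir, started = NULL, overrides = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  started <- started %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  files <- character()
  emit <- function(obj, name) {
    p <- file.path(dir, name)
    readr::write_csv(obj, p)
    files <<- c(files, p)
  }
  emit(run$sources, "sources.csv")
  emit(run$fields, "fields.csv")
  if (!is.null(run$profiles)) emit(run$profiles, "profiles.csv")
  emit(as_tibble(run$peaks), "peaks.csv")
  if (!is.null(run$trackers)) emit(run$trackers, "trackers.csv")

  meta <- list(
    tool = "ctcfields", version = run$meta$version,
    config = drop_nulls(unclass(run$config)),
    config_hash = config_hash(run$config),
    grid = run$meta$grid,
    peak_sampling = drop_nulls(run$meta$peak_sampling),
    tables = basename(files)
  )
  meta_path <- file.path(dir, "archive.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, meta_path)

  manifest <- list(
    config_hash = meta$config_hash,
    version = run$meta$version,
    seed = run$config$seed,
    rng_kind = run$config$rng_kind,
    overrides = as.list(overrides),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
    artifacts = data.frame(
      file = basename(files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a run archive written by [write_run_archive()]
#'
#' @param dir Archive directory.
#' @return List with `meta`, `manifest` and the stored tables.
#' @export
read_run_archive <- function(dir) {
  meta_path <- file.path(dir, "archive.json")
  if (!file.exists(meta_path)) stopf("not a run archive (no archive.json): %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tabs <- purrr::map(meta$tables, function(f) {
    readr::read_csv(file.path(dir, f), show_col_types = FALSE)
  })
  names(tabs) <- sub("\\.csv$", "", meta$tables)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  c(list(meta = meta, manifest = manifest), tabs)
}

#' Materialise the source set described by a run configuration
#'
#' Resolves a config's sources: an explicit list is returned as a table, a
#' placement recipe is drawn reproducibly with the recipe's (or config's)
#' seed and the config's pinned RNG algorithm.
#'
#' @param config A `run_config` (or raw config list).
#' @return A source tibble.
#' @export
config_sources <- function(config) {
  config <- validate_run_config(config)
  resolve_sources(config, flow_spec(config$mode, u = config$u))
}

#' Flow specification of a run configuration
#'
#' @param config A `run_config` (or raw config list).
#' @return A [flow_spec()].
#' @export
config_flow <- function(config) {
  config <- validate_run_config(config)
  flow_spec(config$mode, u = config$u)
}
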