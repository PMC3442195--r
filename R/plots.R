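# figure layer: every plot function takes tidy tables and returns a ggplot

#' Heatmap of a field slice
#'
#' @param field Long field tibble (one time, one slice) with `x`, `y`,
#'   `conc`.
#' @param trans Scale transform for the fill (e.g. `"sqrt"` to compress
#'   peaks).
#' @return A ggplot.
#' @export
plot_field_slice <- function(field, trans = "identity") {
  ggplot(field, aes(x = .data$x, y = .data$y, fill = .data$conc)) +
    geom_raster() +
    scale_fill_viridis_c(option = "inferno", trans = trans, name = "conc") +
    coord_equal() +
    labs(x = "x", y = "y") +
    theme_minimal()
}

#' Concentration profiles along x at fixed wall-normal offsets
#'
#' @param profiles Long tibble with `x`, `conc` and a slice column.
#' @param slice_col Name of the slice column (`"y"` for 2D runs).
#' @return A ggplot.
#' @export
plot_profiles <- function(profiles, slice_col = "y") {
  ggplot(profiles,
         aes(x = .data$x, y = .data$conc,
             colour = factor(.data[[slice_col]]))) +
    geom_line() +
    labs(x = "x", y = "concentration", colour = slice_col) +
    theme_minimal()
}

#' Peak concentration versus time, per slice (log-log)
#'
#' @param peaks A [peak_series()] tibble.
#' @param split Optional [regime_split()] object; draws the fitted breakpoint.
#' @return A ggplot.
#' @export
plot_peak_series <- function(peaks, split = NULL) {
  peaks <- dplyr::filter(as_tibble(peaks), .data$peak > 0)  # log axes
  p <- ggplot(as_tibble(peaks),
              aes(x = .data$t, y = .data$peak,
                  colour = factor(.data$offset))) +
    geom_line() +
    geom_point(size = 0.8) +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = "t", y = "peak concentration", colour = "slice offset") +
    theme_minimal()
  if (!is.null(split)) {
    p <- p + geom_vline(xintercept = split$t_split, linetype = "dashed")
  }
  p
}

#' Tracker positions at selected times
#'
#' High-seeking trackers are drawn red, low-seeking blue, faceted by time;
#' source positions (advected to each panel time when `flow` is supplied) are
#' overlaid as open circles.
#'
#' @param trackers Trajectory tibble from [evolve_trackers()].
#' @param times Times to display (nearest recorded tick is used).
#' @param sources Optional source table to overlay.
#' @param flow Optional [flow_spec()] used to advect the overlaid sources.
#' @return A ggplot.
#' @export
plot_trackers <- function(trackers, times = NULL, sources = NULL, flow = NULL) {
  tt <- sort(unique(trackers$t))
  times <- if (is.null(times)) tt else purrr::map_dbl(times, ~tt[which.min(abs(tt - .x))])
  df <- dplyr::filter(trackers, .data$t %in% times)
  p <- ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$polarity)) +
    geom_point(size = 0.6, alpha = 0.8) +
    scale_colour_manual(values = c(high = "red3", low = "blue3")) +
    facet_wrap(~t, labeller = label_both) +
    labs(x = "x", y = "y") +
    theme_minimal()
  if (!is.null(sources)) {
    src <- purrr::map(times, function(tm) {
      s <- if (is.null(flow)) sources else advect_sources(sources, flow, tm)
      mutate(s, t = tm)
    })
    src <- bind_rows(src)
    p <- p + geom_point(data = src,
                        aes(x = .data$x0, y = .data$y0),
                        inherit.aes = FALSE, shape = 1, size = 2)
  }
  p
}

#' @export
autoplot.peak_series <- function(object, ...) plot_peak_series(object, ...)

#' @export
autoplot.regime_split <- function(object, ...) {
  df <- object$series
  df$fitted <- exp(predict(object$fit))
  ggplot(df, aes(x = .data$t, y = .data$value)) +
    geom_point(size = 0.8) +
    geom_line(aes(y = .data$fitted), colour = "red3") +
    geom_vline(xintercept = object$t_split, linetype = "dashed") +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = "t", y = "peak concentration") +
    theme_minimal()
}

#' @export
autoplot.n_scaling <- function(object, ...) {
  ggplot(object$table, aes(x = .data$n, y = .data$mean_conc)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "red3", linewidth = 0.5) +
    labs(x = "number of CTCs", y = "spatial mean concentration") +
    theme_minimal()
}

#' @export
autoplot.ctc_run <- function(object, time = NULL, ...) {
  tt <- unique(object$fields$t)
  tm <- if (is.null(time)) max(tt) else tt[which.min(abs(tt - time))]
  f <- dplyr::filter(object$fields, .data$t == tm)
  if (is_3d(object$flow)) {
    plot_field_slice(f[f$z == min(f$z), ]) +
      labs(title = sprintf("wall slice, t = %g", tm))
  } else {
    plot_field_slice(f) + labs(title = sprintf("t = %g", tm))
  }
}

#' Rebuild a published-figure layout from a run archive
#'
#' Renders the qualitative panel layouts of the published figures from an
#' archive directory: `"fields"` (slice heatmaps over time), `"profiles"`
#' (1D slice profiles; 2D archives), `"surfaces"` (filled-contour rendering
#' of the fields), `"peaks"` (peak-vs-time with the two-regime breakpoint)
#' and `"trackers"` (tracker scatter frames). Errors if the archive lacks the
#' tables the figure needs, naming what to re-run.
#'
#' @param archive Archive directory or the list from [read_run_archive()].
#' @param figure One of `"fields"`, `"profiles"`, `"surfaces"`, `"peaks"`,
#'   `"trackers"`.
#' @param out Optional PNG path; when given the plot is saved and the path
#'   returned.
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return The ggplot (or `out`, invisibly, when saving).
#' @export
cli_figures <- function(archive, figure = c("fields", "profiles", "surfaces",
                                            "peaks", "trackers"),
                        out = NULL, width = 9, height = 7, dpi = 150) {
  figure <- match.arg(figure)
  arc <- if (is.character(archive)) read_run_archive(archive) else archive
  three_d <- identical(arc$meta$config$mode, "constant_flow_3d")
  p <- switch(
    figure,
    fields = {
      f <- arc$fields
      if (is.null(f)) stopf("archive has no fields table; re-run the config")
      p0 <- ggplot(f, aes(x = .data$x, y = .data$y, fill = .data$conc)) +
        geom_raster() +
        scale_fill_viridis_c(option = "inferno", trans = "sqrt") +
        theme_minimal()
      if (three_d) p0 + facet_grid(z ~ t, labeller = label_both)
      else p0 + facet_wrap(~t, labeller = label_both)
    },
    profiles = {
      if (is.null(arc$profiles)) {
        stopf("archive has no profiles table (3D archive?); re-run a 2D config")
      }
      plot_profiles(arc$profiles) + facet_wrap(~t, labeller = label_both,
                                               scales = "free_y")
    },
    surfaces = {
      f <- arc$fields
      if (is.null(f)) stopf("archive has no fields table; re-run the config")
      p0 <- ggplot(f, aes(x = .data$x, y = .data$y, z = .data$conc)) +
        geom_contour_filled(bins = 12) +
        guides(fill = "none") +
        theme_minimal()
      if (three_d) p0 + facet_grid(z ~ t, labeller = label_both)
      else p0 + facet_wrap(~t, labeller = label_both)
    },
    peaks = {
      if (is.null(arc$peaks)) stopf("archive has no peaks table; re-run the config")
      wall <- min(arc$peaks$offset)
      sp <- tryCatch(
        regime_split(dplyr::filter(arc$peaks, .data$offset == wall)),
        error = function(e) NULL
      )
      plot_peak_series(arc$peaks, split = sp)
    },
    trackers = {
      if (is.null(arc$trackers)) {
        stopf("archive has no trackers table; re-run with a trackers block in the config")
      }
      plot_trackers(arc$trackers,
                    times = unique(round(seq(min(arc$trackers$t),
                                             max(arc$trackers$t),
                                             length.out = 5))))
    }
  )
  if (!is.null(out)) {
    ggsave(out, p, width = width, height = height, dpi = dpi)
    return(invisible(out))
  }
  p
}
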