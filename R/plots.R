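# ggplot2 displays for the package's result types.

#' @importFrom ggplot2 ggplot aes geom_raster geom_step geom_jitter geom_point
#'   geom_errorbar scale_fill_viridis_c coord_fixed labs theme_minimal
#'   stat_summary position_jitter
NULL

#' Plot a redox ratio map
#'
#' @param object A 2-D [compute_ratio_map()] result.
#' @param ... Unused.
#' @return A ggplot: ratio as a filled raster, invalid pixels blank.
#' @export
autoplot.ratio_map <- function(object, ...) {
  if (length(dim(object$ratio)) != 2L) {
    abort("autoplot.ratio_map expects a 2-D map (one focal plane).")
  }
  df <- tidyr::expand_grid(
    y = seq_len(nrow(object$ratio)) - 1L,
    x = seq_len(ncol(object$ratio)) - 1L
  )
  df$ratio <- as.vector(t(object$ratio))  # row-major to match (y, x) grid
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$ratio)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "black", name = "488/405") +
    coord_fixed() +
    labs(x = "x (px)", y = "y (px)", title = "HyPer redox ratio") +
    theme_minimal()
}

#' Plot survival curves
#'
#' @param object A [survival_summary()].
#' @param ... Unused.
#' @return A ggplot of the fraction surviving by day, one step per group.
#' @export
autoplot.survival_summary <- function(object, ...) {
  ggplot(object$curve,
         aes(x = .data$day, y = .data$surviving, colour = .data$group)) +
    geom_step() +
    labs(x = "day", y = "fraction surviving", colour = NULL) +
    theme_minimal()
}

#' Dot plot of per-worm outcomes by group
#'
#' The standard pooled-individual-values display: one jittered point per
#' animal, group mean +/- s.e.m. overlaid.
#'
#' @param table Cohort tibble (`group`, `value`; `excluded` honored).
#' @param value_lab y-axis label.
#' @return A ggplot.
#' @export
plot_cohort <- function(table, value_lab = "value") {
  table <- check_cohort(table)
  ggplot(table, aes(x = .data$group, y = .data$value)) +
    geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    stat_summary(fun = mean, geom = "point", size = 2, colour = "red") +
    stat_summary(
      fun.data = function(v) {
        s <- if (length(v) >= 2) sd(v) / sqrt(length(v)) else 0
        data.frame(y = mean(v), ymin = mean(v) - s, ymax = mean(v) + s)
      },
      geom = "errorbar", width = 0.2, colour = "red"
    ) +
    labs(x = NULL, y = value_lab) +
    theme_minimal()
}

#' Display an RGB array (e.g. an INR rendering)
#'
#' @param rgb `(y, x, 3)` array in `[0, 1]`.
#' @return A ggplot drawing the image with fixed aspect.
#' @export
plot_rgb <- function(rgb) {
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L)) {
    abort("`rgb` must be a (y, x, 3) array.")
  }
  ny <- dim(rgb)[1]; nx <- dim(rgb)[2]
  df <- tidyr::expand_grid(y = seq_len(ny) - 1L, x = seq_len(nx) - 1L)
  df$col <- grDevices::rgb(
    as.vector(t(rgb[, , 1])), as.vector(t(rgb[, , 2])), as.vector(t(rgb[, , 3]))
  )
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_raster(fill = df$col) +
    coord_fixed() +
    ggplot2::scale_y_reverse() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
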