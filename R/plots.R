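#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

slice_df <- function(arr, k, h) {
  d <- dim(arr)
  tibble::tibble(
    x = rep(axis_centers(d[1], h * 1000), d[2]),
    y = rep(axis_centers(d[2], h * 1000), each = d[1]),
    value = as.vector(arr[, , k])
  )
}

#' Plot a mid-slice of a volume
#'
#' @param object An [image3d].
#' @param k Slice index (defaults to the mid-slice).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.image3d <- function(object, k = NULL, ...) {
  d <- dim(object$voxels)
  if (is.null(k)) k <- max(1L, d[3] %/% 2L)
  df <- slice_df(object$voxels, k, object$voxel_size / 1000)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "mgHA/cm³") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("slice k = %d", k)) +
    ggplot2::theme_minimal()
}

#' Plot a mid-slice of a phase map
#'
#' @param object A [phasemap].
#' @param k Slice index (defaults to the mid-slice).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phasemap <- function(object, k = NULL, ...) {
  d <- dim(object$labels)
  if (is.null(k)) k <- max(1L, d[3] %/% 2L)
  lv <- phase_levels()
  df <- slice_df(object$labels, k, object$voxel_size / 1000)
  df$phase <- factor(names(lv)[match(df$value, lv)], levels = names(lv))
  pal <- c(void = "grey95", bone = "#d8b365", bag = "#5ab4ac",
           interface = "#d73027", morsel = "#fee08b")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("slice k = %d", k)) +
    ggplot2::theme_minimal()
}

#' Plot the von Mises stress of a solved model (mid-slice)
#'
#' @param object An `feresult`.
#' @param k Slice index into the voxel grid (defaults to the mid-slice of the
#'   meshed region).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.feresult <- function(object, k = NULL, ...) {
  idx <- object$model$voxel_index
  if (is.null(k)) k <- round(stats::median(idx[, 3]))
  sel <- idx[, 3] == k
  h <- object$model$h
  df <- tibble::tibble(
    x = (idx[sel, 1] - 0.5) * h, y = (idx[sel, 2] - 0.5) * h,
    von_mises = object$fields[sel, "von_mises"]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$von_mises)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "von Mises (MPa)", option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("slice k = %d", k)) +
    ggplot2::theme_minimal()
}

#' Maintained stiffness across window presets
#'
#' @param reductions The `reductions` tibble of a `defect-geometry` study.
#' @param outcome Outcome prefix to plot (default `"bending_stiffness"`).
#' @return A ggplot of maintained fractions (%) by condition.
#' @export
plot_maintained <- function(reductions, outcome = "bending_stiffness") {
  col <- paste0(outcome, "_maintained")
  stopifnot(col %in% names(reductions))
  df <- dplyr::mutate(reductions,
                      condition = factor(.data$condition,
                                         levels = unique(.data$condition)))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, 100 * .data[[col]])) +
    ggplot2::geom_col(fill = "#5ab4ac") +
    ggplot2::labs(x = NULL, y = "maintained (%)") +
    ggplot2::theme_minimal()
}

#' Per-phase load shares at the end planes
#'
#' @param shares The `load_shares` tibble of a `graft-load-sharing` study.
#' @return A ggplot of shares (%) by phase, facetted by plane and condition.
#' @export
plot_load_sharing <- function(shares) {
  ggplot2::ggplot(shares,
                  ggplot2::aes(.data$phase, 100 * .data$share,
                               fill = .data$phase)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(condition ~ plane) +
    ggplot2::labs(x = NULL, y = "share of axial load (%)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
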