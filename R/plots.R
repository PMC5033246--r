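# ggplot2 visualisation helpers.

#' Extract an axial/coronal/sagittal slice as a tidy data frame
#'
#' @param img image-like object (`mm_image`, `mm_mask`, `mm_labels`).
#' @param plane `"axial"` (z), `"coronal"` (y) or `"sagittal"` (x).
#' @param index 1-based slice index; default the middle slice.
#' @return tibble with columns `h`, `v` (world mm) and `value`.
#' @export
slice_data <- function(img, plane = c("axial", "coronal", "sagittal"),
                       index = NULL) {
  plane <- match.arg(plane)
  ax <- switch(plane, sagittal = 1L, coronal = 2L, axial = 3L)
  dm <- dim(img$data)
  if (is.null(index)) index <- ceiling(dm[ax] / 2)
  sl <- switch(ax, img$data[index, , ], img$data[, index, ],
               img$data[, , index])
  other <- setdiff(1:3, ax)
  vs <- voxel_size(img)
  h <- (seq_len(dm[other[1]]) - 1) * vs[other[1]]
  v <- (seq_len(dm[other[2]]) - 1) * vs[other[2]]
  hh <- rep(h, times = length(v))
  vv <- rep(v, each = length(h))
  tibble::tibble(h = hh, v = vv, value = as.vector(sl))
}

#' Plot a slice of a volume
#'
#' @inheritParams slice_data
#' @param palette viridis option for continuous data.
#' @return a ggplot.
#' @export
plot_slice <- function(img, plane = "axial", index = NULL,
                       palette = "magma") {
  df <- slice_data(img, plane, index)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = palette) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "mm", y = "mm", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a statistical map slice over the analysis mask
#'
#' Significant voxels are coloured by signed t (blue: mutant larger;
#' red: mutant smaller, following the usual morphometry convention).
#'
#' @param statmap `mm_statmap`.
#' @param background optional background image on the same grid.
#' @param plane,index slice selection as in [slice_data()].
#' @return a ggplot.
#' @export
plot_statmap <- function(statmap, background = NULL, plane = "axial",
                         index = NULL) {
  timg <- image_volume(ifelse(statmap$fdr_mask$data, statmap$t_values, NA),
                       statmap$affine)
  df <- slice_data(timg, plane, index)
  p <- ggplot2::ggplot()
  if (!is.null(background)) {
    bg <- slice_data(background, plane, index)
    p <- p + ggplot2::geom_raster(
      data = bg, ggplot2::aes(x = .data$h, y = .data$v, alpha = .data$value),
      fill = "grey30") +
      ggplot2::scale_alpha_continuous(range = c(0, 1), guide = "none")
  }
  p + ggplot2::geom_raster(data = df[!is.na(df$value), ],
                           ggplot2::aes(x = .data$h, y = .data$v,
                                        fill = .data$value)) +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white",
                                  high = "blue", midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "mm", y = "mm", fill = "t") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.mm_statmap <- function(object, ...) plot_statmap(object, ...)

#' @export
autoplot.mm_image <- function(object, ...) plot_slice(object, ...)

#' Plot group volume distributions
#'
#' @param table volume table with a `genotype` column.
#' @param measure column to plot.
#' @return a ggplot.
#' @export
plot_volumes <- function(table, measure = "TIV") {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$genotype,
                                      y = .data[[measure]],
                                      fill = .data$genotype)) +
    ggplot2::geom_violin(alpha = 0.4) +
    ggplot2::geom_jitter(width = 0.08, size = 1) +
    ggplot2::labs(y = paste(measure, "(mm³)")) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
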