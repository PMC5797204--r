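#' Plot a lung shape as stacked slice contours
#'
#' Coronal (constant-z) slice polygons in the (x, y) plane, colored by z.
#'
#' @param object a `lung_shape`.
#' @param slices which slice numbers to draw (default every third).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lung_shape <- function(object, slices = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (is.null(slices)) slices <- unique(df$slice)[c(TRUE, FALSE, FALSE)]
  df <- dplyr::filter(df, .data$slice %in% slices)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$slice,
                                   color = .data$z)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", color = "z (mm)",
                  title = paste(attr(object, "side"), "lung shape")) +
    ggplot2::theme_minimal()
}

#' Scree plot of a shape model's eigenmodes
#'
#' @param object an `asm_model`.
#' @param ... unused.
#' @return a ggplot of per-mode and cumulative variance proportions.
#' @export
autoplot.asm_model <- function(object, ...) {
  total <- sum(object$all_eigenvalues)
  df <- tibble::tibble(
    mode = seq_along(object$all_eigenvalues),
    prop = object$all_eigenvalues / total,
    retained = seq_along(object$all_eigenvalues) <= object$t
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$mode, .data$prop,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(ggplot2::aes(y = cumsum(.data$prop)),
                       inherit.aes = FALSE,
                       data = df, mapping = ggplot2::aes(.data$mode,
                                                         cumsum(.data$prop))) +
    ggplot2::labs(x = "eigenmode", y = "variance proportion",
                  title = sprintf("%s lung model: %d retained modes",
                                  object$side, object$t)) +
    ggplot2::theme_minimal()
}

#' Overlay a fitted segmentation on the sum image
#'
#' One coronal slice of the sum image with the fitted left/right contours.
#'
#' @param object an `asm_segmentation`.
#' @param z_index grid slice to show (default the middle slice).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.asm_segmentation <- function(object, z_index = NULL, ...) {
  vol <- object$sum_image
  d <- dim(vol$voxels)
  if (is.null(z_index)) z_index <- round(d[3] / 2)
  img <- tidyr::expand_grid(xi = seq_len(d[1]), yi = seq_len(d[2]))
  img$value <- as.numeric(vol$voxels[, , z_index])
  img$x <- axis_mm(vol, 1)[img$xi]
  img$y <- axis_mm(vol, 2)[img$yi]
  z_mm <- axis_mm(vol, 3)[z_index]
  contours <- purrr::map_dfr(c("left", "right"), function(side) {
    f <- object[[side]]
    if (!inherits(f, "asm_fit")) return(tibble::tibble())
    sl <- split(f$shape, f$shape$slice)
    zc <- vapply(sl, function(s) s$z[1], numeric(1))
    s <- sl[[which.min(abs(zc - z_mm))]]
    tibble::tibble(side = side, x = c(s$x, s$x[1]), y = c(s$y, s$y[1]))
  })
  ggplot2::ggplot(img, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_path(data = contours,
                       ggplot2::aes(group = .data$side, color = .data$side),
                       linewidth = 0.8) +
    ggplot2::scale_color_manual(values = c(left = "green3", right = "red")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "sum",
                  title = sprintf("fitted contours at z = %.0f mm", z_mm)) +
    ggplot2::theme_minimal()
}

#' Benchmark overlap scores per side
#'
#' @param object an `asm_benchmark`.
#' @param ... unused.
#' @return a ggplot: per-case Dice/sensitivity/precision by side.
#' @export
autoplot.asm_benchmark <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_case,
                            c("dice", "sensitivity", "precision"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$side, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6,
                         ggplot2::aes(color = .data$n_defects > 0)) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(y = "score", color = "defects",
                  title = "synthetic benchmark overlap scores") +
    ggplot2::theme_minimal()
}
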