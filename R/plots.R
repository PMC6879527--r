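# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.pbl_cooccurrence <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tooth_a, y = .data$tooth_b,
                                   fill = .data$cooccurrence)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~jaw) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "tooth (within-jaw slot)", y = "tooth (within-jaw slot)",
                  fill = "joint\nfrequency",
                  title = "Per-jaw co-occurrence of periodontal bone loss")
}

raster_df <- function(img) {
  tibble::tibble(row = rep(seq_len(nrow(img)), times = ncol(img)),
                 col = rep(seq_len(ncol(img)), each = nrow(img)),
                 value = as.vector(img))
}

#' @export
autoplot.synthetic_case <- function(object, ...) {
  df <- raster_df(object$image)
  centers <- tibble::as_tibble(object$tooth_centers, .name_repair = ~c("row", "col"))
  centers$diseased <- factor(object$true_tooth_labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = centers,
                        ggplot2::aes(colour = .data$diseased), size = 1) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_colour_manual(values = c(`0` = "steelblue", `1` = "red")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Synthetic panoramic case", colour = "PBL")
}

#' @export
autoplot.roi_crop <- function(object, ...) {
  ggplot2::ggplot(raster_df(object$image), ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Extracted teeth-region crop (z-scored)",
                  fill = "intensity")
}

#' Overlay a Grad-CAM heatmap on its input image
#'
#' @param image Grayscale matrix.
#' @param cam Matrix in `[0, 1]` from [gradcam()], aligned to `image`.
#' @param threshold Hide CAM values below this level (default 0.2).
#' @return A ggplot object.
#' @export
plot_gradcam <- function(image, cam, threshold = 0.2) {
  check_same_shape(image, cam)
  df <- raster_df(image)
  df$cam <- as.vector(cam)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_tile(data = df[df$cam >= threshold, ],
                       ggplot2::aes(alpha = .data$cam), fill = "red") +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_alpha(range = c(0, 0.6)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Grad-CAM", alpha = "activation")
}

#' @importFrom ggplot2 .data
NULL
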