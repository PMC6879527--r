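#' Data augmentation parameters
#'
#' Training-time augmentation for the lesion segmenter and tooth
#' classifiers: random rotation up to `max_rotation_deg` degrees, horizontal
#' and vertical shift up to `max_shift_frac` of the image size, and
#' photometric shifts of brightness, sharpness and contrast up to
#' `max_photometric_frac`. Geometric transforms are applied identically to
#' image and mask (nearest-neighbour for the mask, zero fill); photometric
#' transforms touch the image only. All draws are uniform within the bounds.
#'
#' @param max_rotation_deg Maximum absolute rotation in degrees (default 10).
#' @param max_shift_frac Maximum shift as a fraction of height/width
#'   (default 0.10).
#' @param max_photometric_frac Maximum brightness/sharpness/contrast shift
#'   (default 0.15). Sharpness is an unsharp-mask blend of the same strength.
#' @return An `augment_params` list.
#' @export
augment_params <- function(max_rotation_deg = 10, max_shift_frac = 0.10,
                           max_photometric_frac = 0.15) {
  stopifnot(max_rotation_deg >= 0, max_shift_frac >= 0,
            max_photometric_frac >= 0)
  structure(list(max_rotation_deg = max_rotation_deg,
                 max_shift_frac = max_shift_frac,
                 max_photometric_frac = max_photometric_frac),
            class = "augment_params")
}

#' Apply one random augmentation draw to an image/mask pair
#'
#' @param image Grayscale matrix.
#' @param mask Aligned binary matrix (or `NULL` for image-only use).
#' @param params An [augment_params()] object.
#' @return List with `image`, `mask`, and the drawn `transform`
#'   (`angle`, `shift`, `brightness`, `sharpness`, `contrast`).
#' @export
augment <- function(image, mask = NULL, params = augment_params()) {
  if (!is.null(mask)) check_same_shape(image, mask)
  H <- nrow(image); W <- ncol(image)
  angle <- stats::runif(1, -params$max_rotation_deg, params$max_rotation_deg)
  shift <- c(stats::runif(1, -params$max_shift_frac, params$max_shift_frac) * H,
             stats::runif(1, -params$max_shift_frac, params$max_shift_frac) * W)
  ph <- stats::runif(3, -params$max_photometric_frac,
                     params$max_photometric_frac)
  if (angle != 0 || any(shift != 0)) {
    image <- warp_affine(image, angle, shift)
    if (!is.null(mask))
      mask <- warp_affine(mask, angle, shift, nearest = TRUE)
  }
  # brightness: additive shift of the dynamic range
  if (ph[1] != 0) image <- image + ph[1] * diff(range(image))
  # sharpness: unsharp-mask blend image + s * (image - blur(image))
  if (ph[2] != 0) {
    blurred <- EBImage::gblur(image, sigma = 1)
    image <- image + ph[2] * (image - blurred)
  }
  # contrast: scale around the mean
  if (ph[3] != 0) image <- mean(image) + (1 + ph[3]) * (image - mean(image))
  list(image = image, mask = mask,
       transform = list(angle = angle, shift = shift, brightness = ph[1],
                        sharpness = ph[2], contrast = ph[3]))
}
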