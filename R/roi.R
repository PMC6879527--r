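#' Fill enclosed holes in a binary mask
#'
#' Any background region not connected (4-connectivity) to the image border
#' is turned into foreground. Used before taking the convex hull of a
#' predicted teeth-region mask.
#'
#' @param mask Binary matrix.
#' @return Binary matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- (mask > 0)
  H <- nrow(m); W <- ncol(m)
  bg <- !m
  reach <- matrix(FALSE, H, W)
  reach[1, ] <- bg[1, ]; reach[H, ] <- bg[H, ]
  reach[, 1] <- bg[, 1]; reach[, W] <- bg[, W]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-H, ]
    grown[-H, ] <- grown[-H, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -W]
    grown[, -W] <- grown[, -W] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  (m | (bg & !reach)) + 0L
}

#' Rasterised convex hull of a binary mask
#'
#' Returns the mask of all pixels whose centres lie inside or on the convex
#' hull of the foreground pixel centres. Degenerate hulls (fewer than three
#' non-collinear foreground points) return the input unchanged.
#'
#' @param mask Binary matrix.
#' @return Binary matrix containing the input foreground.
#' @export
convex_hull_mask <- function(mask) {
  pts <- which(mask > 0, arr.ind = TRUE)
  if (nrow(pts) == 0L) return((mask > 0) + 0L)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  if (length(hull) < 3L) return((mask > 0) + 0L)
  vy <- pts[hull, 1]; vx <- pts[hull, 2]   # row, col of hull vertices
  # orient counter-clockwise in (col, row) coordinates
  area2 <- sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy)
  if (area2 == 0) return((mask > 0) + 0L)
  if (area2 < 0) { vx <- rev(vx); vy <- rev(vy) }
  H <- nrow(mask); W <- ncol(mask)
  py <- rep(seq_len(H), times = W)
  px <- rep(seq_len(W), each = H)
  inside <- rep(TRUE, H * W)
  n <- length(vx)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    cross <- (vx[k2] - vx[k]) * (py - vy[k]) - (vy[k2] - vy[k]) * (px - vx[k])
    inside <- inside & (cross >= -1e-9)
  }
  matrix(inside + 0L, H, W)
}

#' Post-process a predicted teeth-region mask
#'
#' Fills enclosed holes and replaces the result by its convex hull. The
#' output always contains the input foreground, and the operation is
#' idempotent. An all-zero mask is returned unchanged with a warning.
#'
#' @param raw_mask Binary matrix (e.g. a thresholded segmenter output).
#' @return Binary matrix.
#' @export
postprocess_mask <- function(raw_mask) {
  if (length(raw_mask) == 0L) stop("mask must be a nonempty matrix")
  if (!any(raw_mask > 0)) {
    warning("all-zero mask: returning it unchanged")
    return((raw_mask > 0) + 0L)
  }
  convex_hull_mask(fill_holes(raw_mask))
}

#' Crop, resize and z-score the teeth region of a radiograph
#'
#' Crops the tight axis-aligned bounding box of the processed mask, resizes
#' the crop to `out_shape` (bilinear for the image, nearest-neighbour for
#' the mask), zeroes every pixel outside the resized mask, and z-scores the
#' in-mask intensities to mean 0 / sd 1. The z-score statistics are computed
#' over in-mask pixels only, so the zeroed background does not bias them.
#' A constant in-mask intensity (zero variance) yields an all-zero crop.
#'
#' @param image Grayscale matrix.
#' @param processed_mask Binary matrix of the same shape, typically from
#'   [postprocess_mask()]; must be nonempty.
#' @param out_shape Output `(height, width)` (default `c(512, 1024)`).
#' @return An object of class `roi_crop`: list with `image` (z-scored
#'   `out_shape` matrix), `mask` (aligned binary matrix) and `bbox`
#'   (`c(row0, col0, row1, col1)`, zero-based half-open source coordinates).
#' @export
extract_roi <- function(image, processed_mask, out_shape = c(512L, 1024L)) {
  if (!identical(dim(image), dim(processed_mask)))
    stop("shape mismatch between image and mask")
  fg <- which(processed_mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("empty mask: nothing to crop")
  r0 <- min(fg[, 1]); r1 <- max(fg[, 1])
  c0 <- min(fg[, 2]); c1 <- max(fg[, 2])
  img_c <- image[r0:r1, c0:c1, drop = FALSE]
  msk_c <- processed_mask[r0:r1, c0:c1, drop = FALSE]
  img_r <- resize_image(img_c, out_shape)
  msk_r <- resize_image((msk_c > 0) + 0, out_shape, nearest = TRUE)
  inm <- msk_r > 0
  img_r[!inm] <- 0
  mu <- mean(img_r[inm])
  sdv <- stats::sd(img_r[inm])
  if (!is.finite(sdv) || sdv < 1e-8) {
    img_r[] <- 0
  } else {
    img_r[inm] <- (img_r[inm] - mu) / sdv
  }
  structure(list(image = img_r, mask = (msk_r > 0) + 0L,
                 bbox = c(r0 - 1L, c0 - 1L, r1, c1)),
            class = "roi_crop")
}

#' @export
print.roi_crop <- function(x, ...) {
  cat("ROI crop", paste(dim(x$image), collapse = "x"),
      "| source bbox [", paste(x$bbox, collapse = ", "), ") |",
      sprintf("%.1f%% in-mask\n", 100 * mean(x$mask)))
  invisible(x)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks overlap perfectly by
#' convention (dice 1).
#'
#' @param a,b Binary matrices of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_same_shape(a, b)
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Carry a mask or a point through an ROI crop's transform
#'
#' Lesion masks are annotated on the source radiograph; training the lesion
#' segmenter on ROI crops requires transforming them jointly with the image:
#' the same bounding-box crop followed by nearest-neighbour resize to the
#' crop shape. `roi_warp_mask()` does that; `roi_map_point()` maps a single
#' `(row, col)` source location into crop coordinates (for localisation
#' checks and overlays).
#'
#' @param mask Binary matrix in source-image coordinates.
#' @param crop A `roi_crop` from [extract_roi()].
#' @return `roi_warp_mask()`: binary matrix aligned to `crop$image`.
#' @export
roi_warp_mask <- function(mask, crop) {
  stopifnot(inherits(crop, "roi_crop"))
  b <- crop$bbox
  sub <- mask[(b[1] + 1L):b[3], (b[2] + 1L):b[4], drop = FALSE]
  resize_image((sub > 0) + 0, dim(crop$image), nearest = TRUE)
}

#' @rdname roi_warp_mask
#' @param pt `(row, col)` in source-image coordinates (1-based).
#' @return `roi_map_point()`: `(row, col)` in crop coordinates.
#' @export
roi_map_point <- function(pt, crop) {
  stopifnot(inherits(crop, "roi_crop"))
  b <- crop$bbox
  hc <- b[3] - b[1]; wc <- b[4] - b[2]
  out <- dim(crop$image)
  c((pt[1] - b[1] - 0.5) * out[1] / hc + 0.5,
    (pt[2] - b[2] - 0.5) * out[2] / wc + 0.5)
}
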