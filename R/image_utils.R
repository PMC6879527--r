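# Image helpers. Matrices are H x W (row = image row), intensities in [0, 1]
# for images and {0, 1} for masks. One bilinear/nearest sampler backs both
# resizing and the affine warps of the augmenter so that geometric
# conventions (pixel-centre alignment, zero fill outside the frame) are
# identical everywhere.

# sample img at fractional (row, col) positions; outside the frame -> fill
sample_image <- function(img, rows, cols, nearest = FALSE, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  if (nearest) {
    ri <- round(rows) + 1L
    ci <- round(cols) + 1L
    ok <- ri >= 1L & ri <= H & ci >= 1L & ci <= W
    out <- rep(fill, length(rows))
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  px <- function(r, c) {
    ok <- r >= 0 & r < H & c >= 0 & c < W
    v <- rep(fill, length(r))
    v[ok] <- img[cbind(r[ok] + 1L, c[ok] + 1L)]
    v
  }
  (1 - fr) * (1 - fc) * px(r0, c0) + (1 - fr) * fc * px(r0, c0 + 1) +
    fr * (1 - fc) * px(r0 + 1, c0) + fr * fc * px(r0 + 1, c0 + 1)
}

# resize to shape = c(h, w); bilinear for images, nearest for masks;
# sampling coordinates are clamped to the frame (edge replication), so a
# constant image stays exactly constant under resizing
resize_image <- function(img, shape, nearest = FALSE) {
  H2 <- shape[1]; W2 <- shape[2]
  H <- nrow(img); W <- ncol(img)
  rows <- pmin(pmax(((seq_len(H2) - 0.5) * H / H2) - 0.5, 0), H - 1)
  cols <- pmin(pmax(((seq_len(W2) - 0.5) * W / W2) - 0.5, 0), W - 1)
  grid_r <- rep(rows, times = W2)
  grid_c <- rep(cols, each = H2)
  out <- sample_image(img, grid_r, grid_c, nearest = nearest)
  matrix(out, H2, W2)
}

# rotate by angle_deg about the image centre then shift by (dr, dc) pixels;
# output pixels are pulled from the inverse-mapped source location
warp_affine <- function(img, angle_deg = 0, shift = c(0, 0), nearest = FALSE) {
  H <- nrow(img); W <- ncol(img)
  th <- angle_deg * pi / 180
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  out_r <- rep(seq_len(H) - 1, times = W) - cr - shift[1]
  out_c <- rep(seq_len(W) - 1, each = H) - cc - shift[2]
  src_r <- cos(th) * out_r - sin(th) * out_c + cr
  src_c <- sin(th) * out_r + cos(th) * out_c + cc
  matrix(sample_image(img, src_r, src_c, nearest = nearest), H, W)
}

# forward map of a single (row, col) point under the same transform
affine_map_point <- function(pt, angle_deg, shift, dims) {
  th <- angle_deg * pi / 180
  cr <- (dims[1] - 1) / 2; cc <- (dims[2] - 1) / 2
  r <- pt[1] - cr; c <- pt[2] - cc
  c(cos(th) * r + sin(th) * c + cr + shift[1],
    -sin(th) * r + cos(th) * c + cc + shift[2])
}

#' Read and write grayscale PNG images
#'
#' Thin wrappers over the `png` package: images are H x W matrices with
#' intensities in `[0, 1]`; multi-channel PNGs are collapsed to their first
#' channel on read.
#'
#' @param path PNG file path.
#' @return `read_gray_png()`: an H x W numeric matrix.
#' @export
read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' @rdname read_gray_png
#' @param img Numeric matrix; values are clipped to `[0, 1]` on write.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
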