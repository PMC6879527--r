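# Independent oracle for the hole-fill + convex-hull post-processing:
# EBImage's fillHull plus point-in-polygon rasterisation of chull().
postprocess_oracle <- function(mask) {
  filled <- EBImage::fillHull(mask > 0) > 0
  pts <- which(filled, arr.ind = TRUE)
  if (nrow(pts) < 3L) return(filled + 0L)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  if (length(hull) < 3L) return(filled + 0L)
  H <- nrow(mask); W <- ncol(mask)
  py <- rep(seq_len(H), times = W)
  px <- rep(seq_len(W), each = H)
  inside <- pracma::inpolygon(px, py, pts[hull, 2], pts[hull, 1],
                              boundary = TRUE)
  matrix(inside + 0L, H, W)
}

random_blob <- function(h = 40, w = 40, n_holes = 3) {
  m <- matrix(0L, h, w)
  ctr <- c(sample(12:(h - 12), 1), sample(12:(w - 12), 1))
  rr <- rep(seq_len(h), times = w); cc <- rep(seq_len(w), each = h)
  rad <- runif(1, 6, 10)
  m[(rr - ctr[1])^2 + 0.7 * (cc - ctr[2])^2 <= rad^2] <- 1L
  for (k in seq_len(n_holes)) {
    hc <- ctr + sample(-3:3, 2, replace = TRUE)
    m[(rr - hc[1])^2 + (cc - hc[2])^2 <= sample(1:2, 1)^2] <- 0L
  }
  m
}

test_that("hole filling removes enclosed background only", {
  ring <- matrix(0L, 15, 15)
  rr <- rep(1:15, times = 15); cc <- rep(1:15, each = 15)
  d2 <- (rr - 8)^2 + (cc - 8)^2
  ring[d2 <= 36 & d2 >= 16] <- 1L
  filled <- fill_holes(ring)
  expect_true(all(filled[d2 <= 36] == 1L))
  expect_true(all(filled[d2 > 36] == 0L))
})

test_that("post-processing matches the flood-fill + hull oracle on random blobs", {
  set.seed(9)
  for (rep in 1:12) {
    m <- random_blob()
    got <- postprocess_mask(m)
    want <- postprocess_oracle(m)
    expect_identical(got, want)
    # output contains the input foreground and is idempotent
    expect_true(all(got[m == 1L] == 1L))
    expect_identical(postprocess_mask(got), got)
  }
  # a ring becomes a solid convex region
  ring <- matrix(0L, 15, 15)
  rr <- rep(1:15, times = 15); cc <- rep(1:15, each = 15)
  d2 <- (rr - 8)^2 + (cc - 8)^2
  ring[d2 >= 16 & d2 <= 36] <- 1L
  out <- postprocess_mask(ring)
  expect_identical(out, postprocess_oracle(ring))
  expect_true(all(out[d2 <= 16] == 1L))
  # an already convex solid mask is unchanged
  solid <- matrix(0L, 10, 10); solid[3:7, 2:8] <- 1L
  expect_identical(postprocess_mask(solid), solid)
  expect_warning(postprocess_mask(matrix(0L, 4, 4)), "all-zero")
})

test_that("ROI extraction crops the scanned bounding box and z-scores in-mask", {
  img <- matrix(runif(32 * 48), 32, 48)
  # centred rectangle: bbox by brute-force scan over foreground coordinates
  mask <- matrix(0L, 32, 48); mask[9:24, 13:36] <- 1L
  fg <- which(mask == 1L, arr.ind = TRUE)
  crop <- extract_roi(img, mask, out_shape = c(16, 32))
  expect_equal(crop$bbox, c(min(fg[, 1]) - 1L, min(fg[, 2]) - 1L,
                            max(fg[, 1]), max(fg[, 2])))
  inm <- crop$mask > 0
  expect_lt(abs(mean(crop$image[inm])), 1e-6)
  expect_lt(abs(sd(crop$image[inm]) - 1), 1e-6)
  expect_true(all(crop$image[!inm] == 0))
  # full-image mask
  full <- extract_roi(img, matrix(1L, 32, 48), out_shape = c(32, 48))
  expect_equal(full$bbox, c(0L, 0L, 32L, 48L))
  expect_lt(abs(mean(full$image)), 1e-6)
  # constant image inside the mask -> all zeros, no division by zero
  flat <- extract_roi(matrix(0.7, 32, 48), mask, out_shape = c(16, 32))
  expect_true(all(flat$image == 0))
  # error taxonomy: empty mask vs shape mismatch
  expect_error(extract_roi(img, matrix(0L, 32, 48)), "empty mask")
  expect_error(extract_roi(img, matrix(1L, 10, 10)), "mismatch")
})

test_that("dice follows its conventions", {
  a <- matrix(0L, 10, 20); a[2:6, 2:11] <- 1L      # 50 pixels
  expect_equal(dice(a, a), 1)
  b <- matrix(0L, 10, 20); b[7:10, 13:20] <- 1L
  expect_equal(dice(a, b), 0)
  # |a| = 50, |b| = 50, overlap 25 -> 0.5
  c2 <- matrix(0L, 10, 20); c2[2:6, 7:16] <- 1L
  expect_equal(sum(a & c2), 25)
  expect_equal(dice(a, c2), 0.5)
  expect_equal(dice(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(dice(a, matrix(0, 3, 3)), "mismatch")
})

test_that("post-processing can only improve dice against a convex truth", {
  set.seed(10)
  rr <- rep(1:40, times = 40); cc <- rep(1:40, each = 40)
  for (rep in 1:5) {
    truth <- matrix(0L, 40, 40)
    truth[(rr - 20)^2 + (cc - 20)^2 <= 12^2] <- 1L
    noisy <- truth
    holes <- sample(which(truth == 1L), 30)
    noisy[holes] <- 0L
    expect_gte(dice(postprocess_mask(noisy), truth), dice(noisy, truth))
  }
})

test_that("masks and points transform consistently with the crop", {
  img <- matrix(runif(40 * 60), 40, 60)
  mask <- matrix(0L, 40, 60); mask[11:30, 16:45] <- 1L
  crop <- extract_roi(img, mask, out_shape = c(40, 60))
  lesion <- matrix(0L, 40, 60); lesion[18:22, 28:32] <- 1L
  warped <- roi_warp_mask(lesion, crop)
  expect_equal(dim(warped), dim(crop$image))
  ctr_src <- c(20, 30)
  ctr_crop <- roi_map_point(ctr_src, crop)
  fg <- which(warped > 0, arr.ind = TRUE)
  expect_lt(sqrt(sum((colMeans(fg) - ctr_crop)^2)), 2.5)
})
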