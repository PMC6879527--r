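test_that("tooth-label aggregation is thresholded voting (exhaustive oracle)", {
  # single-tooth majority example
  expect_equal(aggregate_tooth_labels(matrix(c(1, 1, 1, 0, 0), ncol = 1),
                                      c_r = 3), 1L)
  expect_equal(aggregate_tooth_labels(matrix(0, 5, 1), c_r = 1), 0L)
  # all 2^5 vote patterns, every threshold
  patterns <- as.matrix(expand.grid(rep(list(0:1), 5)))
  for (c_r in 1:5) {
    got <- aggregate_tooth_labels(t(patterns), c_r = c_r)
    want <- as.integer(rowSums(patterns) >= c_r)   # brute-force rule
    expect_equal(got, want, info = paste("c_r =", c_r))
  }
})

test_that("adding a positive vote never flips an aggregated 1 to 0", {
  set.seed(42)
  for (rep in 1:20) {
    votes <- matrix(rbinom(5 * 8, 1, 0.4), 5, 8)
    base <- aggregate_tooth_labels(votes, 3)
    i <- sample(which(votes == 0), 1)
    votes2 <- votes; votes2[i] <- 1
    expect_true(all(aggregate_tooth_labels(votes2, 3) >= base))
  }
})

test_that("lesion mask aggregation matches the per-pixel vote oracle", {
  set.seed(7)
  masks <- lapply(1:5, function(l) matrix(rbinom(64, 1, 0.4), 8, 8))
  for (c_s in 1:5) {
    got <- aggregate_lesion_mask(masks, c_s)
    want <- matrix(0L, 8, 8)
    for (i in 1:8) for (j in 1:8) {           # scalar loop oracle
      v <- sum(vapply(masks, function(m) m[i, j], numeric(1)))
      want[i, j] <- as.integer(v >= c_s)
    }
    expect_identical(got, want)
  }
  # union and intersection identities
  expect_identical(aggregate_lesion_mask(masks, 1),
                   (Reduce(`|`, lapply(masks, `>`, 0))) + 0L)
  expect_identical(aggregate_lesion_mask(masks, 5),
                   (Reduce(`&`, lapply(masks, `>`, 0))) + 0L)
  # a pixel set in exactly one mask survives the union, not the intersection
  one <- c(list(matrix(0, 4, 4)), lapply(1:4, function(i) matrix(0, 4, 4)))
  one[[3]][2, 2] <- 1
  expect_equal(aggregate_lesion_mask(one, 1)[2, 2], 1L)
  expect_equal(aggregate_lesion_mask(one, 5)[2, 2], 0L)
  expect_error(aggregate_lesion_mask(c(masks, list(matrix(0, 3, 3))), 1),
               "share one shape")
})

test_that("co-occurrence matrices match pair counting and its invariances", {
  expect_equal(build_cooccurrence(matrix(0, 4, 32))$upper, matrix(0, 16, 16))
  # identical all-ones upper rows -> upper matrix all ones
  lab <- matrix(0, 2, 32); lab[, 1:16] <- 1
  expect_equal(build_cooccurrence(lab)$upper,
               matrix(1, 16, 16), ignore_attr = TRUE)
  set.seed(1)
  labels <- matrix(rbinom(10 * 32, 1, 0.3), 10, 32)
  cc <- build_cooccurrence(labels)
  # double-loop counting oracle, upper jaw
  want <- matrix(0, 16, 16)
  for (j in 1:16) for (k in 1:16)
    want[j, k] <- sum(labels[, j] == 1 & labels[, k] == 1) / 10
  expect_equal(cc$upper, want, ignore_attr = TRUE)
  expect_equal(cc$upper, t(cc$upper))
  expect_true(all(cc$lower >= 0 & cc$lower <= 1))
  expect_equal(diag(cc$lower), colMeans(labels[, 17:32]), ignore_attr = TRUE)
  # duplicating the dataset leaves the frequency matrix unchanged
  cc2 <- build_cooccurrence(rbind(labels, labels))
  expect_equal(cc2$upper, cc$upper)
  expect_error(build_cooccurrence(labels[0, , drop = FALSE]), "at least one")
})

test_that("co-occurrence target is max-normalised with the all-zero convention", {
  C <- diag(16)
  expect_equal(cooccurrence_target(rep(0, 16), C), rep(0, 16))
  e1 <- c(1, rep(0, 15))
  expect_equal(cooccurrence_target(e1, C), e1)
  set.seed(2)
  for (rep in 1:10) {
    y <- rbinom(16, 1, 0.4)
    Cm <- crossprod(matrix(runif(64), 4, 16)) / 4
    ct <- cooccurrence_target(y, Cm)
    expect_true(all(ct >= 0 & ct <= 1))
    if (any(y == 1)) expect_equal(max(ct), 1)
    # invariant to positive rescaling of C
    expect_equal(cooccurrence_target(y, 7.3 * Cm), ct)
  }
  expect_error(cooccurrence_target(e1, -C), "nonnegative")
})

test_that("label CSV round-trips through the interchange format", {
  votes <- matrix(rbinom(5 * 32, 1, 0.3), 5, 32,
                  dimnames = list(paste0("a", 1:5), NULL))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_tooth_labels(list(img1 = votes, img2 = votes * 0L), tmp)
  df <- read_tooth_labels(tmp)
  expect_setequal(unique(df$image_id), c("img1", "img2"))
  m <- tooth_label_matrix(df, "img1")
  expect_equal(unname(m), unname(votes))
  expect_equal(sum(tooth_label_matrix(df, "img2")), 0L)
})
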