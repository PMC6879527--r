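# Scalar loop oracle for the focal loss family, independent of the
# vectorised implementations.
focal_term_oracle <- function(p, y, gamma, eps = 1e-7) {
  p <- min(max(p, eps), 1 - eps)
  -((1 - p)^gamma * y * log(p) + p^gamma * (1 - y) * log(1 - p))
}

test_that("BCE + L2 loss matches closed forms", {
  y <- matrix(rbinom(24, 1, 0.5), 4, 6)
  expect_lt(bce_l2_loss(pmin(pmax(y, 1e-7), 1 - 1e-7), y), 1e-5)
  # single pixel, p = 0.5, y = 1 -> log 2
  expect_equal(bce_l2_loss(matrix(0.5), matrix(1)), log(2))
  # L2 penalty strictly increases the loss for nonzero weights
  p <- matrix(runif(24), 4, 6)
  expect_gt(bce_l2_loss(p, y, weights = rnorm(10), lambda_l2 = 0.1),
            bce_l2_loss(p, y, weights = numeric(0), lambda_l2 = 0.1))
  expect_error(bce_l2_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "mismatch")
})

test_that("pixel focal loss reduces to BCE at gamma 0 and matches hand values", {
  set.seed(3)
  p <- matrix(runif(40, 0.01, 0.99), 5, 8)
  y <- matrix(rbinom(40, 1, 0.5), 5, 8)
  expect_equal(pixel_focal_loss(p, y, gamma = 0), bce_l2_loss(p, y),
               tolerance = 1e-10)
  # single pixel, p = 0.5, y = 1, gamma = 2 -> 0.25 log 2
  expect_equal(pixel_focal_loss(matrix(0.5), matrix(1), 2), 0.25 * log(2))
  # scalar loop oracle on the full matrix
  want <- mean(mapply(focal_term_oracle, p, y, MoreArgs = list(gamma = 2)))
  expect_equal(pixel_focal_loss(p, y, 2), want, tolerance = 1e-8)
  # strictly decreasing in the predicted probability for a positive pixel
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, function(q) pixel_focal_loss(matrix(q), matrix(1), 2),
               numeric(1))
  expect_true(all(diff(ls) < 0))
  # well-classified pixel down-weighted by (1-p)^gamma exactly
  expect_equal(pixel_focal_loss(matrix(0.9), matrix(1), 2),
               0.1^2 * bce_l2_loss(matrix(0.9), matrix(1)))
  expect_error(pixel_focal_loss(p, y, -1), "nonnegative")
})

test_that("tooth focal loss matches a per-element loop oracle", {
  pred <- rbind(c(0.9, 0.2), c(0.4, 0.7))
  targ <- rbind(c(1, 0), c(0, 1))
  # brute force: per-node mean over samples, summed over nodes
  want <- 0
  for (j in 1:2) {
    node <- mean(vapply(1:2, function(i)
      focal_term_oracle(pred[i, j], targ[i, j], 2), numeric(1)))
    want <- want + node
  }
  expect_equal(tooth_focal_loss(pred, targ, gamma = 2), want,
               tolerance = 1e-8)
  # gamma = 0, lambda = 0 reduces to per-node mean BCE summed over nodes
  set.seed(4)
  p <- matrix(runif(3 * 32, 0.05, 0.95), 3, 32)
  y <- matrix(rbinom(3 * 32, 1, 0.3), 3, 32)
  bce_nodes <- sum(vapply(1:32, function(j) bce_l2_loss(p[, j], y[, j]),
                          numeric(1)))
  expect_equal(tooth_focal_loss(p, y, gamma = 0), bce_nodes,
               tolerance = 1e-10)
  # perfect clamped predictions -> ~0; L2 penalty adds (lambda/2n) sum w^2
  expect_lt(tooth_focal_loss(y, y, gamma = 2), 1e-4)
  expect_equal(tooth_focal_loss(y, y, gamma = 2, lambda_l2 = 0.2,
                                weights = c(3, 4)) -
                 tooth_focal_loss(y, y, gamma = 2),
               0.2 / (2 * 3) * 25)
})

test_that("auxiliary co-occurrence loss matches a term-by-term oracle", {
  set.seed(5)
  Cm <- crossprod(matrix(runif(64), 4, 16)) / 4
  y <- rbinom(16, 1, 0.4)
  ct <- cooccurrence_target(y, Cm)
  expect_equal(aux_cooccurrence_loss(ct, y, Cm), 0)
  # all-zero labels: target is 0, so the loss is sum of squared scores
  ph <- runif(16)
  expect_equal(aux_cooccurrence_loss(ph, rep(0, 16), Cm), sum(ph^2))
  # random instance vs scalar loop
  want <- 0
  for (j in 1:16) want <- want + (ct[j] - ph[j])^2
  expect_equal(aux_cooccurrence_loss(ph, y, Cm), want, tolerance = 1e-12)
  # batch form averages over samples
  P <- rbind(ph, ct)
  Y <- rbind(y, y)
  expect_equal(aux_cooccurrence_loss(P, Y, Cm),
               mean(c(aux_cooccurrence_loss(ph, y, Cm), 0)))
})

test_that("final loss composes focal and per-jaw auxiliary terms", {
  set.seed(6)
  Cu <- crossprod(matrix(runif(64), 4, 16)) / 4
  Cl <- crossprod(matrix(runif(64), 4, 16)) / 4
  p <- runif(32, 0.05, 0.95)
  y <- rbinom(32, 1, 0.3)
  expect_equal(final_loss(p, y, Cu, Cl, beta = 0),
               tooth_focal_loss(p, y))
  want <- tooth_focal_loss(p, y) +
    0.01 * (aux_cooccurrence_loss(p[1:16], y[1:16], Cu) +
              aux_cooccurrence_loss(p[17:32], y[17:32], Cl))
  expect_equal(final_loss(p, y, Cu, Cl, beta = 0.01), want, tolerance = 1e-12)
  # continuous in beta: linear interpolation between the two endpoints
  l0 <- final_loss(p, y, Cu, Cl, beta = 0)
  l1 <- final_loss(p, y, Cu, Cl, beta = 1)
  expect_equal(final_loss(p, y, Cu, Cl, beta = 0.4), l0 + 0.4 * (l1 - l0),
               tolerance = 1e-10)
})
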