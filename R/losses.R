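#' @noRd
clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Pixelwise binary cross-entropy with L2 weight penalty
#'
#' Loss of the teeth-region (ROI) segmenter:
#' `-(1/n) sum_i [ y_i log p_i + (1 - y_i) log(1 - p_i) ] +
#'  (lambda/(2n)) sum_k w_k^2`
#' over the `n` pixels of the prediction. Probabilities are clamped to
#' `[eps, 1 - eps]` with `eps = 1e-7` before the logs.
#'
#' @param pred Predicted per-pixel probabilities (any array shape).
#' @param target Binary array of the same shape.
#' @param weights Numeric vector of model weights entering the L2 penalty
#'   (empty for none).
#' @param lambda_l2 Penalty coefficient `lambda` (default `1e-4` in the
#'   segmenter configuration; 0 disables).
#' @return Scalar loss.
#' @export
bce_l2_loss <- function(pred, target, weights = numeric(0), lambda_l2 = 0) {
  check_same_shape(pred, target)
  if (!all(target %in% c(0, 1))) stop("target must be binary (0/1)")
  p <- clamp_prob(as.numeric(pred))
  y <- as.numeric(target)
  n <- length(p)
  -mean(y * log(p) + (1 - y) * log(1 - p)) +
    lambda_l2 / (2 * n) * sum(weights^2)
}

#' Pixelwise focal loss
#'
#' Loss of the lesion segmenter, down-weighting well-classified pixels to
#' counter the extreme foreground/background imbalance of focal bone-loss
#' lesions:
#' `-(1/n) sum_i [ (1-p_i)^gamma y_i log p_i + p_i^gamma (1-y_i) log(1-p_i) ]`.
#' At `gamma = 0` this is exactly the unweighted binary cross-entropy.
#'
#' @inheritParams bce_l2_loss
#' @param gamma Focusing exponent, `>= 0` (default 2).
#' @return Scalar loss.
#' @export
pixel_focal_loss <- function(pred, target, gamma = 2) {
  check_same_shape(pred, target)
  if (length(gamma) != 1L || is.na(gamma) || gamma < 0)
    stop("gamma must be a nonnegative scalar")
  if (!all(target %in% c(0, 1))) stop("target must be binary (0/1)")
  p <- clamp_prob(as.numeric(pred))
  y <- as.numeric(target)
  -mean((1 - p)^gamma * y * log(p) + p^gamma * (1 - y) * log(1 - p))
}

#' Tooth-level focal classification loss with L2 penalty
#'
#' Multi-label loss of the tooth classifiers: for each of the 32 output
#' nodes the focal term is averaged over the batch, the per-node losses are
#' summed over nodes, and an L2 weight penalty `(lambda/(2N)) sum_k w_k^2`
#' (N = batch size) is added once.
#'
#' @param pred `N x T` matrix of predicted probabilities (or a length-T
#'   vector for a single sample).
#' @param target Binary matrix/vector of the same shape.
#' @param gamma Focusing exponent (default 2).
#' @param lambda_l2 L2 penalty coefficient.
#' @param weights Model weights entering the penalty.
#' @return Scalar loss.
#' @export
tooth_focal_loss <- function(pred, target, gamma = 2, lambda_l2 = 0,
                             weights = numeric(0)) {
  pred <- rbind_vector(pred); target <- rbind_vector(target)
  check_same_shape(pred, target)
  if (length(gamma) != 1L || is.na(gamma) || gamma < 0)
    stop("gamma must be a nonnegative scalar")
  if (!all(target %in% c(0, 1))) stop("target must be binary (0/1)")
  if (any(pred < 0 | pred > 1)) stop("pred must contain probabilities in [0, 1]")
  p <- clamp_prob(pred)
  y <- target
  per_elem <- -((1 - p)^gamma * y * log(p) + p^gamma * (1 - y) * log(1 - p))
  n <- nrow(p)
  sum(colMeans(per_elem)) + lambda_l2 / (2 * n) * sum(weights^2)
}

#' Auxiliary co-occurrence loss
#'
#' Squared error between the classifier scores of one jaw and the
#' co-occurrence target derived from the true labels:
#' `sum_j (c_j - p_j)^2` with `c = cooccurrence_target(y, C)`, averaged over
#' the batch. This pulls the score of a tooth up when its frequent
#' co-occurrence partners are diseased, injecting the clinical prior that
#' bone loss clusters on horizontally adjacent teeth.
#'
#' @param pred `N x 16` score matrix (or length-16 vector) for one jaw.
#' @param y Matching binary label matrix/vector.
#' @param C 16 x 16 co-occurrence matrix for that jaw.
#' @return Scalar loss.
#' @export
aux_cooccurrence_loss <- function(pred, y, C) {
  pred <- rbind_vector(pred); y <- rbind_vector(y)
  check_same_shape(pred, y)
  if (ncol(pred) != nrow(C)) stop("pred width must match nrow(C)")
  per_sample <- vapply(seq_len(nrow(pred)), function(i) {
    ci <- cooccurrence_target(y[i, ], C)
    sum((ci - pred[i, ])^2)
  }, numeric(1))
  mean(per_sample)
}

#' Final classifier training loss
#'
#' `L_F = L_C + beta * (L_aux(upper 16 | C_upper) + L_aux(lower 16 | C_lower))`
#' where `L_C` is [tooth_focal_loss()] and each jaw's auxiliary term uses its
#' own co-occurrence matrix. `beta = 0` recovers the focal loss exactly.
#'
#' @inheritParams tooth_focal_loss
#' @param C_upper,C_lower 16 x 16 co-occurrence matrices (upper / lower jaw).
#' @param beta Auxiliary loss weight (default 0.01).
#' @return Scalar loss.
#' @export
final_loss <- function(pred, target, C_upper, C_lower, gamma = 2,
                       lambda_l2 = 0, beta = 0.01, weights = numeric(0)) {
  pred <- rbind_vector(pred); target <- rbind_vector(target)
  if (ncol(pred) != 32L) stop("pred must have 32 columns (one per tooth)")
  up <- upper_indices() + 1L
  lo <- lower_indices() + 1L
  lc <- tooth_focal_loss(pred, target, gamma = gamma, lambda_l2 = lambda_l2,
                         weights = weights)
  lc + beta * (aux_cooccurrence_loss(pred[, up, drop = FALSE],
                                     target[, up, drop = FALSE], C_upper) +
               aux_cooccurrence_loss(pred[, lo, drop = FALSE],
                                     target[, lo, drop = FALSE], C_lower))
}

rbind_vector <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)

check_same_shape <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (is.null(da)) da <- length(a)
  if (is.null(db)) db <- length(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop("shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  invisible(TRUE)
}
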