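#' Tooth classifier configuration
#'
#' Configuration of the multi-label tooth classifiers: the generalist `fA`
#' reads the whole ROI crop, the premolar/molar specialist `fB` reads its
#' vertical halves. Both share one architecture: the transferred segmenter
#' encoder followed by two additional 3x3 convolution blocks, one global
#' average pooling layer, two fully connected layers and 32 sigmoid output
#' nodes (one per FDI tooth slot).
#'
#' @param input_shape `(height, width)` of the full ROI crop; `fB` consumes
#'   `(height, width/2)` halves. Width must be even.
#' @param depth,base_channels Encoder geometry; must match the transferred
#'   encoder when one is supplied.
#' @param gamma Focal exponent of the classification loss (default 2).
#' @param lambda_l2 L2 penalty coefficient (default `1e-4`).
#' @param beta Auxiliary co-occurrence loss weight (default 0.01).
#' @param alpha Ensemble interpolation weight toward `fA` on premolar/molar
#'   teeth (default 0.1).
#' @param learning_rate Adam initial learning rate (default `1e-5`).
#' @param epochs Training epochs (default 100).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(input_shape = c(512L, 1024L), depth = 4L,
                              base_channels = 16L, gamma = 2,
                              lambda_l2 = 1e-4, beta = 0.01, alpha = 0.1,
                              learning_rate = 1e-5, epochs = 100L) {
  input_shape <- as.integer(input_shape)
  if (input_shape[2] %% 2L != 0L) stop("ROI width must be even")
  if (any(c(input_shape, input_shape[2] / 2L) %% 2L^depth != 0L))
    stop("input shape (and its half width) must be divisible by 2^depth")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  structure(list(input_shape = input_shape, depth = as.integer(depth),
                 base_channels = as.integer(base_channels), gamma = gamma,
                 lambda_l2 = lambda_l2, beta = beta, alpha = alpha,
                 learning_rate = learning_rate, epochs = as.integer(epochs)),
            class = "classifier_config")
}

#' Build a tooth classifier, optionally from transferred encoder weights
#'
#' Assembles the classifier network and initialises its encoder path either
#' from the lesion segmenter's [encoder_weights()] (transfer learning) or
#' randomly (the ablation control). All layers remain trainable. A shape
#' mismatch between the supplied encoder and the configured geometry is
#' rejected with the offending layer named.
#'
#' @param encoder A `pbl_encoder_weights` object, or `NULL` for random
#'   initialisation.
#' @param config A [classifier_config()].
#' @param input_shape Overrides `config$input_shape` (used for the
#'   half-image specialist).
#' @return A `pbl_classifier` model.
#' @export
build_classifier <- function(encoder = NULL, config = classifier_config(),
                             input_shape = config$input_shape) {
  depth <- config$depth; base <- config$base_channels
  params <- unet_params(depth, base)
  params <- params[encoder_param_names(depth)]   # encoder path only
  if (!is.null(encoder)) {
    stopifnot(inherits(encoder, "pbl_encoder_weights"))
    if (encoder$depth != depth || encoder$base_channels != base)
      stop("encoder geometry (depth ", encoder$depth, ", base ",
           encoder$base_channels, ") does not match the configuration")
    for (nm in encoder_param_names(depth)) {
      for (slot in c("w", "b")) {
        tname <- paste0(nm, ".", slot)
        t <- encoder$tensors[[tname]]
        if (is.null(t)) stop("encoder archive is missing tensor ", tname)
        want <- dim(params[[nm]][[slot]]) %||% length(params[[nm]][[slot]])
        got <- dim(t) %||% length(t)
        if (!identical(as.integer(want), as.integer(got)))
          stop("shape mismatch in transferred layer ", tname, ": expected ",
               paste(want, collapse = "x"), ", got ",
               paste(got, collapse = "x"))
        params[[nm]][[slot]] <- t
      }
    }
  }
  cb <- base * 2L^depth
  params[["head_1"]] <- init_conv(3L, 3L, cb, cb)
  params[["head_2"]] <- init_conv(3L, 3L, cb, cb)
  params[["fc1"]] <- init_fc(cb, cb)
  params[["fc2"]] <- init_fc(cb, 32L)
  structure(list(params = params, config = config,
                 input_shape = as.integer(input_shape),
                 transferred = !is.null(encoder)),
            class = "pbl_classifier")
}

classifier_fw <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  depth <- model$config$depth
  enc <- encoder_fw(p, x, depth, keep_cache = keep_cache)
  h1 <- convrelu_fw(enc$feat, p[["head_1"]])
  h2 <- convrelu_fw(h1$a, p[["head_2"]])
  fdim <- dim(h2$a)
  gap <- colMeans(matrix(h2$a, fdim[1] * fdim[2], fdim[3]))
  pre1 <- as.vector(crossprod(p[["fc1"]]$w, gap)) + p[["fc1"]]$b
  a1 <- relu_fw(pre1)
  z <- as.vector(crossprod(p[["fc2"]]$w, a1)) + p[["fc2"]]$b
  prob <- sigmoid(z)
  list(prob = prob,
       cache = if (keep_cache) list(enc = enc, h1 = h1, h2 = h2, fdim = fdim,
                                    gap = gap, pre1 = pre1, a1 = a1, z = z))
}

classifier_bw <- function(model, cache, gz) {
  p <- model$params
  depth <- model$config$depth
  grads <- list()
  grads[["fc2"]] <- list(w = outer(cache$a1, gz), b = gz)
  ga1 <- as.vector(p[["fc2"]]$w %*% gz)
  gpre1 <- ga1 * (cache$pre1 > 0)
  grads[["fc1"]] <- list(w = outer(cache$gap, gpre1), b = gpre1)
  ggap <- as.vector(p[["fc1"]]$w %*% gpre1)
  fdim <- cache$fdim
  npos <- fdim[1] * fdim[2]
  gh2 <- array(rep(ggap / npos, each = npos), dim = fdim)
  g2 <- convrelu_bw(cache$h2, p[["head_2"]], gh2)
  grads[["head_2"]] <- list(w = g2$gw, b = g2$gb)
  g1 <- convrelu_bw(cache$h1, p[["head_1"]], g2$gx)
  grads[["head_1"]] <- list(w = g1$gw, b = g1$gb)
  eb <- encoder_bw(p, cache$enc$cache, depth, g1$gx, gskips = NULL)
  c(grads, eb$grads)
}

#' Predicted tooth scores from a single classifier
#'
#' @param model A `pbl_classifier`.
#' @param image Input matrix at the model's input shape.
#' @return Numeric vector of 32 probabilities named by FDI code.
#' @export
predict_scores <- function(model, image) {
  stopifnot(inherits(model, "pbl_classifier"))
  image <- conform_image(image, model$input_shape)
  s <- classifier_fw(model, image)$prob
  names(s) <- fdi_chart()$code
  s
}

#' Split an ROI crop into its left and right vertical halves
#'
#' Columns `[0, w/2)` form the left half and `[w/2, w)` the right, so
#' concatenating the halves restores the input exactly and each radiograph
#' contributes two specialist training samples. In the panoramic image the
#' left half holds the patient's right side (quadrants 1 and 4), the right
#' half quadrants 2 and 3.
#'
#' @param roi An H x W matrix (or `roi_crop`) of even width.
#' @return List with `left` and `right` H x (W/2) matrices.
#' @export
vertical_split <- function(roi) {
  img <- if (inherits(roi, "roi_crop")) roi$image else roi
  W <- ncol(img)
  if (W %% 2L != 0L) stop("image width must be even to split vertically")
  list(left = img[, seq_len(W / 2L), drop = FALSE],
       right = img[, W / 2L + seq_len(W / 2L), drop = FALSE])
}

#' Zero the incisor and canine entries of a tooth-label vector
#'
#' The premolar/molar specialist `fB` is trained with label-masked targets:
#' incisor and canine slots are set to 0 and the 20 premolar/molar slots are
#' kept. Idempotent.
#'
#' @param y Binary vector of length 32.
#' @return Masked binary vector.
#' @export
mask_labels_premolar_molar <- function(y) {
  if (length(y) != 32L) stop("y must have length 32")
  keep <- c(tooth_type_indices("premolar"), tooth_type_indices("molar")) + 1L
  out <- y * 0
  out[keep] <- y[keep]
  out
}

# fB target for one image half: premolar/molar labels of the quadrants
# visible in that half, zero elsewhere
half_target <- function(y, side = c("left", "right")) {
  side <- match.arg(side)
  vis <- if (side == "left") left_half_indices() else
    setdiff(0:31, left_half_indices())
  out <- mask_labels_premolar_molar(y)
  out[setdiff(0:31, vis) + 1L] <- 0
  out
}

# gradient of the per-sample final loss wrt the 32 output logits
final_loss_grad_logit <- function(p, y, C_upper, C_lower, gamma, beta) {
  g <- focal_grad_logit(p, y, gamma)
  if (beta > 0) {
    up <- upper_indices() + 1L; lo <- lower_indices() + 1L
    cfull <- c(cooccurrence_target(y[up], C_upper),
               cooccurrence_target(y[lo], C_lower))
    g <- g + beta * 2 * (p - cfull) * p * (1 - p)
  }
  g
}

#' Train the generalist and premolar/molar specialist tooth classifiers
#'
#' Jointly trains `fA` (full ROI crops) and `fB` (vertical halves with
#' label-masked targets), both initialised from the transferred lesion
#' encoder (or randomly when `encoder = NULL`), by minimising the final
#' loss: tooth focal loss plus `beta` times the per-jaw auxiliary
#' co-occurrence loss ([final_loss()]). Joint training is realised as
#' alternating per-sample Adam updates of `fA` and `fB` over one shared
#' shuffled pass per epoch; each radiograph contributes one `fA` sample and
#' two `fB` half-samples. The co-occurrence matrices must be built from
#' training labels only.
#'
#' @param dataset List of `list(image, labels)` pairs: ROI crop matrix (or
#'   `roi_crop`) and binary 32-vector of reference tooth labels.
#' @param encoder `pbl_encoder_weights` from [train_lesion_segmenter()], or
#'   `NULL` for the random-initialisation ablation.
#' @param cooc A `pbl_cooccurrence` object (from [build_cooccurrence()] on
#'   the training labels).
#' @param config A [classifier_config()].
#' @param seed Integer seed fixing initialisation and sample order.
#' @param augmentation An [augment_params()] object, or `NULL` to disable.
#' @return A `pbl_tooth_classifiers` object: `fA`, `fB`, `cooc`, `config`
#'   and a per-epoch `history`.
#' @export
train_tooth_classifiers <- function(dataset, encoder, cooc,
                                    config = classifier_config(),
                                    seed = 1L, augmentation = augment_params()) {
  if (length(dataset) == 0L) stop("dataset must contain at least one sample")
  stopifnot(inherits(cooc, "pbl_cooccurrence"))
  set.seed(seed)
  shape <- config$input_shape
  half_shape <- c(shape[1], shape[2] %/% 2L)
  data <- lapply(dataset, function(d) {
    img <- if (inherits(d$image, "roi_crop")) d$image$image else d$image
    list(image = conform_image(img, shape), labels = as.numeric(d$labels))
  })
  fA <- build_classifier(encoder, config, input_shape = shape)
  fB <- build_classifier(encoder, config, input_shape = half_shape)
  optA <- adam_init(fA$params); optB <- adam_init(fB$params)
  history <- list()
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(data))
    ep_loss <- 0
    for (i in ord) {
      d <- data[[i]]
      img <- d$image
      if (!is.null(augmentation)) img <- augment(img, NULL, augmentation)$image
      upA <- classifier_step(fA, optA, img, d$labels, cooc, config)
      fA <- upA$model; optA <- upA$opt
      halves <- vertical_split(img)
      for (side in c("left", "right")) {
        upB <- classifier_step(fB, optB, halves[[side]],
                               half_target(d$labels, side), cooc, config)
        fB <- upB$model; optB <- upB$opt
      }
      ep_loss <- ep_loss + upA$loss
    }
    history[[ep]] <- list(epoch = ep, loss = ep_loss / length(data))
  }
  structure(list(fA = fA, fB = fB, cooc = cooc, config = config,
                 history = dplyr::bind_rows(history)),
            class = "pbl_tooth_classifiers")
}

classifier_step <- function(model, opt, image, y, cooc, config) {
  fw <- classifier_fw(model, image, keep_cache = TRUE)
  p <- clamp_prob(fw$prob)
  loss <- final_loss(p, y, cooc$upper, cooc$lower, gamma = config$gamma,
                     lambda_l2 = config$lambda_l2, beta = config$beta,
                     weights = weight_vector(model$params))
  gz <- final_loss_grad_logit(p, y, cooc$upper, cooc$lower,
                              config$gamma, config$beta)
  grads <- classifier_bw(model, fw$cache, gz)
  grads <- add_l2_grad(grads, model$params, config$lambda_l2, 1L)
  st <- adam_step(model$params, grads, opt, config$learning_rate)
  model$params <- st$params
  list(model = model, opt = st$state, loss = loss)
}

#' Ensemble the generalist and specialist predictions for one ROI crop
#'
#' Incisor and canine scores come from `fA` alone. For premolar and molar
#' teeth the score is the convex combination
#' `alpha * fA(x_ROI) + (1 - alpha) * fB(x_half)`, where `x_half` is the
#' vertical half containing the tooth. `alpha = 1` reduces to `fA`
#' everywhere.
#'
#' @param fA,fB Trained `pbl_classifier` models (full / half input).
#' @param roi ROI crop matrix or `roi_crop`.
#' @param alpha Interpolation weight in `[0, 1]` (default 0.1).
#' @return Numeric vector of 32 scores named by FDI code.
#' @export
ensemble_predict <- function(fA, fB, roi, alpha = 0.1) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  img <- if (inherits(roi, "roi_crop")) roi$image else roi
  pA <- predict_scores(fA, img)
  halves <- vertical_split(img)
  pB <- list(left = predict_scores(fB, halves$left),
             right = predict_scores(fB, halves$right))
  ch <- fdi_chart()
  out <- pA
  pm <- ch$type %in% c("premolar", "molar")
  side <- ifelse(ch$index %in% left_half_indices(), "left", "right")
  for (k in which(pm)) {
    out[k] <- alpha * pA[k] + (1 - alpha) * pB[[side[k]]][k]
  }
  out
}

#' @export
predict.pbl_tooth_classifiers <- function(object, roi,
                                          alpha = object$config$alpha, ...) {
  ensemble_predict(object$fA, object$fB, roi, alpha = alpha)
}

#' @export
print.pbl_tooth_classifiers <- function(x, ...) {
  cat("Tooth classifiers fA (full crop) + fB (premolar/molar specialist)\n")
  cat("  encoder:", if (x$fA$transferred) "transferred" else "random init",
      "| alpha", x$config$alpha, "| beta", x$config$beta, "\n")
  if (nrow(x$history))
    cat("  trained", nrow(x$history), "epochs; final loss",
        sprintf("%.4f", utils::tail(x$history$loss, 1)), "\n")
  invisible(x)
}

#' @export
glance.pbl_tooth_classifiers <- function(x, ...) {
  tibble::tibble(transferred = x$fA$transferred,
                 alpha = x$config$alpha, beta = x$config$beta,
                 gamma = x$config$gamma, epochs = nrow(x$history),
                 final_loss = utils::tail(x$history$loss, 1))
}

#' @export
tidy.pbl_tooth_classifiers <- function(x, ...) tibble::as_tibble(x$history)

#' Grad-CAM localisation map for one tooth's score
#'
#' Gradient-weighted class activation mapping on the last convolutional
#' layer before global average pooling: channel weights are the spatially
#' pooled gradients of the chosen output node, the map is the
#' ReLU-rectified weighted channel sum, max-normalised to 1 and bilinearly
#' upsampled to the input shape. A node with zero gradient everywhere
#' yields an all-zero map with a warning.
#'
#' @param model A trained `pbl_classifier`.
#' @param image Input matrix at the model's input shape.
#' @param tooth_index Zero-based tooth slot in 0..31 ([fdi_to_index()]).
#' @return Matrix in `[0, 1]` aligned to the input image.
#' @export
gradcam <- function(model, image, tooth_index) {
  stopifnot(inherits(model, "pbl_classifier"))
  tooth_index <- as.integer(tooth_index)
  if (is.na(tooth_index) || tooth_index < 0L || tooth_index > 31L)
    stop("tooth_index must be in 0..31")
  image <- conform_image(image, model$input_shape)
  fw <- classifier_fw(model, image, keep_cache = TRUE)
  cache <- fw$cache
  p <- model$params
  j <- tooth_index + 1L
  # d z_j / d GAP vector, through fc2 and the ReLU of fc1
  gpre1 <- as.vector(p[["fc2"]]$w[, j])
  gh1 <- gpre1 * (cache$pre1 > 0)
  ggap <- as.vector(p[["fc1"]]$w %*% gh1)
  fdim <- cache$fdim
  # gradients are constant per channel after GAP; pooled gradient = ggap/npos
  alpha_c <- ggap / (fdim[1] * fdim[2])
  A <- matrix(cache$h2$a, fdim[1] * fdim[2], fdim[3])
  cam <- matrix(pmax(A %*% alpha_c, 0), fdim[1], fdim[2])
  if (max(cam) <= 0) {
    warning("zero gradient for this tooth: returning an all-zero map")
    return(matrix(0, nrow(image), ncol(image)))
  }
  up <- resize_image(cam, dim(image))
  up / max(up)
}
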