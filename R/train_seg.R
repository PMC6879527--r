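# Training loops for the two U-shaped segmenters. Optimisation is plain
# sequential Adam with batch size 1 (sample order reshuffled every epoch from
# the seeded RNG), so a fixed seed reproduces the run exactly.

check_seg_dataset <- function(dataset, shape) {
  if (length(dataset) == 0L) stop("dataset must contain at least one pair")
  lapply(dataset, function(d) {
    img <- conform_image(d$image, shape)
    msk <- conform_image((d$mask > 0) + 0, shape, nearest = TRUE)
    list(image = img, mask = msk)
  })
}

#' Train the teeth-region (ROI) segmenter
#'
#' Fits the U-shaped segmenter to (radiograph, teeth-region mask) pairs by
#' minimising [bce_l2_loss()] with Adam. Inputs are resized to
#' `config$input_shape` if needed.
#'
#' @param dataset List of `list(image, mask)` pairs (grayscale matrix +
#'   binary matrix).
#' @param config A [segmenter_config()].
#' @param seed Integer seed; fixes initial weights, shuffling and every
#'   other random draw, making reruns bit-identical.
#' @param validation Optional list of held-out pairs; per-epoch dice against
#'   them is recorded in the history.
#' @return A trained `pbl_unet` with a `history` data frame
#'   (`epoch`, `loss`, optional `val_dice`).
#' @export
train_roi_segmenter <- function(dataset, config = segmenter_config(),
                                seed = 1L, validation = NULL) {
  dataset <- check_seg_dataset(dataset, config$input_shape)
  set.seed(seed)
  model <- structure(list(params = unet_params(config$depth,
                                               config$base_channels),
                          config = config),
                     class = "pbl_unet")
  train_segmenter_loop(model, dataset, config, validation,
                       loss_kind = "bce", gamma = 0,
                       augment_params = NULL)
}

#' Pre-train the lesion segmenter and export its encoder
#'
#' Fits the same U-shape to (ROI crop, union lesion mask) pairs by
#' minimising [pixel_focal_loss()] (plus the L2 penalty) with Adam and
#' per-sample random augmentation, then extracts the encoder weights for
#' transfer into the tooth classifiers. Lesion masks are expected to be
#' union aggregates ([aggregate_lesion_mask()] at `c_s = 1`), which
#' maximises the recall of lesion pixels the encoder learns from.
#'
#' @inheritParams train_roi_segmenter
#' @param gamma Focal exponent (default 2).
#' @param augmentation An [augment_params()] object, or `NULL` to disable.
#' @return List with `model` (trained `pbl_unet`) and `encoder`
#'   (a `pbl_encoder_weights` object for [build_classifier()]).
#' @export
train_lesion_segmenter <- function(dataset, config = segmenter_config(),
                                   gamma = 2, augmentation = augment_params(),
                                   seed = 1L, validation = NULL) {
  dataset <- check_seg_dataset(dataset, config$input_shape)
  set.seed(seed)
  model <- structure(list(params = unet_params(config$depth,
                                               config$base_channels),
                          config = config),
                     class = "pbl_unet")
  model <- train_segmenter_loop(model, dataset, config, validation,
                                loss_kind = "focal", gamma = gamma,
                                augment_params = augmentation)
  list(model = model, encoder = encoder_weights(model))
}

train_segmenter_loop <- function(model, dataset, config, validation,
                                 loss_kind, gamma, augment_params) {
  opt <- adam_init(model$params)
  n_pix <- prod(config$input_shape)
  history <- list()
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(dataset))
    ep_loss <- 0
    for (i in ord) {
      d <- dataset[[i]]
      if (!is.null(augment_params)) {
        a <- augment(d$image, d$mask, augment_params)
        d <- list(image = a$image, mask = (a$mask > 0) + 0)
      }
      fw <- unet_fw(model, d$image, keep_cache = TRUE)
      p <- clamp_prob(fw$prob)
      y <- d$mask
      loss <- if (loss_kind == "bce") {
        bce_l2_loss(p, y, weight_vector(model$params), config$lambda_l2)
      } else {
        pixel_focal_loss(p, y, gamma) +
          config$lambda_l2 / (2 * n_pix) * sum(weight_vector(model$params)^2)
      }
      gz <- if (loss_kind == "bce") (p - y) / n_pix else
        focal_grad_logit(p, y, gamma) / n_pix
      grads <- unet_bw(model, fw$cache, gz)
      grads <- add_l2_grad(grads, model$params, config$lambda_l2, n_pix)
      st <- adam_step(model$params, grads, opt, config$learning_rate)
      model$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + loss
    }
    rec <- list(epoch = ep, loss = ep_loss / length(dataset))
    if (!is.null(validation)) {
      rec$val_dice <- mean(vapply(validation, function(v) {
        dice(predict_mask(model, v$image) >= 0.5, v$mask)
      }, numeric(1)))
    }
    history[[ep]] <- rec
  }
  model$history <- dplyr::bind_rows(history)
  model
}

#' @export
glance.pbl_unet <- function(x, ...) {
  h <- x$history
  tibble::tibble(depth = x$config$depth,
                 base_channels = x$config$base_channels,
                 epochs = if (is.null(h)) 0L else nrow(h),
                 final_loss = if (is.null(h)) NA_real_ else
                   utils::tail(h$loss, 1),
                 final_val_dice = if (is.null(h$val_dice)) NA_real_ else
                   utils::tail(h$val_dice, 1))
}

#' @export
tidy.pbl_unet <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble())
  tibble::as_tibble(x$history)
}

# ---- encoder weight transfer ----------------------------------------------

#' Extract, save and load encoder weights for transfer learning
#'
#' The encoder path of the lesion segmenter (all `enc*` levels plus the
#' bottleneck) is the transferable representation: `encoder_weights()` pulls
#' it out of a trained `pbl_unet` as an ordered collection of named tensors
#' with a manifest of shapes. `write_encoder_weights()` /
#' `read_encoder_weights()` serialise the archive as JSON (17 significant
#' digits, lossless for doubles) so the transfer contract is text-based and
#' framework-portable.
#'
#' @param model A `pbl_unet`.
#' @return A `pbl_encoder_weights` object: `tensors` (named list of arrays),
#'   `manifest` (tibble of name and dimensions), `depth`, `base_channels`.
#' @export
encoder_weights <- function(model) {
  stopifnot(inherits(model, "pbl_unet"))
  nms <- encoder_param_names(model$config$depth)
  tensors <- list()
  for (nm in nms) {
    tensors[[paste0(nm, ".w")]] <- model$params[[nm]]$w
    tensors[[paste0(nm, ".b")]] <- model$params[[nm]]$b
  }
  manifest <- tibble::tibble(
    name = names(tensors),
    dims = unname(vapply(tensors, function(t)
      paste(dim(t) %||% length(t), collapse = "x"), character(1))))
  structure(list(tensors = tensors, manifest = manifest,
                 depth = model$config$depth,
                 base_channels = model$config$base_channels),
            class = "pbl_encoder_weights")
}

#' @rdname encoder_weights
#' @param enc A `pbl_encoder_weights` object.
#' @param path Output/input JSON path.
#' @export
write_encoder_weights <- function(enc, path) {
  stopifnot(inherits(enc, "pbl_encoder_weights"))
  payload <- list(
    depth = enc$depth, base_channels = enc$base_channels,
    manifest = enc$manifest,
    tensors = lapply(enc$tensors, function(t)
      list(dim = as.integer(dim(t) %||% length(t)), data = as.numeric(t))))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname encoder_weights
#' @export
read_encoder_weights <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  tensors <- lapply(payload$tensors, function(t) {
    d <- as.integer(t$dim)
    x <- as.numeric(t$data)
    if (length(d) > 1L) dim(x) <- d
    x
  })
  structure(list(tensors = tensors,
                 manifest = tibble::as_tibble(payload$manifest),
                 depth = as.integer(payload$depth),
                 base_channels = as.integer(payload$base_channels)),
            class = "pbl_encoder_weights")
}

#' @export
print.pbl_encoder_weights <- function(x, ...) {
  cat("Encoder weights: depth", x$depth, "| base channels", x$base_channels,
      "|", length(x$tensors), "tensors,",
      sum(vapply(x$tensors, length, 1L)), "parameters\n")
  invisible(x)
}
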