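#' Segmenter configuration
#'
#' Configuration of the U-shaped encoder-decoder segmenter used both for the
#' teeth-region (ROI) stage and the lesion pre-training stage. The network
#' follows the standard U-shape: `depth` encoder levels of two 3x3
#' convolution + ReLU layers with 2x2 max pooling between levels, a
#' bottleneck, and a mirrored decoder with nearest-neighbour upsampling and
#' skip connections by channel concatenation, ending in a 1x1 convolution
#' with a sigmoid per-pixel output.
#'
#' @param input_shape `(height, width)`; both must be divisible by
#'   `2^depth`. Default `c(512, 1024)`, the full working resolution; tests
#'   and examples use desk-scale shapes such as `c(64, 128)`.
#' @param depth Number of encoder levels (default 4; desk-scale runs use 2).
#' @param base_channels Channels of the first level, doubled per level
#'   (default 16).
#' @param lambda_l2 L2 penalty coefficient `lambda` (default `1e-4`).
#' @param learning_rate Adam initial learning rate (default `1e-4`; the
#'   lesion segmenter and classifiers use `1e-5` at full scale).
#' @param epochs Training epochs (default 50).
#' @return A `segmenter_config` list.
#' @export
segmenter_config <- function(input_shape = c(512L, 1024L), depth = 4L,
                             base_channels = 16L, lambda_l2 = 1e-4,
                             learning_rate = 1e-4, epochs = 50L) {
  input_shape <- as.integer(input_shape)
  depth <- as.integer(depth)
  if (any(input_shape %% 2L^depth != 0L))
    stop("input height and width must be divisible by 2^depth")
  structure(list(input_shape = input_shape, depth = depth,
                 base_channels = as.integer(base_channels),
                 lambda_l2 = lambda_l2, learning_rate = learning_rate,
                 epochs = as.integer(epochs)),
            class = "segmenter_config")
}

# parameter skeleton of the U-shape; the encoder part (enc* and bottleneck)
# is what gets transferred to the classifiers
unet_params <- function(depth, base) {
  p <- list()
  cin <- 1L
  for (i in seq_len(depth)) {
    cout <- base * 2L^(i - 1L)
    p[[paste0("enc", i, "_1")]] <- init_conv(3L, 3L, cin, cout)
    p[[paste0("enc", i, "_2")]] <- init_conv(3L, 3L, cout, cout)
    cin <- cout
  }
  cbot <- base * 2L^depth
  p[["bot_1"]] <- init_conv(3L, 3L, cin, cbot)
  p[["bot_2"]] <- init_conv(3L, 3L, cbot, cbot)
  prev <- cbot
  for (i in rev(seq_len(depth))) {
    cout <- base * 2L^(i - 1L)
    p[[paste0("dec", i, "_1")]] <- init_conv(3L, 3L, prev + cout, cout)
    p[[paste0("dec", i, "_2")]] <- init_conv(3L, 3L, cout, cout)
    prev <- cout
  }
  p[["out"]] <- init_conv(1L, 1L, prev, 1L)
  p
}

encoder_param_names <- function(depth) {
  c(as.vector(vapply(seq_len(depth),
                     function(i) paste0("enc", i, c("_1", "_2")),
                     character(2))),
    "bot_1", "bot_2")
}

unet_build <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(params = unet_params(config$depth, config$base_channels),
                 config = config),
            class = "pbl_unet")
}

# encoder forward pass shared by the U-net and the classifiers;
# returns final feature map, skip activations, and a cache for backprop
encoder_fw <- function(params, x, depth, keep_cache = TRUE) {
  x <- as_hwc(x)
  skips <- vector("list", depth)
  caches <- list()
  h <- x
  for (i in seq_len(depth)) {
    c1 <- convrelu_fw(h, params[[paste0("enc", i, "_1")]])
    c2 <- convrelu_fw(c1$a, params[[paste0("enc", i, "_2")]])
    skips[[i]] <- c2$a
    pl <- cpp_maxpool2_fw(c2$a, dim(c2$a))
    if (keep_cache)
      caches[[i]] <- list(c1 = c1, c2 = c2, pool_idx = pl$idx,
                          pre_pool_dim = dim(c2$a))
    h <- pl$y
  }
  b1 <- convrelu_fw(h, params[["bot_1"]])
  b2 <- convrelu_fw(b1$a, params[["bot_2"]])
  list(feat = b2$a, skips = skips,
       cache = if (keep_cache) list(levels = caches, b1 = b1, b2 = b2))
}

# backward through the encoder given gradient on the bottleneck output and
# (optionally) gradients flowing into the skip activations
encoder_bw <- function(params, cache, depth, gfeat, gskips = NULL) {
  grads <- list()
  gb2 <- convrelu_bw(cache$b2, params[["bot_2"]], gfeat)
  grads[["bot_2"]] <- list(w = gb2$gw, b = gb2$gb)
  gb1 <- convrelu_bw(cache$b1, params[["bot_1"]], gb2$gx)
  grads[["bot_1"]] <- list(w = gb1$gw, b = gb1$gb)
  g <- gb1$gx
  for (i in rev(seq_len(depth))) {
    lv <- cache$levels[[i]]
    gpre <- cpp_maxpool2_bw(g, lv$pool_idx, lv$pre_pool_dim)
    if (!is.null(gskips) && !is.null(gskips[[i]]))
      gpre <- gpre + gskips[[i]]
    g2 <- convrelu_bw(lv$c2, params[[paste0("enc", i, "_2")]], gpre)
    grads[[paste0("enc", i, "_2")]] <- list(w = g2$gw, b = g2$gb)
    g1 <- convrelu_bw(lv$c1, params[[paste0("enc", i, "_1")]], g2$gx)
    grads[[paste0("enc", i, "_1")]] <- list(w = g1$gw, b = g1$gb)
    g <- g1$gx
  }
  list(grads = grads, gx = g)
}

# full U-net forward; returns per-pixel probability matrix and a cache
unet_fw <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  depth <- model$config$depth
  enc <- encoder_fw(p, x, depth, keep_cache = keep_cache)
  h <- enc$feat
  dcaches <- list()
  for (i in rev(seq_len(depth))) {
    up <- cpp_upsample2(h, dim(h))
    skip <- enc$skips[[i]]
    cat_in <- array(c(up, skip), dim = c(dim(up)[1:2], dim(up)[3] + dim(skip)[3]))
    d1 <- convrelu_fw(cat_in, p[[paste0("dec", i, "_1")]])
    d2 <- convrelu_fw(d1$a, p[[paste0("dec", i, "_2")]])
    if (keep_cache)
      dcaches[[i]] <- list(d1 = d1, d2 = d2, up_dim = dim(up),
                           n_up = dim(up)[3])
    h <- d2$a
  }
  z <- conv_fw(h, p[["out"]]$w, p[["out"]]$b)
  prob <- sigmoid(z[, , 1])
  list(prob = prob,
       cache = if (keep_cache) list(enc = enc, dec = dcaches, head_in = h,
                                    z = z))
}

# backward from gradient wrt the output logit map (H x W)
unet_bw <- function(model, cache, gz) {
  p <- model$params
  depth <- model$config$depth
  gz <- array(gz, dim = c(dim(gz)[1:2], 1L))
  grads <- list()
  go <- conv_bw(cache$head_in, p[["out"]]$w, gz)
  grads[["out"]] <- list(w = go$gw, b = go$gb)
  g <- go$gx
  gskips <- vector("list", depth)
  for (i in seq_len(depth)) {
    dc <- cache$dec[[i]]
    g2 <- convrelu_bw(dc$d2, p[[paste0("dec", i, "_2")]], g)
    grads[[paste0("dec", i, "_2")]] <- list(w = g2$gw, b = g2$gb)
    g1 <- convrelu_bw(dc$d1, p[[paste0("dec", i, "_1")]], g2$gx)
    grads[[paste0("dec", i, "_1")]] <- list(w = g1$gw, b = g1$gb)
    gcat <- g1$gx
    n_up <- dc$n_up
    gup <- gcat[, , seq_len(n_up), drop = FALSE]
    gskips[[i]] <- gcat[, , n_up + seq_len(dim(gcat)[3] - n_up), drop = FALSE]
    g <- cpp_upsample2_bw(gup, dim(gup))
  }
  eb <- encoder_bw(p, cache$enc$cache, depth, g, gskips)
  c(grads, eb$grads)
}

#' Predict a per-pixel probability map from a trained segmenter
#'
#' @param model A trained `pbl_unet` (from [train_roi_segmenter()] or
#'   [train_lesion_segmenter()]).
#' @param image Grayscale matrix at the model's input shape (resized with a
#'   warning otherwise).
#' @return Matrix of per-pixel probabilities in `[0, 1]`.
#' @export
predict_mask <- function(model, image) {
  stopifnot(inherits(model, "pbl_unet"))
  image <- conform_image(image, model$config$input_shape)
  unet_fw(model, image)$prob
}

conform_image <- function(image, shape, nearest = FALSE) {
  if (!identical(as.integer(dim(image)[1:2]), as.integer(shape))) {
    image <- resize_image(image, shape, nearest = nearest)
  }
  image
}

#' @export
print.pbl_unet <- function(x, ...) {
  cat("U-shaped segmenter: depth", x$config$depth, "| base channels",
      x$config$base_channels, "| input",
      paste(x$config$input_shape, collapse = "x"), "\n")
  if (!is.null(x$history))
    cat("  trained", length(x$history$loss), "epochs; final loss",
        sprintf("%.5f", utils::tail(x$history$loss, 1)), "\n")
  invisible(x)
}
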