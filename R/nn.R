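# Internal CNN plumbing shared by the segmenters and classifiers: parameter
# initialisation, forward/backward layer wrappers around the compiled
# kernels, and an Adam optimiser. All randomness is drawn from R's RNG so a
# single set.seed() call makes every training entry point reproducible.

as_hwc <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected an H x W or H x W x C array")
  x
}

init_conv <- function(kh, kw, cin, cout) {
  # He initialisation for ReLU nets
  w <- array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
             dim = c(kh, kw, cin, cout))
  list(w = w, b = numeric(cout))
}

init_fc <- function(nin, nout) {
  list(w = matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

conv_fw <- function(x, w, b) {
  cpp_conv2d_fw(x, w, b, dim(x), dim(w))
}

conv_bw <- function(x, w, gy) {
  cpp_conv2d_bw(x, w, gy, dim(x), dim(w))
}

relu_fw <- function(z) { z[z < 0] <- 0; z }
relu_bw <- function(g, z) { g[z <= 0] <- 0; g }
sigmoid <- function(z) 1 / (1 + exp(-z))

# conv + ReLU with cache for the backward pass
convrelu_fw <- function(x, p) {
  z <- conv_fw(x, p$w, p$b)
  list(a = relu_fw(z), x = x, z = z)
}

convrelu_bw <- function(cache, p, ga) {
  gz <- relu_bw(ga, cache$z)
  conv_bw(cache$x, p$w, gz)
}

# ---- parameter collections -------------------------------------------------

# flatten every weight tensor (not biases) into one vector for L2 penalties
weight_vector <- function(params) {
  unlist(lapply(params, function(p) as.numeric(p$w)), use.names = FALSE)
}

zero_like_params <- function(params) {
  lapply(params, function(p) list(w = array(0, dim(p$w) %||% length(p$w)),
                                  b = numeric(length(p$b))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like_params(params), v = zero_like_params(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (nm in names(params)) {
    for (slot in c("w", "b")) {
      g <- grads[[nm]][[slot]]
      state$m[[nm]][[slot]] <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      state$v[[nm]][[slot]] <- beta2 * state$v[[nm]][[slot]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[slot]] / corr1
      vhat <- state$v[[nm]][[slot]] / corr2
      params[[nm]][[slot]] <- params[[nm]][[slot]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# add lambda/n * w to each weight gradient (gradient of (lambda/2n) sum w^2)
add_l2_grad <- function(grads, params, lambda_l2, n) {
  if (lambda_l2 <= 0) return(grads)
  for (nm in names(params))
    grads[[nm]]$w <- grads[[nm]]$w + lambda_l2 / n * params[[nm]]$w
  grads
}

# gradient of the pixel/tooth focal loss term wrt the logit, per element
# (no 1/n factor); gamma = 0 reduces to the BCE gradient p - y
focal_grad_logit <- function(p, y, gamma) {
  p <- clamp_prob(p)
  if (gamma == 0) return(p - y)
  y * (gamma * p * (1 - p)^gamma * log(p) - (1 - p)^(gamma + 1)) +
    (1 - y) * (p^(gamma + 1) - gamma * (1 - p) * p^gamma * log(1 - p))
}
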