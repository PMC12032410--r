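#' Discriminator (random-patch critic) configuration
#'
#' The discriminator judges realism of fixed-size patches (default 8 leads x
#' 800 samples) drawn at a random time offset once per training batch, rather
#' than of whole records: seven strided 1D-convolution layers with
#' leaky-rectifier activations feed a linear map to one score per item. With
#' the `"critic"` head the score is unbounded, as the Wasserstein objective
#' with gradient penalty expects; the `"sigmoid"` head squashes it to (0, 1)
#' for a probabilistic discriminator.
#'
#' @param patch_channels Number of leads in a patch (at most 8).
#' @param patch_samples Patch length in samples.
#' @param channels Output channels of the seven convolution layers.
#' @param kernel Kernel length.
#' @param stride Stride shared by all layers.
#' @param lrelu_slope Negative slope of the leaky rectifier.
#' @param head `"critic"` (unbounded score) or `"sigmoid"`.
#' @return A list of class `discriminator_config`.
#' @export
discriminator_config <- function(patch_channels = 8, patch_samples = 800,
                                 channels = c(64, 128, 256, 256, 512, 512, 512),
                                 kernel = 9, stride = 2, lrelu_slope = 0.2,
                                 head = c("critic", "sigmoid")) {
  head <- match.arg(head)
  if (patch_channels > 8) stop("patch_channels must be <= 8")
  if (length(channels) != 7L) stop("the discriminator has exactly 7 convolution layers")
  structure(list(patch_channels = as.integer(patch_channels),
                 patch_samples = as.integer(patch_samples),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 stride = as.integer(stride), lrelu_slope = lrelu_slope,
                 head = head),
            class = "discriminator_config")
}

#' Build a patch discriminator
#'
#' @param config A [discriminator_config()].
#' @return An object of class `ecg_discriminator`; score batches of patches
#'   with [predict()][predict.ecg_discriminator()].
#' @export
build_discriminator <- function(config) {
  stopifnot(inherits(config, "discriminator_config"))
  layers <- vector("list", 7L)
  c_prev <- config$patch_channels
  L <- config$patch_samples
  for (i in 1:7) {
    ly <- new_conv_layer(c_prev, config$channels[i], config$kernel,
                         config$stride, pad_mode = 0L, act = "lrelu")
    # symmetric zero padding, PyTorch-style floor output length
    ly$pl <- ly$pr <- (config$kernel - 1L) %/% 2L
    layers[[i]] <- ly
    L <- conv_out_len(L, ly)
    if (L < 1L) stop("patch too short for the convolution ladder")
    c_prev <- config$channels[i]
  }
  flat <- c_prev * L
  structure(list(config = config, layers = layers,
                 head = list(w = stats::rnorm(flat, 0, sqrt(1 / flat)), b0 = 0),
                 flat_dim = as.integer(flat), final_len = as.integer(L)),
            class = "ecg_discriminator")
}

#' @export
print.ecg_discriminator <- function(x, ...) {
  cat(sprintf("<ecg_discriminator> patch %d x %d, %s head, %s parameters\n",
              x$config$patch_channels, x$config$patch_samples, x$config$head,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# Forward pass; x: [patch_channels x P x B] (normalized units).
disc_fwd <- function(disc, x, keep_cache = FALSE) {
  slope <- disc$config$lrelu_slope
  zs <- if (keep_cache) vector("list", 7L)
  ins <- if (keep_cache) vector("list", 7L)
  h <- x
  for (i in 1:7) {
    if (keep_cache) ins[[i]] <- h
    z <- conv_apply(disc$layers[[i]], h)
    if (keep_cache) zs[[i]] <- z
    h <- act_fwd(z, "lrelu", slope)
  }
  B <- dim(h)[3]
  flat <- matrix(h, nrow = disc$flat_dim, ncol = B)
  s <- as.numeric(crossprod(flat, disc$head$w)) + disc$head$b0
  score <- if (disc$config$head == "sigmoid") 1 / (1 + exp(-s)) else s
  list(score = score, raw = s,
       cache = if (keep_cache) list(ins = ins, zs = zs, top = h, x = x))
}

#' Score patches
#'
#' @param object An `ecg_discriminator`.
#' @param newdata Array `[patch_channels x patch_samples x batch]` in
#'   \eqn{\mu V}-normalized units.
#' @param ... Unused.
#' @return Numeric vector of one score per batch item.
#' @export
predict.ecg_discriminator <- function(object, newdata, ...) {
  if (dim(newdata)[1] != object$config$patch_channels) {
    stop(sprintf("patch has %d channels; discriminator expects %d",
                 dim(newdata)[1], object$config$patch_channels))
  }
  disc_fwd(object, newdata)$score
}

# Backward pass from per-item score cotangents. Returns parameter grads and
# (optionally) the gradient with respect to the input patches. For the
# sigmoid head the cotangent is taken on the squashed score.
disc_bwd <- function(disc, fw, cot, need_input = FALSE, need_params = TRUE) {
  slope <- disc$config$lrelu_slope
  cache <- fw$cache
  B <- length(cot)
  if (disc$config$head == "sigmoid") {
    p <- fw$score
    cot <- cot * p * (1 - p)
  }
  grads <- NULL
  top_dim <- dim(cache$top)
  flat <- matrix(cache$top, nrow = disc$flat_dim)
  if (need_params) {
    grads <- stats::setNames(vector("list", 16L), names(collect_params(disc)))
    grads[["head.w"]] <- as.numeric(flat %*% cot)
    grads[["head.b"]] <- sum(cot)
  }
  g <- array(disc$head$w %o% cot, dim = top_dim)
  for (i in 7:1) {
    g <- act_bwd(g, cache$zs[[i]], NULL, "lrelu", slope)
    if (need_params) {
      wb <- conv_grad_wb(disc$layers[[i]], cache$ins[[i]], g)
      grads[[paste0("L", i, ".W")]] <- wb$gW
      grads[[paste0("L", i, ".b")]] <- as.numeric(wb$gb)
    }
    if (i > 1L || need_input) {
      g <- conv_grad_input(disc$layers[[i]], g, dim(cache$ins[[i]])[2])
    }
  }
  list(grads = grads, g_input = if (need_input) g)
}

# Gradient penalty at interpolates xhat: penalty = mean_b (||d D / d xhat||_2
# - 1)^2, together with its exact gradient with respect to the critic
# parameters (double backprop). The activation masks are treated as locally
# constant, which is exact almost everywhere for piecewise-linear nets.
# Biases receive no penalty gradient because the input gradient does not
# depend on them.
disc_gp <- function(disc, xhat) {
  if (disc$config$head != "critic") stop("gradient penalty requires the critic head")
  slope <- disc$config$lrelu_slope
  fw <- disc_fwd(disc, xhat, keep_cache = TRUE)
  cache <- fw$cache
  B <- dim(xhat)[3]
  # first backward: input gradient g, keeping the per-layer post-mask
  # cotangents d_i
  d <- vector("list", 7L)
  g <- array(disc$head$w %o% rep(1, B), dim = dim(cache$top))
  for (i in 7:1) {
    g <- act_bwd(g, cache$zs[[i]], NULL, "lrelu", slope)
    d[[i]] <- g
    g <- conv_grad_input(disc$layers[[i]], g, dim(cache$ins[[i]])[2])
  }
  gnorm <- sqrt(apply(g^2, 3, sum))
  penalty <- mean((gnorm - 1)^2)
  scale <- ifelse(gnorm > 1e-12, 2 * (gnorm - 1) / gnorm, 0) / B
  u <- g * rep(scale, each = prod(dim(g)[1:2]))
  # second (forward) pass of u through the masked, bias-free chain
  grads <- stats::setNames(vector("list", 16L), names(collect_params(disc)))
  v <- u
  for (i in 1:7) {
    zero_b <- numeric(disc$layers[[i]]$c_out)
    t_i <- conv1d_fwd(v, disc$layers[[i]]$W, zero_b,
                      disc$layers[[i]]$k, disc$layers[[i]]$stride,
                      disc$layers[[i]]$pl, disc$layers[[i]]$pr,
                      disc$layers[[i]]$pad_mode)
    wb <- conv_grad_wb(disc$layers[[i]], v, d[[i]])
    grads[[paste0("L", i, ".W")]] <- wb$gW
    grads[[paste0("L", i, ".b")]] <- numeric(disc$layers[[i]]$c_out)
    v <- act_bwd(t_i, cache$zs[[i]], NULL, "lrelu", slope)
  }
  grads[["head.w"]] <- as.numeric(matrix(v, nrow = disc$flat_dim) %*% rep(1, B))
  grads[["head.b"]] <- 0
  list(penalty = penalty, grads = grads)
}

#' Draw an aligned random patch pair
#'
#' One time offset is drawn per call (per training batch), shared between the
#' real and fake batches and across all channels, so the critic always
#' compares aligned windows. The offset is uniform over the valid range and
#' reproducible given the RNG state.
#'
#' @param real,fake Arrays `[channels x N x batch]` of identical shape.
#' @param config A [discriminator_config()].
#' @return A list with `real`, `fake` (the patches) and `offset` (0-based).
#' @export
random_patch <- function(real, fake, config) {
  if (!identical(dim(real), dim(fake))) stop("real and fake batches must share a shape")
  N <- dim(real)[2]
  P <- config$patch_samples
  if (P > N) stop(sprintf("patch of %d samples does not fit a %d-sample signal", P, N))
  offset <- sample.int(N - P + 1L, 1L) - 1L
  idx <- offset + seq_len(P)
  list(real = real[, idx, , drop = FALSE],
       fake = fake[, idx, , drop = FALSE],
       offset = offset)
}
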