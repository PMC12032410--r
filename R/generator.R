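#' Generator (1D U-Net) configuration
#'
#' The generator maps 1 or 2 measured leads to the remaining 7 or 6
#' independent leads with an encoder-decoder: six strided 1D-convolution
#' layers with leaky-rectifier activations on the way down, six
#' upsample-convolution layers with rectifier activations on the way up,
#' reflection padding throughout, skip connections linking down-block i to
#' up-block 6 - i, a hyperbolic-tangent output and inverted dropout on three
#' of the up blocks during training. Signals enter scaled by
#' `1 / amplitude_scale` so the tanh range corresponds to
#' (-amplitude_scale, amplitude_scale) \eqn{\mu V}.
#'
#' The time ladder uses per-layer strides whose product must divide the
#' signal length; the default (2, 2, 2, 5, 5, 5) supports both the 5000- and
#' 2000-sample geometries.
#'
#' @param input_leads 1 (lead I) or 2 (leads I and II).
#' @param n_samples Signal length the network is built for.
#' @param down_channels Output channels of the six down blocks.
#' @param up_channels Output channels of the first five up blocks (the sixth
#'   always outputs `8 - input_leads` leads).
#' @param kernel Convolution kernel length (scalar, all layers).
#' @param strides Per-down-layer stride factors (mirrored as upsampling
#'   factors on the way up).
#' @param lrelu_slope Negative slope of the leaky rectifier.
#' @param dropout_layers Indices (1..6, 1 = deepest) of the three up blocks
#'   that get dropout.
#' @param dropout_rate Dropout probability during training.
#' @param amplitude_scale \eqn{\mu V} value mapped to tanh level 1.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(input_leads = 1, n_samples = 5000,
                             down_channels = c(32, 64, 128, 256, 512, 512),
                             up_channels = c(512, 256, 128, 64, 32),
                             kernel = 15, strides = c(2, 2, 2, 5, 5, 5),
                             lrelu_slope = 0.2, dropout_layers = 1:3,
                             dropout_rate = 0.5, amplitude_scale = 6000) {
  if (!input_leads %in% 1:2) stop("input_leads must be 1 or 2")
  if (length(down_channels) != 6L || length(strides) != 6L) {
    stop("the encoder has exactly 6 layers: down_channels and strides must have length 6")
  }
  if (length(up_channels) != 5L) stop("up_channels must have length 5 (the sixth up block outputs the leads)")
  if (length(dropout_layers) != 3L) stop("dropout is applied to exactly 3 up blocks")
  check_ladder(n_samples, strides)
  structure(list(input_leads = as.integer(input_leads),
                 output_leads = 8L - as.integer(input_leads),
                 n_samples = as.integer(n_samples),
                 down_channels = as.integer(down_channels),
                 up_channels = as.integer(up_channels),
                 kernel = as.integer(kernel), strides = as.integer(strides),
                 lrelu_slope = lrelu_slope,
                 dropout_layers = as.integer(dropout_layers),
                 dropout_rate = dropout_rate,
                 amplitude_scale = amplitude_scale),
            class = "generator_config")
}

check_ladder <- function(n_samples, strides) {
  p <- prod(strides)
  if (n_samples %% p != 0) {
    stop(sprintf(paste0("signal length %d is not divisible by the stride-ladder ",
                        "product %d (strides %s); choose a length that is"),
                 n_samples, p, paste(strides, collapse = "x")))
  }
  invisible(TRUE)
}

#' Model presets
#'
#' `"full"` is the full-scale architecture (channel ladder 32..512, kernel
#' 15, 5000 samples); `"desk"` is a reduced ladder (24..96, kernel 9, 2000
#' samples) sized for CPU-minutes experiments and the test suite.
#'
#' @param preset `"full"` or `"desk"`.
#' @param input_leads 1 or 2.
#' @return A list with elements `generator` ([generator_config()]) and
#'   `discriminator` ([discriminator_config()]).
#' @export
model_preset <- function(preset = c("desk", "full"), input_leads = 1) {
  preset <- match.arg(preset)
  if (preset == "full") {
    list(generator = generator_config(input_leads = input_leads),
         discriminator = discriminator_config())
  } else {
    list(generator = generator_config(
           input_leads = input_leads, n_samples = 2000,
           down_channels = c(24, 32, 48, 64, 96, 96),
           up_channels = c(96, 64, 48, 32, 24), kernel = 9),
         discriminator = discriminator_config(
           channels = c(16, 32, 48, 64, 64, 96, 96), kernel = 9))
  }
}

#' Build a lead-reconstruction generator
#'
#' Initialises the U-Net's weights (He initialisation scaled to each layer's
#' fan-in; the output layer starts small so reconstructions begin near
#' baseline). The returned object maps `input_leads x N` signals to
#' `output_leads x N` signals via [predict()][predict.ecg_generator()]; use
#' [n_parameters()] for the trainable parameter count.
#'
#' @param config A [generator_config()].
#' @return An object of class `ecg_generator`.
#' @export
build_generator <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  dc <- config$down_channels
  uc <- c(config$up_channels, config$output_leads)
  k <- config$kernel
  layers <- vector("list", 12L)
  c_prev <- config$input_leads
  for (i in 1:6) {
    layers[[i]] <- new_conv_layer(c_prev, dc[i], k, config$strides[i],
                                  pad_mode = 1L, act = "lrelu")
    c_prev <- dc[i]
  }
  # up block i consumes upsampled previous output + skip from down block 6-i
  skip_ch <- c(dc[5:1], config$input_leads)
  up_in <- dc[6]
  for (i in 1:6) {
    act <- if (i == 6L) "tanh" else "relu"
    gain <- if (i == 6L) 0.2 else 1
    ly <- new_conv_layer(up_in + skip_ch[i], uc[i], k, stride = 1L,
                         pad_mode = 1L, act = act, init_gain = gain)
    ly$upsample <- config$strides[7L - i]
    ly$dropout <- i %in% config$dropout_layers
    layers[[6L + i]] <- ly
    up_in <- uc[i]
  }
  structure(list(config = config, layers = layers), class = "ecg_generator")
}

#' Trainable parameter count
#'
#' @param x An `ecg_generator` or `ecg_discriminator`.
#' @return Total number of trainable scalars.
#' @export
n_parameters <- function(x) {
  sum(vapply(collect_params(x), length, numeric(1)))
}

#' @export
print.ecg_generator <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ecg_generator> %d -> %d leads, N = %d, %s parameters\n",
              cfg$input_leads, cfg$output_leads, cfg$n_samples,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# Forward pass in normalized units. x: [input_leads x L x B]. Returns the
# output plus (optionally) the cache needed for backprop. Dropout masks are
# drawn from the current RNG when train = TRUE.
gen_fwd <- function(gen, x, train = FALSE, keep_cache = train) {
  cfg <- gen$config
  L0 <- dim(x)[2]
  check_ladder(L0, cfg$strides)
  slope <- cfg$lrelu_slope
  a <- vector("list", 7L)  # down outputs; a[[1]] is the input itself
  z_dn <- vector("list", 6L)
  a[[1]] <- x
  h <- x
  for (i in 1:6) {
    z <- conv_apply(gen$layers[[i]], h)
    h <- act_fwd(z, "lrelu", slope)
    if (keep_cache) z_dn[[i]] <- z
    a[[i + 1L]] <- h
  }
  z_up <- vector("list", 6L)
  in_up <- vector("list", 6L)
  masks <- vector("list", 6L)
  outs <- vector("list", 6L)
  for (i in 1:6) {
    ly <- gen$layers[[6L + i]]
    hu <- upsample_nn(h, ly$upsample)
    skip <- a[[7L - i]]
    hc <- array(0, dim = c(dim(hu)[1] + dim(skip)[1], dim(hu)[2], dim(hu)[3]))
    hc[seq_len(dim(hu)[1]), , ] <- hu
    hc[dim(hu)[1] + seq_len(dim(skip)[1]), , ] <- skip
    z <- conv_apply(ly, hc)
    o <- act_fwd(z, ly$act, slope)
    if (train && ly$dropout && cfg$dropout_rate > 0) {
      m <- array(stats::rbinom(length(o), 1, 1 - cfg$dropout_rate) /
                   (1 - cfg$dropout_rate), dim = dim(o))
      o <- o * m
      if (keep_cache) masks[[i]] <- m
    }
    if (keep_cache) {
      z_up[[i]] <- z
      in_up[[i]] <- hc
      outs[[i]] <- o
    }
    h <- o
  }
  cache <- if (keep_cache) {
    list(a = a, z_dn = z_dn, z_up = z_up, in_up = in_up, masks = masks,
         outs = outs, L0 = L0)
  }
  list(out = h, cache = cache)
}

# Backward pass: gy is the gradient on the (normalized) output. Returns the
# flat gradient list aligned with collect_params(gen).
gen_bwd <- function(gen, cache, gy) {
  cfg <- gen$config
  slope <- cfg$lrelu_slope
  grads <- vector("list", 24L)
  names(grads) <- names(collect_params(gen))
  g_a <- vector("list", 7L)  # grads on down outputs (index parallel to cache$a)
  g <- gy
  for (i in 6:1) {
    ly <- gen$layers[[6L + i]]
    if (!is.null(cache$masks[[i]])) g <- g * cache$masks[[i]]
    g <- act_bwd(g, cache$z_up[[i]], cache$outs[[i]], ly$act, slope)
    wb <- conv_grad_wb(ly, cache$in_up[[i]], g)
    grads[[paste0("L", 6L + i, ".W")]] <- wb$gW
    grads[[paste0("L", 6L + i, ".b")]] <- as.numeric(wb$gb)
    gx <- conv_grad_input(ly, g, dim(cache$in_up[[i]])[2])
    n_up <- dim(gx)[1] - dim(cache$a[[7L - i]])[1]
    g_skip <- gx[n_up + seq_len(dim(gx)[1] - n_up), , , drop = FALSE]
    g_a[[7L - i]] <- if (is.null(g_a[[7L - i]])) g_skip else g_a[[7L - i]] + g_skip
    g <- upsample_nn_bwd(gx[seq_len(n_up), , , drop = FALSE], ly$upsample)
  }
  # g currently holds the gradient on a[[7]] coming through up block 6..1
  g_a[[7L]] <- if (is.null(g_a[[7L]])) g else g_a[[7L]] + g
  for (i in 6:1) {
    ly <- gen$layers[[i]]
    g <- act_bwd(g_a[[i + 1L]], cache$z_dn[[i]], NULL, "lrelu", slope)
    wb <- conv_grad_wb(ly, cache$a[[i]], g)
    grads[[paste0("L", i, ".W")]] <- wb$gW
    grads[[paste0("L", i, ".b")]] <- as.numeric(wb$gb)
    gx <- conv_grad_input(ly, g, dim(cache$a[[i]])[2])
    g_a[[i]] <- if (is.null(g_a[[i]])) gx else g_a[[i]] + gx
  }
  list(grads = grads, g_input = g_a[[1L]])
}

#' Reconstruct missing leads with a generator
#'
#' @param object An `ecg_generator`.
#' @param newdata An [ecg_signal] containing the input lead(s), or a numeric
#'   array `[input_leads x N x batch]` in \eqn{\mu V}.
#' @param ... Unused.
#' @return For a signal input, an [ecg_signal] with the reconstructed leads;
#'   for an array, the output array `[output_leads x N x batch]` in
#'   \eqn{\mu V}.
#' @export
predict.ecg_generator <- function(object, newdata, ...) {
  cfg <- object$config
  ls <- lead_set(if (cfg$input_leads == 1L) "one_lead" else "two_lead")
  if (inherits(newdata, "ecg_signal")) {
    x <- newdata$samples[ls$input, , drop = FALSE]
    xa <- array(x, dim = c(nrow(x), ncol(x), 1L))
    y <- gen_fwd(object, xa / cfg$amplitude_scale)$out * cfg$amplitude_scale
    out <- y[, , 1L, drop = TRUE]
    if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
    rownames(out) <- ls$target
    ecg_signal(out, newdata$sampling_rate)
  } else {
    y <- gen_fwd(object, newdata / cfg$amplitude_scale)$out * cfg$amplitude_scale
    dimnames(y) <- list(ls$target, NULL, NULL)
    y
  }
}
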