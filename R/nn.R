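# Minimal reverse-mode neural-network primitives on [channels x time x batch]
# arrays, built on the compiled conv1d kernels. Only what the reconstruction
# networks need: strided 1D convolution with zero or reflection padding,
# leaky-rectifier / rectifier / tanh activations, nearest-neighbour
# upsampling, inverted dropout, and Adam with global-norm gradient clipping.

as_cube <- function(x, C, L) {
  if (length(dim(x)) == 3L) return(x)
  array(x, dim = c(C, L, 1L))
}

# split total padding k - s into left (ceil) and right (floor)
pad_split <- function(k, stride) {
  tot <- k - stride
  c(ceiling(tot / 2), floor(tot / 2))
}

new_conv_layer <- function(c_in, c_out, k, stride = 1L, pad_mode = 1L,
                           act = "lrelu", init_gain = 1) {
  sd <- init_gain * sqrt(2 / (c_in * k))
  p <- pad_split(k, stride)
  list(W = matrix(stats::rnorm(c_out * c_in * k, 0, sd), c_out),
       b = numeric(c_out),
       c_in = c_in, c_out = c_out, k = as.integer(k), stride = as.integer(stride),
       pl = as.integer(p[1]), pr = as.integer(p[2]),
       pad_mode = as.integer(pad_mode), act = act)
}

conv_out_len <- function(L, layer) {
  (L + layer$pl + layer$pr - layer$k) %/% layer$stride + 1L
}

act_fwd <- function(z, act, slope) {
  switch(act,
         lrelu = pmax(z, 0) + slope * pmin(z, 0),
         relu = pmax(z, 0),
         tanh = tanh(z),
         linear = z)
}

# gradient of the activation given pre-activation z and output a
act_bwd <- function(g, z, a, act, slope) {
  switch(act,
         lrelu = g * ifelse(z > 0, 1, slope),
         relu = g * (z > 0),
         tanh = g * (1 - a^2),
         linear = g)
}

conv_apply <- function(layer, x) {
  conv1d_fwd(x, layer$W, layer$b, layer$k, layer$stride,
             layer$pl, layer$pr, layer$pad_mode)
}

conv_grad_input <- function(layer, gy, L_in) {
  conv1d_bwd_input(gy, layer$W, layer$k, layer$stride,
                   layer$pl, layer$pr, layer$pad_mode, L_in)
}

conv_grad_wb <- function(layer, x, gy) {
  conv1d_bwd_wb(x, gy, layer$k, layer$stride, layer$pl, layer$pr, layer$pad_mode)
}

upsample_nn <- function(x, f) {
  if (f == 1L) return(x)
  x[, rep(seq_len(dim(x)[2]), each = f), , drop = FALSE]
}

upsample_nn_bwd <- function(g, f) {
  if (f == 1L) return(g)
  d <- dim(g)
  L <- d[2] %/% f
  dim(g) <- c(d[1], f, L * d[3])
  out <- g[, 1, , drop = FALSE]
  for (j in 2:f) out <- out + g[, j, , drop = FALSE]
  array(out, dim = c(d[1], L, d[3]))
}

# ---- parameter plumbing ----------------------------------------------------

# Networks store layers as lists with $W / $b (and a head with $w / $b0).
# These helpers flatten parameters and gradients into aligned flat lists so
# the optimizer stays generic.

collect_params <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    out[[paste0("L", i, ".W")]] <- net$layers[[i]]$W
    out[[paste0("L", i, ".b")]] <- net$layers[[i]]$b
  }
  if (!is.null(net$head)) {
    out[["head.w"]] <- net$head$w
    out[["head.b"]] <- net$head$b0
  }
  out
}

set_params <- function(net, params) {
  for (i in seq_along(net$layers)) {
    net$layers[[i]]$W <- params[[paste0("L", i, ".W")]]
    net$layers[[i]]$b <- params[[paste0("L", i, ".b")]]
  }
  if (!is.null(net$head)) {
    net$head$w <- params[["head.w"]]
    net$head$b0 <- params[["head.b"]]
  }
  net
}

global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

clip_grads <- function(grads, clip) {
  if (is.null(clip) || !is.finite(clip)) return(grads)
  nrm <- global_norm(grads)
  if (nrm > clip) grads <- lapply(grads, function(g) g * (clip / nrm))
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.5, beta2 = 0.9,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}
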