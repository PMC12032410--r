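#' Training configuration
#'
#' Optimization hyperparameters. The GAN uses Adam with learning rate 1e-4,
#' beta1 = 0.5, beta2 = 0.9; the pure U-Net (MSE loss) uses the smaller rate
#' 5e-5 for stability. Batch size 32 at full scale. The discriminator is
#' updated after every batch and the generator after every other batch; the
#' returned model is the epoch with minimal validation reconstruction error.
#' `lambda_gp = 10` and `lambda_l1 = 100` follow the canonical gradient
#' penalty and L1-augmented adversarial objectives (the combination used
#' here); `clip = 1` additionally clips each network's global gradient norm.
#' The `"desk"` preset (epochs 20, batch 16) pairs with
#' `model_preset("desk")` and 4 s cohorts for CPU-scale runs; `"full"` keeps
#' the full-scale schedule (1000 epochs, batch 32).
#'
#' @param preset `"desk"` or `"full"`.
#' @param epochs,batch_size,lr,beta1,beta2,lr_unet,lambda_gp,lambda_l1,clip
#'   Overrides of the preset values.
#' @param seed Integer seed governing shuffling, patch offsets, dropout and
#'   interpolates; fixed seed means bitwise-identical training histories.
#' @return A list of class `train_config`.
#' @export
train_config <- function(preset = c("desk", "full"), epochs = NULL,
                         batch_size = NULL, lr = 1e-4, beta1 = 0.5, beta2 = 0.9,
                         lr_unet = 5e-5, lambda_gp = 10, lambda_l1 = 100,
                         clip = 1, seed = 17) {
  preset <- match.arg(preset)
  epochs <- epochs %||% if (preset == "desk") 20L else 1000L
  batch_size <- batch_size %||% if (preset == "desk") 16L else 32L
  stopifnot(lr > 0, lr_unet > 0, batch_size >= 1, lambda_gp >= 0, lambda_l1 >= 0)
  structure(list(preset = preset, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr, beta1 = beta1,
                 beta2 = beta2, lr_unet = lr_unet, lambda_gp = lambda_gp,
                 lambda_l1 = lambda_l1, clip = clip, seed = as.integer(seed)),
            class = "train_config")
}

# Stack a list of records (or 12-lead signals) into normalized input/target/
# full-8-lead arrays for a given input mode.
stack_tensors <- function(records, input_mode, amplitude_scale) {
  ls <- lead_set(input_mode)
  sigs <- lapply(records, function(r) if (inherits(r, "ecg_record")) r$signal else r)
  L <- n_samples(sigs[[1]])
  B <- length(sigs)
  x <- array(0, c(length(ls$input), L, B))
  y <- array(0, c(length(ls$target), L, B))
  full <- array(0, c(8L, L, B))
  for (b in seq_len(B)) {
    s <- sigs[[b]]$samples
    x[, , b] <- s[ls$input, , drop = FALSE]
    y[, , b] <- s[ls$target, , drop = FALSE]
    full[, , b] <- s[LEADS_INDEPENDENT, , drop = FALSE]
  }
  nms <- names(records)
  ids <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    if (inherits(r, "ecg_record")) r$id
    else if (!is.null(nms) && nzchar(nms[i])) nms[i]
    else sprintf("rec_%05d", i)
  }, character(1))
  list(x = x / amplitude_scale, y = y / amplitude_scale,
       full = full / amplitude_scale, ids = ids, lead_set = ls, L = L)
}

# Insert generated target leads into a full 8-lead normalized array next to
# the true input leads (canonical independent-lead order).
assemble_fake <- function(xn, yn, ls) {
  B <- dim(xn)[3]
  full <- array(0, c(8L, dim(xn)[2], B))
  full[match(ls$input, LEADS_INDEPENDENT), , ] <- xn
  full[match(ls$target, LEADS_INDEPENDENT), , ] <- yn
  full
}

#' Wasserstein-GP + L1 losses
#'
#' Computes the discriminator and generator losses of the adversarial
#' objective: \deqn{L_D = E[D(fake)] - E[D(real)] +
#' \lambda_{gp} E[(\|\nabla_{\hat x} D(\hat x)\|_2 - 1)^2]} with
#' \eqn{\hat x = \epsilon\, real + (1-\epsilon) fake}, \eqn{\epsilon \sim
#' U(0,1)} per item, and \deqn{L_G = -E[D(fake)] + \lambda_{L1}
#' E[|real - fake|].} The expectation in the penalty uses one draw of
#' \eqn{\epsilon} per item from the current RNG state.
#'
#' @param critic An `ecg_discriminator` with the critic head.
#' @param real_patch,fake_patch Aligned patch arrays
#'   `[channels x P x batch]`.
#' @param lambda_gp,lambda_l1 Non-negative loss weights.
#' @param real_signal,fake_signal Full signal arrays for the L1 term.
#' @return A list with `loss_d`, `loss_g`, `gp` (the penalty term) and
#'   `l1` (the reconstruction term).
#' @export
wgan_gp_losses <- function(critic, real_patch, fake_patch, lambda_gp, lambda_l1,
                           real_signal, fake_signal) {
  if (!identical(dim(real_patch), dim(fake_patch))) {
    stop("real and fake patches must share a shape")
  }
  if (!identical(dim(real_signal), dim(fake_signal))) {
    stop("real and fake signals must share a shape")
  }
  B <- dim(real_patch)[3]
  eps <- stats::runif(B)
  xhat <- real_patch * rep(eps, each = prod(dim(real_patch)[1:2])) +
    fake_patch * rep(1 - eps, each = prod(dim(real_patch)[1:2]))
  s_real <- disc_fwd(critic, real_patch)$score
  s_fake <- disc_fwd(critic, fake_patch)$score
  gp <- disc_gp(critic, xhat)$penalty
  l1 <- mean(abs(real_signal - fake_signal))
  list(loss_d = mean(s_fake) - mean(s_real) + lambda_gp * gp,
       loss_g = -mean(s_fake) + lambda_l1 * l1,
       gp = gp, l1 = l1)
}

mean_l1_uv <- function(gen, xn, yn, amplitude_scale, batch = 32L) {
  B <- dim(xn)[3]
  tot <- 0
  for (i in seq(1, B, by = batch)) {
    j <- i:min(B, i + batch - 1L)
    out <- gen_fwd(gen, xn[, , j, drop = FALSE])$out
    tot <- tot + sum(abs(out - yn[, , j, drop = FALSE]))
  }
  tot / (prod(dim(yn)[1:2]) * B) * amplitude_scale
}

#' Train the GAN (adversarial + L1 objective)
#'
#' Alternating schedule: the critic's parameters are updated after every
#' batch (Wasserstein loss with gradient penalty on random aligned patches),
#' the generator's after every other batch (adversarial score plus weighted
#' L1 reconstruction loss). Per-epoch train/validation mean absolute errors
#' (\eqn{\mu V}) are recorded and the generator from the epoch with the
#' lowest validation error is returned. Fully reproducible given
#' `config$seed`.
#'
#' @param generator An `ecg_generator`.
#' @param discriminator An `ecg_discriminator` with the critic head.
#' @param splits A list with `train` and `validation` record lists (disjoint,
#'   as produced by [split_cohort()]).
#' @param config A [train_config()].
#' @param input_mode `"one_lead"` or `"two_lead"`; must match the generator.
#' @return An object of class `ecg_gan_fit`: the selected `generator`,
#'   `final_generator`, `discriminator`, a `history` tibble, update counters
#'   and the configuration.
#' @export
train_gan <- function(generator, discriminator, splits, config = train_config(),
                      input_mode = c("one_lead", "two_lead")) {
  input_mode <- match.arg(input_mode)
  stopifnot(inherits(generator, "ecg_generator"),
            inherits(discriminator, "ecg_discriminator"))
  if (discriminator$config$head != "critic") {
    stop("the Wasserstein objective requires the critic head")
  }
  if (!length(splits$train) || !length(splits$validation)) stop("empty split")
  amp <- generator$config$amplitude_scale
  tr <- stack_tensors(splits$train, input_mode, amp)
  va <- stack_tensors(splits$validation, input_mode, amp)
  withr::with_seed(config$seed, {
    g_params <- collect_params(generator)
    d_params <- collect_params(discriminator)
    g_opt <- adam_init(g_params)
    d_opt <- adam_init(d_params)
    B_tot <- dim(tr$x)[3]
    n_batches <- B_tot %/% config$batch_size
    if (config$epochs > 0 && n_batches < 1) stop("fewer records than one batch")
    history <- vector("list", config$epochs)
    best <- list(val = Inf, params = g_params, epoch = 0L)
    d_updates <- 0L; g_updates <- 0L; global_batch <- 0L
    pdim <- function(a) prod(dim(a)[1:2])
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(B_tot)
      ld_acc <- lg_acc <- 0; lg_n <- 0L
      for (bi in seq_len(n_batches)) {
        idx <- ord[(bi - 1L) * config$batch_size + seq_len(config$batch_size)]
        xb <- tr$x[, , idx, drop = FALSE]
        yb <- tr$y[, , idx, drop = FALSE]
        realb <- tr$full[, , idx, drop = FALSE]
        global_batch <- global_batch + 1L
        ## ---- discriminator step (every batch) ----
        generator <- set_params(generator, g_params)
        fake_y <- gen_fwd(generator, xb, train = TRUE, keep_cache = FALSE)$out
        fakeb <- assemble_fake(xb, fake_y, tr$lead_set)
        pat <- random_patch(realb, fakeb, discriminator$config)
        Bn <- length(idx)
        eps <- stats::runif(Bn)
        xhat <- pat$real * rep(eps, each = pdim(pat$real)) +
          pat$fake * rep(1 - eps, each = pdim(pat$real))
        discriminator <- set_params(discriminator, d_params)
        fw_r <- disc_fwd(discriminator, pat$real, keep_cache = TRUE)
        fw_f <- disc_fwd(discriminator, pat$fake, keep_cache = TRUE)
        gr_r <- disc_bwd(discriminator, fw_r, rep(-1 / Bn, Bn))$grads
        gr_f <- disc_bwd(discriminator, fw_f, rep(1 / Bn, Bn))$grads
        gp <- disc_gp(discriminator, xhat)
        d_grads <- purrr::pmap(list(gr_r, gr_f, gp$grads),
                               function(a, b, c) a + b + config$lambda_gp * c)
        d_grads <- clip_grads(d_grads, config$clip)
        stp <- adam_step(d_opt, d_params, d_grads, config$lr, config$beta1, config$beta2)
        d_opt <- stp$state; d_params <- stp$params
        loss_d <- mean(fw_f$score) - mean(fw_r$score) + config$lambda_gp * gp$penalty
        if (!is.finite(loss_d)) {
          stop(sprintf("training diverged (non-finite critic loss at epoch %d, batch %d)",
                       epoch, bi))
        }
        ld_acc <- ld_acc + loss_d
        ## ---- generator step (every other batch) ----
        if (global_batch %% 2L == 1L) {
          generator <- set_params(generator, g_params)
          fwd <- gen_fwd(generator, xb, train = TRUE, keep_cache = TRUE)
          fakeb <- assemble_fake(xb, fwd$out, tr$lead_set)
          pat <- random_patch(realb, fakeb, discriminator$config)
          discriminator <- set_params(discriminator, d_params)
          fw_f <- disc_fwd(discriminator, pat$fake, keep_cache = TRUE)
          gin <- disc_bwd(discriminator, fw_f, rep(-1 / Bn, Bn),
                          need_input = TRUE, need_params = FALSE)$g_input
          g_full <- array(0, dim = dim(fakeb))
          g_full[, pat$offset + seq_len(discriminator$config$patch_samples), ] <- gin
          g_y <- g_full[match(tr$lead_set$target, LEADS_INDEPENDENT), , , drop = FALSE]
          g_y <- g_y + config$lambda_l1 * sign(fwd$out - yb) / length(yb)
          bw <- gen_bwd(generator, fwd$cache, g_y)
          g_grads <- clip_grads(bw$grads, config$clip)
          stp <- adam_step(g_opt, g_params, g_grads, config$lr, config$beta1, config$beta2)
          g_opt <- stp$state; g_params <- stp$params
          loss_g <- -mean(fw_f$score) +
            config$lambda_l1 * mean(abs(fwd$out - yb))
          if (!is.finite(loss_g)) {
            stop(sprintf("training diverged (non-finite generator loss at epoch %d, batch %d)",
                         epoch, bi))
          }
          lg_acc <- lg_acc + loss_g; lg_n <- lg_n + 1L
          g_updates <- g_updates + 1L
        }
        d_updates <- d_updates + 1L
      }
      generator <- set_params(generator, g_params)
      train_l1 <- mean_l1_uv(generator, tr$x, tr$y, amp)
      val_l1 <- mean_l1_uv(generator, va$x, va$y, amp)
      if (val_l1 < best$val) best <- list(val = val_l1, params = g_params, epoch = epoch)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, loss_d = ld_acc / n_batches,
        loss_g = if (lg_n) lg_acc / lg_n else NA_real_,
        train_l1_uv = train_l1, val_l1_uv = val_l1,
        d_updates = d_updates, g_updates = g_updates)
    }
    structure(list(
      generator = set_params(generator, best$params),
      final_generator = set_params(generator, g_params),
      discriminator = set_params(discriminator, d_params),
      history = dplyr::bind_rows(history),
      best_epoch = best$epoch, best_val_l1_uv = best$val,
      d_updates = d_updates, g_updates = g_updates,
      config = config, input_mode = input_mode, objective = "wgan_gp_l1"),
      class = "ecg_gan_fit")
  })
}

#' Train the pure U-Net (MSE objective)
#'
#' Identical data flow without a discriminator: mean squared error on the
#' reconstructed leads, generator updated after every batch, smaller learning
#' rate (`config$lr_unet`).
#'
#' @inheritParams train_gan
#' @return An `ecg_gan_fit` (with `objective = "mse"` and no discriminator).
#' @export
train_unet <- function(generator, splits, config = train_config(),
                       input_mode = c("one_lead", "two_lead")) {
  input_mode <- match.arg(input_mode)
  if (!length(splits$train) || !length(splits$validation)) stop("empty split")
  amp <- generator$config$amplitude_scale
  tr <- stack_tensors(splits$train, input_mode, amp)
  va <- stack_tensors(splits$validation, input_mode, amp)
  withr::with_seed(config$seed, {
    g_params <- collect_params(generator)
    g_opt <- adam_init(g_params)
    B_tot <- dim(tr$x)[3]
    n_batches <- B_tot %/% config$batch_size
    if (config$epochs > 0 && n_batches < 1) stop("fewer records than one batch")
    history <- vector("list", config$epochs)
    best <- list(val = Inf, params = g_params, epoch = 0L)
    g_updates <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(B_tot)
      l_acc <- 0
      for (bi in seq_len(n_batches)) {
        idx <- ord[(bi - 1L) * config$batch_size + seq_len(config$batch_size)]
        xb <- tr$x[, , idx, drop = FALSE]
        yb <- tr$y[, , idx, drop = FALSE]
        generator <- set_params(generator, g_params)
        fwd <- gen_fwd(generator, xb, train = TRUE, keep_cache = TRUE)
        res <- fwd$out - yb
        loss <- mean(res^2)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged (non-finite MSE at epoch %d, batch %d)", epoch, bi))
        }
        bw <- gen_bwd(generator, fwd$cache, 2 * res / length(res))
        g_grads <- clip_grads(bw$grads, config$clip)
        stp <- adam_step(g_opt, g_params, g_grads, config$lr_unet,
                         config$beta1, config$beta2)
        g_opt <- stp$state; g_params <- stp$params
        l_acc <- l_acc + loss
        g_updates <- g_updates + 1L
      }
      generator <- set_params(generator, g_params)
      train_l1 <- mean_l1_uv(generator, tr$x, tr$y, amp)
      val_l1 <- mean_l1_uv(generator, va$x, va$y, amp)
      if (val_l1 < best$val) best <- list(val = val_l1, params = g_params, epoch = epoch)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, loss_mse = l_acc / n_batches,
        train_l1_uv = train_l1, val_l1_uv = val_l1, g_updates = g_updates)
    }
    structure(list(
      generator = set_params(generator, best$params),
      final_generator = set_params(generator, g_params),
      discriminator = NULL,
      history = dplyr::bind_rows(history),
      best_epoch = best$epoch, best_val_l1_uv = best$val,
      d_updates = 0L, g_updates = g_updates,
      config = config, input_mode = input_mode, objective = "mse"),
      class = "ecg_gan_fit")
  })
}

#' @export
print.ecg_gan_fit <- function(x, ...) {
  cat(sprintf("<ecg_gan_fit> %s, %s input, %d epochs; best epoch %d (val L1 %.1f uV)\n",
              x$objective, x$input_mode, nrow(x$history), x$best_epoch,
              x$best_val_l1_uv))
  invisible(x)
}

#' @export
tidy.ecg_gan_fit <- function(x, ...) x$history

#' @export
glance.ecg_gan_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, input_mode = x$input_mode,
                 epochs = nrow(x$history), best_epoch = x$best_epoch,
                 val_l1_uv = x$best_val_l1_uv,
                 d_updates = x$d_updates, g_updates = x$g_updates,
                 n_parameters = n_parameters(x$generator))
}

#' Training-history plot
#'
#' @param object An `ecg_gan_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation reconstruction error per epoch.
#' @export
autoplot.ecg_gan_fit <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("train_l1_uv", "val_l1_uv"),
                        names_to = "set", values_to = "l1_uv")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$l1_uv, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean |error| (uV)", colour = NULL)
}

#' Population-mean baseline predictor
#'
#' Ignores its input and always returns the per-lead, per-sample average of
#' the training targets: the analytic extreme of regression to the mean that
#' the evaluation suite uses as its reference point.
#'
#' @param train_records Training records (list of `ecg_record` or 12-lead
#'   signals).
#' @param input_mode `"one_lead"` or `"two_lead"`.
#' @return An object of class `ecg_mean_predictor`.
#' @export
baseline_mean_predictor <- function(train_records, input_mode = c("one_lead", "two_lead")) {
  input_mode <- match.arg(input_mode)
  tt <- stack_tensors(train_records, input_mode, 1)
  mean_y <- apply(tt$y, c(1, 2), mean)
  rownames(mean_y) <- tt$lead_set$target
  structure(list(mean_y = mean_y, input_mode = input_mode,
                 n_train = length(train_records)),
            class = "ecg_mean_predictor")
}

#' @export
predict.ecg_mean_predictor <- function(object, newdata, ...) {
  ls <- lead_set(object$input_mode)
  if (inherits(newdata, "ecg_signal")) {
    ecg_signal(object$mean_y, newdata$sampling_rate)
  } else {
    B <- dim(newdata)[3]
    array(object$mean_y, dim = c(dim(object$mean_y), B),
          dimnames = list(ls$target, NULL, NULL))
  }
}

#' Samplewise linear-regression baseline
#'
#' For each output lead, an instantaneous least-squares map
#' \eqn{y_t = \sum_j a_j x_{j,t} + b} fitted over all training time points
#' and applied samplewise: the purely mathematical information a linear
#' model can extract from the input lead(s).
#'
#' @inheritParams baseline_mean_predictor
#' @param target_leads Leads to regress on the inputs (default: the input
#'   mode's reconstruction targets; any other lead of the supplied signals,
#'   e.g. a derived limb lead, may be requested instead).
#' @return An object of class `ecg_linear_predictor` with a `coefficients`
#'   matrix (rows: intercept and input leads; columns: output leads).
#' @export
baseline_linear <- function(train_records, input_mode = c("one_lead", "two_lead"),
                            target_leads = NULL) {
  input_mode <- match.arg(input_mode)
  ls <- lead_set(input_mode)
  target_leads <- target_leads %||% ls$target
  sigs <- lapply(train_records, function(r) if (inherits(r, "ecg_record")) r$signal else r)
  X <- cbind(1, do.call(rbind, lapply(sigs, function(s) t(s$samples[ls$input, , drop = FALSE]))))
  Y <- do.call(rbind, lapply(sigs, function(s) t(s$samples[target_leads, , drop = FALSE])))
  beta <- qr.solve(crossprod(X), crossprod(X, Y))
  rownames(beta) <- c("(intercept)", ls$input)
  colnames(beta) <- target_leads
  structure(list(coefficients = beta, input_mode = input_mode,
                 target_leads = target_leads),
            class = "ecg_linear_predictor")
}

#' @export
predict.ecg_linear_predictor <- function(object, newdata, ...) {
  ls <- lead_set(object$input_mode)
  beta <- object$coefficients
  if (inherits(newdata, "ecg_signal")) {
    x <- newdata$samples[ls$input, , drop = FALSE]
    out <- t(cbind(1, t(x)) %*% beta)
    rownames(out) <- colnames(beta)
    ecg_signal(out, newdata$sampling_rate)
  } else {
    p <- dim(newdata)[1]
    B <- dim(newdata)[3]
    Y <- cbind(1, t(matrix(newdata, nrow = p))) %*% beta
    array(t(Y), dim = c(ncol(beta), dim(newdata)[2], B),
          dimnames = list(colnames(beta), NULL, NULL))
  }
}

#' Reconstruct the 12-lead ECG for every record of a cohort
#'
#' Applies a trained model (or baseline predictor) to each record's input
#' lead(s), assembles the generated leads with the true input leads into the
#' 8 independent leads, and completes the 12-lead set via
#' [assemble_12_lead()].
#'
#' @param model An `ecg_gan_fit`, `ecg_generator`, `ecg_mean_predictor` or
#'   `ecg_linear_predictor`.
#' @param records Records or 12-lead signals to reconstruct.
#' @param input_mode Input configuration; taken from the model when it
#'   carries one.
#' @return A named list of 12-lead [ecg_signal] reconstructions, keyed by
#'   record id.
#' @export
reconstruct_cohort <- function(model, records, input_mode = NULL) {
  if (inherits(model, "ecg_gan_fit")) {
    input_mode <- model$input_mode
    model <- model$generator
  }
  input_mode <- input_mode %||% model$input_mode %||%
    if (inherits(model, "ecg_generator")) {
      if (model$config$input_leads == 1L) "one_lead" else "two_lead"
    } else stop("supply input_mode")
  ls <- lead_set(input_mode)
  tt <- stack_tensors(records, input_mode, 1)
  fs <- (if (inherits(records[[1]], "ecg_record")) records[[1]]$signal
         else records[[1]])$sampling_rate
  yhat <- predict(model, tt$x)
  out <- vector("list", length(records))
  names(out) <- tt$ids
  for (b in seq_along(out)) {
    s8 <- matrix(0, 8, tt$L, dimnames = list(LEADS_INDEPENDENT, NULL))
    s8[ls$input, ] <- tt$x[, , b]
    s8[ls$target, ] <- yhat[, , b]
    out[[b]] <- assemble_12_lead(ecg_signal(s8, fs))
  }
  out
}
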