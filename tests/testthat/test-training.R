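# plain-R reference convolution for the loss oracle: zero padding, stride,
# nested loops -- deliberately independent of the package's kernels
ref_conv1d <- function(x, W, b, k, stride, p) {
  C_in <- nrow(x); L <- ncol(x)
  xp <- cbind(matrix(0, C_in, p), x, matrix(0, C_in, p))
  Lout <- (L + 2 * p - k) %/% stride + 1
  C_out <- nrow(W)
  y <- matrix(0, C_out, Lout)
  for (o in 1:C_out) for (t in 1:Lout) {
    acc <- b[o]
    for (c in 1:C_in) for (j in 1:k) {
      acc <- acc + W[o, c + C_in * (j - 1)] * xp[c, (t - 1) * stride + j]
    }
    y[o, t] <- acc
  }
  y
}

ref_critic_score <- function(disc, x) {
  h <- x
  for (ly in disc$layers) {
    z <- ref_conv1d(h, ly$W, ly$b, ly$k, ly$stride, ly$pl)
    h <- pmax(z, 0) + disc$config$lrelu_slope * pmin(z, 0)
  }
  sum(disc$head$w * as.vector(h)) + disc$head$b0
}

small_critic <- function() {
  withr::with_seed(31, build_discriminator(discriminator_config(
    patch_samples = 40, channels = c(3, 4, 4, 5, 5, 6, 6), kernel = 3)))
}

test_that("WGAN-GP losses match a straight-line reference implementation", {
  disc <- small_critic()
  set.seed(12)
  B <- 3
  real_p <- array(rnorm(8 * 40 * B), c(8, 40, B))
  fake_p <- array(rnorm(8 * 40 * B), c(8, 40, B))
  real_s <- array(rnorm(8 * 60 * B), c(8, 60, B))
  fake_s <- array(rnorm(8 * 60 * B), c(8, 60, B))
  losses <- withr::with_seed(77, wgan_gp_losses(disc, real_p, fake_p,
                                                lambda_gp = 10, lambda_l1 = 100,
                                                real_s, fake_s))
  eps <- withr::with_seed(77, stats::runif(B))
  s_real <- vapply(1:B, function(b) ref_critic_score(disc, real_p[, , b]), numeric(1))
  s_fake <- vapply(1:B, function(b) ref_critic_score(disc, fake_p[, , b]), numeric(1))
  # gradient penalty via central finite differences of the reference critic
  gp_ref <- mean(vapply(1:B, function(b) {
    xh <- eps[b] * real_p[, , b] + (1 - eps[b]) * fake_p[, , b]
    h <- 1e-5
    g <- matrix(0, 8, 40)
    for (c in 1:8) for (t in 1:40) {
      x1 <- xh; x1[c, t] <- x1[c, t] + h
      x2 <- xh; x2[c, t] <- x2[c, t] - h
      g[c, t] <- (ref_critic_score(disc, x1) - ref_critic_score(disc, x2)) / (2 * h)
    }
    (sqrt(sum(g^2)) - 1)^2
  }, numeric(1)))
  l1_ref <- mean(abs(real_s - fake_s))
  expect_equal(losses$loss_d, mean(s_fake) - mean(s_real) + 10 * gp_ref,
               tolerance = 1e-5)
  expect_equal(losses$loss_g, -mean(s_fake) + 100 * l1_ref, tolerance = 1e-7)
  expect_equal(losses$l1, l1_ref)
})

test_that("the gradient penalty vanishes for a unit-input-gradient critic", {
  disc <- small_critic()
  set.seed(13)
  xhat <- array(rnorm(8 * 40), c(8, 40, 1))
  fw <- disc_fwd(disc, xhat, keep_cache = TRUE)
  g <- disc_bwd(disc, fw, 1, need_input = TRUE, need_params = FALSE)$g_input
  # the critic is piecewise linear, so rescaling the head rescales the input
  # gradient exactly; normalize it to unit norm
  disc$head$w <- disc$head$w / sqrt(sum(g^2))
  gp <- disc_gp(disc, xhat)
  expect_equal(gp$penalty, 0, tolerance = 1e-10)
  # identical signals have zero reconstruction loss
  s <- array(rnorm(8 * 50), c(8, 50, 1))
  l <- withr::with_seed(1, wgan_gp_losses(disc, xhat, xhat, 10, 100, s, s))
  expect_equal(l$l1, 0)
})

make_split <- function(n = 12, duration = 2) {
  co <- fix_cohort_tiny(n, duration)
  list(train = co[1:(n - 4)], validation = co[(n - 3):(n - 2)],
       test = co[(n - 1):n])
}

tiny_nets <- function(L = 1000) {
  list(gen = withr::with_seed(21, build_generator(tiny_generator_config(1, L))),
       disc = withr::with_seed(22, build_discriminator(tiny_discriminator_config())))
}

test_that("the alternating update schedule is discriminator every batch, generator every other", {
  sp <- make_split(12)
  nets <- tiny_nets()
  # 8 training records / batch 4 -> 2 batches per epoch; 3 epochs -> 6 batches
  cfg <- train_config("desk", epochs = 3, batch_size = 4, seed = 2)
  fit <- train_gan(nets$gen, nets$disc, sp, cfg, "one_lead")
  E_B <- 3L * 2L
  expect_identical(fit$d_updates, E_B)
  expect_identical(fit$g_updates, as.integer(ceiling(E_B / 2)))
  # odd number of batches per epoch: alternation carries across epochs
  cfg3 <- train_config("desk", epochs = 3, batch_size = 3, seed = 2)  # 2 batches... 8 %/% 3 = 2
  cfg3$batch_size <- 8L  # 1 batch per epoch
  fit3 <- train_gan(nets$gen, nets$disc, sp, cfg3, "one_lead")
  expect_identical(fit3$d_updates, 3L)
  expect_identical(fit3$g_updates, as.integer(ceiling(3 / 2)))
})

test_that("zero-epoch training returns the initialized model and empty history", {
  sp <- make_split(12)
  nets <- tiny_nets()
  cfg <- train_config("desk", epochs = 0, batch_size = 4, seed = 2)
  fit <- train_gan(nets$gen, nets$disc, sp, cfg, "one_lead")
  expect_identical(nrow(fit$history), 0L)
  expect_equal(collect_params(fit$generator), collect_params(nets$gen))
  expect_error(train_gan(nets$gen, nets$disc, list(train = list(),
                                                   validation = sp$validation),
                         cfg, "one_lead"), "empty split")
})

test_that("training histories are bitwise reproducible under a fixed seed", {
  sp <- make_split(12)
  nets <- tiny_nets()
  cfg <- train_config("desk", epochs = 2, batch_size = 4, seed = 11)
  f1 <- train_gan(nets$gen, nets$disc, sp, cfg, "one_lead")
  f2 <- train_gan(nets$gen, nets$disc, sp, cfg, "one_lead")
  expect_identical(f1$history, f2$history)
  expect_identical(collect_params(f1$generator), collect_params(f2$generator))
})

test_that("GAN and U-Net desk runs reduce validation error below initialization", {
  sp <- make_split(18)
  nets <- tiny_nets()
  init_val <- ecgrecon:::mean_l1_uv(
    nets$gen,
    ecgrecon:::stack_tensors(sp$validation, "one_lead", 6000)$x,
    ecgrecon:::stack_tensors(sp$validation, "one_lead", 6000)$y, 6000)
  cfg <- train_config("desk", epochs = 6, batch_size = 7, seed = 3)
  fit <- train_gan(nets$gen, nets$disc, sp, cfg, "one_lead")
  expect_lt(fit$best_val_l1_uv, init_val)
  expect_true(all(is.finite(fit$history$loss_d)))

  ufit <- train_unet(nets$gen, sp, cfg, "one_lead")
  expect_lt(ufit$best_val_l1_uv, init_val)
  expect_identical(ufit$d_updates, 0L)
  # model selection returns the epoch with minimal validation error
  expect_identical(ufit$best_epoch, which.min(ufit$history$val_l1_uv))
})

test_that("the mean predictor is constant and equals the training average", {
  co <- fix_cohort_tiny(12, 2)
  mp1 <- baseline_mean_predictor(co[1], "one_lead")
  one <- predict(mp1, co[[1]]$signal)
  expect_equal(one$samples,
               co[[1]]$signal$samples[lead_set("one_lead")$target, ],
               tolerance = 1e-12)
  mp <- baseline_mean_predictor(co[1:8], "one_lead")
  p1 <- predict(mp, co[[9]]$signal)
  p2 <- predict(mp, co[[10]]$signal)
  expect_identical(p1$samples, p2$samples)  # constant regardless of input
  # mean-squared error of the constant prediction matches its closed form
  tt <- ecgrecon:::stack_tensors(co[1:8], "one_lead", 1)
  mse_pred <- mean((array(mp$mean_y, dim = dim(tt$y)) - tt$y)^2)
  mse_closed <- mean(apply(tt$y, c(1, 2), function(v) mean((v - mean(v))^2)))
  expect_equal(mse_pred, mse_closed, tolerance = 1e-12)
})

test_that("the linear baseline recovers exact linear lead maps", {
  set.seed(9)
  mk_rec <- function() {
    s8 <- matrix(rnorm(8 * 300, sd = 100), 8,
                 dimnames = list(lead_set()$independent, NULL))
    s8["V1", ] <- 2 * s8["I", ] - 0.5 * s8["II", ] + 30
    s8["V2", ] <- -1.2 * s8["I", ] + 0.8 * s8["II", ] - 10
    assemble_12_lead(ecg_signal(s8, 500))
  }
  recs <- replicate(4, mk_rec(), simplify = FALSE)
  lin <- baseline_linear(recs, "two_lead")
  expect_equal(unname(lin$coefficients[, "V1"]), c(30, 2, -0.5), tolerance = 1e-8)
  expect_equal(unname(lin$coefficients[, "V2"]), c(-10, -1.2, 0.8), tolerance = 1e-8)
  pr <- predict(lin, recs[[1]])
  expect_equal(pr$samples["V1", ], recs[[1]]$samples["V1", ], tolerance = 1e-8)

  # lead III is the exact Einthoven combination of the two inputs
  lin3 <- baseline_linear(recs, "two_lead", target_leads = "III")
  expect_equal(unname(lin3$coefficients[, "III"]), c(0, -1, 1), tolerance = 1e-8)

  # prediction at zero input is the intercept; with centered inputs the
  # intercept is the training mean of the target
  cent <- lapply(recs, function(r) {
    s <- r$samples
    s[c("I", "II"), ] <- s[c("I", "II"), ] - rowMeans(s[c("I", "II"), ])
    ecg_signal(s, 500)
  })
  linc <- baseline_linear(cent, "two_lead")
  z <- ecg_signal(matrix(0, 12, 10, dimnames = list(lead_names(recs[[1]]), NULL)), 500)
  pz <- predict(linc, z)
  tgt_mean <- rowMeans(do.call(cbind, lapply(cent, function(s)
    s$samples[lead_set("two_lead")$target, ])))
  expect_equal(pz$samples[, 1], tgt_mean, tolerance = 1e-8)
})

test_that("reconstructions keep the true input leads and derive limb leads", {
  co <- fix_cohort_tiny(12, 2)
  mp <- baseline_mean_predictor(co[1:8], "one_lead")
  rec <- reconstruct_cohort(mp, co[9:12])
  expect_length(rec, 4)
  expect_identical(names(rec), vapply(co[9:12], function(r) r$id, character(1)))
  r1 <- rec[[1]]
  expect_identical(lead_names(r1), lead_names(co[[9]]$signal))
  expect_equal(r1$samples["I", ], co[[9]]$signal$samples["I", ])
  expect_equal(r1$samples["III", ], r1$samples["II", ] - r1$samples["I", ])
})
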