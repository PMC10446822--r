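test_that("Cycle-GAN construction has the documented shapes and parameter count", {
  cfg <- train_config("cyclegan", seed = 5L)
  m <- build_cyclegan(24L, 16L, cfg)
  n <- 24; h <- 16
  count <- function(net) sum(lengths(net$W)) + sum(lengths(net$b))
  expect_equal(count(m$G1), (n * h + h) + (h * h + h) + (h * n + n))
  expect_equal(count(m$D1), (n * h + h) + (h * h + h) + (h * 1 + 1))
  # same seed, same initial weights
  m2 <- build_cyclegan(24L, 16L, cfg)
  expect_identical(m$G1$W, m2$G1$W)
  # output width N, non-negative (final rectification)
  X <- matrix(abs(rnorm(40 * 24)), 40, 24)
  out <- bcialign:::.cpp_net_forward(m$G1, X)
  expect_identical(dim(out), c(40L, 24L))
  expect_true(all(out >= 0))
  # untrained residual generator is approximately the identity
  expect_lt(mean(abs(out - X)) / mean(abs(X)), 0.5)
})

test_that("Cycle-GAN loss terms match hand-computed values", {
  cfg <- train_config("cyclegan", seed = 6L)
  m <- build_cyclegan(2L, 4L, cfg)
  # identity generators (zeroed residual nets) and constant discriminators
  m$G1 <- zero_net(m$G1)
  m$G2 <- zero_net(m$G2)
  m$D1 <- zero_net(m$D1)
  m$D2 <- zero_net(m$D2)
  m$D1$b[[3]] <- matrix(0.3, 1, 1)   # D1(x) = 0.3 for every x
  m$D2$b[[3]] <- matrix(-0.2, 1, 1)  # D2(x) = -0.2

  b0 <- rbind(c(1, 2), c(3, 0.5))
  bk <- rbind(c(2, 2), c(0, 1))
  l <- cyclegan_losses(b0, bk, m)
  # identity pair: cycle loss is exactly zero
  expect_identical(l$cyc, 0)
  expect_equal(l$adv_D1, abs(0.3 - 1) + abs(0.3 - 0), tolerance = 1e-12)
  expect_equal(l$adv_D2, abs(-0.2 - 1) + abs(-0.2 - 0), tolerance = 1e-12)
  expect_equal(l$adv_G1, abs(0.3 - 1), tolerance = 1e-12)
  expect_equal(l$adv_G2, abs(-0.2 - 1), tolerance = 1e-12)
  expect_equal(l$total_G, l$adv_G1 + l$adv_G2 + 10 * l$cyc)

  # the L2 variant changes only the deviation exponent, term by term
  l2 <- cyclegan_losses(b0, bk, m, loss_variant = "L2")
  expect_equal(l2$adv_D1, (0.3 - 1)^2 + 0.3^2, tolerance = 1e-12)
  expect_equal(l2$adv_G1, (0.3 - 1)^2, tolerance = 1e-12)
  expect_identical(l2$cyc, l$cyc)

  # a non-identity generator makes the cycle term the mean |G2(G1(x)) - x|
  m$G1$b[[3]] <- matrix(0.5, 1, 2)  # shifts both channels by +0.5
  l3 <- cyclegan_losses(b0, bk, m)
  expect_equal(l3$cyc, mean(abs(bk + 0.5 - bk)) + mean(abs(b0 + 0.5 - b0)),
               tolerance = 1e-12)
})

test_that("aligners are static pointwise maps: row permutation commutes", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  cfg <- train_config("cyclegan", seed = 7L)
  m <- build_cyclegan(32L, 16L, cfg)
  X <- day0$rates$rates[1:50, ]
  p <- sample(50)
  expect_equal(bcialign:::.cpp_net_forward(m$G1, X)[p, ],
               bcialign:::.cpp_net_forward(m$G1, X[p, ]), tolerance = 1e-12)
})

test_that("autoencoder latent discovery approaches the PCA reconstruction bound", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  lm0 <- fit_adan_latent(day0, latent_dim = 6L, aux_weight = 0,
                         epochs = 120L, seed = 3L)
  expect_identical(lm0$latent_dim, 6L)
  expect_identical(ncol(latent_project(lm0, day0$rates$rates)), 6L)
  Xn <- bcialign:::normalize_rates(day0$rates$rates, lm0$norm_scale)
  rec <- bcialign:::.cpp_net_forward(
    lm0$decoder, bcialign:::.cpp_net_forward(lm0$encoder, Xn))
  mse <- mean((rec - Xn)^2)
  pc <- prcomp(Xn, rank. = 6)
  rec_pca <- sweep(pc$x %*% t(pc$rotation), 2, colMeans(Xn), "+")
  mse_pca <- mean((rec_pca - Xn)^2)
  expect_gte(mse, mse_pca - 1e-12)       # PCA is the linear optimum
  expect_lt(mse, 1.1 * mse_pca)          # within 10% of the bound
  # training is deterministic under a fixed seed
  lm0b <- fit_adan_latent(day0, latent_dim = 6L, aux_weight = 0,
                          epochs = 120L, seed = 3L)
  expect_identical(lm0$history, lm0b$history)
  expect_identical(lm0$encoder$W, lm0b$encoder$W)
})

test_that("an identity ADAN aligner returns its input and 10-wide latents", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  lm0 <- fixture("tiny_adan_latent",
                 fit_adan_latent(day0, latent_dim = 6L, epochs = 80L,
                                 seed = 4L))
  g <- zero_net(bcialign:::.cpp_build_net(c(32L, 16L, 32L), c(3L, 0L), TRUE,
                                          1L, 0.1, 1L))
  aligner <- structure(list(G = g, latent_model = lm0,
                            scale0 = rep(1, 32), scalek = rep(1, 32)),
                       class = "adan_aligner")
  X <- day0$rates$rates[1:30, ]
  out <- adan_align(aligner, X)
  expect_equal(out$aligned_rates, X, tolerance = 1e-12)
  expect_identical(ncol(out$aligned_latents), 6L)
})

test_that("null-perturbation training leaves the generator near the identity", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  sp0 <- split_session(day0, 12L)
  fd <- fixture("tiny_full_dec", fit_day0_decoder(sp0$train, "full"))
  dayk <- perturb_to_dayk(day0, perturbation_spec(), day_index = 1L)
  spk <- split_session(dayk, 12L)
  tcfg <- train_config("cyclegan", epochs = 100L, folds = 2L, seed = 5L,
                       batch_size = 64L, hidden = 32L)
  cg <- train_cyclegan(sp0$train, spk$train, tcfg, fd)
  Xk <- spk$test$rates$rates
  al <- cyclegan_align(cg, Xk)
  # same distribution: alignment stays close to the identity in effect
  expect_lt(mean(abs(al - Xk)) / mean(abs(Xk)), 0.25)
  r2_al <- local({
    b <- bcialign:::trial_bin_ranges(spk$test, "start_to_end")
    pr <- predict(fd$decoder, al, b)
    multivariate_r2(spk$test$motor$values[attr(pr, "rows"), ], pr)
  })
  r2_un <- bcialign:::decode_r2(fd, spk$test)
  # loose bound: on this 32-channel toy session (36 training trials) the
  # adversarial fit carries ~0.1 R2 of training noise; the full-scale
  # null-perturbation contract is asserted in the acceptance suite
  expect_lt(abs(r2_al - r2_un), 0.15)
  # training history has one row per epoch, losses finite
  expect_identical(nrow(cg$history), 100L)
  expect_true(all(is.finite(cg$history)))
})

test_that("ADAN inverts a pure gain scaling of the recordings", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  sp0 <- split_session(day0, 12L)
  lm0 <- fixture("tiny_adan_latent",
                 fit_adan_latent(day0, latent_dim = 6L, epochs = 80L,
                                 seed = 4L))
  ld <- fit_day0_decoder(sp0$train, "latent", latent_model = lm0)
  # day-k: the same recordings scaled by 0.5 (inverse map is known)
  half <- manual_session(sp0$train$rates$rates * 0.5,
                         sp0$train$motor$values, trial_len = 20L)
  tcfg <- train_config("adan", epochs = 60L, folds = 2L, seed = 6L,
                       hidden = 32L)
  ad <- train_adan(sp0$train, half, tcfg, latent_model = lm0, decoder = ld)
  test_half <- sp0$test$rates$rates * 0.5
  al <- adan_align(ad, test_half)
  b <- bcialign:::trial_bin_ranges(sp0$test, "start_to_end")
  r2_of <- function(lat) {
    pr <- predict(ld$decoder, lat, b)
    multivariate_r2(sp0$test$motor$values[attr(pr, "rows"), ], pr)
  }
  r2_aligned <- r2_of(al$aligned_latents)
  r2_unaligned <- r2_of(latent_project(lm0, test_half))
  r2_self <- r2_of(latent_project(lm0, sp0$test$rates$rates))
  # recovers at least 80% of the gain-induced deficit
  expect_gte(r2_aligned - r2_unaligned, 0.8 * (r2_self - r2_unaligned))
})

test_that("training configs validate and carry the documented defaults", {
  cg <- train_config("cyclegan")
  expect_identical(cg$batch_size, 256L)
  expect_identical(cg$lr_ratio, 10)
  expect_identical(cg$epochs, 400L)
  ad <- train_config("adan")
  expect_identical(ad$batch_size, 8L)
  expect_identical(ad$lr_ratio, 0.5)
  expect_equal(cg$lr_g, 1e-4)
  expect_error(train_config("cyclegan", epochs = 0), "epochs")
  expect_error(train_config("adan", lr_g = -1))
})

test_that("channel-count mismatches are rejected up front", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  sp0 <- split_session(day0, 12L)
  short <- manual_session(sp0$train$rates$rates[, 1:20],
                          sp0$train$motor$values, trial_len = 20L)
  fd <- fixture("tiny_full_dec", fit_day0_decoder(sp0$train, "full"))
  expect_error(train_cyclegan(sp0$train, short,
                              train_config("cyclegan", folds = 1L), fd),
               "channel-count")
})
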