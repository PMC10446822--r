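test_that("factor analysis EM increases likelihood and beats a smaller model", {
  set.seed(10)
  n <- 2000
  N <- 12
  Lam <- matrix(rnorm(N * 3), N, 3)
  Z <- matrix(rnorm(n * 3), n, 3)
  X <- Z %*% t(Lam) + matrix(rnorm(n * N, sd = 0.5), n, N)
  f3 <- fit_factor_analysis(X, d = 3L)
  expect_true(all(diff(f3$loglik) > -1e-6 * abs(f3$loglik[-1])))
  f2 <- fit_factor_analysis(X, d = 2L)
  expect_gt(max(f3$loglik), max(f2$loglik))
  expect_true(all(f3$psi > 0))
  # model covariance approximates the sample covariance
  S <- cov(X) * (n - 1) / n
  Sig <- f3$loading %*% t(f3$loading) + diag(f3$psi)
  expect_lt(norm(Sig - S, "F") / norm(S, "F"), 0.1)
})

test_that("factor analysis drops zero-variance channels and defaults to d = 10", {
  set.seed(11)
  X <- cbind(matrix(rnorm(3000), 250, 12), 0.7)
  expect_message(f <- fit_factor_analysis(X, d = 3L), "zero-variance")
  expect_equal(f$loading[13, ], rep(0, 3))
  expect_identical(formals(fit_factor_analysis)$d, 10L)
})

test_that("posterior latent projection matches a direct linear-solve oracle", {
  set.seed(12)
  model <- fit_factor_analysis(matrix(rnorm(500 * 3, mean = 5), 500, 3),
                               d = 1L)
  X <- matrix(rnorm(12, mean = 5), 4, 3)
  # direct oracle: z = Lambda' (Lambda Lambda' + diag(Psi))^-1 (x - mu)
  Sig <- model$loading %*% t(model$loading) + diag(model$psi)
  oracle <- matrix(apply(X, 1, function(x)
    t(model$loading) %*% solve(Sig, x - model$mean)), ncol = 1)
  expect_lt(max(abs(fa_project(model, X) - oracle)), 1e-10)
  # x = mean -> z = 0
  expect_equal(fa_project(model, matrix(model$mean, 1)), matrix(0, 1, 1))
  # projection is linear
  A <- matrix(rnorm(9, mean = 5), 3, 3)
  B <- matrix(rnorm(9, mean = 5), 3, 3)
  expect_equal(fa_project(model, A) + fa_project(model, B),
               fa_project(model, A + B) + fa_project(model, 0 * A),
               tolerance = 1e-10)
})

test_that("orthogonal Procrustes solves identity, rotation and reflection cases", {
  set.seed(13)
  ref <- matrix(rnorm(12), 6, 2)
  expect_equal(orthogonal_procrustes(ref, ref)$O, diag(2), tolerance = 1e-10)

  rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  R <- rot(37 * pi / 180)
  pm <- orthogonal_procrustes(ref %*% R, ref)
  expect_lt(max(abs(pm$O - t(R))), 1e-10)

  # brute force over a 0.01-degree rotation grid cannot beat the SVD answer
  src <- ref %*% R
  grid <- seq(0, 2 * pi, by = 0.01 * pi / 180)
  costs <- vapply(grid, function(a) norm(src %*% rot(a) - ref, "F"),
                  numeric(1))
  expect_lte(pm$residual, min(costs) + 1e-10)
  expect_lt(abs(grid[which.min(costs)] - (2 * pi - 37 * pi / 180)),
            0.02 * pi / 180)

  # one negated column is recovered as a reflection
  src2 <- ref
  src2[, 2] <- -src2[, 2]
  pm2 <- orthogonal_procrustes(src2, ref)
  expect_equal(pm2$O, diag(c(1, -1)), tolerance = 1e-8)
  expect_lt(det(pm2$O), 0)
})

test_that("Procrustes maps are orthogonal and optimal among random rotations", {
  set.seed(14)
  src <- matrix(rnorm(60), 12, 5)
  ref <- matrix(rnorm(60), 12, 5)
  pm <- orthogonal_procrustes(src, ref)
  expect_lt(max(abs(t(pm$O) %*% pm$O - diag(5))), 1e-8)
  for (i in 1:300) {
    Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
    expect_lte(pm$residual, norm(src %*% Q - ref, "F") + 1e-10)
  }
})

test_that("PAF self-alignment preserves decoding", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  sp <- split_session(day0, 12L)
  fa0 <- fit_factor_analysis(sp$train$rates, d = 6L)
  dec <- fit_day0_decoder(sp$train, "latent", latent_model = fa0)
  r2_self <- bcialign:::decode_r2(dec, sp$test, latent_model = fa0)

  z <- paf_align(fa0, sp$train, d = 6L)
  aligner <- attr(z, "aligner")
  bounds <- bcialign:::trial_bin_ranges(sp$test, "start_to_end")
  pred <- predict(dec$decoder, paf_project(aligner, sp$test$rates$rates),
                  bounds)
  r2_aligned <- multivariate_r2(
    sp$test$motor$values[attr(pred, "rows"), , drop = FALSE], pred)
  expect_lt(abs(r2_aligned - r2_self), 0.02)

  # FA is permutation-covariant, but loading-based Procrustes needs most
  # channel identities intact: a PARTIAL permutation (20% of channels) is
  # aligned nearly as well as the identity case
  set.seed(16)
  n_ch <- ncol(day0$rates$rates)
  moved <- sample.int(n_ch, round(0.2 * n_ch))
  perm <- seq_len(n_ch)
  perm[moved] <- moved[c(seq_along(moved)[-1], 1L)]
  permuted <- manual_session(sp$train$rates$rates[, perm],
                             sp$train$motor$values, trial_len = 20L)
  zp <- paf_align(fa0, permuted, d = 6L)
  predp <- predict(dec$decoder,
                   paf_project(attr(zp, "aligner"),
                               sp$test$rates$rates[, perm]), bounds)
  r2_perm <- multivariate_r2(
    sp$test$motor$values[attr(predp, "rows"), , drop = FALSE], predp)
  expect_lt(abs(r2_perm - r2_aligned), 0.05)
})

test_that("PAF composed with the decoder is affine in the day-k rates", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  fa0 <- fixture("tiny_fa", fit_factor_analysis(day0$rates, d = 6L))
  z <- paf_align(fa0, day0, d = 6L)
  aligner <- attr(z, "aligner")
  set.seed(15)
  A <- matrix(abs(rnorm(5 * 32, 5)), 5, 32)
  B <- matrix(abs(rnorm(5 * 32, 5)), 5, 32)
  lhs <- paf_project(aligner, A) + paf_project(aligner, B)
  rhs <- paf_project(aligner, A + B) + paf_project(aligner, 0 * A)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("PAF refuses a changed channel set, naming the mismatch", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  fa0 <- fixture("tiny_fa", fit_factor_analysis(day0$rates, d = 6L))
  expect_error(paf_align(fa0, day0$rates$rates[, 1:20], d = 6L),
               "channel-count mismatch")
})
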