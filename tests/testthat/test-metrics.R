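test_that("biased MMD of a sample with itself is zero", {
  set.seed(20)
  X <- matrix(rnorm(50), 10, 5)
  expect_lt(mmd(X, X), 1e-12)
  expect_gt(mmd(X, X + 5), 0)
})

test_that("MMD matches a hand-coded double-sum oracle", {
  x <- c(0, 1, 2, 3.5, 7)
  y <- c(-1, 0.5, 2.2, 4, 9)
  w <- 10
  k <- function(a, b) exp(-(a - b)^2 / (2 * w^2))
  kxx <- kyy <- kxy <- 0
  for (i in 1:5) for (j in 1:5) {
    kxx <- kxx + k(x[i], x[j])
    kyy <- kyy + k(y[i], y[j])
    kxy <- kxy + k(x[i], y[j])
  }
  oracle <- sqrt(kxx / 25 + kyy / 25 - 2 * kxy / 25)
  expect_equal(mmd(matrix(x), matrix(y), kernel_widths = w), oracle,
               tolerance = 1e-12)
})

test_that("vectorized MMD equals the brute-force double sum on random draws", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:10, 1); m <- sample(3:10, 1); p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(m * p), m, p)
    ws <- runif(2, 0.5, 5)
    kf <- function(a, b) sum(exp(-sum((a - b)^2) / (2 * ws^2)))
    kxx <- sum(sapply(1:n, function(i2) sapply(1:n, function(j)
      kf(X[i2, ], X[j, ]))))
    kyy <- sum(sapply(1:m, function(i2) sapply(1:m, function(j)
      kf(Y[i2, ], Y[j, ]))))
    kxy <- sum(sapply(1:n, function(i2) sapply(1:m, function(j)
      kf(X[i2, ], Y[j, ]))))
    oracle2 <- kxx / n^2 + kyy / m^2 - 2 * kxy / (n * m)
    expect_equal(mmd(X, Y, ws)^2, max(oracle2, 0), tolerance = 1e-10)
    expect_equal(mmd(X, Y, ws), mmd(Y, X, ws), tolerance = 1e-12)
    # permutation of sample order is irrelevant
    expect_equal(mmd(X[sample(n), , drop = FALSE], Y, ws), mmd(X, Y, ws),
                 tolerance = 1e-12)
  }
})

test_that("MMD grows with the separation of two Gaussians", {
  set.seed(22)
  n <- 500
  base <- matrix(rnorm(n), n, 1)
  vals <- vapply(c(0, 0.5, 1, 2), function(d)
    mmd(base, matrix(rnorm(n, mean = d), n, 1), kernel_widths = 1),
    numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("MMD input validation", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(mmd(X, X, kernel_widths = 0), "positive")
  Y <- X; Y[1] <- NaN
  expect_error(mmd(X, Y), "NaN")
  expect_error(mmd(X, matrix(1, 1, 2)), "at least 2")
})

test_that("within-session MMD averages the six fold pairs and shrinks with length", {
  set.seed(23)
  X <- matrix(rnorm(160 * 3), 160, 3)
  fold_of <- as.integer(cut(1:160, 4, labels = FALSE))
  pairs <- combn(4, 2)
  oracle <- mean(apply(pairs, 2, function(p)
    mmd(X[fold_of == p[1], ], X[fold_of == p[2], ], kernel_widths = 1)))
  expect_equal(within_session_mmd(X, kernel_widths = 1), oracle,
               tolerance = 1e-12)
  expect_gte(oracle, 0)
  long <- matrix(rnorm(2000 * 3), 2000, 3)
  expect_lt(within_session_mmd(long, kernel_widths = 1),
            within_session_mmd(long[1:200, ], kernel_widths = 1))
})

test_that("between-session MMD uses matched folds and is symmetric", {
  set.seed(24)
  A <- matrix(rnorm(120 * 3), 120, 3)
  B <- matrix(rnorm(120 * 3, mean = 1), 120, 3)
  expect_lt(between_session_mmd(A, A, kernel_widths = 1), 1e-12)
  expect_equal(between_session_mmd(A, B, kernel_widths = 1),
               between_session_mmd(B, A, kernel_widths = 1),
               tolerance = 1e-12)
  fa <- as.integer(cut(1:120, 4, labels = FALSE))
  oracle <- mean(sapply(1:4, function(i)
    mmd(A[fa == i, ], B[fa == i, ], kernel_widths = 1)))
  expect_equal(between_session_mmd(A, B, kernel_widths = 1), oracle,
               tolerance = 1e-12)
})

test_that("principal angles solve constructed geometries", {
  set.seed(25)
  # identical signals: all angles zero
  X <- matrix(rnorm(200 * 5), 200, 5)
  expect_lt(max(principal_angles(X, X, d = 3L)$angles), 1e-5)

  # two orthogonal planes in 4-D: both angles 90 degrees
  C1 <- matrix(rnorm(400), 200, 2)
  C2 <- matrix(rnorm(400), 200, 2)
  X1 <- cbind(C1, 0 * C1)
  X2 <- cbind(0 * C2, C2)
  expect_equal(principal_angles(X1, X2, d = 2L)$angles, c(90, 90),
               tolerance = 1e-6)

  # planes sharing one axis with a 30-degree dihedral: angles {0, 30}
  a <- 30 * pi / 180
  B1 <- rbind(c(1, 0, 0), c(0, 1, 0))
  B2 <- rbind(c(1, 0, 0), c(0, cos(a), sin(a)))
  Y1 <- C1 %*% B1
  Y2 <- C2 %*% B2
  res <- principal_angles(Y1, Y2, d = 2L)
  expect_equal(res$angles, c(0, 30), tolerance = 1e-6)
  expect_true(!is.unsorted(res$angles))
})

test_that("principal angles are invariant to re-basing a spanning set", {
  set.seed(26)
  C <- matrix(rnorm(300 * 3), 300, 3)
  B <- matrix(rnorm(18), 3, 6)
  Xk <- matrix(rnorm(300 * 6), 300, 6)
  a1 <- principal_angles(C %*% B, Xk, d = 3L)$angles
  M <- matrix(rnorm(9), 3, 3)  # invertible mixing of the same sources
  a2 <- principal_angles((C %*% M) %*% B, Xk, d = 3L)$angles
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("shuffle surrogates preserve marginals and are reproducible", {
  set.seed(27)
  X0 <- matrix(rnorm(200 * 6), 200, 6)
  Xk <- matrix(rnorm(200 * 6), 200, 6)
  set.seed(99)
  b1 <- surrogate_angle_bound(X0, Xk, d = 3L, n_pairs = 150L)
  set.seed(99)
  b2 <- surrogate_angle_bound(X0, Xk, d = 3L, n_pairs = 150L)
  expect_identical(b1, b2)
  expect_true(all(b1 >= 0 & b1 <= 90))
  expect_warning(surrogate_angle_bound(X0, Xk, d = 3L, n_pairs = 50L),
                 "unstable")
  # a column shuffle leaves each channel's values (hence marginals) intact
  shuffled <- apply(X0, 2, sample)
  expect_equal(apply(shuffled, 2, sort), apply(X0, 2, sort))
})

test_that("within-day bound splits by trial parity", {
  set.seed(28)
  block <- matrix(abs(rnorm(20 * 4, 5)), 20, 4)
  # even-numbered trials duplicate odd-numbered ones -> identical halves
  rates <- rbind(block, block, block, block)
  sess <- manual_session(rates[c(1:20, 1:20, 21:40, 21:40), ],
                         matrix(rnorm(160), 80, 2), trial_len = 20L)
  expect_lt(max(within_day_angle_bound(sess, d = 2L)), 1e-5)
})

test_that("PETH means and standard errors match hand arithmetic", {
  # two trials, one condition, two channels
  r1 <- cbind(c(1, 2, 3, 4), c(0, 1, 0, 1))
  r2 <- cbind(c(3, 2, 5, 4), c(2, 1, 2, 1))
  rates <- rbind(r1, r2)
  tr <- trial_table(start_time = c(0, 0.2), go_cue_time = c(0, 0.2),
                    end_time = c(0.2, 0.4), condition_label = c("a", "a"))
  out <- peth(rate_array(rates), tr, align_event = "start",
              window = c(0, 0.2))
  expect_equal(out$a$mean, (r1 + r2) / 2)
  # sample SD of two values is |diff|/sqrt(2); SE divides by sqrt(2) again
  expect_equal(out$a$se, abs(r1 - r2) / 2, tolerance = 1e-12)
  expect_identical(out$a$n_trials, 2L)

  # identical trials: zero standard error
  out2 <- peth(rate_array(rbind(r1, r1)), tr, window = c(0, 0.2))
  expect_equal(out2$a$se, 0 * r1)

  # window clipped at the recording edge, with per-bin counts bookkept
  out3 <- peth(rate_array(rates), tr, window = c(-0.1, 0.2))
  expect_identical(out3$a$n, c(1L, 1L, 2L, 2L, 2L, 2L))
  expect_true(all(is.na(out3$a$se[1, ])))
})
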