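test_that("simulation is bit-reproducible under a fixed seed", {
  s1 <- simulate_day0(tiny_cfg(seed = 9L))
  s2 <- simulate_day0(tiny_cfg(seed = 9L))
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$rates$rates, s2$rates$rates)
  expect_identical(s1$ground_truth$latents, s2$ground_truth$latents)
  s3 <- simulate_day0(tiny_cfg(seed = 10L))
  expect_false(identical(s1$rates$rates, s3$rates$rates))
})

test_that("center-out task is balanced across 8 conditions", {
  s <- simulate_day0(tiny_cfg())
  counts <- table(s$trials$condition_label)
  expect_identical(length(counts), 8L)
  expect_lte(diff(range(counts)), 1)
})

test_that("without noise the day-0 full decoder is nearly perfect", {
  cfg <- tiny_cfg(noise = "none", n_trials = 40L)
  day0 <- simulate_day0(cfg)
  sp <- split_session(day0, 10L)
  fit <- fit_day0_decoder(sp$train, "full")
  expect_gt(bcialign:::decode_r2(fit, sp$test), 0.95)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_channels = 4, latent_dim = 10), "n_channels")
  expect_error(sim_config(trial_len_bins = 3), "trial_len")
  expect_error(perturbation_spec(dropout_frac = 2))
  expect_error(perturbation_spec(gain_sd = -1))
})

test_that("identity perturbation leaves day-k statistically close to day-0", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  dayk <- perturb_to_dayk(day0, perturbation_spec(), day_index = 1L)
  within <- within_session_mmd(day0$rates$rates)
  between <- between_session_mmd(day0$rates$rates, dayk$rates$rates)
  expect_lt(between, 2 * within)
  # fresh trials, not transformed copies
  expect_false(identical(day0$rates$rates, dayk$rates$rates))
})

test_that("nonzero perturbations separate sessions far beyond within-day variability", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  # margin 1.2 rather than the asymptotic "far beyond": within-session MMD
  # on these short toy sessions is itself sizeable
  for (spec in list(perturbation_spec(gain_sd = 0.3),
                    perturbation_spec(channel_permutation = TRUE),
                    perturbation_spec(nonlinearity = 1))) {
    dayk <- perturb_to_dayk(day0, spec, day_index = 1L)
    expect_gt(between_session_mmd(day0$rates$rates, dayk$rates$rates),
              1.2 * within_session_mmd(day0$rates$rates))
  }
})

test_that("channel permutation breaks the frozen decoder but its inverse restores it", {
  cfg <- sim_config(n_trials = 120L, trial_len_bins = 26L, mean_rate = 20,
                    seed = 13L)
  day0 <- simulate_day0(cfg)
  sp0 <- split_session(day0, 40L)
  fd <- fit_day0_decoder(sp0$train, "full")
  dayk <- perturb_to_dayk(day0, perturbation_spec(channel_permutation = TRUE))
  spk <- split_session(dayk, 40L)
  sameday <- fit_day0_decoder(spk$train, "full")
  r2_sd <- bcialign:::decode_r2(sameday, spk$test)
  r2_un <- bcialign:::decode_r2(fd, spk$test)
  expect_lt(performance_drop(r2_un, r2_sd), -0.3)

  bounds <- bcialign:::trial_bin_ranges(spk$test, "start_to_end")
  pr <- predict(fd$decoder, oracle_align(spk$test), bounds)
  r2_or <- multivariate_r2(spk$test$motor$values[attr(pr, "rows"), ], pr)
  expect_gt(performance_drop(r2_or, r2_sd), -0.05)
})

test_that("the stored inverse map is exact for invertible perturbations", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  spec <- perturbation_spec(channel_permutation = TRUE, gain_sd = 0.2,
                            baseline_mag = 2)
  dayk <- perturb_to_dayk(day0, spec, day_index = 1L)
  gt <- dayk$ground_truth
  expect_identical(gt$inverse$type, "linear")
  # applying the forward observation change to the inverted rates recovers
  # the observed day-k rates exactly (compared in unpermuted coordinates;
  # entries clamped at zero by the inverse are excluded)
  inv <- oracle_align(dayk)
  fwd <- sweep(sweep(inv, 2L, gt$gain, "*"), 2L, gt$beta, "+")
  observed_unperm <- dayk$rates$rates[, order(gt$perm), drop = FALSE]
  keep <- inv > 1e-9
  expect_lt(max(abs(fwd[keep] - observed_unperm[keep])), 1e-9)
  # non-invertible components fall back to latent reconstruction
  dayk2 <- perturb_to_dayk(day0, perturbation_spec(dropout_frac = 0.2))
  expect_identical(dayk2$ground_truth$inverse$type, "latent")
  expect_identical(dim(oracle_align(dayk2)), dim(dayk2$rates$rates))
})

test_that("gain drift worsens the unaligned decoder monotonically across days", {
  cfg <- tiny_cfg(seed = 14L, n_trials = 72L)
  day0 <- simulate_day0(cfg)
  sp0 <- split_session(day0, 24L)
  fd <- fit_day0_decoder(sp0$train, "full")
  spec <- perturbation_spec(gain_sd = 0.25)
  r2s <- vapply(c(1L, 3L, 6L), function(di) {
    dayk <- perturb_to_dayk(day0, spec, day_index = di)
    bcialign:::decode_r2(fd, split_session(dayk, 24L)$test)
  }, numeric(1))
  expect_true(all(diff(r2s) < 0))
})

test_that("channel drop-out silences and appearance activates reserved channels", {
  day0 <- fixture("tiny_day0", simulate_day0(tiny_cfg()))
  dayk <- perturb_to_dayk(day0, perturbation_spec(dropout_frac = 0.25,
                                                  appearance_frac = 0.1))
  gt <- dayk$ground_truth
  expect_identical(length(gt$dropped), 8L)
  expect_lt(max(colMeans(dayk$rates$rates)[gt$dropped]), 0.5)
  # appeared channels come from the reserved near-silent pool first
  expect_true(all(day0$ground_truth$silent_channels %in% gt$appeared))
  expect_gt(min(colMeans(dayk$rates$rates)[gt$appeared]),
            max(colMeans(day0$rates$rates)[day0$ground_truth$silent_channels]))
})
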