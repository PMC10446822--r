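#' Simulator configuration
#'
#' Describes a synthetic 96-channel recording session: low-dimensional
#' latent trajectories drive the channels through a loading map, a
#' softplus rate nonlinearity and count noise, while a known linear
#' readout of the latents produces the motor outputs.  Defaults emulate a
#' Utah-array session on an 8-target center-out task: 96 channels, a 10-d
#' latent state, 50 ms bins, multiunit Poisson spiking around ~20 Hz, and a small
#' fraction of near-silent channels (available for later "new unit
#' appears" perturbations).
#'
#' @param n_channels Number of recorded channels (default 96).
#' @param latent_dim Latent dimensionality (default 10).
#' @param n_trials Number of trials (default 160, e.g. a 120-trial
#'   training set plus a 40-trial held-out test set).
#' @param trial_len_bins Bins per trial (default 26, i.e. 1.3 s).
#' @param task `"center_out_8"` (8 equally spaced targets, block
#'   randomized) or `"random_target"` (uniformly random directions).
#' @param noise `"poisson"` (counts drawn per bin then kernel-smoothed),
#'   `"gaussian"` (additive rate noise of S.D. `noise_sd` Hz) or `"none"`.
#' @param noise_sd Gaussian rate noise S.D., Hz.
#' @param bin_width Bin width, seconds.
#' @param mean_rate Approximate mean firing rate, Hz (sets the rate scale).
#' @param silent_frac Fraction of near-silent channels.
#' @param seed RNG seed; a fixed seed reproduces the session bit for bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 96L, latent_dim = 10L, n_trials = 160L,
                       trial_len_bins = 26L,
                       task = c("center_out_8", "random_target"),
                       noise = c("poisson", "gaussian", "none"),
                       noise_sd = 2, bin_width = 0.05, mean_rate = 20,
                       silent_frac = 0.05, seed = 1L) {
  task <- match.arg(task)
  noise <- match.arg(noise)
  stopifnot(n_channels >= latent_dim, trial_len_bins >= 6L, n_trials >= 1L)
  structure(list(n_channels = as.integer(n_channels),
                 latent_dim = as.integer(latent_dim),
                 n_trials = as.integer(n_trials),
                 trial_len_bins = as.integer(trial_len_bins),
                 task = task, noise = noise, noise_sd = noise_sd,
                 bin_width = bin_width, mean_rate = mean_rate,
                 silent_frac = silent_frac, seed = as.integer(seed)),
            class = "sim_config")
}

# smooth per-trial latent trajectories; first two dims are direction-tuned
# movement commands, a few dims carry condition-independent temporal
# structure, the rest are low-pass noise
sim_latents <- function(cfg, rng_ready = FALSE) {
  tl <- cfg$trial_len_bins
  nt <- cfg$n_trials
  d <- cfg$latent_dim
  u <- (seq_len(tl) - 0.5) / tl
  bell <- sin(pi * u)^2
  ramp <- u
  swing <- cos(pi * u)
  if (cfg$task == "center_out_8") {
    per_block <- ceiling(nt / 8)
    cond <- unlist(lapply(seq_len(per_block), function(b) sample.int(8L)))
    cond <- cond[seq_len(nt)]
    theta <- (cond - 1) * pi / 4
  } else {
    theta <- stats::runif(nt, 0, 2 * pi)
    cond <- round(theta * 180 / pi, 1)
  }
  smooth_noise <- function(n, sd) {
    x <- stats::rnorm(n + 4L, 0, sd)
    stats::filter(x, rep(1 / 5, 5), sides = 2)[3:(n + 2L)]
  }
  Z <- matrix(0, nt * tl, d)
  for (i in seq_len(nt)) {
    rows <- (i - 1L) * tl + seq_len(tl)
    # direction-dependent movement vigor and timing: reaches in different
    # directions involve different muscles and postures, so their speed
    # profiles differ systematically (a stable property of the behavior,
    # identical across simulated days)
    vigor <- 1 + 0.3 * cos(theta[i] - 0.8)
    sharp <- 1 + 0.5 * sin(theta[i] + 0.5)^2
    prof <- bell^sharp
    amp <- vigor * stats::rnorm(1, 1, 0.1)
    Z[rows, 1] <- amp * cos(theta[i]) * prof
    Z[rows, 2] <- amp * sin(theta[i]) * prof
    if (d >= 3) Z[rows, 3] <- amp * prof
    if (d >= 4) Z[rows, 4] <- ramp
    if (d >= 5) Z[rows, 5] <- swing * amp
    if (d >= 6) for (j in 6:d) Z[rows, j] <- smooth_noise(tl, 0.5)
  }
  Z <- Z + matrix(smooth_noise(nrow(Z) * d, 0.15), nrow(Z), d)
  list(Z = Z, cond = cond, theta = theta)
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

# channel rates (Hz) under an observation model
sim_channel_rates <- function(Z, loading, baseline, rate_scale) {
  rate_scale * softplus(Z %*% t(loading) +
                          matrix(baseline, nrow(Z), length(baseline),
                                 byrow = TRUE))
}

observe_session <- function(lambda_hz, motor_values, cond, cfg, day_index,
                            gt) {
  bw <- cfg$bin_width
  tl <- cfg$trial_len_bins
  nt <- cfg$n_trials
  counts <- NULL
  if (cfg$noise == "poisson") {
    cmat <- matrix(stats::rpois(length(lambda_hz), lambda_hz * bw),
                   nrow(lambda_hz), ncol(lambda_hz))
    counts <- spike_count_array(cmat, bw)
    rates <- smooth_counts(counts)
  } else if (cfg$noise == "gaussian") {
    noisy <- pmax(lambda_hz + matrix(stats::rnorm(length(lambda_hz), 0,
                                                  cfg$noise_sd),
                                     nrow(lambda_hz), ncol(lambda_hz)), 0)
    rates <- rate_array(noisy, bw)
  } else {
    rates <- rate_array(lambda_hz, bw)
  }
  start <- (seq_len(nt) - 1L) * tl * bw
  trials <- trial_table(start_time = start, go_cue_time = start,
                        end_time = start + tl * bw,
                        condition_label = cond, success = TRUE)
  motor <- motor_output(motor_values, kind = "velocity",
                        dim_labels = c("vx", "vy"))
  session_recording(rates, motor, trials, day_index = day_index,
                    task_tag = cfg$task, counts = counts, ground_truth = gt)
}

#' Simulate a day-0 session
#'
#' Draws the day-0 observation model (loading map, baselines, channel
#' gains, a reserved set of near-silent channels), generates smooth
#' trial-structured latent trajectories, emits channel rates through
#' `rate_scale * softplus(latents %*% t(loading) + baseline)` with the
#' configured count noise, smooths counts with [smooth_counts()], and
#' reads out 2-d hand velocity from the first two latents.  All ground
#' truth (latents, loading, readout, noise model) is stored in the
#' session's `ground_truth` field.
#'
#' @param cfg A [sim_config()].
#' @return A [session_recording] with `day_index = 0`.
#' @export
simulate_day0 <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  N <- cfg$n_channels
  d <- cfg$latent_dim
  gain <- exp(stats::rnorm(N, 0, 0.4))
  loading <- matrix(stats::rnorm(N * d, 0, 1 / sqrt(d)), N, d) * gain
  baseline <- stats::rnorm(N, 0.5, 0.7)
  n_silent <- round(cfg$silent_frac * N)
  silent <- if (n_silent > 0) sample.int(N, n_silent) else integer(0)
  loading[silent, ] <- loading[silent, , drop = FALSE] * 0.02
  baseline[silent] <- -4
  rate_scale <- cfg$mean_rate / softplus(0.5)

  lat <- sim_latents(cfg)
  lambda <- sim_channel_rates(lat$Z, loading, baseline, rate_scale)
  vel_scale <- 10
  readout <- rbind(c(vel_scale, 0, rep(0, d - 2)),
                   c(0, vel_scale, rep(0, d - 2)))
  motor <- lat$Z %*% t(readout)
  if (cfg$noise != "none")
    motor <- motor + matrix(stats::rnorm(length(motor), 0, 0.03 * vel_scale),
                            nrow(motor), 2)
  gt <- list(latents = lat$Z, loading = loading, baseline = baseline,
             rate_scale = rate_scale, readout = readout,
             silent_channels = silent, vel_scale = vel_scale,
             cfg = unclass(cfg))
  observe_session(lambda, motor, lat$cond, cfg, 0L, gt)
}

#' Specification of a day-k recording perturbation
#'
#' Describes how the observation model changes between day-0 and day-k
#' while the latent behavior stays the same: the recorded coordinates
#' drift, the movement intent does not.  All components compose; an empty
#' spec is the identity.  Scalar magnitudes scale linearly with
#' `day_index`, giving a simple drift schedule across simulated days.
#'
#' @param channel_permutation Permute channels (logical).  A fraction
#'   `permute_frac` of the channels is remapped in a random cycle,
#'   emulating signals migrating between electrodes; the rest keep their
#'   identity, as on a chronically implanted array where turnover affects
#'   a subset of electrodes between sessions.
#' @param permute_frac Fraction of channels involved in the permutation
#'   (default 0.3).
#' @param mixing Sub-channel turnover: each channel's multiunit signal
#'   leaks into the channel by a near-identity non-negative mixing matrix
#'   `M = (1 - mixing) I + mixing S`, with `S` spreading each channel's
#'   incoming weight over two random source channels.  Emulates units
#'   waxing, waning and migrating between electrodes without any channel
#'   disappearing outright; this left-multiplies the loading map by a
#'   non-orthogonal matrix, which is precisely the regime where an
#'   orthogonal subspace alignment is systematically wrong while a
#'   near-identity nonlinear aligner remains learnable.
#' @param gain_sd Log-normal S.D. of per-channel multiplicative gain drift.
#' @param baseline_mag Maximum per-channel additive baseline shift, Hz
#'   (drawn uniformly in `[0, baseline_mag]`).
#' @param rotation_angle Rotation, degrees, applied to the latent loading
#'   map over successive latent-dimension pairs.
#' @param dropout_frac Fraction of channels silenced ("neuron drop-out").
#' @param appearance_frac Fraction of channels gaining new units: day-0
#'   near-silent channels (preferentially) receive fresh loadings.
#' @param nonlinearity Strength of a per-channel pointwise saturating
#'   distortion of the rate function: each channel's rate is squashed
#'   through `cap * tanh(rate / cap)` with a per-channel cap drawn between
#'   its day-0 90th-percentile rate (mild) and a third of it (severe) as
#'   the strength rises from 0 to 1.  Saturation bends the manifold
#'   differentially along latent directions, the regime where linear
#'   subspace alignment degrades.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(channel_permutation = FALSE,
                              permute_frac = 0.3, mixing = 0, gain_sd = 0,
                              baseline_mag = 0, rotation_angle = 0,
                              dropout_frac = 0, appearance_frac = 0,
                              nonlinearity = 0) {
  stopifnot(gain_sd >= 0, baseline_mag >= 0, dropout_frac >= 0,
            dropout_frac <= 1, appearance_frac >= 0, appearance_frac <= 1,
            nonlinearity >= 0, permute_frac >= 0, permute_frac <= 1,
            mixing >= 0, mixing < 1)
  structure(list(channel_permutation = isTRUE(channel_permutation),
                 permute_frac = permute_frac, mixing = mixing,
                 gain_sd = gain_sd, baseline_mag = baseline_mag,
                 rotation_angle = rotation_angle,
                 dropout_frac = dropout_frac,
                 appearance_frac = appearance_frac,
                 nonlinearity = nonlinearity),
            class = "perturbation_spec")
}

# rotation by `angle` degrees in successive latent-dimension planes
plane_rotation <- function(d, angle) {
  R <- diag(d)
  a <- angle * pi / 180
  for (p in seq(1L, d - 1L, by = 2L)) {
    G <- diag(d)
    G[p, p] <- cos(a); G[p + 1L, p + 1L] <- cos(a)
    G[p, p + 1L] <- -sin(a); G[p + 1L, p] <- sin(a)
    R <- R %*% G
  }
  R
}

#' Generate a perturbed day-k session
#'
#' Regenerates fresh trials from the same latent process (new random
#' draws, so day-k is an unpaired sample, as in real cross-day data — the
#' latent behavioral statistics are unchanged) and observes them through
#' the perturbed model: loading rotation, per-channel gain and baseline
#' drift, optional pointwise nonlinearity, channel drop-out (silencing),
#' channel appearance, and finally channel permutation.  When only
#' permutation, gain and baseline are active, the exact rate-space inverse
#' map is stored in the ground truth (`inverse$type = "linear"`);
#' otherwise the day-0 rates reconstructed from the true latents serve as
#' the oracle reference (`"latent"`).
#'
#' @param day0 The day-0 [session_recording] from [simulate_day0()] (its
#'   ground truth supplies the base observation model).
#' @param spec A [perturbation_spec()].
#' @param day_index Simulated day offset (scales drift magnitudes).
#' @param cfg Optional [sim_config()]; defaults to the one stored in the
#'   day-0 ground truth (pass a modified config to change e.g.
#'   `n_trials`).
#' @param seed RNG seed for the day-k draws (default derived from
#'   `cfg$seed` and `day_index`).
#' @return A day-k [session_recording] with ground truth including the
#'   realized perturbation and (when it exists) its inverse.
#' @export
perturb_to_dayk <- function(day0, spec = perturbation_spec(), day_index = 1L,
                            cfg = NULL, seed = NULL) {
  gt0 <- day0$ground_truth
  if (is.null(gt0)) stop("day0 must carry simulator ground truth")
  if (is.null(cfg)) {
    cfg <- gt0$cfg
    cfg$n_channels <- as.integer(cfg$n_channels)
    cfg$latent_dim <- as.integer(cfg$latent_dim)
    cfg$n_trials <- as.integer(cfg$n_trials)
    cfg$trial_len_bins <- as.integer(cfg$trial_len_bins)
    cfg$seed <- as.integer(cfg$seed)
    class(cfg) <- "sim_config"
  }
  if (is.null(seed)) seed <- cfg$seed + 7919L * as.integer(day_index)
  set.seed(seed)
  N <- cfg$n_channels
  d <- cfg$latent_dim
  mag <- abs(day_index)

  loading <- gt0$loading
  baseline <- gt0$baseline
  R <- NULL
  if (spec$rotation_angle != 0) {
    R <- plane_rotation(d, spec$rotation_angle * mag)
    loading <- loading %*% R
  }
  gain <- rep(1, N)
  if (spec$gain_sd > 0) gain <- exp(stats::rnorm(N, 0, spec$gain_sd * mag))
  beta <- rep(0, N)
  if (spec$baseline_mag > 0)
    beta <- stats::runif(N, 0, spec$baseline_mag * mag)
  sat_frac <- rep(Inf, N)
  if (spec$nonlinearity > 0)
    sat_frac <- 1 - spec$nonlinearity * stats::runif(N, 0, 2 / 3)
  appear <- integer(0)
  if (spec$appearance_frac > 0) {
    n_app <- round(spec$appearance_frac * N)
    pool <- gt0$silent_channels
    appear <- c(pool, sample(setdiff(seq_len(N), pool)))[seq_len(n_app)]
    loading[appear, ] <- matrix(stats::rnorm(length(appear) * d, 0,
                                             1 / sqrt(d)),
                                length(appear), d) *
      exp(stats::rnorm(length(appear), 0, 0.4))
    baseline[appear] <- stats::rnorm(length(appear), 0.5, 0.7)
  }
  dropped <- integer(0)
  if (spec$dropout_frac > 0) {
    n_drop <- round(spec$dropout_frac * N)
    dropped <- sample(setdiff(seq_len(N), appear), n_drop)
  }
  perm <- seq_len(N)
  if (spec$channel_permutation) {
    n_perm <- max(2L, round(spec$permute_frac * N))
    moved <- sample.int(N, n_perm)
    perm[moved] <- moved[c(seq_len(n_perm)[-1L], 1L)]  # one random cycle
  }

  M <- NULL
  if (spec$mixing > 0) {
    eps <- min(spec$mixing * mag, 0.9)
    M <- diag(1 - eps, N)
    for (j in seq_len(N)) {
      src <- sample(setdiff(seq_len(N), j), 2L)
      M[j, src] <- eps * c(0.6, 0.4)
    }
  }

  lat <- sim_latents(cfg)
  lambda <- sim_channel_rates(lat$Z, loading, baseline, gt0$rate_scale)
  if (!is.null(M)) lambda <- lambda %*% t(M)
  lambda <- sweep(lambda, 2L, gain, "*")
  lambda <- sweep(lambda, 2L, beta, "+")
  if (spec$nonlinearity > 0) {
    q90 <- apply(lambda, 2L, stats::quantile, probs = 0.9, names = FALSE)
    cap <- pmax(q90 * sat_frac, 1e-3)
    lambda <- sweep(tanh(sweep(lambda, 2L, cap, "/")), 2L, cap, "*")
  }
  if (length(dropped)) lambda[, dropped] <- 0.1
  lambda <- lambda[, perm, drop = FALSE]

  motor <- lat$Z %*% t(gt0$readout)
  if (cfg$noise != "none")
    motor <- motor + matrix(stats::rnorm(length(motor), 0,
                                         0.03 * gt0$vel_scale),
                            nrow(motor), 2)

  linear_ok <- spec$rotation_angle == 0 && spec$nonlinearity == 0 &&
    spec$dropout_frac == 0 && spec$appearance_frac == 0
  inverse <- if (linear_ok) {
    list(type = "linear", perm = perm, gain = gain, beta = beta,
         mixing = M)
  } else {
    list(type = "latent")
  }
  gt <- list(latents = lat$Z, loading = loading, baseline = baseline,
             rate_scale = gt0$rate_scale, readout = gt0$readout,
             vel_scale = gt0$vel_scale,
             day0_loading = gt0$loading, day0_baseline = gt0$baseline,
             perturbation = unclass(spec), perm = perm, gain = gain,
             beta = beta, rotation = R, sat_frac = sat_frac,
             dropped = dropped, appeared = appear, inverse = inverse,
             cfg_seed = seed)
  observe_session(lambda, motor, lat$cond, cfg, as.integer(day_index), gt)
}

#' Oracle alignment from simulator ground truth
#'
#' The alignment upper bound every trained aligner is scored against.  For
#' invertible perturbations (permutation, gain, baseline) the stored exact
#' inverse is applied to the observed day-k rates; otherwise the noise-free
#' day-0 rates are reconstructed from the true day-k latents through the
#' day-0 observation model.
#'
#' @param dayk_session A [perturb_to_dayk()] session with ground truth.
#' @return Matrix `T x N` of day-0-coordinate rates.
#' @export
oracle_align <- function(dayk_session) {
  gt <- dayk_session$ground_truth
  if (is.null(gt) || is.null(gt$inverse)) stop("no ground-truth inverse")
  if (identical(gt$inverse$type, "linear")) {
    X <- dayk_session$rates$rates
    inv_perm <- order(gt$perm)
    X <- X[, inv_perm, drop = FALSE]
    X <- sweep(X, 2L, gt$beta, "-")
    X <- sweep(X, 2L, gt$gain, "/")
    M <- gt$inverse$mixing
    if (!is.null(M)) X <- t(solve(M, t(X)))
    pmax(X, 0)
  } else {
    sim_channel_rates(gt$latents, gt$day0_loading, gt$day0_baseline,
                      gt$rate_scale)
  }
}
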