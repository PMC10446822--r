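# Shared fixtures: everything is generated in code, sized for speed.

# memoise expensive fixtures across test files within one run
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small simulated recording: 32 channels, 6 latents, 48 trials of 1 s
tiny_cfg <- function(seed = 1L, ...) {
  args <- list(n_channels = 32L, latent_dim = 6L, n_trials = 48L,
               trial_len_bins = 20L, mean_rate = 20, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# build a session_recording directly from matrices, trials of equal length
manual_session <- function(rates, motor, trial_len, bin_width = 0.05,
                           kind = "velocity", day_index = 0L,
                           condition = NULL) {
  nt <- nrow(rates) / trial_len
  stopifnot(nt == round(nt))
  start <- (seq_len(nt) - 1L) * trial_len * bin_width
  if (is.null(condition)) condition <- rep(1L, nt)
  session_recording(
    rate_array(rates, bin_width),
    motor_output(motor, kind = kind),
    trial_table(start_time = start, go_cue_time = start,
                end_time = start + trial_len * bin_width,
                condition_label = condition),
    day_index = day_index, task_tag = "manual")
}

# session whose motor outputs are an exact lagged-linear function of the
# rates (so a Wiener fit is exactly identifiable)
exact_linear_session <- function(n_trials = 8L, trial_len = 20L, d = 5L,
                                 t_lags = 4L, m = 2L, seed = 42L) {
  set.seed(seed)
  X <- matrix(abs(rnorm(n_trials * trial_len * d)), ncol = d)
  W <- matrix(rnorm((d * (t_lags + 1L) + 1L) * m, sd = 0.5), ncol = m)
  bounds <- cbind(seq(1L, nrow(X), by = trial_len),
                  seq(trial_len, nrow(X), by = trial_len))
  emb <- lag_embed(X, t_lags, bounds)
  Y <- matrix(0, nrow(X), m)
  Y[emb$rows, ] <- emb$X %*% W
  list(session = manual_session(X, Y, trial_len), W = W, X = X, Y = Y,
       bounds = bounds)
}

# zero out every weight of a serialized net (residual nets become the
# identity on non-negative inputs)
zero_net <- function(net) {
  net$W <- lapply(net$W, function(w) w * 0)
  net$b <- lapply(net$b, function(b) b * 0)
  net
}
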