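#' Split a session into training and held-out test trials
#'
#' The last `n_test` trials form the fixed held-out test set (e.g. a
#' 120-trial training set plus a 40-trial test set); aligners and same-day
#' decoders only ever see the training split.
#'
#' @param session A [session_recording].
#' @param n_test Number of held-out trials.
#' @return List with `train` and `test` sessions.
#' @export
split_session <- function(session, n_test = 40L) {
  nt <- nrow(session$trials)
  if (n_test >= nt) stop("n_test must be smaller than the trial count")
  list(train = subset_trials(session, seq_len(nt - n_test)),
       test = subset_trials(session, (nt - n_test + 1L):nt))
}

#' Fit the frozen day-0 decoders and latent models
#'
#' One bundle per day-0 session: the full-dimensional Wiener decoder (used
#' with Cycle-GAN), the Factor-Analysis latent model and its latent
#' decoder (used with PAF), and the autoencoder latent model and its
#' latent decoder (used with ADAN).  Only the models needed by `methods`
#' are fit.
#'
#' @param day0_train Day-0 training split.
#' @param methods Character subset of `c("cyclegan", "adan", "paf")`.
#' @param latent_dim Latent dimensionality (default 10).
#' @param t_lags,folds Decoder settings (defaults 4 and 4).
#' @param seed Seed for autoencoder training.
#' @return A list of class `day0_models`.
#' @export
fit_day0_models <- function(day0_train,
                            methods = c("cyclegan", "adan", "paf"),
                            latent_dim = 10L, t_lags = 4L, folds = 4L,
                            seed = 1L) {
  out <- list(latent_dim = latent_dim, t_lags = t_lags, folds = folds)
  if ("cyclegan" %in% methods)
    out$full_decoder <- fit_day0_decoder(day0_train, "full", folds = folds,
                                         t_lags = t_lags)
  if ("paf" %in% methods) {
    out$fa_model <- fit_factor_analysis(day0_train$rates, d = latent_dim)
    out$fa_decoder <- fit_day0_decoder(day0_train, "latent",
                                       latent_model = out$fa_model,
                                       folds = folds, t_lags = t_lags)
  }
  if ("adan" %in% methods) {
    out$adan_latent <- fit_adan_latent(day0_train, latent_dim = latent_dim,
                                       seed = seed)
    out$adan_decoder <- fit_day0_decoder(day0_train, "latent",
                                         latent_model = out$adan_latent,
                                         folds = folds, t_lags = t_lags)
  }
  class(out) <- "day0_models"
  out
}

# frozen day-0 decoder fit for a method
method_decoder <- function(models, method) {
  switch(method, cyclegan = models$full_decoder, paf = models$fa_decoder,
         adan = models$adan_decoder)
}

#' Same-day reference accuracy
#'
#' Recalibrates a decoder on the day-k training split in the same input
#' space as the method's day-0 decoder (including the method's own day-k
#' dimensionality reduction) and scores it on the day-k test split — the
#' reference against which the performance drop is measured.
#'
#' @param method `"cyclegan"`, `"adan"` or `"paf"`.
#' @param dayk_train,dayk_test Day-k splits.
#' @param models A [fit_day0_models()] bundle (for decoder settings).
#' @param seed Seed for the day-k autoencoder fit (ADAN).
#' @return The same-day R-squared.
#' @export
sameday_r2 <- function(method, dayk_train, dayk_test, models, seed = 1L) {
  if (method == "cyclegan") {
    fit <- fit_day0_decoder(dayk_train, "full", folds = models$folds,
                            t_lags = models$t_lags)
    return(decode_r2(fit, dayk_test))
  }
  lm_k <- if (method == "paf") {
    fit_factor_analysis(dayk_train$rates, d = models$latent_dim)
  } else {
    fit_adan_latent(dayk_train, latent_dim = models$latent_dim, seed = seed)
  }
  fit <- fit_day0_decoder(dayk_train, "latent", latent_model = lm_k,
                          folds = models$folds, t_lags = models$t_lags)
  decode_r2(fit, dayk_test, latent_model = lm_k)
}

#' Train one aligner and evaluate it on one day-0/day-k pair
#'
#' Runs the full workflow for a single method: train the aligner on the
#' day-k training split (unpaired with day-0), transform the day-k test
#' split, feed it to the frozen day-0 decoder, and assemble the evaluation
#' report: decoder accuracies (unaligned, aligned, recalibrated same-day),
#' the performance drop, MMD of the full-dimensional distributions before
#' and after alignment against the within-session baseline, and principal
#' angles between the day-0 and (un)aligned day-k subspaces.
#'
#' @param method `"cyclegan"`, `"adan"` or `"paf"`.
#' @param models A [fit_day0_models()] bundle.
#' @param day0_train,day0_test Day-0 splits.
#' @param dayk_train,dayk_test Day-k splits; `dayk_train` is what the
#'   aligner sees (possibly a subset, as in data-budget protocols).
#' @param tcfg A [train_config()] for the GAN methods (ignored for PAF).
#' @param angles Logical: compute principal angles (default TRUE).
#' @param sameday_train Session used to recalibrate the same-day reference
#'   decoder; defaults to `dayk_train`.  Data-budget protocols pass the
#'   full training split here while the aligner trains on a subset.
#' @param r2_sameday Optional precomputed same-day reference accuracy;
#'   when several aligner variants are evaluated against the same day-k
#'   split, computing it once via [sameday_r2()] avoids refitting the
#'   recalibrated decoder per variant.
#' @return A list of class `metric_report`; the trained aligner is
#'   attached as attribute `"aligner"`.
#' @export
evaluate_alignment <- function(method, models, day0_train, day0_test,
                               dayk_train, dayk_test, tcfg = NULL,
                               angles = TRUE, sameday_train = dayk_train,
                               r2_sameday = NULL) {
  method <- match.arg(method, c("cyclegan", "adan", "paf"))
  decoder <- method_decoder(models, method)
  if (is.null(decoder)) stop("day-0 models bundle lacks method ", method)
  X0_test <- day0_test$rates$rates
  Xk_test <- dayk_test$rates$rates

  if (method == "cyclegan") {
    if (is.null(tcfg)) tcfg <- train_config("cyclegan")
    aligner <- train_cyclegan(day0_train, dayk_train, tcfg, decoder)
    aligned_rates <- cyclegan_align(aligner, Xk_test)
    aligned_signal <- aligned_rates
    unaligned_signal <- Xk_test
    cyc_back <- cyclegan_align_back(aligner, aligned_rates)
    cycle_ratio <- mean(abs(cyc_back - Xk_test)) / mean(abs(Xk_test))
  } else if (method == "adan") {
    if (is.null(tcfg)) tcfg <- train_config("adan")
    aligner <- train_adan(day0_train, dayk_train, tcfg,
                          latent_model = models$adan_latent,
                          decoder = decoder)
    al <- adan_align(aligner, Xk_test)
    aligned_rates <- al$aligned_rates
    aligned_signal <- al$aligned_latents
    unaligned_signal <- latent_project(models$adan_latent, Xk_test)
    cycle_ratio <- NA_real_
  } else {
    z <- paf_align(models$fa_model, dayk_train)
    aligner <- attr(z, "aligner")
    aligned_signal <- paf_project(aligner, Xk_test)
    aligned_rates <- NULL          # PAF lives on the manifold
    unaligned_signal <- fa_project(models$fa_model, Xk_test)
    cycle_ratio <- NA_real_
  }

  bounds <- trial_bin_ranges(dayk_test, "start_to_end")
  r2_of <- function(signal) {
    pred <- predict(decoder$decoder, signal, bounds)
    multivariate_r2(dayk_test$motor$values[attr(pred, "rows"), , drop = FALSE],
                    pred)
  }
  r2_aligned <- r2_of(aligned_signal)
  r2_unaligned <- r2_of(unaligned_signal)
  if (is.null(r2_sameday))
    r2_sameday <- sameday_r2(method, sameday_train, dayk_test, models)

  rep <- list(
    method = method,
    day_index = dayk_test$day_index,
    r2_day0 = decode_r2(decoder, day0_test),
    r2_unaligned = r2_unaligned,
    r2_aligned = r2_aligned,
    r2_sameday = r2_sameday,
    drop_aligned = performance_drop(r2_aligned, r2_sameday),
    drop_unaligned = performance_drop(r2_unaligned, r2_sameday),
    mmd_within = within_session_mmd(X0_test),
    mmd_between_unaligned = between_session_mmd(X0_test, Xk_test),
    mmd_between_aligned = if (is.null(aligned_rates)) NA_real_ else
      between_session_mmd(X0_test, aligned_rates),
    cycle_ratio = cycle_ratio)
  if (angles) {
    rep$angles_unaligned <- principal_angles(X0_test, Xk_test)$angles
    rep$angles_aligned <- if (is.null(aligned_rates)) NULL else
      principal_angles(X0_test, aligned_rates)$angles
  }
  class(rep) <- "metric_report"
  attr(rep, "aligner") <- aligner
  rep
}

# inverse direction of a trained Cycle-GAN (G2), used for cycle checks
cyclegan_align_back <- function(model, day0_rates) {
  Xn <- normalize_rates(session_rates(day0_rates), model$scale0)
  denormalize_rates(.cpp_net_forward(model$G2, Xn), model$scalek)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> %s day-%d: R2 day0 %.3f | unaligned %.3f | aligned %.3f | same-day %.3f | drop %.3f\n",
    x$method, x$day_index, x$r2_day0, x$r2_unaligned, x$r2_aligned,
    x$r2_sameday, x$drop_aligned))
  invisible(x)
}

default_pipeline_config <- function() {
  list(
    sim = list(),
    scenarios = list(
      permutation_gain = list(channel_permutation = TRUE,
                              permute_frac = 0.2, gain_sd = 0.1),
      nonlinear = list(channel_permutation = TRUE, permute_frac = 0.2,
                       gain_sd = 0.15, nonlinearity = 0.3)),
    day_index = 1L,
    aligners = c("cyclegan", "adan", "paf"),
    train = list(),
    n_test_trials = 40L,
    latent_dim = 10L,
    t_lags = 4L,
    folds = 4L,
    seed = 1L,
    angles = TRUE)
}

#' Run the end-to-end benchmark pipeline
#'
#' Simulate a day-0 session, perturb it into day-k scenarios, fit and
#' freeze the day-0 decoders, train every requested aligner on each
#' scenario and evaluate it — one seed drives all stages.  The
#' configuration is a nested list (or path to a YAML file) overriding the
#' defaults: `sim` ([sim_config()] arguments), `scenarios` (named lists of
#' [perturbation_spec()] arguments), `aligners`, `train` (per-method
#' [train_config()] overrides), `n_test_trials`, `day_index`, `seed`.
#'
#' @param config Nested list or YAML file path; `NULL` for defaults.
#' @param out_dir Optional directory: reports are written as JSON.
#' @return A list with `reports` (one `metric_report` per scenario and
#'   aligner), the `day0` session and the configuration used.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cf <- default_pipeline_config()
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  for (nm in names(config)) cf[[nm]] <- config[[nm]]
  cf$sim$seed <- cf$seed
  scfg <- do.call(sim_config, cf$sim)

  day0 <- simulate_day0(scfg)
  sp0 <- split_session(day0, cf$n_test_trials)
  models <- fit_day0_models(sp0$train, methods = cf$aligners,
                            latent_dim = cf$latent_dim, t_lags = cf$t_lags,
                            folds = cf$folds, seed = cf$seed)
  reports <- list()
  for (sc in names(cf$scenarios)) {
    spec <- do.call(perturbation_spec, cf$scenarios[[sc]])
    dayk <- perturb_to_dayk(day0, spec, day_index = cf$day_index)
    spk <- split_session(dayk, cf$n_test_trials)
    for (m in cf$aligners) {
      targs <- cf$train[[m]]
      tcfg <- if (m == "paf") NULL else
        do.call(train_config, c(list(method = m, seed = cf$seed), targs))
      rep <- evaluate_alignment(m, models, sp0$train, sp0$test, spk$train,
                                spk$test, tcfg, angles = isTRUE(cf$angles))
      reports[[paste(sc, m, sep = ".")]] <- rep
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(lapply(reports, unclass),
                         file.path(out_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(reports = reports, day0 = day0, config = cf)
}

#' Sweep one training-protocol axis
#'
#' Re-trains the GAN aligners across a grid of one hyperparameter
#' (`batch_size`, `lr_g`, `lr_ratio`) or of the training-set size
#' (`n_train_trials`, randomly selected trial subsets of the training
#' split scored on the fixed held-out test split) and tabulates the
#' resulting performance drops.  Day-0 models, the day-k session and the
#' test split stay fixed across the grid.
#'
#' @param axis One of `"batch_size"`, `"lr_g"`, `"lr_ratio"`,
#'   `"n_train_trials"`.
#' @param values Grid values.
#' @param config Pipeline configuration as in [run_pipeline()]; exactly
#'   one scenario is used (the first).
#' @param methods Aligners to sweep (default the GAN methods; PAF is
#'   included automatically for `n_train_trials`).
#' @return A long-format `data.frame`: method, axis, value, r2_aligned,
#'   r2_sameday, drop.
#' @export
run_sweep <- function(axis = c("batch_size", "lr_g", "lr_ratio",
                               "n_train_trials"),
                      values, config = NULL,
                      methods = c("cyclegan", "adan")) {
  axis <- match.arg(axis)
  cf <- default_pipeline_config()
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  for (nm in names(config)) cf[[nm]] <- config[[nm]]
  cf$sim$seed <- cf$seed
  scfg <- do.call(sim_config, cf$sim)
  if (axis == "n_train_trials" && !"paf" %in% methods)
    methods <- c(methods, "paf")

  day0 <- simulate_day0(scfg)
  sp0 <- split_session(day0, cf$n_test_trials)
  models <- fit_day0_models(sp0$train, methods = methods,
                            latent_dim = cf$latent_dim, t_lags = cf$t_lags,
                            folds = cf$folds, seed = cf$seed)
  spec <- do.call(perturbation_spec, cf$scenarios[[1]])
  dayk <- perturb_to_dayk(day0, spec, day_index = cf$day_index)
  spk <- split_session(dayk, cf$n_test_trials)

  rows <- list()
  for (v in values) {
    for (m in methods) {
      if (m == "paf" && axis != "n_train_trials") next
      targs <- cf$train[[m]]
      if (axis != "n_train_trials") targs[[axis]] <- v
      tcfg <- if (m == "paf") NULL else
        do.call(train_config, c(list(method = m, seed = cf$seed), targs))
      dayk_train <- spk$train
      if (axis == "n_train_trials") {
        nt <- nrow(spk$train$trials)
        if (v > nt) stop("n_train_trials exceeds the training split")
        set.seed(cf$seed + as.integer(v))
        dayk_train <- subset_trials(spk$train, sample.int(nt, v))
      }
      rep <- evaluate_alignment(m, models, sp0$train, sp0$test, dayk_train,
                                spk$test, tcfg, angles = FALSE,
                                sameday_train = spk$train)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, axis = axis, value = v,
        r2_aligned = rep$r2_aligned, r2_sameday = rep$r2_sameday,
        drop = rep$drop_aligned)
    }
  }
  do.call(rbind, rows)
}
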