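#' Training configuration for the adversarial aligners
#'
#' Collects every hyperparameter swept in benchmarking the GAN aligners.
#' Defaults follow the settings found robust across tasks: 400 training
#' epochs for both methods, batch size 256 and discriminator/generator
#' learning-rate ratio 10 for Cycle-GAN, batch size 8 and ratio 0.5 for
#' ADAN, generator learning rate 1e-4 for both, and four-fold model
#' selection.
#'
#' @param method `"cyclegan"` or `"adan"`.
#' @param epochs Training epochs (default 400).
#' @param batch_size Mini-batch size; defaults to 256 for Cycle-GAN, 8 for
#'   ADAN.
#' @param lr_g Generator learning rate (ADAM), default 1e-4.
#' @param lr_ratio `LR_D / LR_G`; defaults to 10 for Cycle-GAN, 0.5 for
#'   ADAN.
#' @param folds Cross-validation folds for model selection (default 4).
#' @param seed Integer RNG seed for weight init and batch shuffling.
#' @param loss_variant `"L1"` (least absolute deviations, default) or
#'   `"L2"` (least squares) for the adversarial and cycle terms.
#' @param selection `"supervised_r2"` (held-out decoder accuracy, requires
#'   day-k motor outputs and a day-0 decoder) or `"unsupervised_mmd"`
#'   (lowest held-out aligned-vs-day-0 MMD).
#' @param lambda_cyc Cycle-consistency weight (Cycle-GAN only), default 10.
#' @param hidden Hidden-layer width of all networks (default 64).
#' @param l1_weight Weight-sparsity (L1) penalty on network weights.
#' @param ckpt_every Generator checkpoint interval in epochs; held-out
#'   selection picks the best checkpoint within each fold (0 = final model
#'   only).
#' @param d_input_noise S.D. of Gaussian jitter added to discriminator
#'   inputs during training (in normalized rate units); keeps the
#'   real/generated densities overlapping so the discriminator cannot
#'   memorize the finite day-0 sample.
#' @return A list of class `train_config`.
#' @export
train_config <- function(method = c("cyclegan", "adan"), epochs = 400L,
                         batch_size = NULL, lr_g = 1e-4, lr_ratio = NULL,
                         folds = 4L, seed = 1L,
                         loss_variant = c("L1", "L2"),
                         selection = c("supervised_r2", "unsupervised_mmd"),
                         lambda_cyc = 10, hidden = 64L, l1_weight = 1e-4,
                         ckpt_every = 10L, d_input_noise = 0.05) {
  method <- match.arg(method)
  loss_variant <- match.arg(loss_variant)
  selection <- match.arg(selection)
  if (is.null(batch_size)) batch_size <- if (method == "cyclegan") 256L else 8L
  if (is.null(lr_ratio)) lr_ratio <- if (method == "cyclegan") 10 else 0.5
  stopifnot(epochs >= 1, batch_size >= 1, lr_g > 0, lr_ratio > 0,
            folds >= 1, lambda_cyc >= 0, hidden >= 1, ckpt_every >= 0,
            d_input_noise >= 0)
  structure(list(method = method, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_g = lr_g,
                 lr_ratio = lr_ratio, lr_d = lr_g * lr_ratio,
                 folds = as.integer(folds), seed = as.integer(seed),
                 loss_variant = loss_variant, selection = selection,
                 lambda_cyc = lambda_cyc, hidden = as.integer(hidden),
                 l1_weight = l1_weight, ckpt_every = as.integer(ckpt_every),
                 d_input_noise = d_input_noise),
            class = "train_config")
}

# per-channel scale statistics used to bring each day's rates to a
# comparable range before adversarial training; inverted after alignment so
# the frozen decoder sees original units
rate_norm_stats <- function(rates, prob = 0.99) {
  X <- if (inherits(rates, "rate_array")) rates$rates else as.matrix(rates)
  scale <- apply(X, 2L, stats::quantile, probs = prob, names = FALSE)
  pmax(scale, 1e-3)
}

normalize_rates <- function(X, scale) sweep(as.matrix(X), 2L, scale, "/")
denormalize_rates <- function(X, scale) sweep(as.matrix(X), 2L, scale, "*")

session_rates <- function(x) {
  if (inherits(x, "session_recording")) x$rates$rates
  else if (inherits(x, "rate_array")) x$rates
  else as.matrix(x)
}

# ---- ADAN ------------------------------------------------------------

#' Discover the day-0 latent space with an autoencoder
#'
#' Trains the nonlinear autoencoder (exponential-linear units, one hidden
#' layer of `hidden` units on each side of a `latent_dim`-unit bottleneck)
#' that defines ADAN's day-0 latent space.  The reconstruction objective is
#' augmented with an auxiliary decoding loss from the latents to the
#' session's motor outputs, which biases the latent space toward
#' motor-relevant dimensions; the auxiliary readout is discarded after
#' training and plays no role in evaluation.
#'
#' @param day0_session The day-0 [session_recording].
#' @param latent_dim Bottleneck width (default 10).
#' @param hidden Hidden-layer width (default 64).
#' @param aux_weight Weight of the auxiliary motor-decoding loss.
#' @param epochs,batch_size,lr Autoencoder training schedule.
#' @param l1_weight Weight-sparsity penalty.
#' @param seed RNG seed; retraining with the same seed reproduces the model
#'   exactly.
#' @return An object of class `adan_latent`: encoder and decoder nets, the
#'   per-channel normalization scale, and the training-loss history.
#' @export
fit_adan_latent <- function(day0_session, latent_dim = 10L, hidden = 64L,
                            aux_weight = 0.2, epochs = 150L, batch_size = 64L,
                            lr = 1e-3, l1_weight = 1e-5, seed = 1L) {
  X <- session_rates(day0_session)
  Y <- day0_session$motor$values
  scale <- rate_norm_stats(X)
  Xn <- normalize_rates(X, scale)
  # z-scored motor targets so the auxiliary loss is unit-balanced
  sds <- apply(Y, 2L, stats::sd)
  sds[sds == 0] <- 1
  Yn <- sweep(sweep(Y, 2L, colMeans(Y)), 2L, sds, "/")
  fit <- .cpp_train_autoencoder(Xn, Yn, as.integer(hidden),
                                as.integer(latent_dim), aux_weight,
                                as.integer(epochs), as.integer(batch_size),
                                lr, l1_weight, as.integer(seed))
  structure(list(encoder = fit$encoder, decoder = fit$decoder,
                 norm_scale = scale, latent_dim = as.integer(latent_dim),
                 history = as.numeric(fit$history)),
            class = "adan_latent")
}

#' @rdname latent_project
#' @export
latent_project.adan_latent <- function(model, rates) {
  Xn <- normalize_rates(session_rates(rates), model$norm_scale)
  .cpp_net_forward(model$encoder, Xn)
}

# reconstruction through the autoencoder (used by tests and diagnostics)
adan_reconstruct <- function(model, rates) {
  z <- latent_project(model, rates)
  denormalize_rates(.cpp_net_forward(model$decoder, z), model$norm_scale)
}

#' Train an ADAN aligner
#'
#' Adversarial Domain Adaptation Network: a residual feedforward generator
#' maps day-k rates toward the day-0 distribution, trained against a
#' discriminator that is an autoencoder (initialized from the day-0 latent
#' model).  The discriminator's per-sample descriptor is the L1 norm of its
#' reconstruction residual; the discriminator is updated to maximize the
#' separation between the mean descriptors of true day-0 samples and
#' generated samples (a Wasserstein-1 lower bound), while the generator is
#' updated to minimize the generated-sample descriptor.  Both networks are
#' static, point-wise maps with no knowledge of temporal dynamics.
#'
#' Model selection follows `cfg$folds`-fold cross validation over day-k
#' trials: one aligner is trained per fold (on the remaining folds) and the
#' aligner scoring best on its held-out fold is kept — by held-out decoder
#' R-squared when `cfg$selection = "supervised_r2"` (requires `decoder`),
#' or by lowest held-out aligned-vs-day-0 MMD when `"unsupervised_mmd"`.
#'
#' @param day0_session,dayk_session Sessions with equal channel counts.
#' @param cfg A [train_config()] with `method = "adan"`.
#' @param latent_model The day-0 [fit_adan_latent()] model (also used to
#'   initialize the discriminator).
#' @param decoder Frozen day-0 latent-space [fit_day0_decoder()] fit, needed
#'   for supervised selection.
#' @return An object of class `adan_aligner`.
#' @export
train_adan <- function(day0_session, dayk_session, cfg = train_config("adan"),
                       latent_model, decoder = NULL) {
  stopifnot(inherits(latent_model, "adan_latent"))
  if (cfg$method != "adan") stop("cfg$method must be 'adan'")
  X0 <- session_rates(day0_session)
  Xk <- session_rates(dayk_session)
  if (ncol(X0) != ncol(Xk)) stop("channel-count mismatch between days")
  scale0 <- latent_model$norm_scale
  scalek <- rate_norm_stats(Xk)
  X0n <- normalize_rates(X0, scale0)

  train_fold <- function(train_sess, fseed) {
    .cpp_train_adan(X0n, normalize_rates(session_rates(train_sess), scalek),
                    latent_model$encoder, latent_model$decoder, cfg$hidden,
                    cfg$epochs, cfg$batch_size, cfg$lr_g, cfg$lr_d,
                    cfg$l1_weight, fseed, cfg$ckpt_every, cfg$d_input_noise,
                    2.0)
  }
  run_fold_selection(
    day0_session, dayk_session, cfg, decoder, train_fold,
    candidates_fun = function(fit) {
      if (length(fit$checkpoints) == 0L)
        list(list(epoch = cfg$epochs, G = fit$G)) else fit$checkpoints
    },
    align_fun = function(cand, rates)
      denormalize_rates(
        .cpp_net_forward(cand$G, normalize_rates(rates, scalek)), scale0),
    make_aligner = function(fit, cand, fold_metrics = NULL,
                            selected = NA_integer_) {
      structure(list(G = cand$G, epoch = cand$epoch,
                     latent_model = latent_model,
                     scale0 = scale0, scalek = scalek,
                     history = fit$history, fold_metrics = fold_metrics,
                     selected_fold = selected, cfg = cfg),
                class = "adan_aligner")
    },
    latent_model = latent_model)
}

#' Apply a trained ADAN aligner
#'
#' @param model An `adan_aligner` from [train_adan()].
#' @param dayk_rates Day-k rates ([rate_array], matrix or session).
#' @return A list with `aligned_rates` (`T x N`, in day-0 units, from the
#'   generator) and `aligned_latents` (`T x 10`, the day-0 encoder applied
#'   to the aligned rates — the input the frozen latent decoder expects).
#' @export
adan_align <- function(model, dayk_rates) {
  X <- session_rates(dayk_rates)
  Xn <- normalize_rates(X, model$scalek)
  g <- .cpp_net_forward(model$G, Xn)
  aligned <- denormalize_rates(g, model$scale0)
  latents <- .cpp_net_forward(model$latent_model$encoder, g)
  list(aligned_rates = aligned, aligned_latents = latents)
}

# ---- Cycle-GAN -------------------------------------------------------

#' Build an untrained Cycle-GAN aligner
#'
#' Two fully connected generators with two hidden layers each (`G1`:
#' day-k to day-0, `G2`: day-0 to day-k) and two discriminators scoring
#' each domain.  Generators are residual maps with a small-scale final
#' layer (so an untrained generator is approximately the identity) and a
#' final rectification keeping rates non-negative; discriminators use
#' leaky rectified units with a scalar linear output.
#'
#' @param n_channels Number of recorded channels N.
#' @param hidden_width Hidden-layer width (default from `cfg$hidden`).
#' @param cfg A [train_config()]; its `seed` fixes the initial weights.
#' @return An object of class `cyclegan_model` with components `G1`, `G2`,
#'   `D1`, `D2` and the cycle-loss weight.
#' @export
build_cyclegan <- function(n_channels, hidden_width = cfg$hidden,
                           cfg = train_config("cyclegan")) {
  n <- as.integer(n_channels)
  h <- as.integer(hidden_width)
  mk <- function(widths, acts, residual, out_act, last_scale, seed)
    .cpp_build_net(widths, acts, residual, out_act, last_scale, seed)
  structure(list(
    G1 = mk(c(n, h, h, n), c(1L, 1L, 0L), TRUE, 1L, 0.1, cfg$seed),
    G2 = mk(c(n, h, h, n), c(1L, 1L, 0L), TRUE, 1L, 0.1, cfg$seed + 1L),
    D1 = mk(c(n, h, h, 1L), c(2L, 2L, 0L), FALSE, 0L, 1, cfg$seed + 2L),
    D2 = mk(c(n, h, h, 1L), c(2L, 2L, 0L), FALSE, 0L, 1, cfg$seed + 3L),
    lambda_cyc = cfg$lambda_cyc, n_channels = n, hidden = h,
    cfg = cfg, history = NULL, scale0 = NULL, scalek = NULL),
    class = "cyclegan_model")
}

#' Cycle-GAN loss terms on a pair of mini-batches
#'
#' Computes every term of the Cycle-GAN objective for given batches:
#' adversarial generator and discriminator terms (absolute deviations of
#' discriminator outputs from the real/fake labels 1/0 under the `"L1"`
#' variant, squared deviations under `"L2"`) and the cycle-consistency
#' term, the mean absolute elementwise deviation of `G2(G1(x_k))` from
#' `x_k` plus that of `G1(G2(x_0))` from `x_0`.
#'
#' @param batch0,batchk Matrices of day-0 / day-k samples (rows).
#' @param model A `cyclegan_model`.
#' @param lambda_cyc Cycle weight used in the reported total.
#' @param loss_variant `"L1"` or `"L2"`.
#' @return List with `adv_G1`, `adv_G2`, `adv_D1`, `adv_D2`, `cyc` and
#'   `total_G` (`adv_G1 + adv_G2 + lambda_cyc * cyc`).
#' @export
cyclegan_losses <- function(batch0, batchk, model,
                            lambda_cyc = model$lambda_cyc,
                            loss_variant = model$cfg$loss_variant) {
  batch0 <- as.matrix(batch0)
  batchk <- as.matrix(batchk)
  if (ncol(batch0) != model$n_channels || ncol(batchk) != model$n_channels)
    stop("batch shape mismatch")
  dev <- if (loss_variant == "L2") function(y, l) mean((y - l)^2) else
    function(y, l) mean(abs(y - l))
  f1 <- .cpp_net_forward(model$G1, batchk)
  f2 <- .cpp_net_forward(model$G2, batch0)
  adv_D1 <- dev(.cpp_net_forward(model$D1, batch0), 1) +
    dev(.cpp_net_forward(model$D1, f1), 0)
  adv_D2 <- dev(.cpp_net_forward(model$D2, batchk), 1) +
    dev(.cpp_net_forward(model$D2, f2), 0)
  adv_G1 <- dev(.cpp_net_forward(model$D1, f1), 1)
  adv_G2 <- dev(.cpp_net_forward(model$D2, f2), 1)
  cyc <- mean(abs(.cpp_net_forward(model$G2, f1) - batchk)) +
    mean(abs(.cpp_net_forward(model$G1, f2) - batch0))
  list(adv_G1 = adv_G1, adv_G2 = adv_G2, adv_D1 = adv_D1, adv_D2 = adv_D2,
       cyc = cyc, total_G = adv_G1 + adv_G2 + lambda_cyc * cyc)
}

#' Train a Cycle-GAN aligner
#'
#' Alternating ADAM updates of the two generator/discriminator pairs with
#' the two-timescale learning-rate rule `LR_D = lr_ratio * LR_G`, the
#' cycle-consistency penalty tying the generators into mutual inverses,
#' and an L1 weight-sparsity term.  Rates are scaled per channel by each
#' day's 99th percentile before training and the scaling is inverted after
#' alignment, so the frozen decoder sees original units.  Model selection
#' over day-k trial folds works as in [train_adan()].
#'
#' @param day0_session,dayk_session Sessions with equal channel counts.
#' @param cfg A [train_config()] with `method = "cyclegan"`.
#' @param decoder Frozen day-0 full-dimensional [fit_day0_decoder()] fit,
#'   needed for supervised selection.
#' @return A trained `cyclegan_model` (with `history`, `fold_metrics`,
#'   `selected_fold` and the normalization scales filled in).
#' @export
train_cyclegan <- function(day0_session, dayk_session,
                           cfg = train_config("cyclegan"), decoder = NULL) {
  if (cfg$method != "cyclegan") stop("cfg$method must be 'cyclegan'")
  X0 <- session_rates(day0_session)
  Xk <- session_rates(dayk_session)
  if (ncol(X0) != ncol(Xk)) stop("channel-count mismatch between days")
  scale0 <- rate_norm_stats(X0)
  scalek <- rate_norm_stats(Xk)
  X0n <- normalize_rates(X0, scale0)

  train_fold <- function(train_sess, fseed) {
    Xkn <- normalize_rates(session_rates(train_sess), scalek)
    .cpp_train_cyclegan(X0n, Xkn, cfg$hidden, cfg$epochs, cfg$batch_size,
                        cfg$lr_g, cfg$lr_d, cfg$lambda_cyc,
                        cfg$loss_variant == "L2", cfg$l1_weight, fseed,
                        cfg$ckpt_every, cfg$d_input_noise)
  }
  run_fold_selection(
    day0_session, dayk_session, cfg, decoder, train_fold,
    candidates_fun = function(fit) {
      if (length(fit$checkpoints) == 0L)
        list(list(epoch = cfg$epochs, G1 = fit$G1, G2 = fit$G2)) else
          fit$checkpoints
    },
    align_fun = function(cand, rates)
      denormalize_rates(
        .cpp_net_forward(cand$G1, normalize_rates(rates, scalek)), scale0),
    make_aligner = function(fit, cand, fold_metrics = NULL,
                            selected = NA_integer_) {
      structure(list(G1 = cand$G1, G2 = cand$G2, epoch = cand$epoch,
                     D1 = fit$D1, D2 = fit$D2,
                     lambda_cyc = cfg$lambda_cyc,
                     n_channels = ncol(X0), hidden = cfg$hidden, cfg = cfg,
                     history = fit$history, scale0 = scale0, scalek = scalek,
                     fold_metrics = fold_metrics, selected_fold = selected),
                class = "cyclegan_model")
    })
}

#' Apply a trained Cycle-GAN aligner
#'
#' Row-wise application of the forward generator `G1`: a static map, so
#' permuting input rows permutes output rows identically.
#'
#' @param model A trained `cyclegan_model`.
#' @param dayk_rates Day-k rates ([rate_array], matrix or session).
#' @return Aligned rates `T x N` in day-0 units (non-negative).
#' @export
cyclegan_align <- function(model, dayk_rates) {
  X <- session_rates(dayk_rates)
  Xn <- if (is.null(model$scalek)) X else normalize_rates(X, model$scalek)
  out <- .cpp_net_forward(model$G1, Xn)
  if (is.null(model$scale0)) out else denormalize_rates(out, model$scale0)
}

# Shared model-selection driver for both adversarial aligners: trains one
# model per day-k trial fold (on the complement), scores every generator
# checkpoint on the held-out fold, and keeps the best checkpoint of the
# best fold (held-out decoder accuracy or aligned-vs-day-0 MMD, per
# cfg$selection).
run_fold_selection <- function(day0_session, dayk_session, cfg, decoder,
                               train_fold, candidates_fun, align_fun,
                               make_aligner, latent_model = NULL) {
  nt <- nrow(dayk_session$trials)
  folds <- cfg$folds
  if (folds > 1L && nt < folds)
    stop(sprintf("need at least %d day-k trials for %d-fold selection",
                 folds, folds))
  if (cfg$selection == "supervised_r2" && is.null(decoder) && folds > 1L)
    stop("supervised_r2 selection requires the frozen day-0 decoder")
  if (folds == 1L) {
    fit <- train_fold(dayk_session, cfg$seed)
    cands <- candidates_fun(fit)
    return(make_aligner(fit, cands[[length(cands)]], fold_metrics = NULL,
                        selected = 1L))
  }
  supervised <- cfg$selection == "supervised_r2"
  X0 <- session_rates(day0_session)
  score_candidate <- function(cand, val_sess) {
    aligned_val <- align_fun(cand, session_rates(val_sess))
    if (supervised) {
      signal <- if (!is.null(latent_model))
        .cpp_net_forward(latent_model$encoder,
                         normalize_rates(aligned_val,
                                         latent_model$norm_scale)) else
        aligned_val
      bounds <- trial_bin_ranges(val_sess, "start_to_end")
      pred <- predict(if (inherits(decoder, "decoder_fit")) decoder$decoder
                      else decoder, signal, bounds)
      multivariate_r2(
        val_sess$motor$values[attr(pred, "rows"), , drop = FALSE], pred)
    } else {
      mmd(aligned_val, X0)
    }
  }
  fold_of <- contiguous_folds(nt, folds)
  fits <- vector("list", folds)
  best_cand <- vector("list", folds)
  metric <- numeric(folds)
  for (f in seq_len(folds)) {
    train_sess <- subset_trials(dayk_session, which(fold_of != f))
    val_sess <- subset_trials(dayk_session, which(fold_of == f))
    fits[[f]] <- train_fold(train_sess, cfg$seed + f - 1L)
    cands <- candidates_fun(fits[[f]])
    scores <- vapply(cands, score_candidate, numeric(1), val_sess = val_sess)
    pick <- if (supervised) which.max(scores) else which.min(scores)
    best_cand[[f]] <- cands[[pick]]
    metric[f] <- scores[pick]
  }
  best <- if (supervised) which.max(metric) else which.min(metric)
  make_aligner(fits[[best]], best_cand[[best]], fold_metrics = metric,
               selected = best)
}

#' Align a day-k session with any fitted aligner
#'
#' Convenience dispatcher returning the signal in the space the matching
#' frozen day-0 decoder expects: full-dimensional rates for Cycle-GAN,
#' 10-d latents for ADAN and PAF.
#'
#' @param aligner A `cyclegan_model`, `adan_aligner` or `paf_aligner`.
#' @param dayk_rates Day-k rates or session.
#' @return Matrix of aligned decoder input.
#' @export
align_signal <- function(aligner, dayk_rates) {
  if (inherits(aligner, "cyclegan_model")) {
    cyclegan_align(aligner, dayk_rates)
  } else if (inherits(aligner, "adan_aligner")) {
    adan_align(aligner, dayk_rates)$aligned_latents
  } else if (inherits(aligner, "paf_aligner")) {
    paf_project(aligner, session_rates(dayk_rates))
  } else stop("unknown aligner type")
}
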