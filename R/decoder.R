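#' Lagged embedding of a multichannel signal
#'
#' Builds the regression design for a Wiener filter: row `t` stacks the
#' signal at bins `t, t-1, ..., t-T_lags` (current bin first) plus a
#' constant column.  Embeddings never wrap across trial boundaries: the
#' first `T_lags` rows of each trial are dropped, and trials shorter than
#' `T_lags + 1` bins are skipped with a message.
#'
#' @param signal Numeric matrix `T x D` (firing rates or latents).
#' @param t_lags Number of history bins behind the current bin (default 4,
#'   i.e. 200 ms of history at 50 ms bins).
#' @param trial_bounds Optional two-column matrix of 1-based inclusive
#'   `(start, end)` row ranges delimiting trials; default treats the whole
#'   matrix as one segment.
#' @return A list of class `lag_embedding` with elements `X` (the design
#'   matrix, `T_valid x (D * (t_lags + 1) + 1)`) and `rows` (the original
#'   row index each design row corresponds to, for aligning targets).
#' @export
lag_embed <- function(signal, t_lags = 4L, trial_bounds = NULL) {
  signal <- as.matrix(signal)
  d <- ncol(signal)
  if (d == 0L) stop("signal has no channels")
  t_lags <- as.integer(t_lags)
  if (t_lags < 0L) stop("t_lags must be >= 0")
  if (is.null(trial_bounds)) trial_bounds <- cbind(1L, nrow(signal))
  trial_bounds <- matrix(as.integer(trial_bounds), ncol = 2L)
  short <- trial_bounds[, 2] - trial_bounds[, 1] + 1L < t_lags + 1L
  if (all(short)) stop("all trials shorter than t_lags + 1 bins")
  if (any(short)) {
    message(sum(short), " trial(s) shorter than t_lags + 1 bins dropped")
    trial_bounds <- trial_bounds[!short, , drop = FALSE]
  }
  rows <- unlist(lapply(seq_len(nrow(trial_bounds)), function(i)
    (trial_bounds[i, 1] + t_lags):trial_bounds[i, 2]))
  X <- matrix(0, length(rows), d * (t_lags + 1L) + 1L)
  for (lag in 0:t_lags)
    X[, lag * d + seq_len(d)] <- signal[rows - lag, , drop = FALSE]
  X[, d * (t_lags + 1L) + 1L] <- 1
  structure(list(X = X, rows = rows, t_lags = t_lags, d = d),
            class = "lag_embedding")
}

#' Fit a Wiener filter by regularized least squares
#'
#' Solves `min_W ||X W - Y||^2` through the normal equations with a tiny
#' ridge term scaled to the mean diagonal of `X'X`; the ridge keeps the
#' ~480-column lagged design well conditioned on short sessions while
#' perturbing well-posed fits by less than 1e-6.
#'
#' @param X A [lag_embed()] result or a plain design matrix.
#' @param Y Target matrix with as many rows as the design.
#' @param ridge Relative ridge factor (default 1e-6); set to 0 to disable,
#'   in which case a rank-deficient design raises a conditioning error.
#' @return An object of class `wiener_decoder` with the weight matrix `W`,
#'   the lag order, the input space tag and a `frozen` flag (FALSE until
#'   frozen by [fit_day0_decoder()]).
#' @export
fit_wiener <- function(X, Y, ridge = 1e-6) {
  emb <- NULL
  if (inherits(X, "lag_embedding")) {
    emb <- X
    X <- emb$X
  }
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < ncol(X))
    stop("conditioning error: fewer rows than design columns")
  xtx <- crossprod(X)
  if (ridge > 0) {
    lam <- ridge * mean(diag(xtx))
    diag(xtx) <- diag(xtx) + lam
  } else if (rcond(xtx) < 1e-12) {
    stop("conditioning error: rank-deficient design and ridge = 0")
  }
  W <- solve(xtx, crossprod(X, Y))
  structure(list(W = W, t_lags = if (is.null(emb)) NA_integer_ else emb$t_lags,
                 d = if (is.null(emb)) NA_integer_ else emb$d,
                 space = "full", frozen = FALSE),
            class = "wiener_decoder")
}

#' Predict motor outputs with a Wiener filter
#'
#' Prediction at bin `t` uses only bins `<= t` (the filter is causal).
#'
#' @param object A `wiener_decoder`.
#' @param signal Numeric matrix `T x D` in the decoder's input space.
#' @param trial_bounds Optional trial ranges as in [lag_embed()].
#' @param ... Unused.
#' @return A matrix of predictions with attribute `"rows"` giving the
#'   signal rows each prediction corresponds to (the first `t_lags` bins of
#'   each trial have no prediction).
#' @export
predict.wiener_decoder <- function(object, signal, trial_bounds = NULL, ...) {
  emb <- lag_embed(signal, object$t_lags, trial_bounds)
  if (ncol(emb$X) != nrow(object$W))
    stop(sprintf("input dimensionality mismatch: design has %d columns, decoder expects %d",
                 ncol(emb$X), nrow(object$W)))
  out <- emb$X %*% object$W
  attr(out, "rows") <- emb$rows
  out
}

#' Variance-weighted multivariate coefficient of determination
#'
#' Computes `R^2_m = 1 - SSE_m / SST_m` per output dimension and returns
#' the weighted average with weights equal to each dimension's variance
#' (identical to scikit-learn's `r2_score` with `multioutput =
#' "variance_weighted"`).  May be negative for predictions worse than the
#' mean.  Zero-variance dimensions are excluded with a warning.
#'
#' @param Y Actual outputs, `T x M`.
#' @param Yhat Predicted outputs, same shape.
#' @return A single numeric value.
#' @export
multivariate_r2 <- function(Y, Yhat) {
  Y <- as.matrix(Y)
  Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("Y and Yhat must have the same shape")
  if (nrow(Y) < 2L) stop("need at least 2 rows")
  sst <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  keep <- sst > 0
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " zero-variance dimension(s)")
    if (!any(keep)) stop("all dimensions have zero variance")
  }
  sse <- colSums((Y - Yhat)^2)
  r2 <- 1 - sse[keep] / sst[keep]
  sum(sst[keep] * r2) / sum(sst[keep])
}

#' Performance drop of an aligned decoder
#'
#' The difference between the day-0 decoder's accuracy on aligned day-k
#' data and the accuracy of a decoder recalibrated on day-k itself
#' (`R^2_aligned - R^2_same-day`).  A value near 0 indicates perfect
#' stabilization.
#'
#' @param r2_aligned,r2_sameday Scalar R-squared values.
#' @return `r2_aligned - r2_sameday`.
#' @export
performance_drop <- function(r2_aligned, r2_sameday) r2_aligned - r2_sameday

# map a session to the decoder input signal for a given space
decoder_signal <- function(session, space, latent_model = NULL) {
  if (space == "full") return(session$rates$rates)
  if (is.null(latent_model))
    stop("space = 'latent' requires a fitted latent model")
  latent_project(latent_model, session$rates$rates)
}

# contiguous trial-block fold assignment
contiguous_folds <- function(n_trials, folds) {
  as.integer(cut(seq_len(n_trials), breaks = folds, labels = FALSE))
}

#' Fit and freeze the day-0 decoder
#'
#' Trains a Wiener filter on the day-0 session with trial-level cross
#' validation: trials are split into `folds` contiguous blocks, the filter
#' is fit on all but one block and scored (variance-weighted R-squared) on
#' the held-out block, and the filter from the best-scoring fold is
#' returned frozen.  Ties are broken by the lowest fold index.
#'
#' @param session The day-0 [session_recording].
#' @param space `"full"` to decode from the recorded rates, `"latent"` to
#'   decode from a 10-d latent projection.
#' @param latent_model Required when `space = "latent"`: a fitted
#'   [fit_factor_analysis()] model or [fit_adan_latent()] encoder.
#' @param folds Number of cross-validation folds (default 4).
#' @param t_lags Wiener filter history bins (default 4).
#' @param ridge Ridge factor passed to [fit_wiener()].
#' @return An object of class `decoder_fit`: the frozen `wiener_decoder`,
#'   per-fold R-squared values and the selected fold.
#' @export
fit_day0_decoder <- function(session, space = c("full", "latent"),
                             latent_model = NULL, folds = 4L, t_lags = 4L,
                             ridge = 1e-6) {
  space <- match.arg(space)
  nt <- nrow(session$trials)
  if (nt < folds) stop(sprintf("need at least %d trials", folds))
  signal <- decoder_signal(session, space, latent_model)
  bounds <- trial_bin_ranges(session, "start_to_end")
  fold_of <- contiguous_folds(nt, folds)
  fits <- vector("list", folds)
  fold_r2 <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    emb <- lag_embed(signal, t_lags, bounds[tr, , drop = FALSE])
    dec <- fit_wiener(emb, session$motor$values[emb$rows, , drop = FALSE],
                      ridge)
    pred <- predict(dec, signal, bounds[te, , drop = FALSE])
    fold_r2[f] <- multivariate_r2(
      session$motor$values[attr(pred, "rows"), , drop = FALSE], pred)
    fits[[f]] <- dec
  }
  best <- which.max(fold_r2)
  dec <- fits[[best]]
  dec$space <- space
  dec$frozen <- TRUE
  structure(list(decoder = dec, fold_r2 = fold_r2,
                 selected_fold = best, latent_model = latent_model),
            class = "decoder_fit")
}

#' Decoder accuracy on a session
#'
#' Convenience wrapper: predicts the session's motor outputs with a
#' (frozen) decoder and returns the variance-weighted multivariate
#' R-squared.  The decoder input is derived from the session's rates in
#' the decoder's input space unless `signal` is supplied directly.
#'
#' @param decoder A `wiener_decoder` or [fit_day0_decoder()] result.
#' @param session The [session_recording] to score.
#' @param signal Optional decoder-input matrix overriding the session's
#'   rates (e.g. aligned rates or latents).
#' @param latent_model Latent model for `space = "latent"` decoders
#'   (defaults to the one stored in a `decoder_fit`).
#' @return A single R-squared value.
#' @export
decode_r2 <- function(decoder, session, signal = NULL, latent_model = NULL) {
  if (inherits(decoder, "decoder_fit")) {
    if (is.null(latent_model)) latent_model <- decoder$latent_model
    decoder <- decoder$decoder
  }
  if (is.null(signal))
    signal <- decoder_signal(session, decoder$space, latent_model)
  bounds <- trial_bin_ranges(session, "start_to_end")
  pred <- predict(decoder, signal, bounds)
  multivariate_r2(session$motor$values[attr(pred, "rows"), , drop = FALSE],
                  pred)
}
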