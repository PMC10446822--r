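#' Maximum mean discrepancy between two samples
#'
#' Kernel two-sample distance under a family of four Gaussian kernels with
#' widths spanning 5 to 50 Hz (defaults `{5, 10, 25, 50}`); the kernel
#' matrices of the family are summed, the squared-MMD estimate is formed,
#' and its square root is reported.  MMD is symmetric in its arguments and
#' zero if and only if the two distributions are identical; the biased
#' estimator (default) is exactly zero when `X` and `Y` are the same
#' sample.
#'
#' @param X,Y Sample matrices (`n x N` and `m x N`; rows are samples).
#' @param kernel_widths Gaussian kernel widths, Hz.
#' @param estimator `"biased"` (V-statistic, default) or `"unbiased"`
#'   (U-statistic, diagonal terms excluded).
#' @return The MMD estimate (non-negative scalar; the unbiased estimator's
#'   squared form may be negative and is floored at 0 before the root).
#' @export
mmd <- function(X, Y, kernel_widths = c(5, 10, 25, 50),
                estimator = c("biased", "unbiased")) {
  estimator <- match.arg(estimator)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same dimensionality")
  if (nrow(X) < 2L || nrow(Y) < 2L) stop("need at least 2 samples per side")
  if (any(!is.finite(X)) || any(!is.finite(Y))) stop("NaNs in input")
  if (any(kernel_widths <= 0)) stop("kernel widths must be positive")
  kxx <- kernel_sum(sq_dists(X, X), kernel_widths)
  kyy <- kernel_sum(sq_dists(Y, Y), kernel_widths)
  kxy <- kernel_sum(sq_dists(X, Y), kernel_widths)
  n <- nrow(X)
  m <- nrow(Y)
  mmd2 <- if (estimator == "biased") {
    mean(kxx) + mean(kyy) - 2 * mean(kxy)
  } else {
    sum(kxx - diag(diag(kxx))) / (n * (n - 1)) +
      sum(kyy - diag(diag(kyy))) / (m * (m - 1)) - 2 * mean(kxy)
  }
  sqrt(max(mmd2, 0))
}

sq_dists <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

kernel_sum <- function(d2, widths) {
  K <- 0
  for (s in widths) K <- K + exp(-d2 / (2 * s^2))
  K
}

# split rows into `folds` contiguous, non-overlapping blocks
contiguous_row_folds <- function(n, folds) {
  as.integer(cut(seq_len(n), breaks = folds, labels = FALSE))
}

#' Within-session MMD baseline
#'
#' The "smallest possible" MMD for a session: its bins are divided into
#' four contiguous non-overlapping folds and the mean MMD over all six
#' unordered fold pairs is returned.
#'
#' @param X Sample matrix (or [rate_array]/session).
#' @param kernel_widths,estimator Passed to [mmd()].
#' @param folds Number of folds (default 4).
#' @return Mean across-fold MMD (non-negative scalar).
#' @export
within_session_mmd <- function(X, kernel_widths = c(5, 10, 25, 50),
                               estimator = "biased", folds = 4L) {
  X <- session_rates(X)
  fold_of <- contiguous_row_folds(nrow(X), folds)
  pairs <- utils::combn(folds, 2L)
  vals <- apply(pairs, 2L, function(p)
    mmd(X[fold_of == p[1], , drop = FALSE],
        X[fold_of == p[2], , drop = FALSE], kernel_widths, estimator))
  mean(vals)
}

#' Between-session MMD
#'
#' Each session is divided into four contiguous non-overlapping folds and
#' the MMD between fold i of one session and fold i of the other
#' (matched-index pairing) is averaged over the four folds.
#'
#' @param A,B Sample matrices (or [rate_array]/session objects).
#' @param kernel_widths,estimator Passed to [mmd()].
#' @param folds Number of folds (default 4).
#' @return Mean matched-fold MMD; symmetric in `(A, B)`.
#' @export
between_session_mmd <- function(A, B, kernel_widths = c(5, 10, 25, 50),
                                estimator = "biased", folds = 4L) {
  A <- session_rates(A)
  B <- session_rates(B)
  fa <- contiguous_row_folds(nrow(A), folds)
  fb <- contiguous_row_folds(nrow(B), folds)
  mean(vapply(seq_len(folds), function(i)
    mmd(A[fa == i, , drop = FALSE], B[fb == i, , drop = FALSE],
        kernel_widths, estimator), numeric(1)))
}

# top-d principal-component basis (columns orthonormal) of a signal; for
# tall matrices the eigendecomposition of the N x N scatter is much
# cheaper than the SVD of the full data matrix
pca_basis <- function(X, d) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2L, colMeans(X))
  if (nrow(Xc) > 4L * ncol(Xc)) {
    eigen(crossprod(Xc), symmetric = TRUE)$vectors[, seq_len(d), drop = FALSE]
  } else {
    svd(Xc, nu = 0, nv = d)$v
  }
}

#' Principal angles between two signals' PCA subspaces
#'
#' Each signal is reduced to its top-`d` principal-component subspace and
#' the `d` canonical angles between the two subspaces are computed from
#' the singular values of the product of the orthonormal bases.  Angles
#' are reported in degrees, sorted ascending, each in `[0, 90]`.
#'
#' @param X0,Xk Signal matrices `T x N` (or [rate_array]/session objects)
#'   on the same channels.
#' @param d Subspace dimensionality (default 10).
#' @return An object of class `principal_angle_result` with `angles`
#'   (length `d`, degrees, non-decreasing) and `d`; bounds can be attached
#'   by [surrogate_angle_bound()] / [within_day_angle_bound()].
#' @export
principal_angles <- function(X0, Xk, d = 10L) {
  X0 <- session_rates(X0)
  Xk <- session_rates(Xk)
  if (ncol(X0) != ncol(Xk)) stop("signals must share channels")
  q0 <- pca_basis(X0, d)
  qk <- pca_basis(Xk, d)
  structure(list(angles = basis_angles(q0, qk), d = as.integer(d)),
            class = "principal_angle_result")
}

basis_angles <- function(q0, qk) {
  s <- svd(crossprod(q0, qk), nu = 0, nv = 0)$d
  sort(acos(pmin(pmax(s, -1), 1)) * 180 / pi)
}

#' Shuffle-surrogate upper bound for principal angles
#'
#' Generates random pairs of "day-0-like" and "day-k-like" subspaces by
#' independently permuting the time indices within each channel of each
#' signal — preserving every channel's marginal firing-rate statistics
#' while destroying the cross-channel correlation structure — then
#' recomputes the principal angles for each pair.  The `pct`-th percentile
#' per angle index is the threshold below which observed angles are
#' smaller than expected by chance given firing-rate statistics alone.
#'
#' @param X0,Xk Signal matrices (or [rate_array]/session objects).
#' @param d Subspace dimensionality.
#' @param n_pairs Number of surrogate pairs (default 10000; values below
#'   100 give an unstable percentile and raise a warning).
#' @param pct Percentile (default 0.1, i.e. the 0.1th percentile).
#' @return Numeric vector of `d` bound angles (degrees).
#' @export
surrogate_angle_bound <- function(X0, Xk, d = 10L, n_pairs = 10000L,
                                  pct = 0.1) {
  X0 <- session_rates(X0)
  Xk <- session_rates(Xk)
  if (n_pairs < 100L) warning("n_pairs < 100: percentile estimate unstable")
  shuffle_cols <- function(X) {
    for (j in seq_len(ncol(X))) X[, j] <- X[sample.int(nrow(X)), j]
    X
  }
  angs <- matrix(0, n_pairs, d)
  for (i in seq_len(n_pairs)) {
    angs[i, ] <- basis_angles(pca_basis(shuffle_cols(X0), d),
                              pca_basis(shuffle_cols(Xk), d))
  }
  apply(angs, 2L, stats::quantile, probs = pct / 100, names = FALSE)
}

#' Within-day principal-angle bound
#'
#' Splits the day-0 session by trial parity (odd-numbered trials vs
#' even-numbered trials, by position in the trial table) and returns the
#' principal angles between the two halves' subspaces — the angle floor
#' attributable to within-day drift and sampling noise.
#'
#' @param session A day-0 [session_recording].
#' @param d Subspace dimensionality.
#' @return Numeric vector of `d` bound angles (degrees).
#' @export
within_day_angle_bound <- function(session, d = 10L) {
  stopifnot(inherits(session, "session_recording"))
  nt <- nrow(session$trials)
  if (nt < 2L) stop("need at least 2 trials")
  odd <- subset_trials(session, seq(1L, nt, by = 2L))
  even <- subset_trials(session, seq(2L, nt, by = 2L))
  principal_angles(odd$rates$rates, even$rates$rates, d)$angles
}

#' Peri-event time histograms
#'
#' Trial-averaged firing rates per condition and channel, aligned at a
#' trial event.  No temporal warping is applied; trials whose window
#' extends past the recording edge contribute only their in-range bins,
#' and the per-bin trial count is reported.
#'
#' @param rates A [rate_array] or matrix.
#' @param trials A [trial_table] on the same bin grid.
#' @param align_event `"start"` or `"go_cue"`.
#' @param window Two numbers, seconds before/after the event (e.g.
#'   `c(-0.2, 1.0)`).
#' @param conditions Optional subset of condition labels to include.
#' @return A list per condition, each with `mean` and `se` matrices
#'   (`W x N`), the per-bin `n` used, `time` (bin-center offsets, s) and
#'   `n_trials`.
#' @export
peth <- function(rates, trials, align_event = c("start", "go_cue"),
                 window = c(-0.2, 1.0), conditions = NULL) {
  align_event <- match.arg(align_event)
  bw <- if (inherits(rates, "rate_array")) rates$bin_width else 0.05
  t0 <- if (inherits(rates, "rate_array")) rates$t0 else 0
  X <- session_rates(rates)
  ev <- if (align_event == "start") trials$start_time else trials$go_cue_time
  b_ev <- time_to_bin(ev, bw, t0) + 1L
  off <- seq(as.integer(floor(window[1] / bw)),
             as.integer(ceiling(window[2] / bw)) - 1L)
  labs <- trials$condition_label
  if (is.null(conditions)) conditions <- sort(unique(labs))
  out <- list()
  for (cond in conditions) {
    idx <- which(labs == cond)
    acc <- matrix(0, length(off), ncol(X))
    acc2 <- matrix(0, length(off), ncol(X))
    cnt <- integer(length(off))
    for (i in idx) {
      b <- b_ev[i] + off
      ok <- b >= 1L & b <= nrow(X)
      acc[ok, ] <- acc[ok, ] + X[b[ok], , drop = FALSE]
      acc2[ok, ] <- acc2[ok, ] + X[b[ok], , drop = FALSE]^2
      cnt[ok] <- cnt[ok] + 1L
    }
    mu <- acc / pmax(cnt, 1L)
    vr <- pmax(acc2 / pmax(cnt, 1L) - mu^2, 0) * cnt / pmax(cnt - 1L, 1L)
    se <- sqrt(vr) / sqrt(pmax(cnt, 1L))
    se[cnt < 2L, ] <- NA_real_
    mu[cnt == 0L, ] <- NA_real_
    out[[as.character(cond)]] <- list(mean = mu, se = se, n = cnt,
                                      time = (off + 0.5) * bw,
                                      n_trials = length(idx))
  }
  out
}
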