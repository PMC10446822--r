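#' Gaussian-kernel smoothing of binned spike counts
#'
#' Convolves each channel's spike counts with a discrete Gaussian kernel
#' (default S.D. 100 ms on 50 ms bins), truncated at +/- 4 S.D. and
#' renormalized to sum 1.  Near the array edges the kernel is renormalized
#' over the bins actually available, so no reflection padding is used and
#' edge bins are not dimmed.  Output is a firing-rate estimate in Hz with
#' the same number of bins as the input.
#'
#' @param counts A [spike_count_array] (or a plain count matrix, in which
#'   case `bin_width` 0.05 s is assumed).
#' @param kernel_sd Gaussian kernel standard deviation, seconds (default
#'   0.1, i.e. 100 ms).
#' @return A [rate_array] with the same bin grid.
#' @export
smooth_counts <- function(counts, kernel_sd = 0.1) {
  if (!inherits(counts, "spike_count_array"))
    counts <- spike_count_array(counts)
  if (!is.numeric(kernel_sd) || kernel_sd <= 0)
    stop("kernel_sd must be positive")
  bw <- counts$bin_width
  x <- counts$counts
  tb <- nrow(x)
  r <- as.integer(ceiling(4 * kernel_sd / bw))
  k <- stats::dnorm((-r):r, mean = 0, sd = kernel_sd / bw)
  k <- k / sum(k)
  # same-length convolution plus per-bin renormalization over in-range taps
  acc <- matrix(0, tb, ncol(x))
  wsum <- numeric(tb)
  for (j in (-r):r) {
    src <- seq_len(tb) + j
    ok <- src >= 1L & src <= tb
    w <- k[j + r + 1L]
    acc[ok, ] <- acc[ok, ] + w * x[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + w
  }
  rate_array(acc / wsum / bw, bin_width = bw, t0 = counts$t0)
}

#' EMG envelope preprocessing
#'
#' Per channel: full-wave rectification, 4-pole 10 Hz low-pass Butterworth
#' (applied forward-backward, i.e. zero phase, since decoding here is
#' offline), subsampling to 20 Hz, clipping at the channel mean plus
#' `clip_sd` standard deviations, baseline subtraction of the 2nd
#' percentile, and normalization by the 90th percentile of the
#' baseline-subtracted envelope.  All statistics are computed per channel
#' within the recording session, in that fixed order.  Channels that are
#' constant after filtering (normalization would divide by zero) are
#' dropped with a message; channels listed in `exclude` (e.g. known noisy
#' leads) are dropped up front.
#'
#' @param raw Numeric matrix `samples x M` of raw (band-passed, amplified)
#'   EMG.
#' @param fs Sampling frequency in Hz; must be at least 1000.
#' @param subsample Either `"decimate"` (take every n-th filtered sample,
#'   the default) or `"bin_average"` (average consecutive blocks).
#' @param target_fs Output sampling rate, Hz (default 20, matching 50 ms
#'   bins).
#' @param clip_sd Clip threshold in standard deviations above the mean.
#' @param exclude Optional channel indices or names to drop before
#'   processing.
#' @param dim_labels Optional channel names.
#' @return A [motor_output] of kind `"emg"` at `target_fs`.
#' @export
preprocess_emg <- function(raw, fs, subsample = c("decimate", "bin_average"),
                           target_fs = 20, clip_sd = 6, exclude = NULL,
                           dim_labels = NULL) {
  subsample <- match.arg(subsample)
  raw <- as.matrix(raw)
  if (fs < 1000) stop("fs must be at least 1000 Hz")
  if (is.null(dim_labels)) dim_labels <- paste0("emg", seq_len(ncol(raw)))
  if (!is.null(exclude)) {
    drop_idx <- if (is.character(exclude)) match(exclude, dim_labels) else
      as.integer(exclude)
    keep <- setdiff(seq_len(ncol(raw)), drop_idx)
    raw <- raw[, keep, drop = FALSE]
    dim_labels <- dim_labels[keep]
  }
  ratio <- fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("fs must be an integer multiple of target_fs")
  ratio <- as.integer(round(ratio))

  # constant nonzero channels would divide by zero at normalization
  const <- which(apply(raw, 2L, function(ch) stats::sd(ch) == 0 &&
                         any(ch != 0)))
  if (length(const)) {
    message("dropping constant EMG channel(s): ",
            paste(dim_labels[const], collapse = ", "))
    raw <- raw[, -const, drop = FALSE]
    dim_labels <- dim_labels[-const]
  }

  env <- filter_rectified_emg(raw, fs)
  env <- if (subsample == "decimate") {
    env[seq(1L, nrow(env), by = ratio), , drop = FALSE]
  } else {
    nblk <- floor(nrow(env) / ratio)
    apply(env[seq_len(nblk * ratio), , drop = FALSE], 2L, function(ch)
      colMeans(matrix(ch, nrow = ratio)))
  }

  out <- env
  for (j in seq_len(ncol(out))) {
    ch <- out[, j]
    if (all(ch == 0)) next
    hi <- mean(ch) + clip_sd * stats::sd(ch)
    ch <- pmin(ch, hi)
    ch <- ch - stats::quantile(ch, 0.02, names = FALSE)
    p90 <- stats::quantile(ch, 0.90, names = FALSE)
    if (p90 <= 0) p90 <- max(ch, 1)
    out[, j] <- ch / p90
  }
  motor_output(out, kind = "emg", dim_labels = dim_labels, units = "a.u.")
}

# rectify + zero-phase 4-pole 10 Hz Butterworth, full rate
filter_rectified_emg <- function(raw, fs) {
  if (fs / 2 <= 10) stop("sampling rate below Nyquist for the 10 Hz filter")
  bf <- signal::butter(4, 10 / (fs / 2), type = "low")
  out <- abs(raw)
  for (j in seq_len(ncol(out)))
    out[, j] <- signal::filtfilt(bf, out[, j])
  out
}

#' Restrict a session to within-trial data
#'
#' Keeps only the bins inside each trial's window and concatenates them,
#' preserving trial boundaries in the table.  No temporal resampling or
#' cross-trial alignment is performed; trials keep their native lengths.
#' The window convention follows the task: reaching/wrist tasks use the
#' full trial (`"start_to_end"`), grasp and center-out tasks where the
#' subject is idle before the cue use `"gocue_to_end"`.
#'
#' @param session A [session_recording].
#' @param window `"start_to_end"` or `"gocue_to_end"`.
#' @return A [session_recording] restricted to within-trial bins.  The
#'   operation is idempotent: applying it twice equals applying it once.
#' @export
extract_trial_data <- function(session,
                               window = c("start_to_end", "gocue_to_end")) {
  window <- match.arg(window)
  if (nrow(session$trials) < 1L) stop("session has no trials")
  rng <- trial_bin_ranges(session, window)
  bins <- unlist(lapply(seq_len(nrow(rng)), function(i) rng[i, 1]:rng[i, 2]))
  bw <- session$rates$bin_width
  len <- rng[, 2] - rng[, 1] + 1L
  new_start <- c(0L, cumsum(len))[seq_along(len)] * bw
  trials <- trial_table(start_time = new_start,
                        go_cue_time = new_start,
                        end_time = new_start + len * bw,
                        condition_label = session$trials$condition_label,
                        success = session$trials$success,
                        trial_id = session$trials$trial_id)
  session_recording(
    rate_array(session$rates$rates[bins, , drop = FALSE], bw,
               session$rates$channel_ids, t0 = 0),
    motor_output(session$motor$values[bins, , drop = FALSE],
                 session$motor$kind, session$motor$dim_labels,
                 session$motor$units),
    trials, session$day_index, session$task_tag,
    ground_truth = local({
      gt <- session$ground_truth
      if (!is.null(gt) && !is.null(gt$latents))
        gt$latents <- gt$latents[bins, , drop = FALSE]
      gt
    }))
}
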