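#' Binned spike counts
#'
#' Container for multiunit threshold-crossing counts in non-overlapping time
#' bins (one column per electrode).  Bins are half-open `[t, t + bin_width)`
#' and indexed from 0 at time `t0`.
#'
#' @param counts Integer matrix, `T_bins x N_channels`, all values `>= 0`.
#' @param bin_width Bin width in seconds (default 0.05, i.e. 50 ms).
#' @param t0 Time of the left edge of the first bin, seconds.
#' @return An object of class `spike_count_array`.
#' @export
spike_count_array <- function(counts, bin_width = 0.05, t0 = 0) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L) stop("counts must have at least one bin")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  structure(list(counts = counts, bin_width = bin_width, t0 = t0),
            class = "spike_count_array")
}

#' Smoothed firing rates
#'
#' @param rates Real matrix, `T_bins x N_channels`, in Hz, all values `>= 0`.
#' @param bin_width Bin width in seconds.
#' @param channel_ids Optional electrode labels (defaults to `ch1..chN`).
#' @param t0 Time of the first bin edge, seconds.
#' @return An object of class `rate_array`.
#' @export
rate_array <- function(rates, bin_width = 0.05, channel_ids = NULL, t0 = 0) {
  rates <- as.matrix(rates)
  if (any(!is.finite(rates)) || any(rates < -1e-9))
    stop("rates must be finite and non-negative")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(ncol(rates)))
  if (length(channel_ids) != ncol(rates))
    stop("channel_ids length must match the number of channels")
  structure(list(rates = rates, bin_width = bin_width,
                 channel_ids = as.character(channel_ids), t0 = t0),
            class = "rate_array")
}

#' Motor outputs paired with a neural recording
#'
#' @param values Real matrix `T_bins x M_dims` on the same bin grid as the
#'   paired rates.
#' @param kind Either `"emg"` (normalized envelopes) or `"velocity"`.
#' @param dim_labels Optional labels for the output dimensions.
#' @param units Unit string; defaults to `"a.u."` for EMG, `"cm/s"` for
#'   velocity.
#' @return An object of class `motor_output`.
#' @export
motor_output <- function(values, kind = c("emg", "velocity"),
                         dim_labels = NULL, units = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("motor values must be finite")
  if (is.null(dim_labels)) dim_labels <- paste0("dim", seq_len(ncol(values)))
  if (is.null(units)) units <- if (kind == "emg") "a.u." else "cm/s"
  structure(list(values = values, kind = kind,
                 dim_labels = as.character(dim_labels), units = units),
            class = "motor_output")
}

#' Trial event table
#'
#' @param start_time,go_cue_time,end_time Event times in seconds; must obey
#'   `start <= go_cue <= end` and trials must be time-ordered and
#'   non-overlapping.
#' @param condition_label Condition (e.g. target direction) per trial.
#' @param success Logical success flag per trial.
#' @param trial_id Optional ids (defaults to `1..n`).
#' @return A `data.frame` of class `trial_table`.
#' @export
trial_table <- function(start_time, go_cue_time = start_time, end_time,
                        condition_label = NA, success = TRUE,
                        trial_id = NULL) {
  n <- length(start_time)
  if (is.null(trial_id)) trial_id <- seq_len(n)
  tt <- data.frame(trial_id = trial_id, start_time = start_time,
                   go_cue_time = go_cue_time, end_time = end_time,
                   condition_label = condition_label,
                   success = rep_len(as.logical(success), n))
  if (any(tt$start_time > tt$go_cue_time) || any(tt$go_cue_time > tt$end_time))
    stop("trials must satisfy start <= go_cue <= end")
  if (n > 1L) {
    if (is.unsorted(tt$start_time)) stop("trials must be time-ordered")
    if (any(tt$end_time[-n] > tt$start_time[-1] + 1e-9))
      stop("trials must be non-overlapping")
  }
  class(tt) <- c("trial_table", "data.frame")
  tt
}

#' One day's recording session
#'
#' The universal unit of input: smoothed firing rates, paired motor outputs
#' and the trial table, all sharing one bin grid, plus the day index relative
#' to the designated day-0 (may be negative for sessions recorded earlier).
#'
#' @param rates A [rate_array].
#' @param motor A [motor_output] on the same bin grid.
#' @param trials A [trial_table].
#' @param day_index Integer day offset from day-0.
#' @param task_tag Free-form task identifier.
#' @param counts Optional [spike_count_array] the rates were smoothed from.
#' @param ground_truth Optional simulator ground truth (latents, loading,
#'   perturbation and inverse map); `NULL` for recorded data.
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(rates, motor, trials, day_index = 0L,
                              task_tag = "unknown", counts = NULL,
                              ground_truth = NULL) {
  stopifnot(inherits(rates, "rate_array"), inherits(motor, "motor_output"),
            inherits(trials, "trial_table"))
  if (nrow(rates$rates) != nrow(motor$values))
    stop("rates and motor outputs must share one bin grid")
  structure(list(rates = rates, motor = motor, trials = trials,
                 day_index = as.integer(day_index), task_tag = task_tag,
                 counts = counts, ground_truth = ground_truth),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> day %d, task '%s': %d bins x %d channels, %d %s dims, %d trials\n",
    x$day_index, x$task_tag, nrow(x$rates$rates), ncol(x$rates$rates),
    ncol(x$motor$values), x$motor$kind, nrow(x$trials)))
  invisible(x)
}

# bin index (0-based) of an event time on a session's grid; events are
# snapped to floor(t / bin_width)
time_to_bin <- function(t, bin_width, t0 = 0) {
  as.integer(floor((t - t0) / bin_width + 1e-9))
}

#' Number of time bins in a session
#' @param session A [session_recording].
#' @return Integer bin count.
#' @export
n_bins <- function(session) nrow(session$rates$rates)

#' Row ranges covered by each trial
#'
#' The 1-based, inclusive `(start, end)` row range of each trial on the
#' session's bin grid — the `trial_bounds` format [lag_embed()] and
#' [predict.wiener_decoder()] expect.
#'
#' @param session A [session_recording].
#' @param window `"start_to_end"` or `"gocue_to_end"`.
#' @return Two-column integer matrix, one row per trial.
#' @export
trial_bin_ranges <- function(session,
                             window = c("start_to_end", "gocue_to_end")) {
  window <- match.arg(window)
  bw <- session$rates$bin_width
  t0 <- session$rates$t0
  from <- if (window == "start_to_end") session$trials$start_time else
    session$trials$go_cue_time
  b0 <- time_to_bin(from, bw, t0) + 1L
  b1 <- time_to_bin(session$trials$end_time, bw, t0)
  b0 <- pmax(b0, 1L)
  b1 <- pmin(b1, n_bins(session))
  if (any(b1 < b0)) stop("trial window outside recording or empty")
  cbind(start = b0, end = b1)
}

schema_version <- "1"

write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  if (is.integer(m) || all(m == round(m))) {
    txt <- apply(m, 1L, function(r) paste(format(r, scientific = FALSE),
                                          collapse = "\t"))
  } else {
    txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  }
  writeLines(txt, path)
}

read_matrix_tsv <- function(path, integer = FALSE) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (integer) storage.mode(m) <- "integer"
  m
}

#' Write a session to disk
#'
#' Sessions are stored as a directory holding plain-text components:
#' `meta.json` (bin width, channel ids, day index, task tag, schema version),
#' `rates.tsv`, `motor.tsv`, `trials.csv`, optional `counts.tsv` and, for
#' simulated sessions, a `ground_truth/` sidecar.  The round trip through
#' [read_session()] is lossless (bit-exact for integer counts, full double
#' precision for rates).
#'
#' @param session A [session_recording].
#' @param path Directory to create (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_recording"))
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  meta <- list(schema_version = schema_version,
               bin_width = session$rates$bin_width,
               t0 = session$rates$t0,
               channel_ids = session$rates$channel_ids,
               motor_kind = session$motor$kind,
               motor_labels = session$motor$dim_labels,
               motor_units = session$motor$units,
               day_index = session$day_index,
               task_tag = session$task_tag)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  write_matrix_tsv(session$rates$rates, file.path(path, "rates.tsv"))
  write_matrix_tsv(session$motor$values, file.path(path, "motor.tsv"))
  utils::write.csv(as.data.frame(session$trials),
                   file.path(path, "trials.csv"), row.names = FALSE)
  if (!is.null(session$counts))
    write_matrix_tsv(session$counts$counts, file.path(path, "counts.tsv"))
  if (!is.null(session$ground_truth)) {
    gt <- session$ground_truth
    gdir <- file.path(path, "ground_truth")
    dir.create(gdir)
    for (nm in c("latents", "loading")) {
      if (!is.null(gt[[nm]]))
        write_matrix_tsv(gt[[nm]], file.path(gdir, paste0(nm, ".tsv")))
    }
    rest <- gt[setdiff(names(gt), c("latents", "loading"))]
    jsonlite::write_json(rest, file.path(gdir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a session from disk
#'
#' @param path Directory written by [write_session()].
#' @return A [session_recording].
#' @export
read_session <- function(path) {
  need <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) stop(sprintf("session at '%s' is missing '%s'",
                                      path, f))
    p
  }
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), schema_version))
    stop(sprintf("schema version mismatch: found '%s', expected '%s'",
                 meta$schema_version, schema_version))
  rates <- rate_array(read_matrix_tsv(need("rates.tsv")),
                      bin_width = meta$bin_width,
                      channel_ids = meta$channel_ids, t0 = meta$t0)
  motor <- motor_output(read_matrix_tsv(need("motor.tsv")),
                        kind = meta$motor_kind,
                        dim_labels = meta$motor_labels,
                        units = meta$motor_units)
  td <- utils::read.csv(need("trials.csv"))
  trials <- trial_table(td$start_time, td$go_cue_time, td$end_time,
                        td$condition_label, td$success, td$trial_id)
  counts <- NULL
  if (file.exists(file.path(path, "counts.tsv")))
    counts <- spike_count_array(read_matrix_tsv(file.path(path, "counts.tsv"),
                                                integer = TRUE),
                                bin_width = meta$bin_width, t0 = meta$t0)
  gt <- NULL
  gdir <- file.path(path, "ground_truth")
  if (dir.exists(gdir)) {
    gt <- jsonlite::read_json(file.path(gdir, "params.json"),
                              simplifyVector = TRUE)
    for (nm in c("latents", "loading")) {
      f <- file.path(gdir, paste0(nm, ".tsv"))
      if (file.exists(f)) gt[[nm]] <- read_matrix_tsv(f)
    }
  }
  session_recording(rates, motor, trials, meta$day_index, meta$task_tag,
                    counts = counts, ground_truth = gt)
}

#' Restrict a session to a subset of trials
#'
#' Keeps the selected trials' bins (concatenated, time order preserved) and
#' rewrites the trial table onto the new contiguous grid.  Used to carve
#' train/test trial splits.
#'
#' @param session A [session_recording].
#' @param idx Trial indices (positions in the trial table) to keep.
#' @return A [session_recording] containing only the selected trials.
#' @export
subset_trials <- function(session, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) < 1L || any(idx < 1L) || any(idx > nrow(session$trials)))
    stop("trial indices out of range")
  rng <- trial_bin_ranges(session, "start_to_end")[idx, , drop = FALSE]
  bins <- unlist(lapply(seq_len(nrow(rng)),
                        function(i) rng[i, 1]:rng[i, 2]))
  bw <- session$rates$bin_width
  len <- rng[, 2] - rng[, 1] + 1L
  new_start <- c(0L, cumsum(len))[seq_along(len)] * bw
  old <- session$trials[idx, , drop = FALSE]
  gc_off <- pmax(time_to_bin(old$go_cue_time, bw, session$rates$t0) + 1L -
                   rng[, 1], 0L)
  trials <- trial_table(start_time = new_start,
                        go_cue_time = new_start + gc_off * bw,
                        end_time = new_start + len * bw,
                        condition_label = old$condition_label,
                        success = old$success, trial_id = old$trial_id)
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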