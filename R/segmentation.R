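#' Construct an EEG recording object
#'
#' A light container for one subject's multichannel signal: a channels x time
#' numeric matrix with electrode names, a sampling rate and a subject id.
#'
#' @param subject_id Identifier.
#' @param samples Numeric matrix, channels x time, rownames = electrode labels
#'   (or supply `channel_names`).
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional electrode labels overriding rownames.
#' @return An object of class `eeg_recording` with fields `subject_id`,
#'   `channel_names`, `fs`, `samples`, `duration_s`.
#' @export
eeg_recording <- function(subject_id, samples, fs, channel_names = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop_input("samples must be a channels x time numeric matrix")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop_input("recording for subject ", subject_id, " has non-finite samples")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop_input("fs must be a single positive number")
  }
  channel_names <- channel_names %||% rownames(samples)
  if (is.null(channel_names) || length(channel_names) != nrow(samples)) {
    stop_input("one channel name per signal row is required")
  }
  rownames(samples) <- channel_names
  structure(
    list(
      subject_id = as.character(subject_id),
      channel_names = channel_names,
      fs = fs,
      samples = samples,
      duration_s = ncol(samples) / fs
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(
    "<eeg_recording>", x$subject_id, "-", length(x$channel_names),
    "channel(s) [", paste(x$channel_names, collapse = ", "), "] @",
    x$fs, "Hz,", x$duration_s, "s\n"
  )
  invisible(x)
}

#' Define a windowing scheme
#'
#' Non-overlapping windows tile the recording from t = 0 in steps of the
#' window length; overlapping (sliding) windows advance by `step_s` seconds,
#' so consecutive windows share `window_s - step_s` seconds of signal. With
#' `window_s == step_s` the overlapping scheme degenerates to the
#' non-overlapping one.
#'
#' @param mode `"non_overlapping"` or `"overlapping"`.
#' @param window_s Window length in seconds (default 10 for non-overlapping,
#'   20 for overlapping).
#' @param step_s Step size in seconds (overlapping mode; default 10).
#' @return An object of class `segmentation_scheme`.
#' @export
segmentation_scheme <- function(mode = c("non_overlapping", "overlapping"),
                                window_s = NULL, step_s = 10) {
  mode <- match.arg(mode)
  window_s <- window_s %||% if (mode == "non_overlapping") 10 else 20
  if (window_s <= 0) stop_input("window_s must be > 0")
  if (mode == "overlapping") {
    if (step_s <= 0) stop_input("step_s must be > 0")
    if (window_s < step_s) {
      stop_input("overlapping mode requires window_s >= step_s")
    }
  } else {
    step_s <- window_s
  }
  structure(
    list(mode = mode, window_s = window_s, step_s = step_s),
    class = "segmentation_scheme"
  )
}

#' Closed-form window count
#'
#' Number of windows per channel a scheme yields on a recording of the given
#' duration: `floor(duration_s / window_s)` for non-overlapping tiling,
#' `floor((duration_s - window_s) / step_s) + 1` for sliding windows (0 when
#' the recording is shorter than one window).
#'
#' @param duration_s Recording length in seconds.
#' @param scheme A [segmentation_scheme()].
#' @return Integer window count per channel.
#' @export
count_segments <- function(duration_s, scheme) {
  stopifnot(inherits(scheme, "segmentation_scheme"))
  if (duration_s < scheme$window_s) {
    return(0L)
  }
  if (scheme$mode == "non_overlapping") {
    as.integer(floor(duration_s / scheme$window_s))
  } else {
    as.integer(floor((duration_s - scheme$window_s) / scheme$step_s) + 1)
  }
}

#' Split a recording into windows
#'
#' Cuts each channel independently into fixed-length windows at identical
#' offsets. Windows are half-open `[k * step, k * step + window)` in seconds;
#' trailing partial windows are discarded (no padding), so a 480 s recording
#' yields exactly 48 non-overlapping 10 s windows per channel. A recording
#' shorter than one window yields zero segments with a warning, not an error.
#'
#' @param rec An [eeg_recording()].
#' @param scheme A [segmentation_scheme()].
#' @return A tibble with one row per (channel, window): `subject_id`,
#'   `channel`, `start_s`, `fs`, and a `samples` list-column of numeric
#'   vectors of exact length `round(window_s * fs)`.
#' @export
segment_recording <- function(rec, scheme) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(scheme, "segmentation_scheme"))
  n_win <- count_segments(rec$duration_s, scheme)
  if (n_win == 0) {
    warning(
      "recording ", rec$subject_id, " (", rec$duration_s,
      " s) is shorter than one ", scheme$window_s, " s window; no segments",
      call. = FALSE
    )
    return(tibble::tibble(
      subject_id = character(), channel = character(),
      start_s = numeric(), fs = numeric(), samples = list()
    ))
  }
  win_len <- round(scheme$window_s * rec$fs)
  step_len <- scheme$step_s * rec$fs
  starts <- (seq_len(n_win) - 1) * step_len
  if (abs(step_len - round(step_len)) > 1e-9) {
    stop_input("step_s * fs must be an integer number of samples")
  }
  starts <- round(starts)

  rows <- vector("list", length(rec$channel_names) * n_win)
  k <- 1L
  for (ch in rec$channel_names) {
    sig <- rec$samples[ch, ]
    for (j in seq_len(n_win)) {
      idx <- (starts[j] + 1L):(starts[j] + win_len)
      rows[[k]] <- tibble::tibble(
        subject_id = rec$subject_id,
        channel = ch,
        start_s = starts[j] / rec$fs,
        fs = rec$fs,
        samples = list(sig[idx])
      )
      k <- k + 1L
    }
  }
  dplyr::bind_rows(rows)
}
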