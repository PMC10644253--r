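#' Construct an EEG recording object
#'
#' @param data channels x samples numeric matrix (any amplitude scale; PLV is
#'   amplitude-invariant).
#' @param fs sampling rate in Hz.
#' @param subject_id subject label carried through windowing to training.
#' @param condition optional free tag (e.g. `"EO"`, `"EC"`).
#' @param labels optional channel labels (montage order).
#' @return A `vnfc_recording`.
#' @export
new_recording <- function(data, fs, subject_id, condition = NULL, labels = NULL) {
  data <- as.matrix(data)
  dimnames(data) <- NULL
  if (!is.numeric(data) || !all(is.finite(data))) {
    rlang::abort("recording data must be a finite numeric matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    rlang::abort("fs must be a positive scalar (Hz)")
  }
  if (!is.null(labels) && length(labels) != nrow(data)) {
    rlang::abort("labels length must equal the number of channels")
  }
  structure(list(data = data, fs = fs,
                 subject_id = as.character(subject_id),
                 condition = condition, labels = labels),
            class = "vnfc_recording")
}

#' @export
print.vnfc_recording <- function(x, ...) {
  cat(sprintf("<vnfc_recording: %d ch x %d samples @ %g Hz, subject %s%s>\n",
              nrow(x$data), ncol(x$data), x$fs, x$subject_id,
              if (is.null(x$condition)) "" else paste0(" (", x$condition, ")")))
  invisible(x)
}

#' Optional band-pass preprocessing hook
#'
#' Off by default throughout the package: the identification pipeline
#' consumes raw, unpreprocessed signals. When invoked, applies a zero-phase
#' 4th-order Butterworth band-pass.
#'
#' @param rec a `vnfc_recording`.
#' @param low,high band edges in Hz.
#' @return A filtered `vnfc_recording`.
#' @export
bandpass <- function(rec, low, high) {
  stopifnot(inherits(rec, "vnfc_recording"), low > 0, high > low, high < rec$fs / 2)
  if (!requireNamespace("signal", quietly = TRUE)) {
    rlang::abort("the 'signal' package is required for bandpass()")
  }
  bf <- signal::butter(4, c(low, high) / (rec$fs / 2), type = "pass")
  out <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  new_recording(out, rec$fs, rec$subject_id, rec$condition, rec$labels)
}

#' Cut a recording into fixed-length overlapping windows
#'
#' The identification pipeline trains and tests on short windows rather than
#' whole recordings; the default is a 1-s moving window with 50% overlap. The
#' hop is `window_s * (1 - overlap)` seconds and any trailing partial window
#' is discarded.
#'
#' @param rec a `vnfc_recording`, or a list of them.
#' @param window_s window length in seconds (default 1).
#' @param overlap fractional overlap between consecutive windows in `[0, 1)`
#'   (default 0.5).
#' @return A tibble with one row per window: `subject_id`, `condition`,
#'   `offset` (first sample index, 0-based), `fs`, and a list-column `data` of
#'   channels x window-samples matrices.
#' @examples
#' rec <- new_recording(matrix(rnorm(2 * 320), 2), fs = 160, subject_id = "s1")
#' nrow(sliding_windows(rec))  # floor((320-160)/80)+1 = 3
#' @export
sliding_windows <- function(rec, window_s = 1.0, overlap = 0.5) {
  if (is.list(rec) && !inherits(rec, "vnfc_recording")) {
    return(dplyr::bind_rows(lapply(rec, sliding_windows,
                                   window_s = window_s, overlap = overlap)))
  }
  stopifnot(inherits(rec, "vnfc_recording"))
  if (overlap < 0 || overlap >= 1) rlang::abort("overlap must be in [0, 1)")
  win <- as.integer(round(rec$fs * window_s))
  if (win < 1) rlang::abort("window too short for this sampling rate")
  total <- ncol(rec$data)
  if (total < win) rlang::abort("recording shorter than one window")
  hop <- as.integer(round(win * (1 - overlap)))
  if (hop < 1) rlang::abort("overlap too large: hop would be zero samples")
  n_win <- (total - win) %/% hop + 1L
  starts <- (seq_len(n_win) - 1L) * hop
  tibble::tibble(
    subject_id = rec$subject_id,
    condition = rec$condition %||% NA_character_,
    offset = starts,
    fs = rec$fs,
    data = lapply(starts, function(s) rec$data[, (s + 1L):(s + win), drop = FALSE])
  )
}
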