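#' Standard 10-20 channel names
#'
#' The 21-name montage used for synthetic recordings; dropping the midline
#' references Cz and Pz leaves the 19 channels the classifier expects.
#'
#' @param n 19 (post-drop) or 21 (full montage).
#' @return Character vector of channel names.
#' @export
standard_channels <- function(n = 19) {
  full <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
            "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz", "A1", "A2")
  if (n == 21) return(full)
  if (n == 19) return(setdiff(full, c("Cz", "Pz")))
  stop("n must be 19 or 21")
}

FEATURE_STATS <- c("std", "kurt", "skew", "mean")

#' Construct an EEG segment
#'
#' One windowed second of multichannel signal plus its label and provenance.
#'
#' @param data Channels x samples numeric matrix (microvolt scale).
#' @param label Integer class in `{0, 1, 2, 3}` (normal, complex partial,
#'   electrographic, video-detected).
#' @param fs Sampling rate in Hz.
#' @param t_start Window start time in seconds from recording start.
#' @param subject_id Identifier string.
#' @param channel_names Optional channel names (length `nrow(data)`).
#' @return Object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, label = 0L, fs = 500, t_start = 0,
                        subject_id = "", channel_names = NULL) {
  data <- as.matrix(data)
  stopifnot(fs > 0, label %in% 0:3)
  if (is.null(channel_names)) channel_names <- rownames(data)
  if (!is.null(channel_names)) {
    stopifnot(length(channel_names) == nrow(data))
    rownames(data) <- channel_names
  }
  structure(list(data = data, label = as.integer(label), fs = fs,
                 t_start = t_start, subject_id = subject_id,
                 channel_names = channel_names),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat("EEG segment:", nrow(x$data), "channels x", ncol(x$data), "samples @",
      x$fs, "Hz, label", x$label,
      if (nzchar(x$subject_id)) paste0("(", x$subject_id, ")") else "", "\n")
  invisible(x)
}

#' Cut a recording into labeled one-second segments
#'
#' Non-overlapping contiguous windows of `window_seconds` are cut from the
#' start of the recording; a trailing partial window is discarded, so the
#' segment count is `floor(samples / (fs * window_seconds))`.
#'
#' @param signal Channels x samples numeric matrix.
#' @param fs Sampling rate (Hz).
#' @param labels Per-window label sequence; must cover every whole window.
#' @param window_seconds Window length in seconds (default 1).
#' @param subject_id,channel_names Provenance passed to each segment.
#' @param expected_channels If given, the channel count is checked against it.
#' @return List of [eeg_segment()] objects.
#' @export
segment_recording <- function(signal, fs, labels, window_seconds = 1,
                              subject_id = "", channel_names = NULL,
                              expected_channels = NULL) {
  signal <- as.matrix(signal)
  stopifnot(fs > 0, window_seconds > 0)
  if (!is.null(expected_channels) && nrow(signal) != expected_channels)
    stop("recording has ", nrow(signal), " channels; expected ",
         expected_channels)
  win <- as.integer(round(fs * window_seconds))
  n_win <- ncol(signal) %/% win
  if (n_win == 0) return(list())
  if (length(labels) < n_win)
    stop("label sequence shorter than the number of whole windows")
  if (is.null(channel_names)) channel_names <- rownames(signal)
  lapply(seq_len(n_win), function(i) {
    cols <- ((i - 1) * win + 1):(i * win)
    eeg_segment(signal[, cols, drop = FALSE], label = labels[i], fs = fs,
                t_start = (i - 1) * window_seconds, subject_id = subject_id,
                channel_names = channel_names)
  })
}

#' Drop named channels from a recording
#'
#' Removes reference channels (by default the midline electrodes Cz and Pz)
#' so records with differing montages become uniform. Channels absent from
#' the recording are skipped with a warning; remaining channel order is
#' preserved, and an empty drop list is the identity.
#'
#' @param signal Channels x samples matrix with channel names as rownames,
#'   or an [eeg_segment()].
#' @param names Channels to remove (default `c("Cz", "Pz")`).
#' @return Object of the same kind with the named channels removed.
#' @export
drop_channels <- function(signal, names = c("Cz", "Pz")) {
  if (inherits(signal, "eeg_segment")) {
    signal$data <- drop_channels(signal$data, names)
    signal$channel_names <- rownames(signal$data)
    return(signal)
  }
  signal <- as.matrix(signal)
  if (length(names) == 0) return(signal)
  have <- rownames(signal)
  if (is.null(have)) stop("recording has no channel names; cannot drop by name")
  missing <- setdiff(names, have)
  if (length(missing))
    warning("channel(s) not present, skipped: ", paste(missing, collapse = ", "))
  signal[!(have %in% names), , drop = FALSE]
}

channel_moments <- function(x) {
  m <- mean(x)
  c2 <- mean((x - m)^2)
  if (c2 == 0) return(c(std = 0, kurt = 0, skew = 0, mean = m))
  c3 <- mean((x - m)^3)
  c4 <- mean((x - m)^4)
  c(std = sqrt(c2), kurt = c4 / c2^2 - 3, skew = c3 / c2^1.5, mean = m)
}

#' Extract per-channel statistical features from a segment
#'
#' For every channel, four statistics of its samples: population standard
#' deviation, Fisher excess kurtosis, skewness, and arithmetic mean
#' (channel-major order, 4 values per channel, 76 for 19 channels). Moments
#' are bias-uncorrected; a constant channel yields std = kurtosis =
#' skewness = 0 by convention.
#'
#' @param segment An [eeg_segment()] or channels x samples matrix.
#' @return Named numeric vector of length `4 * n_channels`, with the
#'   segment's label attached as attribute `label` when available.
#' @export
extract_features <- function(segment) {
  mat <- if (inherits(segment, "eeg_segment")) segment$data else
    as.matrix(segment)
  if (anyNA(mat)) {
    bad <- which(apply(mat, 1, anyNA))
    nm <- rownames(mat)[bad] %||% bad
    stop("NaN/NA in channel(s): ", paste(nm, collapse = ", "))
  }
  feats <- t(apply(mat, 1, channel_moments))
  v <- as.numeric(t(feats))
  ch <- rownames(mat) %||% paste0("ch", seq_len(nrow(mat)))
  names(v) <- as.vector(t(outer(ch, FEATURE_STATS, paste, sep = "_")))
  if (inherits(segment, "eeg_segment")) attr(v, "label") <- segment$label
  v
}

#' Build a feature table from a list of segments
#'
#' @param segments List of [eeg_segment()] objects.
#' @return Data frame with columns `subject_id`, `t_start`, `label`, then
#'   one column per feature.
#' @export
featurize_segments <- function(segments) {
  stopifnot(length(segments) > 0)
  feats <- t(vapply(segments, extract_features,
                    numeric(4 * nrow(segments[[1]]$data))))
  meta <- data.frame(
    subject_id = vapply(segments, function(s) s$subject_id, character(1)),
    t_start = vapply(segments, function(s) s$t_start, numeric(1)),
    label = vapply(segments, function(s) s$label, integer(1)))
  cbind(meta, as.data.frame(feats))
}

feature_columns <- function(df) {
  setdiff(colnames(df), c("subject_id", "t_start", "label"))
}

#' Fit min-max normalization parameters
#'
#' Per-feature minima and maxima, fitted on training data only, for the
#' scaling `(x - x_min) / (x_max - x_min)` onto `[0, 1]`.
#'
#' @param train Numeric matrix or feature data frame (metadata columns
#'   `subject_id`, `t_start`, `label` are ignored).
#' @return Object of class `minmax_params` with `x_min`, `x_max`.
#' @export
fit_normalizer <- function(train) {
  X <- normalizer_matrix(train)
  stopifnot(nrow(X) > 0)
  structure(list(x_min = apply(X, 2, min), x_max = apply(X, 2, max)),
            class = "minmax_params")
}

normalizer_matrix <- function(x) {
  if (is.data.frame(x)) x <- x[, feature_columns(x), drop = FALSE]
  as.matrix(x)
}

#' Apply fitted min-max normalization
#'
#' Scales each feature by its fitted training range; values outside the
#' range (possible on test data) are clipped to `[0, 1]`, and a feature
#' that was constant in training maps to 0.
#'
#' @param params A `minmax_params` from [fit_normalizer()].
#' @param x Numeric vector, matrix, or feature data frame.
#' @return Normalized object of the same shape (data frames keep their
#'   metadata columns).
#' @export
apply_normalizer <- function(params, x) {
  stopifnot(inherits(params, "minmax_params"))
  if (is.data.frame(x)) {
    fc <- feature_columns(x)
    x[, fc] <- apply_normalizer(params, as.matrix(x[, fc, drop = FALSE]))
    return(x)
  }
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  stopifnot(ncol(X) == length(params$x_min))
  rng <- params$x_max - params$x_min
  X <- sweep(X, 2, params$x_min)
  X <- sweep(X, 2, ifelse(rng > 0, rng, 1), "/")
  X[, rng == 0] <- 0
  X <- pmin(pmax(X, 0), 1)
  if (vec) drop(X) else X
}
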