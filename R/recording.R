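#' EEG recording container
#'
#' Holds a channels x samples data matrix in microvolts together with the
#' sampling rate, montage, epoch structure and subject metadata.  Epochs
#' are half-open sample intervals `[start, end)` in 0-based sample indices;
#' they must be disjoint, sorted, and lie within the recording.
#'
#' @param data numeric E x T matrix (rows = electrodes in montage order).
#' @param fs_hz sampling rate in Hz.
#' @param montage a [montage()] whose electrode count matches `nrow(data)`.
#' @param epochs integer matrix with columns `start`, `end` (half-open,
#'   0-based); default: one epoch spanning the whole recording.
#' @param subject_id,group,migraine subject metadata (group is an arbitrary
#'   label, migraine a logical flag used for subgroup filtering).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs_hz, montage, epochs = NULL,
                          subject_id = "s1", group = NA_character_,
                          migraine = NA) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("non-finite values in EEG data")
  if (fs_hz <= 0) stop("fs_hz must be positive")
  if (nrow(data) != length(montage$labels))
    stop("data has ", nrow(data), " channels but montage has ",
         length(montage$labels))
  dimnames(data) <- list(montage$labels, NULL)
  n <- ncol(data)
  if (is.null(epochs)) epochs <- cbind(start = 0L, end = n)
  epochs <- as.matrix(epochs)
  storage.mode(epochs) <- "integer"
  colnames(epochs) <- c("start", "end")
  if (nrow(epochs) == 0L) stop("at least one epoch required")
  if (any(epochs[, 1L] >= epochs[, 2L]) || any(epochs[, 1L] < 0L) ||
      any(epochs[, 2L] > n))
    stop("epochs must be non-empty half-open intervals within [0, T)")
  if (nrow(epochs) > 1L) {
    o <- order(epochs[, 1L])
    epochs <- epochs[o, , drop = FALSE]
    if (any(epochs[-1L, 1L] < epochs[-nrow(epochs), 2L]))
      stop("epochs must be disjoint")
  }
  structure(list(data = data, fs_hz = fs_hz, montage = montage,
                 epochs = epochs, subject_id = subject_id,
                 group = group, migraine = migraine),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s (group=%s): %d ch x %d samples @ %g Hz, %d epoch(s)\n",
    x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs_hz,
    nrow(x$epochs)))
  invisible(x)
}

# 1-based sample index vector of an epoch row
epoch_idx <- function(epochs, i) (epochs[i, 1L] + 1L):epochs[i, 2L]

# total epoched samples
epoch_samples <- function(rec) sum(rec$epochs[, 2L] - rec$epochs[, 1L])
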