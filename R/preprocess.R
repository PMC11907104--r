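#' Average re-reference
#'
#' Subtracts the instantaneous mean across channels from every sample, the
#' first preprocessing step of the pipeline.  Idempotent.
#'
#' @param rec an [eeg_recording()].
#' @return The re-referenced recording.
#' @export
average_reference <- function(rec) {
  if (!all(is.finite(rec$data))) stop("non-finite values in EEG data")
  if (nrow(rec$data) < 2L) stop("need at least 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

#' Zero-phase band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (zero phase; effective attenuation doubled) to every channel,
#' independently within each epoch, since epochs were excised from a longer
#' record and are not continuous across their boundaries.
#'
#' @param rec an [eeg_recording()].
#' @param lo_hz,hi_hz band edges in Hz (defaults 2 and 20).
#' @param order Butterworth order of the one-way filter (default 4).
#' @return The filtered recording.
#' @export
bandpass <- function(rec, lo_hz = 2, hi_hz = 20, order = 4L) {
  fs <- rec$fs_hz
  if (!(0 < lo_hz && lo_hz < hi_hz && hi_hz < fs / 2))
    stop("band edges must satisfy 0 < lo < hi < fs/2")
  bf <- signal::butter(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  # filtfilt pads internally; require epochs comfortably longer than the
  # filter's impulse-response warm-up
  min_len <- 3L * (2L * order + 1L)
  for (e in seq_len(nrow(rec$epochs))) {
    idx <- epoch_idx(rec$epochs, e)
    if (length(idx) < min_len)
      stop("epoch ", e, " too short (", length(idx),
           " samples) for the band-pass filter warm-up")
    rec$data[, idx] <- t(apply(rec$data[, idx, drop = FALSE], 1L,
                               function(ch) signal::filtfilt(bf, ch)))
  }
  rec
}

#' Trim recordings to a common analyzed length
#'
#' Keeps exactly `floor(seconds * fs)` samples per subject, taken
#' epoch-by-epoch from the start; the last retained epoch is shortened as
#' needed and later epochs are dropped.  Equalizing analyzed duration
#' across subjects makes occurrence and coverage comparable.
#'
#' @param recs a list of [eeg_recording()] (or a single recording).
#' @param seconds target duration in seconds.
#' @return The trimmed list (or single recording).
#' @export
trim_to_length <- function(recs, seconds) {
  single <- inherits(recs, "eeg_recording")
  if (single) recs <- list(recs)
  out <- lapply(recs, function(rec) {
    target <- floor(seconds * rec$fs_hz)
    lens <- rec$epochs[, 2L] - rec$epochs[, 1L]
    if (sum(lens) < target)
      stop("subject ", rec$subject_id, " has only ", sum(lens),
           " epoched samples; ", target, " required")
    keep <- integer(0)
    new_ep <- NULL
    remaining <- target
    pos <- 0L
    for (e in seq_len(nrow(rec$epochs))) {
      if (remaining == 0L) break
      take <- min(lens[e], remaining)
      keep <- c(keep, rec$epochs[e, 1L] + seq_len(take))
      new_ep <- rbind(new_ep, c(pos, pos + take))
      pos <- pos + take
      remaining <- remaining - take
    }
    eeg_recording(rec$data[, keep, drop = FALSE], rec$fs_hz, rec$montage,
                  new_ep, subject_id = rec$subject_id, group = rec$group,
                  migraine = rec$migraine)
  })
  if (single) out[[1L]] else out
}

#' Global field power time course
#'
#' GFP at each sample is the instantaneous population standard deviation of
#' the potential across all electrodes, a reference-free index of global
#' response strength (the 1/E divisor is the convention of the microstate
#' literature).
#'
#' @param rec an [eeg_recording()]; should be average-referenced.
#' @return An object of class `gfp_series` with per-sample `values`, empty
#'   `peak_indices` (see [detect_gfp_peaks()]), and the epoch structure.
#' @export
compute_gfp <- function(rec) {
  E <- nrow(rec$data)
  if (E < 2L) stop("GFP needs at least 2 channels")
  mu <- colMeans(rec$data)
  values <- sqrt(colMeans(rec$data^2) - mu^2)
  values[is.na(values)] <- 0
  structure(list(values = values, peak_indices = integer(0),
                 epochs = rec$epochs, fs_hz = rec$fs_hz),
            class = "gfp_series")
}

#' Detect GFP peaks
#'
#' Local maxima of the GFP time course, evaluated within each epoch
#' independently so that no peak falls on an epoch boundary.  A sample `t`
#' is a peak when `values[t-1] < values[t] > values[t+1]`; on a flat run
#' the first sample of the run is taken.  GFP peaks are the time points of
#' highest topographic signal-to-noise ratio and are the input to
#' clustering and backfitting.
#'
#' @param gfp a `gfp_series` from [compute_gfp()].
#' @return The series with `peak_indices` filled in (1-based).
#' @export
detect_gfp_peaks <- function(gfp) {
  v <- gfp$values
  peaks <- integer(0)
  for (e in seq_len(nrow(gfp$epochs))) {
    idx <- epoch_idx(gfp$epochs, e)
    if (length(idx) < 3L) next
    x <- v[idx]
    n <- length(x)
    # a peak rises strictly from the left and the next *different* value to
    # the right is lower; on a flat run only its first sample rises, so the
    # rule picks the first sample of a plateau.  nxt[n] = +Inf keeps flat
    # runs or rises that touch the epoch edge from counting as peaks.
    rising <- c(FALSE, diff(x) > 0)
    nxt <- numeric(n)
    nxt[n] <- Inf
    for (i in (n - 1L):1L)
      nxt[i] <- if (x[i + 1L] != x[i]) x[i + 1L] else nxt[i + 1L]
    peaks <- c(peaks, idx[rising & (nxt < x)])
  }
  gfp$peak_indices <- peaks
  gfp
}
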