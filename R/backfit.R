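#' Backfit class templates to a recording
#'
#' Class membership is decided at the GFP peaks: each peak map is labelled
#' with the class whose template it matches best by polarity-invariant
#' spatial correlation.  Every non-peak sample then inherits the label of
#' its nearest peak within the same epoch (midpoint split between adjacent
#' peaks, ties to the earlier peak); epochs without any peak remain
#' unassigned; an equidistant sample goes to the later peak.  Maximal
#' same-label runs form the segments; a segment is
#' flagged truncated when it touches an epoch boundary, since its true
#' life span is unknown.
#'
#' No temporal smoothing or minimum-duration rejection is applied by
#' default; `min_duration_ms` merges shorter segments into their
#' better-correlated neighbour when set.
#'
#' @param rec preprocessed [eeg_recording()].
#' @param gfp `gfp_series` with peaks detected.
#' @param templates sorted [template_set()].
#' @param min_duration_ms optional minimum segment duration; 0 disables.
#' @return An object of class `segmentation`: per-sample `labels` (NA =
#'   unassigned), a `segments` data frame (`epoch`, `start`, `end`
#'   half-open 0-based, `class`, `truncated`, `mean_gfp`, `peak_count`),
#'   `fs_hz`, `epochs` and the class `class_labels`.
#' @export
backfit <- function(rec, gfp, templates, min_duration_ms = 0) {
  peaks <- gfp$peak_indices
  n <- ncol(rec$data)
  K <- length(templates$labels)
  labels <- rep(NA_integer_, n)
  pm <- rec$data[, peaks, drop = FALSE]
  pm <- sweep(pm, 2L, colMeans(pm))
  nrm <- sqrt(colSums(pm^2))
  bad <- nrm == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance peak map(s) skipped in backfit")
    peaks <- peaks[!bad]
    pm <- pm[, !bad, drop = FALSE]
    nrm <- nrm[!bad]
  }
  corr <- abs(crossprod(templates$maps, sweep(pm, 2L, nrm, "/")))  # K x P
  peak_class <- max.col(t(corr), ties.method = "first")

  for (e in seq_len(nrow(rec$epochs))) {
    idx <- epoch_idx(rec$epochs, e)
    in_ep <- which(peaks %in% idx)
    if (length(in_ep) == 0L) next
    p <- peaks[in_ep]
    cl <- peak_class[in_ep]
    # nearest peak with midpoint split; an equidistant sample goes to the
    # later peak (so peaks at 0-based 10 and 20 split as 0-14 / 15-end)
    if (length(p) == 1L) {
      labels[idx] <- cl
    } else {
      cuts <- ceiling((p[-length(p)] + p[-1L]) / 2) - 1L  # last of left bin
      bin <- findInterval(idx, cuts + 1L) + 1L
      labels[idx] <- cl[bin]
    }
  }

  if (min_duration_ms > 0)
    labels <- merge_short_segments(labels, rec, templates, min_duration_ms)
  seg <- segments_from_labels(labels, rec$epochs)

  # per-segment mean GFP and peak count
  if (nrow(seg)) {
    seg$mean_gfp <- vapply(seq_len(nrow(seg)), function(i)
      mean(gfp$values[(seg$start[i] + 1L):seg$end[i]]), 0)
    seg$peak_count <- vapply(seq_len(nrow(seg)), function(i)
      sum(peaks > seg$start[i] & peaks <= seg$end[i]), 0L)
  } else {
    seg$mean_gfp <- numeric(0)
    seg$peak_count <- integer(0)
  }

  structure(list(labels = labels, segments = seg, fs_hz = rec$fs_hz,
                 epochs = rec$epochs, class_labels = templates$labels,
                 subject_id = rec$subject_id, group = rec$group,
                 migraine = rec$migraine,
                 peaks = peaks, peak_class = peak_class),
            class = "segmentation")
}

# maximal same-label runs per epoch; start/end are half-open 0-based
# global sample coordinates; truncated = touches an epoch boundary
segments_from_labels <- function(labels, epochs) {
  out <- vector("list", nrow(epochs))
  for (e in seq_len(nrow(epochs))) {
    idx <- epoch_idx(epochs, e)
    x <- labels[idx]
    if (all(is.na(x))) {
      out[[e]] <- NULL
      next
    }
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- !is.na(r$values)
    df <- data.frame(epoch = e,
                     start = epochs[e, 1L] + starts[keep],
                     end = epochs[e, 1L] + ends[keep],
                     class = r$values[keep])
    df$truncated <- df$start == epochs[e, 1L] | df$end == epochs[e, 2L]
    out[[e]] <- df
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(epoch = integer(0), start = integer(0),
                      end = integer(0), class = integer(0),
                      truncated = logical(0))
  res
}

# merge sub-threshold segments into the neighbour whose template better
# matches the segment's mean map (config hook; off by default).  Works on
# the label vector and relabels shortest-first until no short interior
# segment remains.
merge_short_segments <- function(labels, rec, templates, min_duration_ms) {
  min_len <- ceiling(min_duration_ms / 1000 * rec$fs_hz)
  repeat {
    seg <- segments_from_labels(labels, rec$epochs)
    len <- seg$end - seg$start
    short <- which(len < min_len & !seg$truncated)
    if (!length(short)) break
    i <- short[which.min(len[short])]
    cand <- which(seg$epoch == seg$epoch[i] &
                    (seg$end == seg$start[i] | seg$start == seg$end[i]))
    if (!length(cand)) break
    mmap <- rowMeans(rec$data[, (seg$start[i] + 1L):seg$end[i],
                              drop = FALSE])
    sc <- vapply(cand, function(j)
      spatial_correlation(mmap, templates$maps[, seg$class[j]]), 0)
    j <- cand[which.max(sc)]
    labels[(seg$start[i] + 1L):seg$end[i]] <- seg$class[j]
  }
  labels
}

#' GEV achieved by a backfit assignment
#'
#' The same global-explained-variance formula as in clustering, evaluated
#' over the peak maps under the backfit's peak labels — the quantity
#' reported as "explained variance" of a template set on a subject.
#'
#' @param seg a [backfit()] segmentation.
#' @param rec,gfp the recording and GFP series the segmentation came from.
#' @param templates the [template_set()] used for the backfit.
#' @return As [gev()]: list with `per_class` and `total`.
#' @export
assignment_quality <- function(seg, rec, gfp, templates) {
  peaks <- seg$peaks
  gev(rec$data[, peaks, drop = FALSE], gfp$values[peaks], templates,
      seg$peak_class)
}
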