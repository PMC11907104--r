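# Plain-text readers and writers for recordings, segmentations and tables.
# Recordings travel as a delimited samples x channels matrix (header row of
# electrode labels) plus a YAML sidecar holding sampling rate, epoch
# boundaries and subject metadata.

#' Write / read an EEG recording as delimited text
#'
#' The matrix file holds samples x channels with a header of electrode
#' labels; `<path>.yaml` holds `fs_hz`, `epochs` (half-open 0-based sample
#' intervals), `subject_id`, `group` and `migraine`.
#'
#' @param rec an [eeg_recording()].
#' @param path path of the matrix file (sidecar written next to it).
#' @param montage montage to validate channel labels against when reading.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an [eeg_recording()].
#' @export
write_recording <- function(rec, path) {
  # %.17g keeps doubles bit-exact through the text round trip
  txt <- matrix(sprintf("%.17g", t(rec$data)), ncol(rec$data),
                nrow(rec$data))
  colnames(txt) <- rec$montage$labels
  utils::write.table(txt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(fs_hz = rec$fs_hz,
               subject_id = rec$subject_id,
               group = if (is.na(rec$group)) NULL else rec$group,
               migraine = if (is.na(rec$migraine)) NULL else rec$migraine,
               epochs = apply(rec$epochs, 1L, function(r)
                 list(start = unname(r[1L]), end = unname(r[2L])),
                 simplify = FALSE))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, montage = ifcn_montage()) {
  tab <- utils::read.delim(path, check.names = FALSE)
  missing <- setdiff(montage$labels, colnames(tab))
  if (length(missing))
    stop("channel(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  data <- t(as.matrix(tab[, montage$labels, drop = FALSE]))
  meta_path <- paste0(path, ".yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    epochs <- if (length(meta$epochs))
      do.call(rbind, lapply(meta$epochs, function(e)
        c(e$start, e$end))) else NULL
    eeg_recording(data, meta$fs_hz, montage, epochs,
                  subject_id = meta$subject_id %||% basename(path),
                  group = meta$group %||% NA_character_,
                  migraine = meta$migraine %||% NA)
  } else {
    stop("sidecar metadata not found: ", meta_path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to a directory
#'
#' One matrix + sidecar pair per subject, named by subject id.
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings)
    write_recording(rec, file.path(dir, paste0(rec$subject_id, ".tsv")))
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir directory of `.tsv` matrix files written by [write_cohort()].
#' @param montage montage to validate against.
#' @return A list of [eeg_recording()].
#' @export
read_cohort <- function(dir, montage = ifcn_montage()) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no .tsv recordings in ", dir)
  lapply(files, read_recording, montage = montage)
}

#' Write a segmentation as a delimited segment table
#'
#' One row per segment: subject, epoch, start/end in ms (half-open),
#' class label, truncation flag, mean GFP.
#'
#' @param seg a [backfit()] segmentation.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  s <- seg$segments
  utils::write.table(
    data.frame(subject = seg$subject_id, epoch = s$epoch,
               start_ms = s$start / seg$fs_hz * 1000,
               end_ms = s$end / seg$fs_hz * 1000,
               class = seg$class_labels[s$class],
               truncated = s$truncated,
               mean_gfp = s$mean_gfp),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
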