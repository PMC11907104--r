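#' Microstate template set
#'
#' A labelled set of K unit-norm, average-referenced topography maps at one
#' level of the sorting hierarchy (individual subject, group grand mean,
#' grand grand mean, or canonical norms).
#'
#' @param maps numeric E x K matrix, one column per class; each column must
#'   be (numerically) mean-zero.  Columns are re-scaled to unit L2 norm.
#' @param labels class labels; defaults to the first K letters A, B, ...
#' @param level one of `"individual"`, `"grand_mean"`, `"grand_grand_mean"`,
#'   `"norms"`.
#' @param gev optional total global explained variance achieved when the set
#'   was fitted.
#' @param subject_id,group optional provenance metadata.
#' @return An object of class `template_set`.
#' @export
template_set <- function(maps, labels = LETTERS[seq_len(ncol(maps))],
                         level = c("individual", "grand_mean",
                                   "grand_grand_mean", "norms"),
                         gev = NULL, subject_id = NULL, group = NULL) {
  level <- match.arg(level)
  maps <- as.matrix(maps)
  storage.mode(maps) <- "double"
  if (ncol(maps) != length(labels)) stop("one label per map required")
  if (anyDuplicated(labels)) stop("template labels must be unique")
  scale_ok <- apply(maps, 2L, function(v) sqrt(sum(v^2)))
  if (any(scale_ok == 0)) stop("zero map in template set")
  cm <- colMeans(maps)
  if (any(abs(cm) > 1e-6 * scale_ok))
    stop("template maps must be average-referenced (mean zero)")
  maps <- sweep(maps, 2L, scale_ok, "/")
  colnames(maps) <- labels
  structure(list(maps = maps, labels = as.character(labels), level = level,
                 gev = gev, subject_id = subject_id, group = group),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat("<template_set> level=", x$level, ", K=", length(x$labels),
      " [", paste(x$labels, collapse = ","), "], E=", nrow(x$maps),
      if (!is.null(x$gev)) sprintf(", GEV=%.3f", x$gev) else "",
      "\n", sep = "")
  invisible(x)
}

#' Spatial correlation between two topography maps
#'
#' Pearson correlation between two average-referenced maps; with
#' `polarity_invariant = TRUE` the absolute value is returned, treating a
#' map and its sign-flipped copy as identical, as is appropriate for
#' spontaneous (non event-locked) EEG.
#'
#' @param u,v numeric vectors of equal length (mean-zero maps).
#' @param polarity_invariant drop the sign of the correlation?
#' @return A scalar in \[-1, 1\] (or \[0, 1\] when polarity-invariant).
#' @export
spatial_correlation <- function(u, v, polarity_invariant = TRUE) {
  u <- u - mean(u); v <- v - mean(v)
  su <- sqrt(sum(u^2)); sv <- sqrt(sum(v^2))
  if (su == 0 || sv == 0) stop("zero-variance map in spatial correlation")
  r <- sum(u * v) / (su * sv)
  r <- max(-1, min(1, r))
  if (polarity_invariant) abs(r) else r
}

#' Write / read a template set as delimited text
#'
#' Rows are electrodes, columns classes; a comment header records the
#' hierarchy level and the achieved global explained variance.
#'
#' @param set a [template_set()].
#' @param path file path.
#' @return `read_template_set` returns a [template_set()];
#'   `write_template_set` returns `path` invisibly.
#' @export
write_template_set <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# level=%s gev=%s", set$level,
                     if (is.null(set$gev)) "NA" else
                       format(set$gev, digits = 17)), con)
  utils::write.table(
    data.frame(electrode = rownames(set$maps), set$maps,
               check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_template_set
#' @export
read_template_set <- function(path) {
  header <- readLines(path, n = 1L)
  fields <- regmatches(header,
                       regexec("level=(\\S+) gev=(\\S+)", header))[[1L]]
  if (length(fields) != 3L) stop("not a template-set file: ", path)
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  maps <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(maps) <- tab[[1L]]
  gev <- suppressWarnings(as.numeric(fields[3L]))
  template_set(maps, labels = colnames(maps), level = fields[2L],
               gev = if (is.na(gev)) NULL else gev)
}
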