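#' Electrode montage
#'
#' A montage is an ordered set of electrode labels with optional 2D layout
#' positions (unitless, top view: x increases to the right, y towards the
#' front).  Positions are required by [make_canonical_templates()].
#'
#' @param labels character vector of unique electrode names (length >= 2).
#' @param positions optional numeric matrix with one row per electrode and
#'   columns `x`, `y`.
#' @return An object of class `montage` with elements `labels` and
#'   `positions`.
#' @seealso [ifcn_montage()] for the default 25-electrode clinical array.
#' @export
montage <- function(labels, positions = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("a montage needs at least 2 electrodes")
  if (anyDuplicated(labels)) {
    stop("duplicate electrode labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != length(labels) || ncol(positions) != 2L)
      stop("positions must be a length(labels) x 2 matrix")
    storage.mode(positions) <- "double"
    rownames(positions) <- labels
    colnames(positions) <- c("x", "y")
  }
  structure(list(labels = labels, positions = positions),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$labels), " electrodes: ",
      paste(x$labels, collapse = " "),
      if (is.null(x$positions)) " (no positions)" else "", "\n", sep = "")
  invisible(x)
}

#' Standard 25-electrode clinical montage
#'
#' The 25-channel array recommended by the IFCN for clinical EEG:
#' the 10-20 ring (Fp1/2, F3/4, F7/8, C3/4, Cz, Fz, Pz, P3/4, T3/4, T5/6,
#' O1/2) extended by the inferior temporal chain F9/10, T9/10, P9/10.
#' Layout positions are a schematic polar projection of the scalp
#' (unit radius at the 10-20 outer ring; the inferior chain sits at
#' radius 1.2).
#'
#' @return A [montage()] with 25 labelled electrodes and 2D positions.
#' @export
ifcn_montage <- function() {
  pos <- rbind(
    Fp1 = c(-0.31,  0.95), Fp2 = c( 0.31,  0.95),
    F9  = c(-0.97,  0.71), F7  = c(-0.81,  0.59), F3 = c(-0.40, 0.52),
    Fz  = c( 0.00,  0.50),
    F4  = c( 0.40,  0.52), F8  = c( 0.81,  0.59), F10 = c( 0.97, 0.71),
    T9  = c(-1.20,  0.00), T3  = c(-1.00,  0.00), C3 = c(-0.50, 0.00),
    Cz  = c( 0.00,  0.00),
    C4  = c( 0.50,  0.00), T4  = c( 1.00,  0.00), T10 = c( 1.20, 0.00),
    P9  = c(-0.97, -0.71), T5  = c(-0.81, -0.59), P3 = c(-0.40, -0.52),
    Pz  = c( 0.00, -0.50),
    P4  = c( 0.40, -0.52), T6  = c( 0.81, -0.59), P10 = c( 0.97, -0.71),
    O1  = c(-0.31, -0.95), O2  = c( 0.31, -0.95))
  montage(rownames(pos), pos)
}

#' Canonical microstate template maps
#'
#' Builds the four canonical resting-state microstate topographies from a
#' montage layout, in their conventional orientations: class A has a
#' right-frontal / left-posterior diagonal gradient, class B the mirrored
#' left-frontal / right-posterior diagonal, class C an anterior-posterior
#' gradient, and class D a fronto-central extreme (centre versus
#' periphery).  Maps are average-referenced and scaled to unit L2 norm,
#' so they serve directly as a polarity-invariant sorting reference or as
#' generative templates for [synthesize_recording()].
#'
#' @param montage a [montage()] with positions for every electrode.
#' @param K number of classes; only the canonical `K = 4` set is defined.
#' @return A [template_set()] with labels A-D and level `"norms"`.
#' @export
make_canonical_templates <- function(montage = ifcn_montage(), K = 4L) {
  if (is.null(montage$positions)) {
    stop("montage has no positions; needed for electrodes: ",
         paste(montage$labels, collapse = ", "))
  }
  bad <- montage$labels[!stats::complete.cases(montage$positions)]
  if (length(bad))
    stop("missing positions for electrode(s): ", paste(bad, collapse = ", "))
  if (K != 4L) stop("only the canonical K = 4 template set is defined")
  x <- montage$positions[, "x"]
  y <- montage$positions[, "y"]
  raw <- cbind(
    A = (x + y) / sqrt(2),   # right-frontal positive, left-posterior negative
    B = (y - x) / sqrt(2),   # left-frontal positive, right-posterior negative
    C = y,                   # anterior-posterior
    D = -(x^2 + y^2))        # fronto-central extreme
  maps <- apply(raw, 2L, function(v) {
    v <- v - mean(v)
    v / sqrt(sum(v^2))
  })
  rownames(maps) <- montage$labels
  template_set(maps, labels = colnames(raw), level = "norms")
}
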