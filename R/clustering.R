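# Polarity-invariant AAHC clustering of GFP-peak topographies and the
# template hierarchy built on top of it.

# normalize map columns: demean, unit L2 norm; returns NULL columns dropped
normalize_maps <- function(maps) {
  maps <- sweep(maps, 2L, colMeans(maps))
  nrm <- sqrt(colSums(maps^2))
  if (any(nrm == 0)) stop("zero-variance map cannot be normalized")
  sweep(maps, 2L, nrm, "/")
}

# all permutations of 1..k in lexicographic order, one per row
permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  r <- 0L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    out[r + seq_len(nrow(sub)), 1L] <- first
    out[r + seq_len(nrow(sub)), -1L] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Global explained variance of an assignment
#'
#' The fraction of GFP-weighted topographic variance accounted for by a set
#' of class templates under a given map-to-class assignment:
#' `GEV_k = sum over maps assigned to k of (gfp * corr(map, template_k))^2`
#' divided by the total `sum(gfp^2)`, where `corr` is the spatial
#' correlation (its square is polarity-invariant).
#'
#' @param maps numeric E x N matrix of average-referenced maps (need not be
#'   normalized; correlation is scale-free).
#' @param gfp numeric length-N GFP value of each map.
#' @param templates a [template_set()] (maps unit-norm).
#' @param assignment integer length-N class index per map (NA = unassigned).
#' @return A list with per-class fractions `per_class` (named by template
#'   labels) and their sum `total`, all in \[0, 1\].
#' @export
gev <- function(maps, gfp, templates, assignment) {
  maps <- as.matrix(maps)
  K <- length(templates$labels)
  if (length(gfp) != ncol(maps) || length(assignment) != ncol(maps))
    stop("gfp and assignment must have one entry per map")
  denom <- sum(gfp^2)
  if (denom == 0) stop("all-zero GFP weights")
  cmaps <- sweep(maps, 2L, colMeans(maps))
  nrm <- sqrt(colSums(cmaps^2))
  if (any(nrm == 0)) stop("zero-variance map")
  corr <- crossprod(templates$maps, sweep(cmaps, 2L, nrm, "/"))  # K x N
  per_class <- numeric(K)
  for (k in seq_len(K)) {
    idx <- which(assignment == k)
    per_class[k] <- sum((gfp[idx] * corr[k, idx])^2) / denom
  }
  names(per_class) <- templates$labels
  list(per_class = per_class, total = sum(per_class))
}

# dominant spatial component of member maps, GFP^2-weighted, sign-aligned
# to the (weighted) majority of members; maps must be unit-norm columns
dominant_map <- function(maps, w2) {
  m <- ncol(maps)
  if (m == 1L) return(maps[, 1L])
  if (m <= nrow(maps)) {
    G <- crossprod(maps) * tcrossprod(sqrt(w2))      # m x m
    ev <- eigen(G, symmetric = TRUE)
    z <- ev$vectors[, 1L]
    u <- maps %*% (sqrt(w2) * z)
  } else {
    A <- maps * rep(sqrt(w2), each = nrow(maps))
    ev <- eigen(tcrossprod(A), symmetric = TRUE)     # E x E
    u <- ev$vectors[, 1L, drop = FALSE]
  }
  u <- as.numeric(u)
  u <- u / sqrt(sum(u^2))
  if (sum(w2 * sign(crossprod(maps, u))) < 0) u <- -u
  u
}

#' Atomize-and-agglomerate hierarchical clustering (AAHC)
#'
#' Bottom-up polarity-invariant clustering of topographic maps: every map
#' starts as its own cluster; at each step the cluster whose dissolution
#' costs the least global explained variance is atomized and each of its
#' member maps is reassigned to the cluster whose template it matches best
#' by polarity-invariant spatial correlation; affected templates are then
#' recomputed as the dominant spatial component (GFP^2-weighted first
#' principal direction, sign-aligned to the majority) of their member maps.
#' The procedure stops when `K_target` clusters remain.
#'
#' The dissolution cost is the cluster's GEV contribution net of the GEV
#' its members recover in the clusters that absorb them; the net term is
#' evaluated exactly once few clusters remain (where it matters), while
#' with many fine-grained clusters the raw contribution is an accurate
#' and much cheaper surrogate.  Cost ties dissolve the cluster with fewer
#' members, then the lower index — deterministic and order-independent.
#'
#' @param maps numeric E x N matrix of average-referenced maps.
#' @param gfp length-N GFP weight per map.
#' @param K_target number of clusters to return.
#' @param labels optional class labels for the result.
#' @return A list with `templates` (a [template_set()], clusters ordered by
#'   descending GEV contribution), `assignment` (length-N class index into
#'   the returned order), and `gev` (per-class and total, as [gev()]).
#' @export
aahc <- function(maps, gfp, K_target,
                 labels = LETTERS[seq_len(K_target)]) {
  maps <- normalize_maps(as.matrix(maps))
  N <- ncol(maps)
  if (K_target < 1L || K_target > N)
    stop("K_target must be between 1 and the number of maps (", N, ")")
  w2 <- gfp^2
  denom <- sum(w2)
  if (denom == 0) stop("all-zero GFP weights")

  members <- as.list(seq_len(N))
  templates <- maps                      # E x C, one column per live cluster
  # singleton contribution: (gfp * 1)^2 / denom
  contrib <- w2 / denom

  contrib_of <- function(idx, u)
    sum(w2[idx] * as.numeric(crossprod(maps[, idx, drop = FALSE], u))^2) /
      denom

  # Atomization criterion: the cluster whose disappearance costs least
  # GEV *net* of what its members regain when absorbed elsewhere.  While
  # many clusters remain, a dissolved cluster is a near-duplicate of some
  # survivor, the regain nearly cancels the loss, and the raw contribution
  # ranks clusters the same way at a fraction of the cost; once few
  # clusters remain the net cost is evaluated exactly (this is where
  # dissolving a genuine class would otherwise leave fragments of another
  # class that can never re-merge).
  exact_below <- 50L
  while (length(members) > K_target) {
    sizes <- lengths(members)
    C <- length(members)
    if (C <= exact_below) {
      assign_now <- integer(N)
      for (k in seq_len(C)) assign_now[members[[k]]] <- k
      corr2 <- crossprod(templates, maps)^2            # C x N
      corr2[cbind(assign_now, seq_len(N))] <- -Inf
      alt_idx <- max.col(t(corr2), ties.method = "first")
      alt <- corr2[cbind(alt_idx, seq_len(N))]         # best other cluster
      regain <- vapply(seq_len(C), function(k) {
        idx <- members[[k]]
        sum(w2[idx] * alt[idx]) / denom
      }, 0)
      cost <- contrib - regain
    } else {
      cost <- contrib
    }
    worst <- order(cost, sizes, seq_along(members))[1L]
    orphan <- members[[worst]]
    members <- members[-worst]
    templates <- templates[, -worst, drop = FALSE]
    contrib <- contrib[-worst]
    # reassign each orphan map to the best-matching remaining template
    match_corr <- abs(crossprod(templates, maps[, orphan, drop = FALSE]))
    dest <- max.col(t(match_corr), ties.method = "first")
    touched <- unique(dest)
    for (d in touched)
      members[[d]] <- c(members[[d]], orphan[dest == d])
    for (d in touched) {
      idx <- members[[d]]
      templates[, d] <- dominant_map(maps[, idx, drop = FALSE], w2[idx])
      contrib[d] <- contrib_of(idx, templates[, d])
    }
  }

  # final assignment: every map to its best-matching final template (the
  # same polarity-invariant argmax rule backfitting uses), so the reported
  # GEV is exactly the GEV a backfit with these templates achieves
  assignment <- max.col(t(abs(crossprod(templates, maps))),
                        ties.method = "first")
  contrib <- vapply(seq_along(members), function(k) {
    idx <- which(assignment == k)
    if (!length(idx)) 0 else contrib_of(idx, templates[, k])
  }, 0)
  ord <- order(contrib, decreasing = TRUE)
  templates <- templates[, ord, drop = FALSE]
  contrib <- contrib[ord]
  assignment <- order(ord)[assignment]
  rownames(templates) <- rownames(maps)
  ts <- template_set(templates, labels = labels, level = "individual",
                     gev = sum(contrib))
  names(contrib) <- labels
  list(templates = ts, assignment = assignment,
       gev = list(per_class = contrib, total = sum(contrib)))
}

#' Fit individual microstate templates to one subject
#'
#' Runs [aahc()] on the subject's topographies at GFP peaks, weighted by
#' the GFP at each peak.  Zero-variance peak maps (possible only in
#' degenerate input) are skipped with a warning.
#'
#' @param rec preprocessed (re-referenced, filtered) [eeg_recording()].
#' @param gfp a `gfp_series` with peaks detected.
#' @param K number of microstate classes (4 in the standard analysis).
#' @return A [template_set()] (level `"individual"`, subject metadata
#'   attached, `gev` = achieved total GEV).
#' @export
fit_individual_microstates <- function(rec, gfp, K = 4L) {
  peaks <- gfp$peak_indices
  if (length(peaks) == 0L) stop("no GFP peaks detected")
  pm <- rec$data[, peaks, drop = FALSE]
  pm <- sweep(pm, 2L, colMeans(pm))
  ok <- colSums(pm^2) > 0
  if (!all(ok)) {
    warning(sum(!ok), " zero-variance peak map(s) skipped")
    pm <- pm[, ok, drop = FALSE]
    peaks <- peaks[ok]
  }
  if (ncol(pm) < K)
    stop("only ", ncol(pm), " usable peaks; need at least K = ", K)
  fit <- aahc(pm, gfp$values[peaks], K)
  ts <- fit$templates
  ts$subject_id <- rec$subject_id
  ts$group <- rec$group
  ts
}

#' Sort a template set against a reference
#'
#' Relabels and sign-aligns the maps by the class permutation maximizing
#' the summed polarity-invariant correlation with the reference classes,
#' searched exhaustively over all K! permutations (K <= 6); ties are broken
#' by the lexicographically smallest permutation.  Each map's sign is then
#' flipped, if needed, so its signed correlation with its reference class
#' is non-negative.
#'
#' @param set,reference [template_set()]s with the same K and montage.
#' @return The sorted set, relabelled with the reference labels, with
#'   attribute `"mean_corr"` (mean polarity-invariant correlation to the
#'   reference) and `"permutation"`.
#' @export
sort_templates <- function(set, reference) {
  K <- length(set$labels)
  if (K != length(reference$labels))
    stop("template sets have different K")
  if (K > 6L) stop("exhaustive sorting supports K <= 6")
  C <- crossprod(reference$maps, set$maps)   # K_ref x K_set signed corr
  A <- abs(C)
  perms <- permutations(K)
  scores <- apply(perms, 1L, function(p) sum(A[cbind(seq_len(K), p)]))
  best <- perms[which.max(scores), ]         # which.max: first = lexico min
  maps <- set$maps[, best, drop = FALSE]
  signs <- sign(C[cbind(seq_len(K), best)])
  signs[signs == 0] <- 1
  maps <- sweep(maps, 2L, signs, "*")
  out <- template_set(maps, labels = reference$labels, level = set$level,
                      gev = set$gev, subject_id = set$subject_id,
                      group = set$group)
  attr(out, "mean_corr") <- max(scores) / K
  attr(out, "permutation") <- best
  out
}

#' Mean template set across subjects or groups
#'
#' Aligns each input set (class order and polarity) to a reference — the
#' supplied one, or the first input if none — with [sort_templates()],
#' then averages the normalized maps class-wise with equal weight per set
#' and re-normalizes.  Used for the group grand means (over individual
#' sets) and the grand grand mean (over group means).
#'
#' @param sets list of [template_set()]s with a common K and montage.
#' @param reference optional [template_set()] used for alignment.
#' @param level hierarchy level recorded on the result.
#' @return A [template_set()].
#' @export
grand_mean <- function(sets, reference = NULL,
                       level = c("grand_mean", "grand_grand_mean")) {
  level <- match.arg(level)
  K <- length(sets[[1L]]$labels)
  if (any(vapply(sets, function(s) length(s$labels), 1L) != K))
    stop("all template sets must have the same K")
  ref <- if (is.null(reference)) sets[[1L]] else reference
  aligned <- lapply(sets, sort_templates, reference = ref)
  acc <- Reduce(`+`, lapply(aligned, `[[`, "maps"))
  template_set(acc / length(sets), labels = ref$labels, level = level)
}

#' Exhaustive-partition GEV optimum (brute-force reference)
#'
#' For small instances only: enumerates every partition of the maps into
#' at most `K` non-empty clusters (restricted growth strings) and returns
#' the best achievable total GEV, where each cluster's template is the
#' optimal (dominant-eigenvector) map for its members.  Serves as an
#' independent reference point for how close [aahc()] gets to the global
#' optimum; cost grows as the Stirling number S(N, K), so keep N small
#' (N <= 14 or so).
#'
#' @param maps E x N matrix of average-referenced maps.
#' @param gfp length-N GFP weights.
#' @param K maximum number of clusters.
#' @return The maximal total GEV over all partitions (scalar in \[0, 1\]).
#' @export
exhaustive_partition_gev <- function(maps, gfp, K) {
  maps <- normalize_maps(as.matrix(maps))
  N <- ncol(maps)
  if (N > 16L) stop("exhaustive search is limited to N <= 16 maps")
  w2 <- gfp^2
  denom <- sum(w2)
  # weighted Gram: eigenvalues of the block submatrix give the block's
  # best GEV contribution (same spectrum as the E x E weighted scatter)
  Gw <- crossprod(maps) * tcrossprod(sqrt(w2))
  block_val <- function(idx) {
    if (length(idx) == 1L) return(Gw[idx, idx])
    max(eigen(Gw[idx, idx], symmetric = TRUE, only.values = TRUE)$values)
  }
  best <- -Inf
  a <- integer(N)           # restricted growth string, a[1] = 1
  recurse <- function(i, maxa) {
    if (i > N) {
      blocks <- split(seq_len(N), a)
      val <- sum(vapply(blocks, block_val, 0))
      if (val > best) best <<- val
      return(invisible(NULL))
    }
    for (v in seq_len(min(maxa + 1L, K))) {
      a[i] <<- v
      recurse(i + 1L, max(maxa, v))
    }
  }
  recurse(1L, 0L)
  best / denom
}
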