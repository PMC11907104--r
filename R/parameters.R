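#' Microstate parameters of one segmentation
#'
#' Quantifies, per class: *duration* (mean life span in ms of the
#' non-truncated segments — segments cut by an epoch boundary have an
#' unknown true duration and are refused), *occurrence* (segments per
#' second of analyzed data), *coverage* (percent of assigned samples),
#' and *mean GFP* (mean amplitude in microvolts over the class's samples).
#' The truncation policy controls whether truncated segments still count
#' towards occurrence (and transitions): under `"duration-only"` (default)
#' they do — only duration refuses them; under `"strict"` they are
#' excluded everywhere.
#'
#' @param seg a [backfit()] segmentation.
#' @param gfp the matching `gfp_series`.
#' @param truncation_policy `"duration-only"` or `"strict"`.
#' @param gev_per_class optional named per-class GEV fractions (from
#'   [assignment_quality()]) to record alongside.
#' @return A data frame with one row per class: `subject_id`, `group`,
#'   `migraine`, `class`, `duration_ms`, `occurrence_per_s`,
#'   `coverage_pct`, `mean_gfp_uv`, `gev_class`; attribute `"total_gev"`.
#'   A class with no qualifying segment gets `NA` duration (not zero).
#' @export
compute_parameters <- function(seg, gfp,
                               truncation_policy = c("duration-only",
                                                     "strict"),
                               gev_per_class = NULL) {
  truncation_policy <- match.arg(truncation_policy)
  K <- length(seg$class_labels)
  s <- seg$segments
  analyzed_s <- sum(seg$epochs[, 2L] - seg$epochs[, 1L]) / seg$fs_hz
  assigned <- !is.na(seg$labels)
  n_assigned <- sum(assigned)
  fs <- seg$fs_hz
  rows <- lapply(seq_len(K), function(k) {
    sk <- s[s$class == k, , drop = FALSE]
    keep_dur <- !sk$truncated
    duration <- if (any(keep_dur))
      mean((sk$end[keep_dur] - sk$start[keep_dur]) / fs * 1000) else
        NA_real_
    n_occ <- if (truncation_policy == "strict") sum(keep_dur) else
      nrow(sk)
    cls_samples <- sum(seg$labels == k, na.rm = TRUE)
    data.frame(
      subject_id = seg$subject_id, group = seg$group,
      migraine = seg$migraine, class = seg$class_labels[k],
      duration_ms = duration,
      occurrence_per_s = n_occ / analyzed_s,
      coverage_pct = if (n_assigned) 100 * cls_samples / n_assigned else
        NA_real_,
      mean_gfp_uv = if (cls_samples) mean(gfp$values[which(seg$labels == k)])
        else NA_real_,
      gev_class = if (is.null(gev_per_class)) NA_real_ else
        unname(gev_per_class[k]))
  })
  out <- do.call(rbind, rows)
  attr(out, "total_gev") <- if (is.null(gev_per_class)) NA_real_ else
    sum(gev_per_class)
  out
}

#' Transition (syntax) table of one segmentation
#'
#' Counts ordered pairs of consecutive segments with distinct classes
#' within the same epoch (never across epoch boundaries) and expresses
#' each row as relative percentages — the transition probability from one
#' microstate class to each other class, excluding self-transitions.
#'
#' @param seg a [backfit()] segmentation.
#' @param include_truncated count pairs involving a truncated segment?
#'   Default TRUE (the denser convention needed for stable percentages);
#'   FALSE drops any pair whose members include a truncated segment.
#' @return A list with integer `counts` (K x K, zero diagonal),
#'   `percentages` (rows summing to 100 where the row has any count, else
#'   `NaN`), and `n_transitions`.
#' @export
transition_table <- function(seg, include_truncated = TRUE) {
  K <- length(seg$class_labels)
  s <- seg$segments
  counts <- matrix(0L, K, K,
                   dimnames = list(from = seg$class_labels,
                                   to = seg$class_labels))
  if (nrow(s) >= 2L) {
    same_ep <- s$epoch[-1L] == s$epoch[-nrow(s)]
    ok <- same_ep
    if (!include_truncated)
      ok <- ok & !s$truncated[-1L] & !s$truncated[-nrow(s)]
    from <- s$class[-nrow(s)][ok]
    to <- s$class[-1L][ok]
    distinct <- from != to
    from <- from[distinct]; to <- to[distinct]
    for (i in seq_along(from))
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  }
  rs <- rowSums(counts)
  percentages <- 100 * counts / rs
  list(counts = counts, percentages = percentages,
       n_transitions = sum(counts))
}

#' Screen a parameter for extreme outliers
#'
#' A subject is excluded from a parameter's analyses when any of its class
#' values lies outside its own group's mean +/- 3 SD for that class
#' (single pass; the screen is not re-applied after removal).  Exclusion
#' applies to the given parameter only.
#'
#' @param table a cohort parameter table (rows as
#'   [compute_parameters()], multiple subjects).
#' @param parameter column name to screen, e.g. `"duration_ms"`.
#' @return A list with `table` (rows of excluded subjects removed) and
#'   `excluded` (character vector of subject ids).
#' @export
exclude_outliers <- function(table, parameter) {
  stopifnot(parameter %in% names(table))
  excluded <- character(0)
  for (g in unique(table$group)) {
    gt <- table[table$group == g, ]
    for (cl in unique(gt$class)) {
      v <- gt[gt$class == cl, parameter]
      ids <- gt$subject_id[gt$class == cl]
      ok <- is.finite(v)
      m <- mean(v[ok]); sdv <- stats::sd(v[ok])
      if (!is.finite(sdv) || sdv == 0) next
      out <- ok & (v > m + 3 * sdv | v < m - 3 * sdv)
      excluded <- union(excluded, ids[out])
    }
  }
  list(table = table[!(table$subject_id %in% excluded), , drop = FALSE],
       excluded = excluded)
}

#' Per-subject overall parameter value
#'
#' The unweighted mean of a subject's four class values — the "Mean" row
#' of the per-class summary tables.
#'
#' @param table a cohort parameter table.
#' @param parameter column to aggregate.
#' @return A data frame `subject_id`, `group`, `migraine`, `overall`;
#'   subjects missing any class value get `NA` overall.
#' @export
aggregate_overall <- function(table, parameter) {
  stopifnot(parameter %in% names(table))
  sp <- split(table, table$subject_id)
  out <- lapply(sp, function(d) {
    v <- d[[parameter]]
    data.frame(subject_id = d$subject_id[1L], group = d$group[1L],
               migraine = d$migraine[1L],
               overall = if (any(!is.finite(v))) NA_real_ else mean(v))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$group, res$subject_id), , drop = FALSE]
}
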