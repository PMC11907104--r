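#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end analysis needs.
#'
#' @param band_lo_hz,band_hi_hz band-pass edges (Hz).
#' @param trim_s common analyzed length per subject (seconds).
#' @param K number of microstate classes.
#' @param truncation_policy `"duration-only"` (truncated segments refused
#'   for duration only) or `"strict"` (refused everywhere).
#' @param min_duration_ms minimum-duration merge hook; 0 disables.
#' @param n_permutations TANOVA permutation count.
#' @param stat_seed RNG seed of the permutation tests (independent of the
#'   cohort seed so simulation and inference are separately reproducible).
#' @param subgroup `"all"`, `"migraine"` or `"no-migraine"` cohort filter.
#' @param norms reference [template_set()] used to sort the grand grand
#'   mean; default: the canonical analytic templates.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(band_lo_hz = 2, band_hi_hz = 20,
                            trim_s = 129.996, K = 4L,
                            truncation_policy = c("duration-only",
                                                  "strict"),
                            min_duration_ms = 0,
                            n_permutations = 5000L, stat_seed = 2L,
                            subgroup = c("all", "migraine", "no-migraine"),
                            norms = NULL) {
  truncation_policy <- match.arg(truncation_policy)
  subgroup <- match.arg(subgroup)
  stopifnot(band_lo_hz > 0, band_hi_hz > band_lo_hz, trim_s > 0, K >= 2,
            min_duration_ms >= 0, n_permutations >= 100)
  structure(list(band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
                 trim_s = trim_s, K = as.integer(K),
                 truncation_policy = truncation_policy,
                 min_duration_ms = min_duration_ms,
                 n_permutations = as.integer(n_permutations),
                 stat_seed = as.integer(stat_seed), subgroup = subgroup,
                 norms = norms),
            class = "pipeline_config")
}

#' Run the full microstate analysis
#'
#' Executes the standard analysis cascade on a cohort of recordings:
#' average re-reference; 2-20 Hz zero-phase band-pass; trim to a common
#' length; GFP and peak detection; individual AAHC (K classes per
#' subject); group grand means; grand grand mean; sorting of the grand
#' grand mean against the canonical norms and downward through the
#' hierarchy (grand grand mean -> group means -> individual sets);
#' backfitting of each subject's sorted individual templates; parameter
#' and transition quantification on GFP peaks refusing truncated
#' microstates; per-parameter outlier screening (group mean +/- 3 SD);
#' and the group statistics battery (mixed ANOVAs with
#' Greenhouse-Geisser correction, overall Welch t tests with Cohen's d,
#' Bonferroni-corrected transition tests, randomization TANOVA).
#'
#' @param recordings list of [eeg_recording()] (e.g.
#'   `make_cohort(...)$recordings` or [read_cohort()]).
#' @param config a [pipeline_config()].
#' @param run_stats set FALSE to stop after parameter quantification
#'   (e.g. single-group cohorts).
#' @return A list with elements `preprocessed`, `gfps`, `individual_sets`,
#'   `group_means`, `grand_grand_mean`, `segmentations`, `parameters`
#'   (cohort table), `transitions` (per-subject tables), `gev`
#'   (per-subject totals), `outliers`, and `stats`.
#' @export
run_pipeline <- function(recordings, config = pipeline_config(),
                         run_stats = TRUE) {
  if (config$subgroup != "all") {
    want <- config$subgroup == "migraine"
    recordings <- Filter(function(r) isTRUE(r$migraine) == want, recordings)
  }
  if (!length(recordings)) stop("no recordings to analyze")
  groups <- vapply(recordings, `[[`, "", "group")
  if (run_stats && length(unique(groups)) != 2L)
    stop("group statistics need exactly 2 groups; got: ",
         paste(unique(groups), collapse = ", "))

  # Steps 1-3: re-reference, filter, trim
  pp <- lapply(recordings, function(r)
    bandpass(average_reference(r), config$band_lo_hz, config$band_hi_hz))
  pp <- trim_to_length(pp, config$trim_s)
  # GFP + peaks
  gfps <- lapply(pp, function(r) detect_gfp_peaks(compute_gfp(r)))
  # Step 4: individual AAHC
  indiv <- Map(fit_individual_microstates, pp, gfps,
               MoreArgs = list(K = config$K))
  # Steps 5-6: group grand means, grand grand mean
  glev <- sort(unique(groups))
  gmeans <- lapply(glev, function(g)
    grand_mean(indiv[groups == g], level = "grand_mean"))
  names(gmeans) <- glev
  ggm <- if (length(gmeans) > 1L)
    grand_mean(gmeans, level = "grand_grand_mean") else gmeans[[1L]]
  # Steps 7-8: sort against norms, then down the hierarchy
  norms <- config$norms %||%
    make_canonical_templates(recordings[[1L]]$montage, config$K)
  ggm <- sort_templates(ggm, norms)
  gmeans <- lapply(gmeans, sort_templates, reference = ggm)
  indiv <- Map(function(s, g) sort_templates(s, gmeans[[g]]),
               indiv, groups)
  # Steps 8-9: backfit sorted individual templates, quantify
  segs <- Map(function(r, g, s)
    backfit(r, g, s, min_duration_ms = config$min_duration_ms),
    pp, gfps, indiv)
  quality <- Map(assignment_quality, segs, pp, gfps, indiv)
  params <- do.call(rbind, Map(function(s, g, q)
    compute_parameters(s, g, truncation_policy = config$truncation_policy,
                       gev_per_class = q$per_class),
    segs, gfps, quality))
  rownames(params) <- NULL
  trans <- lapply(segs, function(s)
    transition_table(s, include_truncated =
                       config$truncation_policy == "duration-only"))
  names(trans) <- vapply(segs, `[[`, "", "subject_id")
  gev_total <- vapply(quality, `[[`, 0, "total")
  names(gev_total) <- names(trans)

  out <- list(preprocessed = pp, gfps = gfps, individual_sets = indiv,
              group_means = gmeans, grand_grand_mean = ggm,
              segmentations = segs, parameters = params,
              transitions = trans, gev = gev_total, config = config)
  if (run_stats)
    out$stats <- cohort_statistics(out, config)
  out
}

#' Group statistics battery on pipeline results
#'
#' Runs, for a two-group pipeline result: per-parameter outlier screening;
#' mixed ANOVAs (group x class) on duration, occurrence, coverage and
#' mean GFP; overall Welch t tests (pooled over subject x class
#' observations) with Cohen's d for duration, mean GFP and per-class GEV;
#' Bonferroni-corrected Welch tests on the 12 transition pairs; and the
#' randomization TANOVA on per-subject mean maps plus its per-class
#' variant on the sorted individual class templates.
#'
#' @param result a [run_pipeline()] result (stats may be absent).
#' @param config the [pipeline_config()] used.
#' @return A list: `anova` (named list of mixed-ANOVA tables), `overall`
#'   (Welch rows), `transitions`, `tanova`, `tanova_per_class`,
#'   `outliers` (per-parameter excluded subject ids).
#' @export
cohort_statistics <- function(result, config = result$config) {
  params <- result$parameters
  glev <- sort(unique(params$group))
  if (length(glev) != 2L) stop("statistics need exactly 2 groups")
  anova_params <- c(duration = "duration_ms", occurrence = "occurrence_per_s",
                    coverage = "coverage_pct", mean_gfp = "mean_gfp_uv")
  outliers <- list()
  anovas <- list()
  overall <- list()
  for (nm in names(anova_params)) {
    col <- anova_params[[nm]]
    scr <- exclude_outliers(params, col)
    outliers[[nm]] <- scr$excluded
    tab <- scr$table
    ok_subj <- names(which(tapply(is.finite(tab[[col]]),
                                  tab$subject_id, all)))
    tab <- tab[tab$subject_id %in% ok_subj, ]
    anovas[[nm]] <- mixed_anova(tab, value = col, group = "group",
                                class = "class", subject = "subject_id")
    a <- tab[tab$group == glev[1L], col]
    b <- tab[tab$group == glev[2L], col]
    overall[[nm]] <- cbind(parameter = nm, welch_t(a, b))
  }
  # per-class GEV pooled comparison
  scr <- exclude_outliers(params, "gev_class")
  gv <- scr$table
  overall$gev <- cbind(parameter = "gev",
                       welch_t(gv$gev_class[gv$group == glev[1L]],
                               gv$gev_class[gv$group == glev[2L]]))
  outliers$gev <- scr$excluded

  subj_groups <- vapply(result$segmentations, `[[`, "", "group")
  transA <- result$transitions[subj_groups == glev[1L]]
  transB <- result$transitions[subj_groups == glev[2L]]
  trans_cmp <- compare_transitions(transA, transB)

  # TANOVA entry point 1: per-subject mean of the sorted class templates
  mean_map <- function(s) rowMeans(s$maps)
  mA <- vapply(result$individual_sets[subj_groups == glev[1L]],
               mean_map, numeric(nrow(result$grand_grand_mean$maps)))
  mB <- vapply(result$individual_sets[subj_groups == glev[2L]],
               mean_map, numeric(nrow(result$grand_grand_mean$maps)))
  tan <- tanova(mA, mB, config$n_permutations, seed = config$stat_seed)
  # entry point 2: per class, on the sorted individual templates
  labs <- result$grand_grand_mean$labels
  tan_class <- lapply(seq_along(labs), function(k) {
    cA <- vapply(result$individual_sets[subj_groups == glev[1L]],
                 function(s) s$maps[, k], numeric(nrow(mA)))
    cB <- vapply(result$individual_sets[subj_groups == glev[2L]],
                 function(s) s$maps[, k], numeric(nrow(mA)))
    tanova(cA, cB, config$n_permutations, seed = config$stat_seed + k)
  })
  names(tan_class) <- labs

  list(anova = anovas, overall = do.call(rbind, overall),
       transitions = trans_cmp, tanova = tan,
       tanova_per_class = tan_class, outliers = outliers)
}
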