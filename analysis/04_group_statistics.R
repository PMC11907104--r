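#!/usr/bin/env Rscript
# The group statistics battery on the full cohort: per-parameter outlier
# screen, mixed ANOVAs (Greenhouse-Geisser corrected where sphericity is
# rejected), overall Welch t tests with Cohen's d, Bonferroni-corrected
# tests on the 12 transition pairs, and the randomization TANOVA
# (per-subject mean maps and per-class variant).

source("analysis/_common.R")

st <- readRDS(checkpoint("templates"))
qt <- readRDS(checkpoint("quantified"))

result <- list(parameters = qt$params, transitions = qt$trans,
               segmentations = qt$segs, individual_sets = st$indiv,
               grand_grand_mean = st$ggm, group_means = st$gmeans,
               gev = vapply(qt$quality, `[[`, 0, "total"),
               config = pipe_config)
stats <- cohort_statistics(result, pipe_config)

anova_tab <- do.call(rbind, Map(function(nm, a)
  cbind(parameter = nm, a), names(stats$anova), stats$anova))
write_tsv(anova_tab, "stats_mixed_anova.tsv")
write_tsv(stats$overall, "stats_overall_welch.tsv")
write_tsv(stats$transitions, "stats_transitions.tsv")
tanova_tab <- rbind(
  data.frame(maps = "subject_mean", observed = stats$tanova$observed_effect,
             p = stats$tanova$p),
  do.call(rbind, lapply(names(stats$tanova_per_class), function(k)
    data.frame(maps = paste0("class_", k),
               observed = stats$tanova_per_class[[k]]$observed_effect,
               p = stats$tanova_per_class[[k]]$p))))
write_tsv(tanova_tab, "stats_tanova.tsv")
saveRDS(stats, checkpoint("stats"))

for (nm in names(stats$anova)) {
  a <- stats$anova[[nm]]
  g <- a[a$effect == "group", ]
  message(sprintf(
    "%s: group F(%.0f, %.0f) = %.2f, p = %.4g, partial eta2 = %.2f%s",
    nm, g$df1, g$df2, g$F, g$p, g$peta2,
    if (g$p < 0.05) "  *" else ""))
}
sig <- stats$transitions[stats$transitions$p_bonf < 0.05, ]
if (nrow(sig)) {
  message("transition pairs significant after Bonferroni (m = 12):")
  for (i in seq_len(nrow(sig)))
    message(sprintf("  %s->%s: t(%.1f) = %.2f, corrected p = %.3g, d = %.2f",
                    sig$from[i], sig$to[i], sig$df[i], sig$t[i],
                    sig$p_bonf[i], sig$d[i]))
}
message(sprintf("TANOVA (subject mean maps): p = %.3f", stats$tanova$p))
if (length(stats$outliers$duration))
  message("duration outliers excluded: ",
          paste(stats$outliers$duration, collapse = ", "))
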