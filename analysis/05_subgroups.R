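#!/usr/bin/env Rscript
# Exploratory subgroup analyses: the whole battery re-run on the
# migraine-flagged and unflagged subsets of the cohort.

source("analysis/_common.R")

cohort <- readRDS(checkpoint("cohort"))

for (sub in c("migraine", "no-migraine")) {
  cfg <- pipeline_config(n_permutations = pipe_config$n_permutations,
                         stat_seed = pipe_config$stat_seed,
                         subgroup = sub)
  res <- run_pipeline(cohort$recordings, cfg)
  tag <- gsub("-", "_", sub)
  write_tsv(res$parameters, paste0("subgroup_", tag, "_parameters.tsv"))
  anova_tab <- do.call(rbind, Map(function(nm, a)
    cbind(parameter = nm, a), names(res$stats$anova), res$stats$anova))
  write_tsv(anova_tab, paste0("subgroup_", tag, "_anova.tsv"))
  n_sub <- length(unique(res$parameters$subject_id))
  g <- res$stats$anova$duration
  message(sprintf(
    "%s (n = %d): duration group p = %.4g; mean GFP group p = %.4g",
    sub, n_sub, g$p[g$effect == "group"],
    res$stats$anova$mean_gfp$p[res$stats$anova$mean_gfp$effect == "group"]))
}
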