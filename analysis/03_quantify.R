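#!/usr/bin/env Rscript
# Backfit each subject's sorted templates to their recording and quantify
# the microstate parameters on GFP peaks, refusing truncated microstates
# for duration; assemble the cohort parameter and transition tables.

source("analysis/_common.R")

st <- readRDS(checkpoint("templates"))

segs <- Map(backfit, st$recs, st$gfps, st$indiv)
quality <- Map(assignment_quality, segs, st$recs, st$gfps, st$indiv)
params <- do.call(rbind, Map(function(s, g, q)
  compute_parameters(s, g, truncation_policy = pipe_config$truncation_policy,
                     gev_per_class = q$per_class),
  segs, st$gfps, quality))
rownames(params) <- NULL
trans <- lapply(segs, transition_table)
names(trans) <- vapply(segs, `[[`, "", "subject_id")

saveRDS(list(segs = segs, params = params, trans = trans,
             quality = quality), checkpoint("quantified"))

write_tsv(params, "parameters.tsv")
flat <- do.call(rbind, lapply(names(trans), function(id) {
  pc <- trans[[id]]$percentages
  data.frame(subject_id = id,
             from = rep(rownames(pc), each = ncol(pc)),
             to = rep(colnames(pc), nrow(pc)),
             percent = as.vector(t(pc)))
}))
write_tsv(flat[flat$from != flat$to, ], "transitions.tsv")

groups <- vapply(segs, `[[`, "", "group")
for (g in sort(unique(groups))) {
  m <- params[params$group == g, ]
  msg <- sprintf(
    "%s: duration %.1f ms, occurrence %.2f /s, mean GFP %.2f uV, GEV %.1f%%",
    g, mean(m$duration_ms, na.rm = TRUE), mean(m$occurrence_per_s),
    mean(m$mean_gfp_uv), 100 * mean(tapply(m$gev_class, m$subject_id, sum)))
  message(msg)
}
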