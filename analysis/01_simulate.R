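#!/usr/bin/env Rscript
# Simulate the study cohort: 21 "control" and 21 "patient" subjects with
# known microstate ground truth.  Patients get shorter dwell times, lower
# source amplitude, and a transition shift from A->C towards A->B; two
# thirds of each group carry a migraine flag for the subgroup analyses.

source("analysis/_common.R")

cohort <- make_cohort(n_per_group, base_config, study_effect,
                      seed = cohort_seed)
saveRDS(cohort, checkpoint("cohort"))

write_tsv(cohort$subjects, "cohort_subjects.tsv")

dwell <- vapply(cohort$truths, function(tr) {
  s <- tr$segments
  ep_len <- round(tr$config$epoch_s * tr$config$fs_hz)
  keep <- s$start != 0L & s$end != ep_len
  mean((s$end - s$start)[keep]) / tr$config$fs_hz * 1000
}, 0)
groups <- cohort$subjects$group
message(sprintf(
  "ground-truth mean dwell: %.1f ms (g1 controls) vs %.1f ms (g2 patients)",
  mean(dwell[groups == "g1"]), mean(dwell[groups == "g2"])))
message(sprintf("%d subjects simulated (%d with migraine flag)",
                nrow(cohort$subjects), sum(cohort$subjects$migraine)))
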