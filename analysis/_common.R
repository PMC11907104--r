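# Shared configuration for the numbered analysis scripts.  Heavy
# intermediates (raw cohort, preprocessed recordings) live under scratch/;
# every table a reader would consult is written under results/.

library(microstatr)

paths <- list(scratch = "scratch/analysis", results = "results/analysis")
for (p in paths) dir.create(p, recursive = TRUE, showWarnings = FALSE)

# Study conditions: two groups of 21 subjects, 25-channel clinical montage,
# 250 Hz, eight 20 s eyes-closed epochs, four canonical classes with 80 ms
# mean dwell, alpha carrier, snr 2.  Group 2 ("patient") carries the
# effects reported for the clinical contrast: shorter dwell (x0.85), lower
# amplitude (x0.8), and a transition shift from A->C towards A->B (+0.15).
n_per_group <- 21L
cohort_seed <- 1105L
base_config <- sim_config()
effect_delta <- matrix(0, 4, 4)
effect_delta[1, 2] <- 0.15
effect_delta[1, 3] <- -0.15
study_effect <- group_effect(dwell_mult = 0.85, amplitude_mult = 0.8,
                             transition_add = effect_delta)
pipe_config <- pipeline_config(n_permutations = 5000L, stat_seed = 2207L)

checkpoint <- function(name) file.path(paths$scratch, paste0(name, ".rds"))
result_file <- function(name) file.path(paths$results, name)

write_tsv <- function(x, name) {
  utils::write.table(x, result_file(name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("wrote ", result_file(name))
}
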