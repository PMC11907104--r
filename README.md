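# microstatr

Resting-state EEG **microstate analysis** in R, for researchers who want
the complete clinical analysis chain — preprocessing, polarity-invariant
AAHC clustering, hierarchical template sorting, backfitting, parameter
and transition-syntax quantification, and the group-statistics battery —
as plain, tested functions, together with a synthetic cohort generator
with known ground truth so every stage can be verified by parameter
recovery.

Spontaneous EEG passes through brief (~60–120 ms) periods during which
the scalp potential topography stays quasi-stable — *microstates* —
conventionally clustered into four classes A–D.  The package implements
the standard pipeline: average reference → 2–20 Hz zero-phase band-pass →
trimming to equal length → global field power (GFP, the instantaneous SD
across electrodes) and its peaks → atomize-and-agglomerate hierarchical
clustering (AAHC) of the peak topographies into K = 4 classes per subject
→ group grand means → grand grand mean → sorting against canonical norms
and down the hierarchy → backfitting → quantification of duration,
occurrence, coverage, mean GFP, global explained variance

$$\mathrm{GEV}_k=\frac{\sum_{t:a(t)=k}\big(\mathrm{GFP}_t\,
\mathrm{corr}(v_t,u_k)\big)^2}{\sum_t\mathrm{GFP}_t^2},$$

and transition syntax — then mixed ANOVAs (Greenhouse–Geisser corrected),
Welch t tests with Cohen's d, Bonferroni-corrected tests over the 12
transition pairs, and a randomization TANOVA on GFP-normalized maps.

## Worked example

Simulate a two-group cohort in which the second group has 15% shorter
microstates, 20% lower amplitude and a transition shift from A→C towards
A→B, then run the full pipeline:

```r
library(microstatr)

delta <- matrix(0, 4, 4); delta[1, 2] <- 0.15; delta[1, 3] <- -0.15
cohort <- make_cohort(
  n_per_group = 21,
  base   = sim_config(),                      # 25 ch, 250 Hz, 8 x 20 s,
  effect = group_effect(dwell_mult = 0.85,    # dwell 80 ms, snr 2
                        amplitude_mult = 0.8,
                        transition_add = delta),
  seed = 1105)
res <- run_pipeline(cohort$recordings,
                    pipeline_config(n_permutations = 5000,
                                    stat_seed = 2207))
```

`res$parameters` holds the subject × class table.  Group summaries from
this exact run:

```
g1: duration 86.1 ms, occurrence 2.92 /s, mean GFP 3.09 uV, GEV 95.7%
g2: duration 74.8 ms, occurrence 3.36 /s, mean GFP 2.43 uV, GEV 94.6%
```

(durations recover the configured 80 / 68 ms dwells with the few-ms
upward bias inherent to peak-based backfitting at a 10 Hz carrier), and
`res$stats` the battery:

```
duration: group F(1, 40) = 41.53, p = 1.123e-07, partial eta2 = 0.51  *
mean_gfp: group F(1, 40) = 81.31, p = 3.492e-11, partial eta2 = 0.67  *
A->B: t(40.0) = -14.61, corrected p = 1.53e-16, d = -4.51
A->C: t(35.9) = 17.69, corrected p = 3.17e-18, d = 5.46
TANOVA (subject mean maps): p = 0.856
```

— the injected duration, amplitude and syntax effects are detected, and
the TANOVA is properly null (both groups share the same topographies).
The same run, stage by stage with all tables written under
`results/analysis/`, is in the numbered scripts:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_templates.R
Rscript analysis/03_quantify.R
Rscript analysis/04_group_statistics.R
Rscript analysis/05_subgroups.R
```

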