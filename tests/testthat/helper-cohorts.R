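# Shared fixtures.  The two cohort-scale pipeline runs are expensive, so
# they are memoized for the session; every block that needs them sees the
# identical deterministic result.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache))
    assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# small montage with positions, for fast clustering tests
small_montage <- function(E = 10L) {
  ang <- seq(0, 2 * pi, length.out = E + 1L)[-1L]
  montage(paste0("e", seq_len(E)),
          cbind(x = cos(ang), y = sin(ang)))
}

# random mean-zero unit-norm maps
random_maps <- function(E, n, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(E * n), E, n)
  m <- sweep(m, 2L, colMeans(m))
  sweep(m, 2L, sqrt(colSums(m^2)), "/")
}

# 12 noisy maps drawn from 3 well-separated ground-truth templates; the
# instance class requires within-group polarity-invariant |corr| >= 0.9,
# so draws violating it are rejected and redrawn
three_class_instance <- function(seed, E = 10L, per_class = 4L,
                                 noise_sd = 0.1) {
  set.seed(seed)
  repeat {
    base <- qr.Q(qr(matrix(rnorm(E * 3L), E, 3L)))
    base <- sweep(base, 2L, colMeans(base))
    base <- sweep(base, 2L, sqrt(colSums(base^2)), "/")
    maps <- base[, rep(1:3, each = per_class)] +
      matrix(rnorm(E * 3L * per_class, sd = noise_sd), E, 3L * per_class)
    signs <- sample(c(-1, 1), ncol(maps), replace = TRUE)
    maps <- sweep(maps, 2L, signs, "*")
    nm <- sweep(maps, 2L, colMeans(maps))
    nm <- sweep(nm, 2L, sqrt(colSums(nm^2)), "/")
    ok <- vapply(seq_len(3L), function(g) {
      cc <- abs(crossprod(nm[, (g - 1L) * per_class + seq_len(per_class)]))
      min(cc[upper.tri(cc)]) >= 0.9
    }, NA)
    if (all(ok)) break
  }
  # weights mimic GFP at detected peaks in the synthetic recordings
  # (mean ~4.3 uV, CV ~0.21)
  list(maps = maps, gfp = pmax(rnorm(ncol(maps), 4.3, 0.9), 1),
       truth = base)
}

# quick single-subject preprocessed recording + GFP (for unit tests)
quick_subject <- function(seed = 11L, n_epochs = 2L, epoch_s = 10,
                          snr = 2, dwell_mean_ms = 80) {
  cfg <- sim_config(n_epochs = n_epochs, epoch_s = epoch_s, snr = snr,
                    dwell_mean_ms = dwell_mean_ms)
  tr <- sample_label_sequence(cfg, seed = seed)
  rec <- synthesize_recording(tr, seed = seed + 1L)
  rec <- bandpass(average_reference(rec))
  gfp <- detect_gfp_peaks(compute_gfp(rec))
  list(rec = rec, gfp = gfp, truth = tr, config = cfg)
}

# study-conditions null cohort: n = 10/group, dwell 80 ms, snr 2,
# 8 x 20 s epochs, no group effect; full pipeline without statistics
null_recovery_run <- function() {
  memo("null_recovery", {
    co <- make_cohort(10L, sim_config(), seed = 42L)
    res <- run_pipeline(co$recordings, pipeline_config(), run_stats = FALSE)
    list(cohort = co, result = res)
  })
}

# effect-injected cohort: dwell x0.85, amplitude x0.8, A->B +0.15
# (compensated on A->C/A->D), n = 20/group; full pipeline with statistics
effect_run <- function() {
  memo("effect_run", {
    delta <- matrix(0, 4, 4)
    delta[1, 2] <- 0.15
    delta[1, 3] <- -0.075
    delta[1, 4] <- -0.075
    eff <- group_effect(dwell_mult = 0.85, amplitude_mult = 0.8,
                        transition_add = delta)
    co <- make_cohort(20L, sim_config(), eff, seed = 20L)
    run_pipeline(co$recordings,
                 pipeline_config(n_permutations = 1000L, stat_seed = 7L))
  })
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
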