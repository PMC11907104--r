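#' Simulation configuration for synthetic microstate EEG
#'
#' Bundles everything the generator needs: the generative class templates,
#' the semi-Markov transition matrix, per-class dwell-time and amplitude
#' parameters, the oscillatory carrier, the noise level, and the epoch
#' structure.  Defaults reproduce an eyes-closed resting-state recording:
#' 25-channel clinical montage, 250 Hz, eight 20 s epochs, four canonical
#' microstate classes that stay quasi-stable for about 60-120 ms
#' (gamma-distributed dwell with mean 80 ms), a 10 Hz alpha carrier, and
#' source amplitudes giving mean GFP values of a few microvolts.
#'
#' @param templates generative [template_set()] (default: canonical A-D).
#' @param transition_matrix K x K row-stochastic matrix with zero diagonal;
#'   default: uniform over the other classes.
#' @param dwell_mean_ms per-class mean dwell time, ms (recycled to K).
#' @param dwell_shape gamma shape of the dwell distribution (larger =
#'   narrower; 4 gives a realistic 60-120 ms spread around an 80 ms mean).
#' @param amplitude_uv per-class source amplitude, microvolts (recycled).
#' @param carrier_hz oscillation frequency of the source waveform, Hz.
#' @param snr ratio of state-signal RMS to additive-noise RMS.
#' @param fs_hz sampling rate, Hz.
#' @param n_epochs,epoch_s epoch count and epoch length in seconds.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(templates = make_canonical_templates(),
                       transition_matrix = NULL,
                       dwell_mean_ms = 80, dwell_shape = 4,
                       amplitude_uv = 25, carrier_hz = 10,
                       snr = 2, fs_hz = 250,
                       n_epochs = 8L, epoch_s = 20) {
  K <- length(templates$labels)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (K - 1), K, K)
    diag(transition_matrix) <- 0
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!identical(dim(transition_matrix), c(K, K)))
    stop("transition_matrix must be K x K with K = ", K)
  if (any(transition_matrix < 0)) stop("negative transition probability")
  if (any(diag(transition_matrix) != 0))
    stop("transition_matrix must have a zero diagonal")
  rs <- rowSums(transition_matrix)
  if (any(rs == 0)) stop("transition_matrix has an all-zero row")
  if (any(abs(rs - 1) > 1e-8))
    stop("transition_matrix rows must sum to 1")
  dwell_mean_ms <- rep_len(dwell_mean_ms, K)
  amplitude_uv <- rep_len(amplitude_uv, K)
  stopifnot(all(dwell_mean_ms > 0), dwell_shape > 0,
            all(amplitude_uv > 0), carrier_hz > 0, snr > 0, fs_hz > 0,
            n_epochs >= 1, epoch_s > 0)
  structure(list(templates = templates,
                 transition_matrix = transition_matrix,
                 dwell_mean_ms = dwell_mean_ms, dwell_shape = dwell_shape,
                 amplitude_uv = amplitude_uv, carrier_hz = carrier_hz,
                 snr = snr, fs_hz = fs_hz,
                 n_epochs = as.integer(n_epochs), epoch_s = epoch_s),
            class = "sim_config")
}

#' Sample a ground-truth microstate label sequence
#'
#' Semi-Markov generator: within each epoch, the class of the first segment
#' is uniform; each subsequent class is drawn from the transition matrix row
#' of its predecessor; each segment's dwell time is gamma with the class's
#' configured mean and the common shape, truncated at the epoch end.
#' Dwells are rounded to at least one sample.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; the sequence is deterministic given the seed.
#' @return An object of class `ground_truth` with per-sample 1-based
#'   `labels`, a `segments` data frame (`epoch`, `start`, `end` half-open
#'   0-based, `class`), and the `config`.
#' @export
sample_label_sequence <- function(config, seed = 1L) {
  set.seed(seed)
  K <- length(config$templates$labels)
  n_ep <- config$n_epochs
  ep_len <- round(config$epoch_s * config$fs_hz)
  rate <- config$dwell_shape / (config$dwell_mean_ms / 1000)  # per class
  labels <- integer(n_ep * ep_len)
  seg <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    pos <- 0L
    cls <- sample.int(K, 1L)
    starts <- integer(0); ends <- integer(0); classes <- integer(0)
    while (pos < ep_len) {
      # dwell_shape = Inf gives a degenerate (fixed-dwell) distribution
      dwell_s <- if (is.finite(config$dwell_shape))
        stats::rgamma(1L, shape = config$dwell_shape, rate = rate[cls])
      else config$dwell_mean_ms[cls] / 1000
      len <- max(1L, as.integer(round(dwell_s * config$fs_hz)))
      len <- min(len, ep_len - pos)
      starts <- c(starts, pos); ends <- c(ends, pos + len)
      classes <- c(classes, cls)
      labels[(e - 1L) * ep_len + (pos + 1L):(pos + len)] <- cls
      pos <- pos + len
      cls <- sample.int(K, 1L, prob = config$transition_matrix[cls, ])
    }
    seg[[e]] <- data.frame(epoch = e, start = starts, end = ends,
                           class = classes)
  }
  segments <- do.call(rbind, seg)
  structure(list(labels = labels, segments = segments, config = config,
                 seed = seed),
            class = "ground_truth")
}

#' Synthesize a multichannel EEG recording from a label sequence
#'
#' Each sample is `amplitude[class] * sin(2 pi f t + phi_segment) *
#' template[class]` plus spatially and temporally white Gaussian noise
#' scaled so that the ratio of state-signal RMS to noise RMS equals the
#' configured `snr`.  The oscillation phase is re-drawn uniformly at each
#' segment onset, so state changes are marked by topography change rather
#' than phase continuity.  The output is average-referenced.
#'
#' @param truth a `ground_truth` from [sample_label_sequence()].
#' @param montage montage used to label channels (default: the template
#'   set's electrode order via [ifcn_montage()]).
#' @param seed RNG seed for phases and noise.
#' @param subject_id,group,migraine metadata forwarded to the recording.
#' @return An [eeg_recording()] with the epoch structure of the simulation.
#' @export
synthesize_recording <- function(truth, montage = ifcn_montage(),
                                 seed = 1L, subject_id = "s1",
                                 group = NA_character_, migraine = NA) {
  set.seed(seed)
  cfg <- truth$config
  tm <- cfg$templates$maps
  E <- nrow(tm)
  n <- length(truth$labels)
  tt <- (seq_len(n) - 1L) / cfg$fs_hz
  # per-sample oscillation with a fresh uniform phase per segment
  phase <- numeric(n)
  segs <- truth$segments
  ep_len <- round(cfg$epoch_s * cfg$fs_hz)
  for (i in seq_len(nrow(segs))) {
    idx <- (segs$epoch[i] - 1L) * ep_len + (segs$start[i] + 1L):segs$end[i]
    phase[idx] <- stats::runif(1L, 0, 2 * pi)
  }
  amp <- cfg$amplitude_uv[truth$labels]
  wave <- amp * sin(2 * pi * cfg$carrier_hz * tt + phase)
  data <- tm[, truth$labels, drop = FALSE] *
    rep(wave, each = E)                       # E x n state signal
  sig_rms <- sqrt(mean(data^2))
  noise_sd <- sig_rms / cfg$snr
  data <- data + matrix(stats::rnorm(E * n, sd = noise_sd), E, n)
  data <- sweep(data, 2L, colMeans(data))     # average reference
  epochs <- cbind(start = (seq_len(cfg$n_epochs) - 1L) * ep_len,
                  end = seq_len(cfg$n_epochs) * ep_len)
  eeg_recording(data, cfg$fs_hz, montage, epochs, subject_id = subject_id,
                group = group, migraine = migraine)
}

#' Group effect specification for cohort simulation
#'
#' Multiplicative deltas on dwell time and amplitude and an additive delta
#' matrix on the transition rows (re-normalized after addition) applied to
#' the second group only.
#'
#' @param dwell_mult,amplitude_mult multiplicative factors (scalar or
#'   per-class).
#' @param transition_add K x K additive matrix (zero diagonal) or NULL.
#' @return A list of class `group_effect`.
#' @export
group_effect <- function(dwell_mult = 1, amplitude_mult = 1,
                         transition_add = NULL) {
  structure(list(dwell_mult = dwell_mult, amplitude_mult = amplitude_mult,
                 transition_add = transition_add),
            class = "group_effect")
}

apply_group_effect <- function(config, effect) {
  tm <- config$transition_matrix
  if (!is.null(effect$transition_add)) {
    tm <- tm + effect$transition_add
    if (any(tm < 0))
      stop("group effect produces negative transition probabilities")
    diag(tm) <- 0
    tm <- tm / rowSums(tm)
  }
  sim_config(templates = config$templates, transition_matrix = tm,
             dwell_mean_ms = config$dwell_mean_ms * effect$dwell_mult,
             dwell_shape = config$dwell_shape,
             amplitude_uv = config$amplitude_uv * effect$amplitude_mult,
             carrier_hz = config$carrier_hz, snr = config$snr,
             fs_hz = config$fs_hz, n_epochs = config$n_epochs,
             epoch_s = config$epoch_s)
}

#' Simulate a two-group cohort with known ground truth
#'
#' Group 1 subjects are drawn from `base`; group 2 subjects from `base`
#' modified by the `group_effect()`.  Each subject additionally receives
#' lognormal multiplicative jitter (sigma on the log scale) on dwell and
#' amplitude, creating realistic between-subject variance, and a migraine
#' flag (balanced within group) for subgroup filtering.  Everything is
#' reproducible from `seed` alone.
#'
#' @param n_per_group subjects per group.
#' @param base a [sim_config()].
#' @param effect a [group_effect()]; default: none (null cohort).
#' @param seed master RNG seed.
#' @param jitter_sd lognormal sigma of the per-subject dwell/amplitude
#'   multipliers (0 disables jitter).
#' @param montage channel montage for the synthesized recordings.
#' @param migraine_frac fraction of each group flagged as having migraine.
#' @return A list with `recordings` (list of [eeg_recording()]),
#'   `truths` (matching `ground_truth` objects), and `subjects`
#'   (metadata data frame).
#' @export
make_cohort <- function(n_per_group, base = sim_config(),
                        effect = group_effect(), seed = 1L,
                        jitter_sd = 0.1, montage = ifcn_montage(),
                        migraine_frac = 2 / 3) {
  set.seed(seed)
  configs <- list(g1 = base, g2 = apply_group_effect(base, effect))
  n_tot <- 2L * n_per_group
  subj_seeds <- sample.int(.Machine$integer.max, 2L * n_tot)
  recs <- vector("list", n_tot)
  truths <- vector("list", n_tot)
  meta <- vector("list", n_tot)
  n_mig <- round(migraine_frac * n_per_group)
  jit <- matrix(exp(stats::rnorm(2L * n_tot, 0, jitter_sd)), ncol = 2L)
  for (i in seq_len(n_tot)) {
    g <- if (i <= n_per_group) 1L else 2L
    cfg <- configs[[g]]
    cfg_i <- sim_config(templates = cfg$templates,
                        transition_matrix = cfg$transition_matrix,
                        dwell_mean_ms = cfg$dwell_mean_ms * jit[i, 1L],
                        dwell_shape = cfg$dwell_shape,
                        amplitude_uv = cfg$amplitude_uv * jit[i, 2L],
                        carrier_hz = cfg$carrier_hz, snr = cfg$snr,
                        fs_hz = cfg$fs_hz, n_epochs = cfg$n_epochs,
                        epoch_s = cfg$epoch_s)
    id <- sprintf("g%d_s%02d", g, if (g == 1L) i else i - n_per_group)
    mig <- (if (g == 1L) i else i - n_per_group) <= n_mig
    truths[[i]] <- sample_label_sequence(cfg_i, seed = subj_seeds[2L * i - 1L])
    recs[[i]] <- synthesize_recording(truths[[i]], montage,
                                      seed = subj_seeds[2L * i],
                                      subject_id = id,
                                      group = paste0("g", g),
                                      migraine = mig)
    meta[[i]] <- data.frame(subject_id = id, group = paste0("g", g),
                            migraine = mig)
  }
  list(recordings = recs, truths = truths,
       subjects = do.call(rbind, meta))
}
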