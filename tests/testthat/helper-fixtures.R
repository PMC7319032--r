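# Shared fixtures, all generated in code at test time.

# Small single-participant design with both conditions.
small_design <- function(n_cued = 48, n_uncued = 48, block = 24, seed = 5) {
  generate_design(design_spec(n_participants = 1, n_cued_trials = n_cued,
                              n_uncued_trials = n_uncued, block_size = block,
                              seed = seed))
}

# Reduced-scale EEG simulation config used throughout the tests: 128 Hz,
# 3 s epochs with the cue at +1.0 s.
small_eeg_cfg <- function(seed, lateralization_db = 6, behavior_coupling = 0,
                          lateralization_trial_sd = 2) {
  eeg_sim_config(sfreq = 128, epoch_start = -0.5, epoch_end = 2.5,
                 cue_onset = 1.0, lateralization_db = lateralization_db,
                 lateralization_trial_sd = lateralization_trial_sd,
                 behavior_coupling = behavior_coupling, seed = seed)
}

# Alpha-band-only frequency grid (keeps wavelet convolution cheap when only
# the 7-14 Hz band feeds the downstream stages).
alpha_freqs <- function() tfr_default_freqs(5, 7, 14)

# Simulate one participant and reduce to dB alpha power (trials x ch x time).
simulate_alpha <- function(trials, montage, cfg) {
  ep <- simulate_eeg(trials, montage, cfg)
  tfr <- morlet_tfr(ep, freqs = alpha_freqs())
  tfr <- db_baseline(tfr, cfg$cue_onset + c(-0.5, 0))
  list(alpha = band_average(tfr, c(7, 14)), trials = ep$trial_info, tfr = tfr)
}

# Per-trial alpha topographies in the post-cue window for one participant.
# The TF time axis is decimated to ~32 Hz before averaging (power envelopes
# carry no information at higher rates).
simulate_topographies <- function(trials, montage, cfg, window = cfg$cue_onset + c(0.3, 1.2)) {
  ep <- simulate_eeg(trials, montage, cfg)
  tfr <- tfr_decimate(morlet_tfr(ep, freqs = alpha_freqs()),
                      max(1L, round(cfg$sfreq / 32)))
  tfr <- db_baseline(tfr, cfg$cue_onset + c(-0.5, 0))
  list(topo = band_time_average(tfr, c(7, 14), window), trials = ep$trial_info)
}
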