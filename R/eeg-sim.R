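# Synthetic multichannel EEG epochs: 1/f background + lateralized posterior alpha.

#' Configuration for the EEG epoch simulator
#'
#' Defaults mirror the study timing: epochs from 1.0 s before target onset to
#' 4.5 s after, retro-cue at +1.5 s, 512 Hz sampling. The generated signal is
#' a 1/f ("pink") noise background plus a posterior alpha oscillation whose
#' amplitude over the hemisphere contralateral to the cued side drops after
#' cue onset by `lateralization_db` (in power dB) plus Gaussian per-trial
#' jitter.
#'
#' @param sfreq sampling rate, Hz.
#' @param epoch_start,epoch_end epoch limits in seconds relative to target
#'   onset.
#' @param cue_onset cue time in seconds relative to target onset.
#' @param alpha_freq alpha oscillation frequency, Hz (within 7-14).
#' @param baseline_alpha_amp alpha amplitude at the posterior foci, microvolt.
#' @param lateralization_db mean post-cue contralateral power suppression, dB
#'   (>= 0 suppresses the contralateral hemisphere).
#' @param lateralization_trial_sd per-trial SD of the suppression, dB.
#' @param topography_width great-circle width (radians) of the Gaussian
#'   posterior alpha topography.
#' @param noise_exponent spectral slope of the background (power ~ 1/f^exp).
#' @param noise_amp background noise SD, microvolt.
#' @param behavior_coupling coupling of per-trial lateralization to response
#'   precision: the trial's jitter z-score maps to a kappa multiplier
#'   `max(0.1, 1 + behavior_coupling * z)` recorded in the trial metadata.
#' @param lateralize_uncued if `TRUE`, non-cued trials are lateralized
#'   relative to the to-be-probed side; by default they are not.
#' @param seed integer seed.
#' @return an object of class `"eeg_sim_config"`.
#' @export
eeg_sim_config <- function(sfreq = 512,
                           epoch_start = -1.0, epoch_end = 4.5,
                           cue_onset = 1.5,
                           alpha_freq = 10,
                           baseline_alpha_amp = 4,
                           lateralization_db = 6,
                           lateralization_trial_sd = 2,
                           topography_width = 0.8,
                           noise_exponent = 1,
                           noise_amp = 5,
                           behavior_coupling = 0,
                           lateralize_uncued = FALSE,
                           seed = 1L) {
  cfg <- list(sfreq = sfreq, epoch_start = epoch_start, epoch_end = epoch_end,
              cue_onset = cue_onset, alpha_freq = alpha_freq,
              baseline_alpha_amp = baseline_alpha_amp,
              lateralization_db = lateralization_db,
              lateralization_trial_sd = lateralization_trial_sd,
              topography_width = topography_width,
              noise_exponent = noise_exponent, noise_amp = noise_amp,
              behavior_coupling = behavior_coupling,
              lateralize_uncued = lateralize_uncued, seed = as.integer(seed))
  if (!(cfg$epoch_start < cfg$cue_onset && cfg$cue_onset < cfg$epoch_end)) {
    stop("eeg_sim_config: need epoch_start < cue_onset < epoch_end")
  }
  if (cfg$alpha_freq < 7 || cfg$alpha_freq > 14) {
    stop("eeg_sim_config: alpha_freq must lie in the 7-14 Hz analysis band")
  }
  if (cfg$sfreq <= 4 * cfg$alpha_freq) {
    stop("eeg_sim_config: sfreq must exceed 4 x alpha_freq")
  }
  structure(cfg, class = "eeg_sim_config")
}

# 1/f noise matrix (n_t x m) via spectral shaping of white Gaussian noise.
pink_noise <- function(n_t, m, exponent, amp) {
  white <- matrix(stats::rnorm(n_t * m), n_t, m)
  f <- c(0, seq_len(n_t - 1))
  f <- pmin(f, n_t - f) # two-sided frequency index
  s <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::mvfft(stats::mvfft(white) * s, inverse = TRUE)) / n_t
  sds <- sqrt(colMeans(x^2))
  x * (amp / mean(sds))
}

#' Simulate epoched EEG for a trial table
#'
#' Generates one epoch per trial over the channels of `montage`: pink noise
#' plus a posterior-focal alpha oscillation. After cue onset the alpha
#' amplitude over the hemisphere contralateral to the cued side (or probed
#' side on non-cued trials, when configured) is reduced by the trial's
#' realized suppression in dB. Realized suppression and the derived kappa
#' multiplier are recorded per trial in `$trial_info`.
#'
#' @param trials trial table from [generate_design()].
#' @param montage a [generate_montage()] montage.
#' @param cfg an [eeg_sim_config()].
#' @return an object of class `"epoch_array"`: list with `data` (array
#'   trials x channels x time, microvolt), `times` (s, relative to target
#'   onset), `sfreq`, `channels`, `cue_onset`, and `trial_info` (the trial
#'   table plus `realized_lat_db` and `kappa_mult` columns). Deterministic
#'   given `cfg$seed`.
#' @export
simulate_eeg <- function(trials, montage, cfg) {
  stopifnot(inherits(montage, "montage"), inherits(cfg, "eeg_sim_config"))
  if (!all(c("condition", "cue_side", "probed_side") %in% names(trials))) {
    stop("simulate_eeg(): trials must carry condition, cue_side and probed_side")
  }
  n_trials <- nrow(trials)
  n_ch <- length(montage$channel_names)
  n_t <- round((cfg$epoch_end - cfg$epoch_start) * cfg$sfreq)
  times <- cfg$epoch_start + (seq_len(n_t) - 1) / cfg$sfreq

  pos <- montage$positions
  focus_r <- c(0.55, -0.65, 0.25); focus_r <- focus_r / sqrt(sum(focus_r^2))
  focus_l <- c(-1, 1, 1) * focus_r
  ang_to <- function(f) acos(pmax(-1, pmin(1, as.vector(pos %*% f))))
  w_left <- exp(-(ang_to(focus_l) / cfg$topography_width)^2)  # peaks over LEFT scalp
  w_right <- exp(-(ang_to(focus_r) / cfg$topography_width)^2)

  # smooth onset of the post-cue gain over 100 ms, avoiding a broadband edge
  ramp <- pmin(1, pmax(0, (times - cfg$cue_onset) / 0.1))

  with_seed(cfg$seed, {
    lat_side <- ifelse(trials$condition == "cued", trials$cue_side,
                       if (cfg$lateralize_uncued) trials$probed_side else "none")
    jitter <- stats::rnorm(n_trials, 0, 1)
    realized <- ifelse(lat_side == "none", 0,
                       cfg$lateralization_db + cfg$lateralization_trial_sd * jitter)
    # coupling acts only where lateralization is actually expressed
    kappa_mult <- ifelse(lat_side == "none", 1,
                         pmax(0.1, 1 + cfg$behavior_coupling * jitter))

    data <- array(0, dim = c(n_trials, n_ch, n_t))
    noise <- pink_noise(n_t, n_trials * n_ch, cfg$noise_exponent, cfg$noise_amp)
    dim(noise) <- c(n_t, n_trials, n_ch)

    omega <- 2 * pi * cfg$alpha_freq
    for (i in seq_len(n_trials)) {
      phase <- stats::runif(n_ch, 0, 2 * pi)
      # post-cue amplitude gain per hemisphere component
      g_contra <- 10^(-realized[i] / 20)
      gain_l <- if (lat_side[i] == "right") 1 + (g_contra - 1) * ramp else rep(1, n_t)
      gain_r <- if (lat_side[i] == "left") 1 + (g_contra - 1) * ramp else rep(1, n_t)
      osc <- sin(outer(phase, omega * times, `+`)) # n_ch x n_t
      amp <- cfg$baseline_alpha_amp *
        (outer(w_left, gain_l) + outer(w_right, gain_r))
      data[i, , ] <- amp * osc + t(noise[, i, ])
    }

    info <- trials
    info$realized_lat_db <- realized
    info$kappa_mult <- kappa_mult

    structure(list(data = data, times = times, sfreq = cfg$sfreq,
                   channels = montage$channel_names,
                   cue_onset = cfg$cue_onset, trial_info = info),
              class = "epoch_array")
  })
}

#' Construct an epoch array from raw data
#'
#' Wraps a trials x channels x time voltage array together with its sampling
#' metadata, e.g. for epochs imported from other software.
#'
#' @param data numeric array trials x channels x time (microvolt).
#' @param sfreq sampling rate, Hz.
#' @param times time axis in seconds (length = third data dimension), or
#'   `NULL` to derive it from `epoch_start` and `sfreq`.
#' @param epoch_start epoch start in seconds (used when `times` is `NULL`).
#' @param cue_onset cue time in seconds on the epoch time axis.
#' @param channels channel names (length = second data dimension).
#' @param trial_info optional data frame of per-trial metadata, row-aligned.
#' @return an `epoch_array`.
#' @export
epoch_array <- function(data, sfreq, times = NULL, epoch_start = 0,
                        cue_onset = 0, channels = NULL, trial_info = NULL) {
  d <- dim(data)
  stopifnot(length(d) == 3)
  if (is.null(times)) times <- epoch_start + (seq_len(d[3]) - 1) / sfreq
  stopifnot(length(times) == d[3])
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(d[2]))
  stopifnot(length(channels) == d[2])
  if (!is.null(trial_info)) stopifnot(nrow(trial_info) == d[1])
  structure(list(data = data, times = times, sfreq = sfreq,
                 channels = channels, cue_onset = cue_onset,
                 trial_info = trial_info),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EpochArray: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  cat(sprintf("  window [%.2f, %.2f] s, cue at %.2f s\n",
              min(x$times), max(x$times) + 1 / x$sfreq, x$cue_onset))
  invisible(x)
}
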