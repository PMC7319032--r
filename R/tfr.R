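# Morlet wavelet time-frequency decomposition and dB baseline correction.

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every epoch and channel with complex Morlet wavelets and returns
#' squared-magnitude power. Defaults follow the analysis convention of 30
#' logarithmically spaced frequencies from 2 to 40 Hz with the number of
#' cycles increasing (log-spaced) from 1 to 10 across that grid. Convolution
#' is computed in the frequency domain after reflection-padding each epoch by
#' one half-support of the longest wavelet; samples within one half-support of
#' the epoch edges are flagged in `$edge_mask` as contaminated.
#'
#' @param epochs an `epoch_array` from [simulate_eeg()].
#' @param freqs frequency grid in Hz (default `tfr_default_freqs()`).
#' @param n_cycles wavelet cycles per frequency (default log-spaced 1 to 10;
#'   recycled to `length(freqs)`).
#' @return an object of class `"tf_power"`: list with `power` (array
#'   trials x channels x frequencies x time, raw power), `freqs`, `times`,
#'   `channels`, `units = "raw"`, `baseline_window = NULL` and `edge_mask`
#'   (frequencies x time, `TRUE` where edge-contaminated).
#' @export
morlet_tfr <- function(epochs, freqs = tfr_default_freqs(),
                       n_cycles = tfr_default_cycles(length(freqs))) {
  stopifnot(inherits(epochs, "epoch_array"))
  stopifnot(all(diff(freqs) > 0))
  n_cycles <- rep_len(n_cycles, length(freqs))
  sfreq <- epochs$sfreq
  if (sfreq < 2 * max(freqs)) {
    stop("morlet_tfr(): sampling rate below twice the highest analysis frequency")
  }
  d <- dim(epochs$data)
  n_trials <- d[1]; n_ch <- d[2]; n_t <- d[3]

  sigma_t <- n_cycles / (2 * pi * freqs)
  half_support <- ceiling(3.5 * sigma_t * sfreq)
  n_pad <- max(half_support)
  if (n_pad > n_t - 1) {
    stop("morlet_tfr(): epoch shorter than the longest wavelet support")
  }

  # time x (trial*channel) matrix with reflection padding, zero-extended to a
  # 5-smooth FFT length (prime lengths hit the slow DFT path)
  x <- matrix(aperm(epochs$data, c(3, 1, 2)), n_t, n_trials * n_ch)
  x_pad <- rbind(x[(n_pad + 1):2, , drop = FALSE], x,
                 x[(n_t - 1):(n_t - n_pad), , drop = FALSE])
  nn <- stats::nextn(nrow(x_pad), c(2, 3, 5))
  if (nn > nrow(x_pad)) {
    x_pad <- rbind(x_pad, matrix(0, nn - nrow(x_pad), ncol(x_pad)))
  }
  xf <- stats::mvfft(x_pad)

  power <- array(NA_real_, dim = c(n_trials, n_ch, length(freqs), n_t))
  for (k in seq_along(freqs)) {
    hs <- half_support[k]
    tw <- (-hs:hs) / sfreq
    w <- exp(2i * pi * freqs[k] * tw) * exp(-tw^2 / (2 * sigma_t[k]^2))
    # unit peak frequency response: a sinusoid at the wavelet's center
    # frequency keeps its amplitude, independent of the cycle schedule
    w <- w / sum(Mod(w))
    wv <- complex(length.out = nn)
    wv[c(nn - hs + seq_len(hs) - 1 + 1, 1:(hs + 1))] <- w # centered at index 1
    cf <- stats::mvfft(xf * stats::fft(wv), inverse = TRUE) / nn
    pw <- Mod(cf[(n_pad + 1):(n_pad + n_t), , drop = FALSE])^2
    power[, , k, ] <- aperm(array(pw, dim = c(n_t, n_trials, n_ch)), c(2, 3, 1))
  }

  edge_mask <- matrix(FALSE, length(freqs), n_t)
  for (k in seq_along(freqs)) {
    hs <- half_support[k]
    if (hs >= 1) edge_mask[k, c(seq_len(min(hs, n_t)),
                                seq.int(max(1, n_t - hs + 1), n_t))] <- TRUE
  }

  structure(list(power = power, freqs = freqs, times = epochs$times,
                 channels = epochs$channels, units = "raw",
                 baseline_window = NULL, edge_mask = edge_mask,
                 cue_onset = epochs$cue_onset),
            class = "tf_power")
}

#' Default frequency and cycle grids
#'
#' @param n number of frequency bins.
#' @param fmin,fmax grid limits, Hz.
#' @return numeric vector of length `n`.
#' @export
tfr_default_freqs <- function(n = 30, fmin = 2, fmax = 40) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' @rdname tfr_default_freqs
#' @param cmin,cmax cycle limits.
#' @export
tfr_default_cycles <- function(n = 30, cmin = 1, cmax = 10) {
  exp(seq(log(cmin), log(cmax), length.out = n))
}

#' Decimate the time axis of a TF power object
#'
#' Keeps every `q`-th time sample. Power envelopes vary far more slowly than
#' the raw signal, so decimating after the wavelet transform cuts the cost of
#' baselining and averaging without affecting band-level results.
#'
#' @param tfr a `tf_power`.
#' @param q positive integer decimation factor.
#' @return a `tf_power` with `times`, `power` and `edge_mask` subsampled.
#' @export
tfr_decimate <- function(tfr, q) {
  stopifnot(inherits(tfr, "tf_power"), q >= 1)
  keep <- seq(1, length(tfr$times), by = q)
  tfr$power <- tfr$power[, , , keep, drop = FALSE]
  tfr$times <- tfr$times[keep]
  tfr$edge_mask <- tfr$edge_mask[, keep, drop = FALSE]
  tfr
}

#' @export
print.tf_power <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("TFPower (%s): %d trials x %d channels x %d freqs x %d samples\n",
              x$units, d[1], d[2], d[3], d[4]))
  cat(sprintf("  freqs %.2f-%.2f Hz; times %.2f-%.2f s\n",
              min(x$freqs), max(x$freqs), min(x$times), max(x$times)))
  if (!is.null(x$baseline_window)) {
    cat(sprintf("  baseline [%.3f, %.3f] s\n", x$baseline_window[1], x$baseline_window[2]))
  }
  invisible(x)
}

#' Single-trial dB baseline correction
#'
#' Converts raw power to decibel change relative to a per-trial,
#' per-frequency (and per-channel) baseline:
#' `pwc = 10 * log10(pw / bsl)`, where `bsl` is raw power averaged over the
#' baseline window. The default baseline is per trial, as the single-trial
#' analyses require; `per_trial = FALSE` uses the cross-trial mean baseline
#' instead.
#'
#' @param tfr a raw `tf_power`.
#' @param baseline_window numeric length-2, seconds (same axis as
#'   `tfr$times`); must lie within the epoch and outside wavelet edge
#'   contamination.
#' @param per_trial use a per-trial baseline (default) or the cross-trial
#'   mean.
#' @return a `tf_power` with `units = "dB"` and `baseline_window` set.
#' @export
db_baseline <- function(tfr, baseline_window, per_trial = TRUE) {
  stopifnot(inherits(tfr, "tf_power"))
  if (tfr$units != "raw") stop("db_baseline(): input must be raw power")
  sel <- which(tfr$times >= baseline_window[1] & tfr$times <= baseline_window[2])
  if (!length(sel)) stop("db_baseline(): baseline window contains no samples")
  if (any(tfr$edge_mask[, sel])) {
    warning("db_baseline(): baseline window overlaps wavelet edge contamination at some frequencies")
  }
  d <- dim(tfr$power)
  bsl <- rowMeans(tfr$power[, , , sel, drop = FALSE], dims = 3)
  if (!per_trial) {
    m <- colMeans(bsl, dims = 1)
    bsl <- aperm(array(m, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  }
  if (any(bsl <= 0)) {
    bad <- which(bsl <= 0, arr.ind = TRUE)
    stop(sprintf("db_baseline(): non-positive baseline power (first at trial %d, channel %d, freq %.2f Hz)",
                 bad[1, 1], bad[1, 2], tfr$freqs[bad[1, 3]]))
  }
  # bsl (trial,channel,freq) recycles exactly over the trailing time dimension
  pwc <- 10 * log10(tfr$power / as.vector(bsl))
  out <- tfr
  out$power <- pwc
  out$units <- "dB"
  out$baseline_window <- baseline_window
  out$baseline <- bsl
  out
}

#' Average dB power over a frequency band (time-resolved)
#'
#' Unweighted mean over all frequency bins whose center lies in `band`
#' (inclusive bounds), keeping the time axis.
#'
#' @param tfr a dB-scaled `tf_power`.
#' @param band length-2 numeric, Hz. Default alpha, 7-14 Hz.
#' @return array trials x channels x time with attributes `band`, `times`,
#'   `channels`.
#' @export
band_average <- function(tfr, band = c(7, 14)) {
  stopifnot(inherits(tfr, "tf_power"))
  fb <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (!length(fb)) stop("band_average(): no frequency bins inside the band")
  out <- rowMeans(aperm(tfr$power[, , fb, , drop = FALSE], c(1, 2, 4, 3)), dims = 3)
  dimnames(out) <- list(NULL, tfr$channels, NULL)
  attr(out, "band") <- band
  attr(out, "times") <- tfr$times
  attr(out, "channels") <- tfr$channels
  out
}

#' Per-trial alpha topographies
#'
#' Averages dB power over a frequency band and a time window, yielding one
#' value per trial and channel (a topography per trial).
#'
#' @param tfr a dB-scaled `tf_power`.
#' @param band length-2 numeric, Hz (bin centers, inclusive).
#' @param window length-2 numeric, seconds.
#' @return matrix trials x channels of class `"trial_topography"` with
#'   attributes `band` and `window`.
#' @export
band_time_average <- function(tfr, band = c(7, 14), window) {
  stopifnot(inherits(tfr, "tf_power"))
  fb <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  tb <- which(tfr$times >= window[1] & tfr$times <= window[2])
  if (!length(fb) || !length(tb)) {
    stop("band_time_average(): empty band or window selection")
  }
  out <- rowMeans(tfr$power[, , fb, tb, drop = FALSE], dims = 2)
  colnames(out) <- tfr$channels
  attr(out, "band") <- band
  attr(out, "window") <- window
  class(out) <- c("trial_topography", class(out))
  out
}

#' @export
print.trial_topography <- function(x, ...) {
  cat(sprintf("TrialTopography: %d trials x %d channels, band %.1f-%.1f Hz, window [%.3f, %.3f] s\n",
              nrow(x), ncol(x), attr(x, "band")[1], attr(x, "band")[2],
              attr(x, "window")[1], attr(x, "window")[2]))
  invisible(x)
}
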