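# Wavelet time-frequency decomposition and dB baselining.

# one-trial, one-channel epoch array around a given signal
signal_epochs <- function(x, sfreq = 256, epoch_start = 0, n_trials = 1) {
  arr <- array(rep(x, each = n_trials), dim = c(n_trials, 1, length(x)))
  epoch_array(arr, sfreq = sfreq, epoch_start = epoch_start)
}

test_that("a pure sinusoid peaks at the nearest frequency bin", {
  sfreq <- 256
  tt <- (0:(3 * sfreq - 1)) / sfreq
  ep <- signal_epochs(sin(2 * pi * 10 * tt), sfreq)
  tfr <- morlet_tfr(ep)
  expect_length(tfr$freqs, 30)
  expect_equal(range(tfr$freqs), c(2, 40))
  # average power over clean samples only
  clean <- !apply(tfr$edge_mask, 2, any)
  prof <- vapply(seq_along(tfr$freqs),
                 function(k) mean(tfr$power[1, 1, k, clean]), numeric(1))
  expect_equal(which.max(prof), which.min(abs(tfr$freqs - 10)))
})

test_that("power is quadratic in amplitude and zero for silence", {
  sfreq <- 128
  tt <- (0:(2 * sfreq - 1)) / sfreq
  x <- sin(2 * pi * 9 * tt) + 0.3 * sin(2 * pi * 21 * tt)
  t1 <- morlet_tfr(signal_epochs(x, sfreq), freqs = tfr_default_freqs(10, 5, 30))
  t2 <- morlet_tfr(signal_epochs(2 * x, sfreq), freqs = tfr_default_freqs(10, 5, 30))
  expect_equal(t2$power, 4 * t1$power, tolerance = 1e-10)
  t0 <- morlet_tfr(signal_epochs(rep(0, length(tt)), sfreq),
                   freqs = tfr_default_freqs(10, 5, 30))
  expect_true(all(t0$power == 0))
})

test_that("a time shift of the input shifts TF power accordingly", {
  sfreq <- 128
  n <- 3 * sfreq
  set.seed(5)
  base <- rnorm(n + 16)
  x1 <- base[1:n]
  x2 <- base[17:(n + 16)] # x2[t] = x1[t + 16 samples]
  f <- tfr_default_freqs(8, 6, 20)
  p1 <- morlet_tfr(signal_epochs(x1, sfreq), freqs = f)
  p2 <- morlet_tfr(signal_epochs(x2, sfreq), freqs = f)
  interior <- 80:(n - 96) # away from both signals' edges
  expect_equal(p2$power[1, 1, , interior], p1$power[1, 1, , interior + 16],
               tolerance = 1e-6)
})

test_that("decomposition fails on undersampled or too-short epochs", {
  sfreq <- 64
  tt <- (0:(2 * sfreq - 1)) / sfreq
  expect_error(morlet_tfr(signal_epochs(sin(tt), sfreq)), "sampling rate")
  short <- signal_epochs(rnorm(40), 256)
  expect_error(morlet_tfr(short), "shorter")
})

test_that("dB baseline matches closed-form ratios and inverts exactly", {
  sfreq <- 128
  tt <- (0:(2 * sfreq - 1)) / sfreq
  ep <- signal_epochs(sin(2 * pi * 10 * tt), sfreq, n_trials = 3)
  tfr <- morlet_tfr(ep, freqs = tfr_default_freqs(6, 8, 14))
  # overwrite with known power values; baseline window 0.5-0.8 s
  tfr$power[] <- 2
  sel <- tfr$times > 0.9
  tfr$power[, , , sel] <- 20                       # 10 x baseline
  tfr$power[, , 1, sel] <- 1                       # baseline / 2 at bin 1
  db <- db_baseline(tfr, c(0.5, 0.8))
  expect_equal(db$units, "dB")
  expect_true(all(abs(db$power[, , , tfr$times <= 0.8 & tfr$times >= 0.5]) < 1e-12))
  expect_equal(db$power[1, 1, 2, which(sel)[1]], 10, tolerance = 1e-10)
  expect_equal(db$power[1, 1, 1, which(sel)[1]], 10 * log10(0.5), tolerance = 1e-10)
  # exact invertibility: 10^(pwc/10) * bsl == pw
  pw_back <- 10^(db$power / 10) * as.vector(db$baseline)
  expect_equal(pw_back, tfr$power, tolerance = 1e-10)
  # degenerate baseline is refused with location info
  tfr$power[2, 1, 1, tfr$times >= 0.5 & tfr$times <= 0.8] <- 0
  expect_error(db_baseline(tfr, c(0.5, 0.8)), "trial 2")
})

test_that("band and window averaging reduce correctly", {
  sfreq <- 128
  tt <- (0:(2 * sfreq - 1)) / sfreq
  ep <- signal_epochs(sin(2 * pi * 10 * tt), sfreq, n_trials = 2)
  tfr <- morlet_tfr(ep, freqs = tfr_default_freqs(6, 5, 20))
  tfr$power[] <- 3
  db <- db_baseline(tfr, c(0.5, 0.8))
  db$power[] <- 1.5
  topo <- band_time_average(db, band = c(7, 14), window = c(1.0, 1.5))
  expect_equal(dim(topo), c(2, 1))
  expect_true(all(topo == 1.5))
  # single-bin band equals that bin's time average
  one_bin <- db$freqs[3] + c(-0.01, 0.01)
  db$power[1, 1, 3, db$times >= 1.0 & db$times <= 1.5] <- 7
  t_one <- band_time_average(db, band = one_bin, window = c(1.0, 1.5))
  expect_equal(unname(t_one[1, 1]),
               mean(db$power[1, 1, 3, db$times >= 1.0 & db$times <= 1.5]))
  expect_error(band_time_average(db, band = c(100, 110), window = c(1, 1.5)),
               "empty")
})
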