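# The frequency-response oracle evaluates the designed kernel's transfer
# function directly by FFT, independently of the convolution code path.
kernel_gain <- function(f_hz, fs = 250) {
  h <- eegdecode:::fir_kernel(filter_spec(), fs)
  nfft <- 2^15
  H <- abs(fft(c(h, numeric(nfft - length(h)))))
  H[round(f_hz / fs * nfft) + 1]
}

test_that("band-pass meets its passband and stopband specification", {
  expect_gt(kernel_gain(10), 10^(-1 / 20))   # within -1 dB at 10 Hz
  expect_lt(kernel_gain(10), 10^(1 / 20))
  expect_lt(kernel_gain(0.1), 10^(-20 / 20)) # >= 20 dB down at 0.1 Hz
  expect_lt(kernel_gain(60), 10^(-20 / 20))  # >= 20 dB down at 60 Hz
})

test_that("filtering preserves a 10 Hz tone, kills DC and drift, zero phase", {
  n <- 30 * 250
  t <- seq_len(n) / 250
  tone <- sin(2 * pi * 10 * t)
  data <- cbind(tone = tone, dc = rep(1, n), drift = sin(2 * pi * 0.1 * t))
  rec <- eegdecode:::new_recording("S", "GI", colnames(data), 250L, data)
  out <- bandpass(rec)$data
  mid <- 2000:5000 # away from edges
  expect_equal(dim(out), dim(data))
  amp <- max(abs(out[mid, "tone"]))
  expect_lt(abs(amp - 1), 0.12)
  expect_lt(max(abs(out[mid, "dc"])), 0.01)
  expect_lt(max(abs(out[mid, "drift"])), 10^(-20 / 20))
  # zero phase: filtered tone aligned with the input tone
  expect_gt(cor(out[mid, "tone"], tone[mid]), 0.999)
})

test_that("filtering is idempotent up to tolerance", {
  set.seed(3)
  data <- matrix(rnorm(20 * 250 * 2), 20 * 250, 2)
  colnames(data) <- c("A", "B")
  rec <- eegdecode:::new_recording("S", "GI", c("A", "B"), 250L, data)
  once <- bandpass(rec)
  twice <- bandpass(once)
  mid <- 1500:3500
  r1 <- sqrt(mean(once$data[mid, ]^2))
  r2 <- sqrt(mean(twice$data[mid, ]^2))
  expect_lt(abs(r2 - r1) / r1, 0.05)
})

test_that("incompatible filter band errors", {
  rec <- eegdecode:::new_recording("S", "GI", "A", 250L,
                                   matrix(rnorm(250), ncol = 1,
                                          dimnames = list(NULL, "A")))
  expect_error(bandpass(rec, filter_spec(1, 130)), "sampling rate")
})

test_that("detector flags flat and noisy channels and spares clean ones", {
  rec <- fx_smooth_recording(duration_s = 40, seed = 2)
  rec$data[, "E10"] <- 0                          # flat fault
  rec$data[, "E40"] <- rnorm(nrow(rec$data), sd = 100) # high-noise fault
  rep <- detect_bad_channels(rec, fx_montage(), seed = 4)
  expect_true(all(c("E10", "E40") %in% rep$flagged))
  expect_length(rep$flagged, 2)
  expect_true(all(rep$scores >= 0 & rep$scores <= 1))
})

test_that("detector is deterministic given a seed and needs >= 3 channels", {
  rec <- fx_smooth_recording(duration_s = 20, seed = 5)
  r1 <- detect_bad_channels(rec, fx_montage(), seed = 9)
  r2 <- detect_bad_channels(rec, fx_montage(), seed = 9)
  expect_identical(r1$scores, r2$scores)
  small <- eegdecode:::new_recording("S", "GI", c("E1", "E2"), 250L,
                                     matrix(rnorm(1000), 500, 2,
                                            dimnames = list(NULL, c("E1", "E2"))))
  expect_error(detect_bad_channels(small, fx_montage()), "3 channels")
})

test_that("interpolation replaces flagged channels by their neighbourhood", {
  m <- fx_montage()
  rec <- fx_smooth_recording(duration_s = 10, seed = 6)
  truth <- rec$data[, "E99"]
  rec$data[, "E99"] <- 0
  out <- interpolate_bad_channels(rec, "E99", m)
  expect_equal(dim(out$data), dim(rec$data))
  expect_gt(cor(out$data[, "E99"], truth), 0.8)
  expect_true("E99" %in% out$bad_channel_log)
  # no flags -> identity
  expect_identical(interpolate_bad_channels(rec, character(), m)$data,
                   rec$data)
})

test_that("interpolating a channel whose neighbours share one signal copies it", {
  m <- fx_montage()
  s <- sin(2 * pi * 5 * seq_len(2500) / 250)
  data <- matrix(rep(s, 256), 2500, 256)
  colnames(data) <- m$labels
  data[, "E100"] <- 0
  rec <- eegdecode:::new_recording("S", "GI", m$labels, 250L, data)
  out <- interpolate_bad_channels(rec, "E100", m)
  expect_equal(out$data[, "E100"], s, tolerance = 1e-12)
})

test_that("too many flagged channels abort interpolation", {
  m <- fx_montage()
  rec <- fx_smooth_recording(duration_s = 5, seed = 7)
  expect_error(interpolate_bad_channels(rec, m$labels[1:64], m),
               "too corrupted")
})

test_that("cropping keeps exactly the half-open analysis window", {
  m <- fx_montage()
  sp <- subject_spec("S", "GI", seed = 2, duration_s = 1200)
  rec <- simulate_recording(sp, m, channels = cognitive_channels[1:2])
  out <- crop_window(rec)
  expect_equal(nrow(out$data), 120 * 250)
  expect_equal(out$data, rec$data[(600 * 250 + 1):(720 * 250), , drop = FALSE])
  short <- rec
  short$data <- short$data[1:(700 * 250), , drop = FALSE]
  expect_error(crop_window(short), "shorter")
})

test_that("full preprocessing chain repairs an injected fault end to end", {
  m <- fx_montage()
  sub64 <- m$labels[seq(1, 256, by = 4)]
  sp <- subject_spec("W1", "MT", seed = 61, duration_s = 720,
                     bad_channels = c(E53 = "high_noise"))
  rec <- simulate_recording(sp, m, channels = sub64)
  out <- preprocess_recording(rec, m, detect = TRUE, max_windows = 6, seed = 3)
  expect_equal(nrow(out$data), 120 * 250)
  expect_equal(ncol(out$data), 64)
  expect_true("E53" %in% out$bad_channel_log)
  # the repaired channel now resembles its neighbourhood, not white noise
  clean <- simulate_recording(subject_spec("W1", "MT", seed = 61,
                                           duration_s = 720), m,
                              channels = sub64)
  clean <- crop_window(bandpass(clean))
  expect_gt(cor(out$data[, "E53"], clean$data[, "E53"]), 0.5)
})
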