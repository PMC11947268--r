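#' Band-pass filter specification
#'
#' Zero-phase FIR band-pass used before epoching. The default 1-45 Hz band
#' keeps delta (above 1 Hz) through low gamma and removes drift and line
#' noise. The kernel is a Hamming-windowed linear-phase FIR; zero phase is
#' obtained by forward convolution with the group delay compensated exactly
#' (the delay of a linear-phase kernel is (n_taps-1)/2 samples).
#'
#' @param low_hz,high_hz Band edges in Hz.
#' @param n_taps Odd kernel length. The default 1251 at 250 Hz gives a
#'   transition band of about 0.66 Hz, so 0.1 Hz drift falls deep in the
#'   stopband while 1-45 Hz is flat to within the window ripple.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low_hz = 1, high_hz = 45, n_taps = 1251) {
  stopifnot(low_hz > 0, high_hz > low_hz, n_taps %% 2 == 1)
  structure(list(low_hz = low_hz, high_hz = high_hz, n_taps = n_taps),
            class = "filter_spec")
}

# The FIR kernel for a given sampling rate.
fir_kernel <- function(spec, fs) {
  if (spec$high_hz >= fs / 2) {
    stop("filter band [", spec$low_hz, ", ", spec$high_hz,
         "] Hz incompatible with sampling rate ", fs, " Hz")
  }
  as.numeric(signal::fir1(spec$n_taps - 1,
                          c(spec$low_hz, spec$high_hz) / (fs / 2),
                          type = "pass"))
}

#' Zero-phase band-pass filter a recording
#'
#' Applies the [filter_spec()] kernel by FFT convolution, compensating the
#' linear-phase delay so the output has no group delay. Shape is preserved.
#'
#' @param recording An `eeg_recording`.
#' @param spec A [filter_spec()].
#' @return The filtered `eeg_recording`.
#' @export
bandpass <- function(recording, spec = filter_spec()) {
  fs <- recording$sampling_rate
  h <- fir_kernel(spec, fs)
  d <- (length(h) - 1) / 2
  n <- nrow(recording$data)
  nfft <- stats::nextn(n + length(h) - 1, c(2, 3, 5))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  out <- recording$data
  idx <- (d + 1):(d + n)
  # channel blocks keep the complex work arrays modest for 256-channel data
  blocks <- split(seq_len(ncol(out)), ceiling(seq_len(ncol(out)) / 32))
  for (b in blocks) {
    X <- stats::mvfft(rbind(recording$data[, b, drop = FALSE],
                            matrix(0, nfft - n, length(b))))
    Y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
    out[, b] <- Y[idx, , drop = FALSE]
  }
  recording$data <- out
  recording
}

#' Detect bad channels by spatial-consensus (RANSAC-style) prediction
#'
#' Each channel is repeatedly predicted by inverse-distance-weighted
#' interpolation from its 4 nearest neighbours within a random subset of the
#' other channels; the median predicted signal over `n_resamples` draws is
#' correlated with the actual signal in non-overlapping windows. A channel is
#' flagged when its correlation falls below `corr_threshold` in more than
#' `bad_fraction_threshold` of the windows. Flat channels (zero variance)
#' receive correlation 0 and are flagged. Deterministic given `seed`.
#'
#' Correlations are computed on a 2x-decimated sample grid within each
#' window; at 250 Hz this leaves >600 points per 5-s window and does not
#' change the statistic materially.
#'
#' @param recording A (filtered) `eeg_recording`.
#' @param montage The montage covering all channels.
#' @param n_resamples Random channel subsets drawn per window.
#' @param subset_fraction Fraction of channels in each predictor subset.
#' @param corr_threshold Correlation below which a window "fails".
#' @param bad_fraction_threshold Fraction of failed windows that flags a
#'   channel.
#' @param window_s Window length in seconds.
#' @param edge_s Seconds excluded at both ends (filter edge effects).
#' @param max_windows Cap on the number of windows examined; when the
#'   recording holds more, an evenly spaced subset is used (long recordings
#'   carry far more windows than the statistic needs).
#' @param seed Integer seed for the subset draws.
#' @return A `bad_channel_report`: list with `flagged` (labels), `scores`
#'   (named fraction of failed windows per channel) and `params`.
#' @export
detect_bad_channels <- function(recording, montage,
                                n_resamples = 50, subset_fraction = 0.25,
                                corr_threshold = 0.75,
                                bad_fraction_threshold = 0.4,
                                window_s = 5, edge_s = 2, max_windows = Inf,
                                seed = 1) {
  data <- recording$data
  labels <- recording$channel_labels
  m <- length(labels)
  if (m < 3) stop("bad-channel detection needs at least 3 channels")
  fs <- recording$sampling_rate
  wlen <- as.integer(window_s * fs)
  lo <- as.integer(edge_s * fs)
  hi <- nrow(data) - lo
  starts <- seq(lo + 1L, hi - wlen + 1L, by = wlen)
  if (!length(starts)) stop("recording too short for one detection window")
  if (length(starts) > max_windows) {
    starts <- starts[round(seq(1, length(starts), length.out = max_windows))]
  }

  ang <- montage_distances(montage, labels)
  diag(ang) <- Inf
  nsub <- max(5L, round(subset_fraction * m))

  # Per resample: 4-nearest-neighbour IDW predictor for every channel,
  # restricted to the drawn subset (excluding the channel itself).
  draws <- with_seed(seed, lapply(seq_len(n_resamples), function(r) {
    sub <- sample.int(m, nsub)
    nbr <- matrix(0L, m, 4)
    wgt <- matrix(0, m, 4)
    for (c in seq_len(m)) {
      cand <- setdiff(sub, c)
      k <- cand[order(ang[c, cand])[1:4]]
      w <- 1 / pmax(ang[c, k], 1e-6)
      nbr[c, ] <- k
      wgt[c, ] <- w / sum(w)
    }
    list(nbr = nbr, wgt = wgt)
  }))

  dec <- seq(1L, wlen, by = 2L)
  fails <- matrix(0L, length(starts), m)
  for (wi in seq_along(starts)) {
    D <- data[starts[wi] + dec - 1L, , drop = FALSE]
    N <- nrow(D)
    preds <- array(0, c(N, m, n_resamples))
    for (r in seq_len(n_resamples)) {
      dr <- draws[[r]]
      P <- matrix(0, N, m)
      for (j in 1:4) {
        P <- P + D[, dr$nbr[, j], drop = FALSE] *
          rep(dr$wgt[, j], each = N)
      }
      preds[, , r] <- P
    }
    med <- row_medians(matrix(preds, N * m, n_resamples))
    med <- matrix(med, N, m)
    cc <- suppressWarnings(col_cors(D, med))
    cc[!is.finite(cc)] <- 0
    fails[wi, ] <- as.integer(cc < corr_threshold)
  }
  scores <- colMeans(fails)
  names(scores) <- labels
  structure(
    list(flagged = labels[scores > bad_fraction_threshold],
         scores = scores,
         params = list(n_resamples = n_resamples,
                       subset_fraction = subset_fraction,
                       corr_threshold = corr_threshold,
                       bad_fraction_threshold = bad_fraction_threshold,
                       window_s = window_s, edge_s = edge_s, seed = seed)),
    class = "bad_channel_report"
  )
}

# Row-wise medians of an N x R matrix, vectorised via a single order().
row_medians <- function(M) {
  N <- nrow(M); R <- ncol(M)
  o <- order(rep(seq_len(N), times = R), c(M))
  sv <- c(M)[o]
  base <- (seq_len(N) - 1L) * R
  if (R %% 2L == 0L) {
    (sv[base + R %/% 2L] + sv[base + R %/% 2L + 1L]) / 2
  } else {
    sv[base + (R + 1L) %/% 2L]
  }
}

# Column-wise Pearson correlation between matching columns of two matrices.
col_cors <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  colSums(A * B) / sqrt(colSums(A^2) * colSums(B^2))
}

#' Interpolate flagged channels
#'
#' Replaces each flagged channel by the inverse-distance-weighted average of
#' its 4 nearest good channels, preserving shape. Fails if a quarter or more
#' of all channels are flagged.
#'
#' @param recording An `eeg_recording`.
#' @param report A `bad_channel_report` (or character vector of labels).
#' @param montage The montage.
#' @return The repaired `eeg_recording` with `bad_channel_log` updated.
#' @export
interpolate_bad_channels <- function(recording, report, montage) {
  flagged <- if (inherits(report, "bad_channel_report")) report$flagged else report
  if (!length(flagged)) return(recording)
  labels <- recording$channel_labels
  if (length(flagged) >= 0.25 * length(labels)) {
    stop("recording too corrupted: ", length(flagged), " of ",
         length(labels), " channels flagged")
  }
  ang <- montage_distances(montage, labels)
  diag(ang) <- Inf
  good <- setdiff(seq_along(labels), match(flagged, labels))
  for (lab in flagged) {
    c <- match(lab, labels)
    k <- good[order(ang[c, good])[1:4]]
    w <- 1 / pmax(ang[c, k], 1e-6)
    w <- w / sum(w)
    recording$data[, c] <- recording$data[, k, drop = FALSE] %*% w
  }
  recording$bad_channel_log <- union(recording$bad_channel_log, flagged)
  recording
}

#' Crop a recording to the analysis window
#'
#' Keeps the half-open interval `[start_s, end_s)`; the default 600-720 s
#' window (minutes 10-12) yields the 120 s per subject that enter epoching.
#'
#' @param recording An `eeg_recording`.
#' @param start_s,end_s Window bounds in seconds.
#' @return The cropped `eeg_recording`.
#' @export
crop_window <- function(recording, start_s = 600, end_s = 720) {
  fs <- recording$sampling_rate
  if (nrow(recording$data) < end_s * fs) {
    stop("recording shorter than end_s = ", end_s, " s")
  }
  idx <- (start_s * fs + 1L):(end_s * fs)
  recording$data <- recording$data[idx, , drop = FALSE]
  recording
}

#' Standard preprocessing chain
#'
#' Filter, detect bad channels, interpolate them, crop: the step order of the
#' preparation pipeline. Detection runs on the filtered full-length signal;
#' injected (generator-declared) bad channels are merged into the detector's
#' flags before interpolation.
#'
#' @param recording Raw `eeg_recording`.
#' @param montage Montage.
#' @param fspec [filter_spec()].
#' @param detect Run the (relatively expensive) detector (default TRUE).
#' @param ... Passed to [detect_bad_channels()].
#' @return Preprocessed, cropped `eeg_recording`.
#' @export
preprocess_recording <- function(recording, montage, fspec = filter_spec(),
                                 detect = TRUE, ...) {
  rec <- bandpass(recording, fspec)
  if (detect) {
    rep <- detect_bad_channels(rec, montage, ...)
    flags <- union(rep$flagged, recording$bad_channel_log)
    rec <- interpolate_bad_channels(rec, flags, montage)
  }
  crop_window(rec)
}
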