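#' Specification of one synthetic subject
#'
#' Bundles everything that determines a subject's simulated recording:
#' identity, condition, seed, duration, and the class-contrast gains applied
#' to the band-limited rhythm generators. Gains are dimensionless multipliers
#' on rhythm amplitude: `alpha_gain` boosts the posterior 8-12 Hz rhythm in
#' the relaxation (GI) condition, `theta_gain` (4-7 Hz) and `beta_gain`
#' (13-30 Hz) boost fronto-parietal rhythms in the workload (MT) condition.
#' With all gains equal to 1 the two conditions are exchangeable in
#' distribution (the null cohort).
#'
#' @param subject_id Character subject identifier.
#' @param condition `"GI"` (guided imagery / relaxation) or `"MT"`
#'   (mental task / workload).
#' @param seed Integer seed; identical specs give bit-identical recordings.
#' @param duration_s Recording length in seconds; at least 720 so the
#'   600-720 s analysis window exists. Default 1200 (20 min).
#' @param alpha_gain,theta_gain,beta_gain Positive class-contrast multipliers.
#'   Defaults (1.6, 1.5, 1.4) define the standard synthetic study conditions.
#' @param noise_scale Background 1/f noise scale in microvolts RMS.
#' @param bad_channels Named character vector mapping channel label to fault
#'   model, e.g. `c(E12 = "flat", E40 = "high_noise")`.
#' @param artifact_rate Blink-like artifact events per minute (default 0).
#' @return A `subject_spec` object.
#' @export
subject_spec <- function(subject_id, condition = c("GI", "MT"), seed,
                         duration_s = 1200,
                         alpha_gain = 1.6, theta_gain = 1.5, beta_gain = 1.4,
                         noise_scale = 10,
                         bad_channels = character(), artifact_rate = 0) {
  condition <- match.arg(condition)
  stop_field(is.character(subject_id) && length(subject_id) == 1L,
             "subject_id", "must be a single string")
  stop_field(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
             "seed", "must be a single integer")
  stop_field(is.numeric(duration_s) && duration_s >= 720,
             "duration_s", "must be >= 720 s so the 600-720 s crop exists")
  for (g in c("alpha_gain", "theta_gain", "beta_gain")) {
    v <- get(g)
    stop_field(is.numeric(v) && length(v) == 1L && v > 0, g, "must be > 0")
  }
  stop_field(is.numeric(noise_scale) && noise_scale > 0,
             "noise_scale", "must be > 0")
  stop_field(is.numeric(artifact_rate) && artifact_rate >= 0,
             "artifact_rate", "must be >= 0")
  if (length(bad_channels)) {
    stop_field(!is.null(names(bad_channels)) &&
                 all(bad_channels %in% c("flat", "high_noise")),
               "bad_channels",
               "must be a named vector with values 'flat' or 'high_noise'")
  }
  structure(
    list(subject_id = subject_id, condition = condition,
         seed = as.integer(seed), duration_s = duration_s,
         alpha_gain = alpha_gain, theta_gain = theta_gain,
         beta_gain = beta_gain, noise_scale = noise_scale,
         bad_channels = bad_channels, artifact_rate = artifact_rate),
    class = "subject_spec"
  )
}

# 1/f^gamma noise via FFT shaping of white noise, unit RMS.
pink_noise <- function(n, gamma = 1) {
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  freq <- c(1, seq_len(n - 1))
  freq <- pmin(freq, n - freq + 1) # symmetric magnitude profile
  f <- f / freq^(gamma / 2)
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Narrow-band stochastic oscillator: white noise through an AR(2) resonator
# at frequency f_hz with pole radius set by the bandwidth. Unit RMS.
band_source <- function(n, f_hz, fs = 250, bw_hz = 1.5) {
  r <- exp(-pi * bw_hz / fs)
  a <- c(2 * r * cos(2 * pi * f_hz / fs), -r^2)
  burn <- 500L
  e <- stats::rnorm(n + burn)
  x <- stats::filter(e, a, method = "recursive")
  x <- as.numeric(x)[(burn + 1):(burn + n)]
  x / stats::sd(x)
}

#' Simulate one synthetic EEG recording
#'
#' Generates a multichannel recording as a sum of (i) spatially smooth 1/f
#' ("pink") background sources, (ii) per-channel independent 1/f sensor noise,
#' and (iii) band-limited rhythms (alpha 8-12 Hz, theta 4-7 Hz, beta
#' 13-30 Hz), each a small set of stochastic narrow-band oscillators projected
#' through Gaussian scalp topographies. The alpha topography is centred on the
#' posterior (cognitive-electrode) cap; theta and beta topographies are
#' fronto-parietal. Condition gains from the [subject_spec()] scale the
#' rhythms, so relaxation recordings carry elevated posterior alpha power and
#' workload recordings carry broader fronto-parietal theta/beta power.
#' Declared bad channels are overwritten by their fault model after signal
#' synthesis. Amplitudes are in microvolts.
#'
#' Per-channel noise is seeded per channel label, so simulating a channel
#' subset yields the same samples those channels get in a full-montage
#' simulation.
#'
#' @param spec A [subject_spec()].
#' @param montage An [build_montage()] montage.
#' @param channels Optional character vector of channel labels to generate
#'   (default: the full montage).
#' @return An `eeg_recording`: list with `subject_id`, `condition`,
#'   `channel_labels`, `sampling_rate`, `data` (time x channel matrix, uV) and
#'   `bad_channel_log`.
#' @export
simulate_recording <- function(spec, montage, channels = NULL) {
  stopifnot(inherits(spec, "subject_spec"), inherits(montage, "eeg_montage"))
  channels <- channels %||% montage$labels
  miss <- setdiff(channels, montage$labels)
  if (length(miss)) {
    stop("channels not in montage: ", paste(miss, collapse = ", "))
  }
  fs <- 250L
  n <- as.integer(round(spec$duration_s * fs))
  nch <- length(channels)

  gains <- list(alpha = 1, theta = 1, beta = 1)
  if (spec$condition == "GI") gains$alpha <- spec$alpha_gain
  if (spec$condition == "MT") {
    gains$theta <- spec$theta_gain
    gains$beta <- spec$beta_gain
  }

  posterior <- c(0, -0.80, -0.35)
  frontal <- c(0, 0.90, 0.35)
  parietal <- c(0, -0.15, 0.99)

  src <- with_seed(spec$seed, {
    n_bg <- 10L
    bg_centers <- matrix(stats::rnorm(3 * n_bg), n_bg, 3)
    bg_centers <- bg_centers / sqrt(rowSums(bg_centers^2))
    bands <- list(
      alpha = list(k = 4L, lo = 8, hi = 12, amp = 6 * gains$alpha,
                   centers = matrix(posterior, 1), width = 0.55),
      theta = list(k = 3L, lo = 4, hi = 7, amp = 5 * gains$theta,
                   centers = matrix(frontal, 1), width = 0.65),
      beta  = list(k = 4L, lo = 13, hi = 30, amp = 4 * gains$beta,
                   centers = rbind(frontal, parietal), width = 0.65)
    )
    plan <- list(bg_centers = bg_centers, bands = lapply(bands, function(b) {
      b$freqs <- stats::runif(b$k, b$lo, b$hi)
      b$jitter <- exp(stats::rnorm(1, 0, 0.15)) * exp(stats::rnorm(b$k, 0, 0.10))
      b$which_center <- rep_len(seq_len(nrow(b$centers)), b$k)
      b
    }))
    plan$src_seeds <- derive_seed(spec$seed, 1:(n_bg + sum(vapply(plan$bands, `[[`, 1L, "k"))))
    plan$artifacts <- if (spec$artifact_rate > 0) {
      n_ev <- stats::rpois(1, spec$artifact_rate * spec$duration_s / 60)
      list(t0 = sort(stats::runif(n_ev, 1, spec$duration_s - 1)),
           amp = stats::runif(n_ev, 60, 140))
    }
    plan
  })

  # Source time courses (seeded independently of the channel subset).
  n_bg <- nrow(src$bg_centers)
  ks <- vapply(src$bands, `[[`, 1L, "k")
  S <- matrix(0, n, n_bg + sum(ks))
  amp <- numeric(ncol(S))
  P <- matrix(0, ncol(S), nch)
  si <- 0L
  for (j in seq_len(n_bg)) {
    si <- si + 1L
    S[, si] <- with_seed(src$src_seeds[si], pink_noise(n))
    amp[si] <- spec$noise_scale * 0.9 / sqrt(n_bg)
    P[si, ] <- scalp_topography(montage, src$bg_centers[j, ], width = 1.1,
                                floor = 0.15, labels = channels)
  }
  for (b in src$bands) {
    for (j in seq_len(b$k)) {
      si <- si + 1L
      S[, si] <- with_seed(src$src_seeds[si], band_source(n, b$freqs[j]))
      amp[si] <- b$amp * b$jitter[j] / sqrt(b$k)
      P[si, ] <- scalp_topography(montage, b$centers[b$which_center[j], ],
                                  width = b$width, labels = channels)
    }
  }
  data <- S %*% (P * amp)

  # Independent per-channel 1/f sensor noise, seeded per channel label.
  ch_idx <- match(channels, montage$labels)
  for (c in seq_len(nch)) {
    data[, c] <- data[, c] + spec$noise_scale * 0.3 *
      with_seed(derive_seed(spec$seed, 100000L + ch_idx[c]), pink_noise(n))
  }

  # Blink-like artifacts weighted toward face channels.
  if (!is.null(src$artifacts) && length(src$artifacts$t0)) {
    facew <- scalp_topography(montage, c(0, 0.95, -0.30), width = 0.45,
                              labels = channels)
    tt <- seq_len(n) / fs
    for (e in seq_along(src$artifacts$t0)) {
      t0 <- src$artifacts$t0[e]
      win <- which(abs(tt - t0) < 0.6)
      bump <- exp(-((tt[win] - t0)^2) / (2 * 0.12^2)) * src$artifacts$amp[e]
      data[win, ] <- data[win, ] + outer(bump, facew)
    }
  }

  log <- character()
  if (length(spec$bad_channels)) {
    for (lab in names(spec$bad_channels)) {
      c <- match(lab, channels)
      if (is.na(c)) next
      fault <- spec$bad_channels[[lab]]
      if (fault == "flat") {
        data[, c] <- 0
      } else {
        data[, c] <- with_seed(derive_seed(spec$seed, 200000L + ch_idx[c]),
                               stats::rnorm(n, sd = 100))
      }
      log <- c(log, lab)
    }
  }

  colnames(data) <- channels
  new_recording(spec$subject_id, spec$condition, channels, fs, data, log)
}

new_recording <- function(subject_id, condition, channel_labels, fs, data,
                          bad_channel_log = character()) {
  stopifnot(!anyNA(data), all(is.finite(data)))
  structure(
    list(subject_id = subject_id, condition = condition,
         channel_labels = channel_labels, sampling_rate = fs,
         data = data, bad_channel_log = bad_channel_log),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s] %d ch x %.1f s @ %d Hz\n",
              x$subject_id, x$condition, ncol(x$data),
              nrow(x$data) / x$sampling_rate, x$sampling_rate))
  if (length(x$bad_channel_log)) {
    cat("  bad channels:", paste(x$bad_channel_log, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate a labelled two-condition cohort
#'
#' Generates `n_subjects` recordings, the first `balance[1]` in the GI
#' (relaxation) condition and the remaining `balance[2]` in the MT (workload)
#' condition, with per-subject seeds derived deterministically from
#' `base_seed`. All [subject_spec()] gain/noise arguments can be overridden
#' through `...`.
#'
#' A full-montage 20-minute recording occupies ~600 MB; pass `channels` or a
#' shorter `duration_s` when simulating whole cohorts in memory, or consume
#' subjects one at a time via [run_pipeline()].
#'
#' @param n_subjects Number of subjects (default 26).
#' @param balance Integer pair: subjects per condition (GI, MT); must sum to
#'   `n_subjects`.
#' @param base_seed Integer master seed.
#' @param montage Montage (default [build_montage()]).
#' @param channels Optional channel subset passed to [simulate_recording()].
#' @param ... Further arguments to [subject_spec()].
#' @return List of `eeg_recording` objects.
#' @export
simulate_cohort <- function(n_subjects = 26, balance = c(13, 13), base_seed = 1,
                            montage = build_montage(), channels = NULL, ...) {
  if (sum(balance) != n_subjects) {
    stop("`balance` must sum to `n_subjects` (got ",
         paste(balance, collapse = "+"), " != ", n_subjects, ")")
  }
  conditions <- rep(c("GI", "MT"), times = balance)
  lapply(seq_len(n_subjects), function(i) {
    sp <- subject_spec(subject_id = sprintf("S%02d", i),
                       condition = conditions[i],
                       seed = derive_seed(base_seed, i), ...)
    simulate_recording(sp, montage, channels = channels)
  })
}

#' Cohort manifest
#'
#' Summarises a cohort as a data frame (subject, condition, duration,
#' channels); written as JSON by [run_pipeline()].
#'
#' @param cohort List of `eeg_recording` objects.
#' @return A data.frame.
#' @export
cohort_manifest <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    condition = vapply(cohort, `[[`, "", "condition"),
    duration_s = vapply(cohort, function(r) nrow(r$data) / r$sampling_rate, 0),
    n_channels = vapply(cohort, function(r) ncol(r$data), 0L)
  )
}
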