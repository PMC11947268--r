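# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fx_montage <- function() {
  if (is.null(.fixtures$montage)) .fixtures$montage <- build_montage()
  .fixtures$montage
}

# Strong-contrast 26-subject cohort at COGN-26 scale (already cropped to the
# 600-720 s analysis window and epoched). Used by the dataset-arithmetic and
# separability suites.
fx_strong_epochs <- function() {
  if (is.null(.fixtures$strong)) {
    cohort <- simulate_cohort(26, c(13, 13), base_seed = 11,
                              montage = fx_montage(),
                              channels = cognitive_channels,
                              duration_s = 720, alpha_gain = 3)
    cohort <- lapply(cohort, crop_window)
    .fixtures$strong <- bind_epoch_sets(lapply(cohort, segment_epochs))
  }
  .fixtures$strong
}

# Small epoch set with an easy linear class difference, for fast model tests.
fx_toy_epochs <- function(n = 60, C = 6, T = 250, seed = 99, sep = 1.5) {
  set.seed(seed)
  lab <- rep(c(0L, 1L), length.out = n)
  eps <- array(rnorm(n * C * T), c(n, C, T))
  tone <- sin(2 * pi * 10 * seq_len(T) / 250)
  for (i in which(lab == 1L)) {
    eps[i, 1:3, ] <- eps[i, 1:3, ] + rep(sep * tone, each = 3)
  }
  eegdecode:::new_epoch_set(eps, lab,
                            rep(sprintf("T%02d", 1:6), length.out = n),
                            paste0("E", seq_len(C)))
}

# Cheap smooth-field multichannel recording (not via the cohort generator):
# a few spatially smooth random sources plus small independent noise. Used
# by the bad-channel detector unit tests.
fx_smooth_recording <- function(duration_s = 40, seed = 1,
                                montage = fx_montage()) {
  set.seed(seed)
  n <- duration_s * 250
  nsrc <- 12
  S <- matrix(rnorm(n * nsrc), n, nsrc)
  S <- apply(S, 2, function(s) stats::filter(s, rep(1 / 8, 8),
                                             sides = 1) |> as.numeric())
  S[is.na(S)] <- 0
  centers <- matrix(rnorm(3 * nsrc), nsrc, 3)
  centers <- centers / sqrt(rowSums(centers^2))
  P <- t(sapply(seq_len(nsrc), function(j) {
    eegdecode:::scalp_topography(montage, centers[j, ], width = 1.2)
  }))
  data <- S %*% P * 8 + matrix(rnorm(n * 256), n, 256) * 1.5
  colnames(data) <- montage$labels
  eegdecode:::new_recording("SM", "GI", montage$labels, 250L, data)
}
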