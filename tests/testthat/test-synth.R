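test_that("recording has the declared geometry and is finite", {
  m <- fx_montage()
  sp <- subject_spec("S1", "GI", seed = 4, duration_s = 720)
  rec <- simulate_recording(sp, m, channels = cognitive_channels[1:8])
  expect_equal(nrow(rec$data), 720 * 250)
  expect_equal(ncol(rec$data), 8)
  expect_true(all(is.finite(rec$data)))
  expect_equal(rec$sampling_rate, 250)
})

test_that("identical specs give bit-identical recordings", {
  m <- fx_montage()
  sp <- subject_spec("S1", "MT", seed = 12, duration_s = 720)
  r1 <- simulate_recording(sp, m, channels = cognitive_channels)
  r2 <- simulate_recording(sp, m, channels = cognitive_channels)
  expect_identical(r1$data, r2$data)
})

test_that("invalid specs fail naming the offending field", {
  expect_error(subject_spec("S", "GI", seed = 1, duration_s = 100),
               "duration_s")
  expect_error(subject_spec("S", "GI", seed = 1, alpha_gain = -1),
               "alpha_gain")
  expect_error(subject_spec("S", "GI", seed = 1, artifact_rate = -2),
               "artifact_rate")
  expect_error(subject_spec("S", "XX", seed = 1))
})

test_that("GI carries more posterior alpha relative power than MT (periodogram oracle)", {
  m <- fx_montage()
  rel_alpha <- function(rec) {
    d <- rec$data[1:15000, ] # 60 s
    mean(vapply(seq_len(ncol(d)), function(c) {
      sp <- stats::spec.pgram(d[, c], plot = FALSE, taper = 0)
      f <- sp$freq * 250
      sum(sp$spec[f >= 8 & f < 13]) / sum(sp$spec[f >= 1 & f < 45])
    }, 0))
  }
  gi <- simulate_recording(subject_spec("g", "GI", seed = 21, duration_s = 720),
                           m, channels = cognitive_channels)
  mt <- simulate_recording(subject_spec("t", "MT", seed = 22, duration_s = 720),
                           m, channels = cognitive_channels)
  expect_gt(rel_alpha(gi), rel_alpha(mt))
})

test_that("null mode makes conditions exchangeable in distribution", {
  m <- fx_montage()
  # same seed, equal gains: the two conditions generate identical data
  gi <- simulate_recording(subject_spec("x", "GI", seed = 7, duration_s = 720,
                                        alpha_gain = 1, theta_gain = 1,
                                        beta_gain = 1),
                           m, channels = cognitive_channels[1:4])
  mt <- simulate_recording(subject_spec("x", "MT", seed = 7, duration_s = 720,
                                        alpha_gain = 1, theta_gain = 1,
                                        beta_gain = 1),
                           m, channels = cognitive_channels[1:4])
  expect_identical(gi$data, mt$data)
})

test_that("declared bad channels are overwritten by their fault model", {
  m <- fx_montage()
  sp <- subject_spec("S1", "GI", seed = 5, duration_s = 720,
                     bad_channels = c(E98 = "flat", E100 = "high_noise"))
  rec <- simulate_recording(sp, m, channels = cognitive_channels[1:6])
  expect_true(all(rec$data[, "E98"] == 0))
  expect_gt(sd(rec$data[, "E100"]), 50) # white noise sd 100
  expect_setequal(rec$bad_channel_log, c("E98", "E100"))
})

test_that("cohort respects balance, distinct ids and seed determinism", {
  m <- fx_montage()
  co <- simulate_cohort(4, c(2, 2), base_seed = 3, montage = m,
                        channels = cognitive_channels[1:4], duration_s = 720)
  expect_length(co, 4)
  conds <- vapply(co, `[[`, "", "condition")
  expect_equal(sum(conds == "GI"), 2)
  expect_equal(sum(conds == "MT"), 2)
  ids <- vapply(co, `[[`, "", "subject_id")
  expect_false(anyDuplicated(ids) > 0)
  co2 <- simulate_cohort(4, c(2, 2), base_seed = 3, montage = m,
                         channels = cognitive_channels[1:4], duration_s = 720)
  expect_identical(lapply(co, `[[`, "data"), lapply(co2, `[[`, "data"))
  expect_error(simulate_cohort(4, c(3, 2), base_seed = 1, montage = m),
               "balance")
})

test_that("channel-subset simulation matches the full-montage projection", {
  m <- fx_montage()
  sp <- subject_spec("S1", "GI", seed = 31, duration_s = 720)
  sub <- simulate_recording(sp, m, channels = cognitive_channels[1:3])
  full <- simulate_recording(sp, m, channels = c(cognitive_channels[1:3],
                                                 "E1", "E2"))
  expect_equal(sub$data, full$data[, 1:3], tolerance = 1e-12)
})

test_that("cohort manifest summarizes subjects and conditions", {
  m <- fx_montage()
  co <- simulate_cohort(2, c(1, 1), base_seed = 9, montage = m,
                        channels = cognitive_channels[1:2], duration_s = 720)
  mf <- cohort_manifest(co)
  expect_equal(nrow(mf), 2)
  expect_setequal(mf$condition, c("GI", "MT"))
  expect_true(all(mf$duration_s == 720))
  expect_true(all(mf$n_channels == 2))
})
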