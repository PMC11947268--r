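make_rec <- function(id = "S1", cond = "GI", secs = 4, nch = 3, seed = 1) {
  set.seed(seed)
  data <- matrix(rnorm(secs * 250 * nch), secs * 250, nch)
  labs <- paste0("E", seq_len(nch))
  colnames(data) <- labs
  eegdecode:::new_recording(id, cond, labs, 250L, data)
}

test_that("segmentation yields non-overlapping 1-s epochs that reassemble exactly", {
  rec <- make_rec(secs = 6)
  es <- segment_epochs(rec)
  expect_equal(dim(es$epochs), c(6, 3, 250))
  expect_equal(es$labels, rep(0L, 6))
  expect_equal(es$subject_ids, rep("S1", 6))
  # epoch i covers samples [i*250, (i+1)*250)
  expect_equal(t(es$epochs[2, , ]), unname(rec$data[251:500, ]))
  # reassembly reproduces the signal exactly
  rebuilt <- do.call(rbind, lapply(seq_len(6), function(i) t(es$epochs[i, , ])))
  expect_identical(rebuilt, unname(rec$data))
})

test_that("MT recordings are labelled 1 and ragged durations error", {
  es <- segment_epochs(make_rec(cond = "MT"))
  expect_true(all(es$labels == 1L))
  rec <- make_rec()
  rec$data <- rec$data[1:625, , drop = FALSE]
  expect_error(segment_epochs(rec), "multiple")
})

test_that("channel selection: COGN-26 order, identity, idempotence, errors", {
  m <- fx_montage()
  set.seed(2)
  n <- 4
  eps <- array(rnorm(n * 256 * 250), c(n, 256, 250))
  es <- eegdecode:::new_epoch_set(eps, rep(0:1, 2), rep("a", n), m$labels)
  cog <- select_channels(es, "COGN-26")
  expect_equal(dim(cog$epochs)[2], 26)
  expect_identical(cog$channel_labels, cognitive_channels)
  expect_identical(select_channels(es, "FULL-256"), es)
  expect_identical(select_channels(cog, "COGN-26"), cog)
  expect_equal(cog$epochs[, 1, ], eps[, match("E98", m$labels), ])
  es2 <- es
  es2$channel_labels[match("E98", es2$channel_labels)] <- "Zz"
  expect_error(select_channels(es2, "COGN-26"), "E98")
})

test_that("standardization uses training statistics only", {
  set.seed(5)
  tr <- eegdecode:::new_epoch_set(array(rnorm(20 * 3 * 250, 5, 2), c(20, 3, 250)),
                                  rep(0:1, 10), rep("a", 20), c("E1", "E2", "E3"))
  te <- eegdecode:::new_epoch_set(array(rnorm(8 * 3 * 250, -1, 4), c(8, 3, 250)),
                                  rep(0:1, 4), rep("b", 8), c("E1", "E2", "E3"))
  st <- standardize_epochs(tr, list(te))
  for (c in 1:3) {
    expect_lt(abs(mean(st$train$epochs[, c, ])), 1e-6)
    expect_equal(sd(st$train$epochs[, c, ]), 1, tolerance = 1e-3)
  }
  # test set transformed with train stats, so its mean is NOT zero
  expect_gt(max(abs(apply(st$others[[1]]$epochs, 2, mean))), 0.5)
  # re-standardizing the transformed test set with ITS own stats changes it
  st2 <- standardize_epochs(st$others[[1]])
  expect_false(isTRUE(all.equal(st2$train$epochs, st$others[[1]]$epochs)))
})

test_that("zero-variance channels are clamped with a warning", {
  eps <- array(rnorm(4 * 2 * 250), c(4, 2, 250))
  eps[, 2, ] <- 7
  es <- eegdecode:::new_epoch_set(eps, rep(0:1, 2), rep("a", 4), c("E1", "E2"))
  expect_warning(st <- standardize_epochs(es), "clamped")
  expect_true(all(is.finite(st$train$epochs)))
})

test_that("grouped stratified folds partition 26 subjects into balanced test groups", {
  ids <- sprintf("S%02d", 1:26)
  labs <- rep(c(0L, 1L), each = 13)
  plan <- make_grouped_stratified_folds(ids, labs, k = 6, seed = 2)
  expect_length(plan$folds, 6)
  test_sets <- lapply(plan$folds, `[[`, "test")
  sizes <- lengths(test_sets)
  expect_true(all(sizes %in% c(4, 5)))
  expect_setequal(unlist(test_sets), ids)
  expect_equal(sum(sizes), 26) # each subject tested exactly once
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids)
    cls <- labs[match(f$test, ids)]
    # class counts within one of proportional (13/6): 2 or 3 per class
    expect_true(all(table(factor(cls, levels = 0:1)) %in% 2:3))
  }
})

test_that("fold plans are reproducible and validate their inputs", {
  ids <- sprintf("S%02d", 1:10)
  labs <- rep(0:1, 5)
  p1 <- make_grouped_stratified_folds(ids, labs, k = 5, seed = 42)
  p2 <- make_grouped_stratified_folds(ids, labs, k = 5, seed = 42)
  expect_identical(p1$folds, p2$folds)
  expect_error(make_grouped_stratified_folds(ids, labs, k = 11), "exceeds")
  expect_error(make_grouped_stratified_folds(ids, rep(0L, 10), k = 2),
               "both classes")
})

test_that("LOSO builds one single-subject test fold per subject", {
  ids <- sprintf("S%02d", 1:26)
  plan <- make_loso_folds(ids)
  expect_length(plan$folds, 26)
  expect_identical(vapply(plan$folds, `[[`, "", "test"), ids)
  for (f in plan$folds) {
    expect_length(f$train, 25)
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_error(make_loso_folds("S1"), "at least 2")
})

test_that("fold plan serializes to JSON", {
  plan <- make_loso_folds(c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".json")
  write_fold_plan(plan, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$scheme, "loso")
  expect_length(back$folds, 3)
})

test_that("epoch sets round-trip through their on-disk container", {
  es <- fx_toy_epochs(n = 6, C = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  write_epoch_set(es, path)
  expect_identical(read_epoch_set(path), es)
  mf <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(mf$n_epochs, 6)
  expect_equal(mf$n_channels, 3)
})
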