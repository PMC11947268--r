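#' Split a recording into 1-second epochs
#'
#' Cuts the recording into consecutive, non-overlapping epochs of
#' `epoch_s` seconds (250 samples at 250 Hz); epoch `i` covers samples
#' `[i*250, (i+1)*250)`. The condition label (GI = 0, MT = 1) and subject id
#' are broadcast to every epoch.
#'
#' @param recording An `eeg_recording` whose duration is a whole multiple of
#'   `epoch_s`.
#' @param epoch_s Epoch length in seconds (default 1).
#' @return An `epoch_set`: list with `epochs` (array n x channels x samples),
#'   `labels` (integer 0/1), `subject_ids`, `channel_labels`.
#' @export
segment_epochs <- function(recording, epoch_s = 1) {
  fs <- recording$sampling_rate
  n <- nrow(recording$data)
  step <- epoch_s * fs
  if (n %% step != 0) {
    stop("recording duration is not a whole multiple of epoch_s")
  }
  n_ep <- n %/% step
  nch <- ncol(recording$data)
  # data is time x channel; reorder to epoch x channel x sample
  arr <- array(recording$data, c(step, n_ep, nch))
  epochs <- aperm(arr, c(2, 3, 1))
  new_epoch_set(
    epochs = epochs,
    labels = rep(if (recording$condition == "MT") 1L else 0L, n_ep),
    subject_ids = rep(recording$subject_id, n_ep),
    channel_labels = recording$channel_labels
  )
}

new_epoch_set <- function(epochs, labels, subject_ids, channel_labels) {
  stopifnot(dim(epochs)[1] == length(labels),
            length(labels) == length(subject_ids),
            dim(epochs)[2] == length(channel_labels),
            all(labels %in% c(0L, 1L)))
  structure(list(epochs = epochs, labels = as.integer(labels),
                 subject_ids = subject_ids, channel_labels = channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d ch x %d samples (%d subjects, %d/%d GI/MT)\n",
              d[1], d[2], d[3], length(unique(x$subject_ids)),
              sum(x$labels == 0), sum(x$labels == 1)))
  invisible(x)
}

#' Concatenate epoch sets
#'
#' @param ... `epoch_set` objects with identical channel sets.
#' @return A single `epoch_set`.
#' @export
bind_epoch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "epoch_set")) sets <- sets[[1]]
  ch <- sets[[1]]$channel_labels
  stopifnot(all(vapply(sets, function(s) identical(s$channel_labels, ch), TRUE)))
  d <- dim(sets[[1]]$epochs)
  ns <- vapply(sets, function(s) dim(s$epochs)[1], 0L)
  epochs <- array(0, c(sum(ns), d[2], d[3]))
  at <- 0L
  for (s in sets) {
    n <- dim(s$epochs)[1]
    epochs[at + seq_len(n), , ] <- s$epochs
    at <- at + n
  }
  new_epoch_set(epochs,
                unlist(lapply(sets, `[[`, "labels")),
                unlist(lapply(sets, `[[`, "subject_ids")),
                ch)
}

# Row subset of an epoch set.
subset_epochs <- function(es, idx) {
  new_epoch_set(es$epochs[idx, , , drop = FALSE], es$labels[idx],
                es$subject_ids[idx], es$channel_labels)
}

#' Select a channel subset
#'
#' `"FULL-256"` keeps all channels (identity); `"COGN-26"` reduces to the 26
#' cognitive electrodes in their canonical order; a character vector selects
#' arbitrary labels.
#'
#' @param epochs An `epoch_set`.
#' @param subset `"FULL-256"`, `"COGN-26"`, or a character vector of labels.
#' @return The reduced `epoch_set`.
#' @export
select_channels <- function(epochs, subset = c("FULL-256", "COGN-26")) {
  if (length(subset) == 1L && subset %in% c("FULL-256", "COGN-26")) {
    if (subset == "FULL-256") return(epochs)
    subset <- cognitive_channels
  }
  idx <- match(subset, epochs$channel_labels)
  if (anyNA(idx)) {
    stop("channel label(s) missing: ",
         paste(subset[is.na(idx)], collapse = ", "))
  }
  new_epoch_set(epochs$epochs[, idx, , drop = FALSE], epochs$labels,
                epochs$subject_ids, subset)
}

#' Standardize epochs with training-set statistics
#'
#' Computes a per-channel mean and standard deviation over all training
#' epochs and samples, and applies the same affine transform to the training
#' set and every other set, so no test-set statistics leak into training.
#' Channels with (near) zero variance get their scale clamped to `eps` with a
#' warning.
#'
#' @param train Training `epoch_set`.
#' @param others List of further `epoch_set`s transformed with the training
#'   statistics.
#' @param eps Scale clamp for zero-variance channels.
#' @return List with `train`, `others`, `center`, `scale`.
#' @export
standardize_epochs <- function(train, others = list(), eps = 1e-8) {
  d <- dim(train$epochs)
  stopifnot(d[1] > 0)
  m <- apply(train$epochs, 2, mean)
  s <- apply(train$epochs, 2, stats::sd)
  if (any(s < eps)) {
    warning("zero-variance channel(s): scale clamped to ", eps)
    s[s < eps] <- eps
  }
  tf <- function(es) {
    arr <- es$epochs
    arr <- sweep(arr, 2, m)
    arr <- sweep(arr, 2, s, `/`)
    es$epochs <- arr
    es
  }
  list(train = tf(train), others = lapply(others, tf), center = m, scale = s)
}

#' Subject-grouped stratified k-fold plan
#'
#' Partitions subjects (never epochs) into `k` test groups so that no
#' subject's epochs can appear in both train and test, while keeping the
#' class mix of every fold within one subject of proportional. Shuffling is
#' controlled by `seed`.
#'
#' @param subject_ids Character vector of subject ids (one per subject).
#' @param subject_labels Matching 0/1 condition labels.
#' @param k Number of folds (default 6).
#' @param seed Shuffle seed.
#' @return A `fold_plan`: list of folds, each with `train` and `test` subject
#'   id vectors; attributes `scheme` and `seed`.
#' @export
make_grouped_stratified_folds <- function(subject_ids, subject_labels, k = 6,
                                          seed = 1) {
  stopifnot(length(subject_ids) == length(subject_labels),
            !anyDuplicated(subject_ids))
  if (k > length(subject_ids)) {
    stop("k = ", k, " exceeds the number of subjects (", length(subject_ids), ")")
  }
  if (length(unique(subject_labels)) < 2) stop("both classes must be present")
  assign_fold <- integer(length(subject_ids))
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(subject_labels))) {
      idx <- which(subject_labels == cl)
      idx <- idx[sample.int(length(idx))]
      # round-robin with a per-class offset so fold sizes stay even when
      # class counts are not multiples of k
      assign_fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx) %% k
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    test <- subject_ids[assign_fold == f]
    list(train = setdiff(subject_ids, test), test = test)
  })
  structure(list(folds = folds, scheme = "grouped_stratified_k", k = k,
                 seed = seed, subject_ids = subject_ids,
                 subject_labels = subject_labels),
            class = "fold_plan")
}

#' Leave-one-subject-out plan
#'
#' One fold per subject; each fold tests on that subject's epochs alone.
#'
#' @param subject_ids Character vector of subject ids.
#' @return A `fold_plan`.
#' @export
make_loso_folds <- function(subject_ids) {
  stopifnot(!anyDuplicated(subject_ids))
  if (length(subject_ids) < 2) stop("LOSO needs at least 2 subjects")
  folds <- lapply(subject_ids, function(s) {
    list(train = setdiff(subject_ids, s), test = s)
  })
  structure(list(folds = folds, scheme = "loso", k = length(subject_ids),
                 seed = NA_integer_, subject_ids = subject_ids),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %s, %d folds over %d subjects\n",
              x$scheme, x$k, length(x$subject_ids)))
  invisible(x)
}

#' Serialize a fold plan to JSON
#'
#' @param plan A `fold_plan`.
#' @param path Output path.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(
    list(scheme = plan$scheme, k = plan$k, seed = plan$seed,
         folds = lapply(plan$folds, function(f) f)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Save / load an epoch set
#'
#' Epoch sets are stored as native R serialization (RDS) with a JSON
#' sidecar manifest describing shape, classes and subjects.
#'
#' @param epochs An `epoch_set`.
#' @param path Output `.rds` path; the manifest is written next to it.
#' @return `path`, invisibly.
#' @export
write_epoch_set <- function(epochs, path) {
  saveRDS(epochs, path)
  jsonlite::write_json(
    list(n_epochs = dim(epochs$epochs)[1],
         n_channels = dim(epochs$epochs)[2],
         n_timesteps = dim(epochs$epochs)[3],
         n_gi = sum(epochs$labels == 0), n_mt = sum(epochs$labels == 1),
         subjects = unique(epochs$subject_ids)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  es <- readRDS(path)
  stopifnot(inherits(es, "epoch_set"))
  es
}
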