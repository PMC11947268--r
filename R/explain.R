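#' Grad-CAM attribution for the convolutional classifiers
#'
#' Computes gradient-weighted class-activation maps for a trained `cnn1d`
#' (or the convolutional front-end of a `cnn1d_lstm`) model. For each epoch,
#' the gradient of the predicted-class score (the logit, negated when the
#' predicted class is GI) with respect to the target convolutional block's
#' activation map is averaged over time to give one importance weight per
#' filter; the ReLU-rectified weighted sum of the feature maps is the
#' temporal importance curve, linearly upsampled to the 250 input timesteps.
#'
#' A 1-D temporal convolution mixes all channels in its first layer, so the
#' temporal curve carries no channel axis. The channel-resolved map is
#' obtained by gradient-times-input attribution at the input (rectified),
#' modulated by the normalized temporal importance:
#' `heat[c, t] = ReLU(x[c, t] * dscore/dx[c, t]) * cam(t)`, then max-scaled
#' to `[0, 1]`. This construction is pluggable (`channel_attribution`).
#'
#' @param model Trained `eegdecode_model` of family `cnn1d` or `cnn1d_lstm`.
#' @param epochs An `epoch_set`.
#' @param target_layer Which convolutional block to target, `"conv1"` ..
#'   `"conv4"` (default the last block, `"conv4"`).
#' @param channel_attribution `"grad_x_input"` (default) or `"uniform"` (the
#'   bare temporal curve replicated over channels).
#' @return A list of `cam_heatmap` objects, one per epoch: `intensities`
#'   (channels x 250, in `[0, 1]`), `time_importance`, `subject_id`,
#'   `n_epochs_averaged`, `layer`.
#' @export
gradcam <- function(model, epochs, target_layer = "conv4",
                    channel_attribution = c("grad_x_input", "uniform")) {
  channel_attribution <- match.arg(channel_attribution)
  if (!model$spec$family %in% c("cnn1d", "cnn1d_lstm")) {
    stop("Grad-CAM requires a convolutional model (cnn1d or cnn1d_lstm)")
  }
  conv_idx <- which(vapply(model$layers, function(l) l$type == "conv1d", TRUE))
  k <- suppressWarnings(as.integer(sub("^conv", "", target_layer)))
  if (is.na(k) || k < 1 || k > length(conv_idx)) {
    stop("target_layer must name a convolutional block (conv1..conv",
         length(conv_idx), ")")
  }
  # activation layer directly after the target conv
  tpos <- conv_idx[k] + 1L
  stopifnot(startsWith(model$layers[[tpos]]$type, "act_"))

  x <- epochs_to_tensor(epochs)
  N <- dim(x)[3]
  outs <- vector("list", length(model$layers))
  h <- x
  for (i in seq_along(model$layers)) {
    h <- model$layers[[i]]$forward(h, training = FALSE)
    outs[[i]] <- h
  }
  z <- as.numeric(h)
  sgn <- ifelse(sigm(z) >= 0.5, 1, -1) # predicted-class score direction
  dy <- matrix(sgn, 1, N)
  grad_at_target <- NULL
  for (i in rev(seq_along(model$layers))) {
    if (i == tpos) grad_at_target <- dy
    dy <- model$layers[[i]]$backward(dy)
  }
  g_in <- dy # (C, T, N)
  A <- outs[[tpos]] # (f, L, N)
  G <- array(grad_at_target, dim(A))
  Lf <- dim(A)[2]
  Tn <- model$n_timesteps

  lapply(seq_len(N), function(n) {
    w <- rowMeans(matrix(G[, , n], dim(A)[1], Lf)) # time-averaged gradients
    cam <- pmax(colSums(matrix(A[, , n], dim(A)[1], Lf) * w), 0)
    cam_up <- stats::approx(seq(1, Tn, length.out = Lf), cam, xout = seq_len(Tn),
                            rule = 2)$y
    camn <- if (max(cam_up) > 0) cam_up / max(cam_up) else cam_up
    if (channel_attribution == "grad_x_input") {
      gi <- pmax(matrix(x[, , n], dim(x)[1], Tn) *
                   matrix(g_in[, , n], dim(x)[1], Tn), 0)
      heat <- gi * rep(camn, each = dim(x)[1])
    } else {
      heat <- matrix(rep(camn, each = dim(x)[1]), dim(x)[1], Tn)
    }
    if (max(heat) > 0) heat <- heat / max(heat)
    rownames(heat) <- epochs$channel_labels
    structure(list(intensities = heat, time_importance = cam_up,
                   subject_id = epochs$subject_ids[n], n_epochs_averaged = 1L,
                   layer = target_layer),
              class = "cam_heatmap")
  })
}

#' Average attribution maps of one subject
#'
#' Element-wise mean of the maps (all same subject and shape), max-scaled
#' back to `[0, 1]`.
#'
#' @param maps List of `cam_heatmap` objects for a single subject.
#' @return One `cam_heatmap` with `n_epochs_averaged` set.
#' @export
subject_average <- function(maps) {
  if (!length(maps)) stop("empty list of heatmaps")
  subj <- unique(vapply(maps, `[[`, "", "subject_id"))
  if (length(subj) != 1) stop("heatmaps from mixed subjects: ",
                              paste(subj, collapse = ", "))
  d <- dim(maps[[1]]$intensities)
  acc <- Reduce(`+`, lapply(maps, function(m) {
    stopifnot(identical(dim(m$intensities), d))
    m$intensities
  })) / length(maps)
  if (max(acc) > 0) acc <- acc / max(acc)
  ti <- Reduce(`+`, lapply(maps, `[[`, "time_importance")) / length(maps)
  structure(list(intensities = acc, time_importance = ti, subject_id = subj,
                 n_epochs_averaged = sum(vapply(maps, `[[`, 1L,
                                                "n_epochs_averaged")),
                 layer = maps[[1]]$layer),
            class = "cam_heatmap")
}

#' @export
print.cam_heatmap <- function(x, ...) {
  cat(sprintf("<cam_heatmap> %s, %d ch x %d steps, averaged over %d epoch(s)\n",
              x$subject_id, nrow(x$intensities), ncol(x$intensities),
              x$n_epochs_averaged))
  invisible(x)
}

#' Canonical EEG band boundaries
#'
#' Delta, theta, alpha, beta and gamma, pinned to the analysis band so that
#' the five bands partition 1-45 Hz without overlap.
#'
#' @return Data frame with `band`, `low`, `high` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(1, 4, 8, 13, 30),
             high = c(4, 8, 13, 30, 45))
}

#' Band power via Welch's method
#'
#' Welch periodogram (Hann window, 50% overlap; a single window when the
#' signal is exactly one window long) integrated over the five canonical
#' bands. For multichannel input the spectra are averaged over channels.
#'
#' @param x Numeric vector, a time x channels matrix, or an `eeg_recording`.
#' @param fs Sampling rate (taken from the recording if given).
#' @param window_s Welch window length in seconds (default 1).
#' @return Data frame `band`, `low`, `high`, `power` (uV^2), with the full
#'   1-45 Hz power as attribute `total` and the per-channel band matrix as
#'   attribute `per_channel`.
#' @export
band_psd <- function(x, fs = 250, window_s = 1) {
  if (inherits(x, "eeg_recording")) {
    fs <- x$sampling_rate
    x <- x$data
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  nwin <- as.integer(window_s * fs)
  if (nrow(x) < nwin) stop("signal shorter than one Welch window")
  step <- max(1L, nwin %/% 2L)
  starts <- seq(1L, nrow(x) - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1)) # Hann
  scale <- 1 / (fs * sum(w^2))
  nf <- nwin %/% 2L
  freqs <- (seq_len(nf + 1L) - 1L) * fs / nwin
  psd <- matrix(0, nf + 1L, ncol(x))
  for (s0 in starts) {
    seg <- x[s0:(s0 + nwin - 1L), , drop = FALSE] * w
    sp <- stats::mvfft(seg)
    P <- (Mod(sp[seq_len(nf + 1L), , drop = FALSE])^2) * scale
    P[2:nf, ] <- 2 * P[2:nf, ] # one-sided
    psd <- psd + P
  }
  psd <- psd / length(starts)
  df <- fs / nwin
  bands <- eeg_bands()
  per_ch <- t(vapply(seq_len(nrow(bands)), function(i) {
    sel <- freqs >= bands$low[i] & freqs < bands$high[i]
    colSums(psd[sel, , drop = FALSE]) * df
  }, numeric(ncol(x))))
  if (ncol(x) == 1L) per_ch <- matrix(per_ch, nrow = nrow(bands))
  rownames(per_ch) <- bands$band
  bands$power <- rowMeans(per_ch)
  sel_tot <- freqs >= 1 & freqs < 45
  attr(bands, "total") <- mean(colSums(psd[sel_tot, , drop = FALSE]) * df)
  attr(bands, "per_channel") <- per_ch
  bands
}
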