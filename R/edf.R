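#' Write a recording to EDF
#'
#' Writes a minimal, standard-conforming EDF (European Data Format) file:
#' 16-bit samples, one-second data records, physical units microvolts,
#' channel labels preserved (truncated to the 16-character field). Physical
#' scaling is per channel (min/max of the data), so quantisation error is
#' bounded by the channel range / 65535.
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  fs <- recording$sampling_rate
  n <- nrow(data)
  nch <- ncol(data)
  if (n %% fs != 0) stop("recording length must be a whole number of seconds")
  nrec <- n %/% fs

  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    formatC(x, width = w, flag = "-")
  }
  # render a numeric into the 8-character header field, parseable back
  num8 <- function(x) {
    vapply(x, function(v) {
      s <- formatC(v, digits = 6, format = "g")
      if (nchar(s) > 8) s <- formatC(v, digits = 1, format = "e")
      s
    }, "")
  }

  # digitize with exactly the physical bounds as they will be read back from
  # the 8-char header fields, so reader and writer share one scaling; widen
  # until the (rounded) bounds cover the data
  lo <- apply(data, 2, min)
  hi <- apply(data, 2, max)
  margin <- 2e-4 * (hi - lo + 1e-6)
  repeat {
    pmin_ <- as.numeric(num8(lo - margin))
    pmax_ <- as.numeric(num8(hi + margin))
    if (all(pmin_ <= lo) && all(pmax_ >= hi)) break
    margin <- margin * 4
  }
  flat <- pmax_ - pmin_ < 1e-9
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768
  dmax <- 32767
  num <- function(x, w) pad(num8(x), w)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),
    pad(recording$subject_id, 80),
    pad(paste("cond", recording$condition), 80),
    pad("01.01.20", 8), pad("00.00.00", 8),
    pad(256 + nch * 256, 8),
    pad("", 44),
    pad(nrec, 8),
    pad(1, 8),
    pad(nch, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(recording$channel_labels, pad, "", w = 16),
    rep(pad("", 80), nch),
    rep(pad("uV", 8), nch),
    vapply(pmin_, num, "", w = 8),
    vapply(pmax_, num, "", w = 8),
    rep(pad(dmin, 8), nch),
    rep(pad(dmax, 8), nch),
    rep(pad("", 80), nch),
    rep(pad(fs, 8), nch),
    rep(pad("", 32), nch)
  )
  writeChar(paste(fields, collapse = ""), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- sweep(data, 2, pmin_) # shift to zero
  dig <- round(sweep(dig, 2, scale, `*`)) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  arr <- array(as.integer(dig), c(fs, nrec, nch))
  arr <- aperm(arr, c(1, 3, 2)) # sample, channel, record
  writeBin(as.integer(arr), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a 16-bit EDF file written by [write_edf()] (or any plain EDF with a
#' uniform sampling rate across channels) back into an `eeg_recording`.
#'
#' @param path EDF file path.
#' @param condition Condition label to attach (EDF itself carries none);
#'   defaults to parsing the recording-id field, falling back to `"GI"`.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, condition = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8) # version
  subject_id <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  getn <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  labels <- getn(16)
  getn(80) # transducer
  getn(8)  # units
  pmin_ <- as.numeric(getn(8))
  pmax_ <- as.numeric(getn(8))
  dmin <- as.numeric(getn(8))
  dmax <- as.numeric(getn(8))
  getn(80) # prefiltering
  spr <- as.integer(getn(8))
  getn(32)
  if (length(unique(spr)) != 1L) stop("mixed sampling rates are not supported")
  fs <- spr[1] / rec_dur
  raw <- readBin(con, "integer", n = nrec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  arr <- array(as.numeric(raw), c(spr[1], nch, nrec))
  arr <- aperm(arr, c(1, 3, 2))
  data <- matrix(arr, nrow = spr[1] * nrec, ncol = nch)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- sweep(sweep(data, 2, dmin), 2, scale, `*`)
  data <- sweep(data, 2, pmin_, `+`)
  colnames(data) <- labels
  if (is.null(condition)) {
    condition <- if (grepl("MT", rec_id)) "MT" else "GI"
  }
  new_recording(subject_id, condition, labels, as.integer(round(fs)), data)
}
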