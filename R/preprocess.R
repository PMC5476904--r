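#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass (2nd-order prototype run
#' forward-backward with [signal::filtfilt], so the effective magnitude
#' response is 4th order and the phase response is zero) to every channel.
#' Zero phase matters here: spike morphology and peak latency must not be
#' distorted before alignment and epoching.
#'
#' @param rec an [eeg_recording].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @return A filtered copy of `rec` (same channels, labels, fs).
#' @export
bandpass_filter <- function(rec, low_hz = 2, high_hz = 70) {
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz))
    stop_ied("need 0 < low_hz < high_hz, got [", low_hz, ", ", high_hz, "]")
  if (high_hz >= nyq)
    stop_ied("high_hz (", high_hz, " Hz) must be below the Nyquist frequency (",
             nyq, " Hz)")
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  rownames(out$data) <- rec$channel_labels
  out
}

#' Resample a recording
#'
#' Polyphase FIR resampling (anti-alias filtering included) of every channel
#' to `target_fs`. The output length is `floor(n * target_fs / fs)`.
#'
#' @param rec an [eeg_recording].
#' @param target_fs new sampling rate in Hz, `< fs`.
#' @return The resampled [eeg_recording] with `fs = target_fs`.
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs >= rec$fs)
    stop_ied("target_fs (", target_fs, ") must be below the current rate (",
             rec$fs, ")")
  ratio <- target_fs / rec$fs
  frac <- .approx_fraction(ratio)
  n_out <- floor(ncol(rec$data) * ratio)
  out <- rec
  out$data <- t(apply(rec$data, 1, function(ch) {
    y <- .resample_poly(ch, frac$p, frac$q)
    length(y) <- n_out                     # truncate/pad to the contract length
    y[is.na(y)] <- 0
    y
  }))
  rownames(out$data) <- rec$channel_labels
  out$fs <- target_fs
  out
}

# Polyphase rational resampling by p/q: zero-stuff by p, linear-phase FIR
# low-pass at the tighter of the two Nyquist edges (unity DC gain, so a
# constant signal is reproduced exactly in the interior), pick every q-th
# sample. Edges are handled by replicate-padding before filtering.
.resample_poly <- function(x, p, q) {
  n <- length(x)
  if (p == q) return(x)
  m <- max(p, q)
  taps <- 20L * m + 1L                     # ~10 input samples each side
  h <- signal::fir1(taps - 1, 1 / m, "low")
  h <- h * p / sum(h)                      # exact DC gain after zero-stuffing
  half <- (taps - 1L) / 2L
  pad <- ceiling(half / p) + 1L
  xe <- c(rep(x[1], pad), x, rep(x[n], pad))
  up <- numeric(length(xe) * p)
  up[seq(1, length(up), by = p)] <- xe
  f <- stats::convolve(up, rev(h), type = "open")
  f <- f[(half + 1):(half + length(up))]   # compensate FIR group delay
  start <- pad * p + 1L
  idx <- seq(start, start + ceiling(n * p / q - 1) * q, by = q)
  f[idx]
}

# Small continued-fraction rational approximation of a resampling ratio.
.approx_fraction <- function(x, max_den = 10000L) {
  best <- c(p = 1L, q = 1L)
  err <- Inf
  for (q in 1:max_den) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err - 1e-15) {
      best <- c(p = p, q = q)
      err <- e
    }
    if (err < 1e-12) break
  }
  as.list(best)
}

#' Global field power
#'
#' GFP at one time point: the root-mean-square deviation of the channel
#' values from their instantaneous across-channel mean (the population
#' standard deviation of the field). The GFP peak marks the moment of
#' maximal field expression of a spike and anchors marker realignment.
#'
#' @param values numeric vector, one value per channel (microvolts).
#' @return scalar GFP in microvolts.
#' @export
gfp <- function(values) {
  if (length(values) < 2)
    stop_ied("GFP needs at least 2 channels, got ", length(values))
  m <- mean(values)
  sqrt(mean((values - m)^2))
}

# GFP time course of a channels x samples matrix (population sd per column).
gfp_trace <- function(mat) {
  if (nrow(mat) < 2) stop_ied("GFP needs at least 2 channels")
  mu <- colMeans(mat)
  sqrt(colMeans(mat^2) - mu^2)
}

#' Realign markers to the local GFP peak
#'
#' Moves each marker to the sample of maximum global field power (computed on
#' the channels of interest) within `search_halfwidth_s` of its current
#' position. Human markers sit "close to" the spike peak; classification
#' requires all epochs to share an identical peak-relative grid, so markers
#' are snapped to the field-power maximum. Ties break to the earliest sample,
#' making the operation deterministic and idempotent.
#'
#' @param rec an [eeg_recording].
#' @param markers data frame `event_id,sample` (0-based).
#' @param channels_of_interest channel labels to compute GFP on (>= 2).
#' @param search_halfwidth_s half-width of the search window in seconds.
#' @param policy `"drop"` drops out-of-bounds events with a warning;
#'   `"fail"` raises an error listing them.
#' @return marker data frame with adjusted `sample` values.
#' @export
realign_markers <- function(rec, markers, channels_of_interest,
                            search_halfwidth_s = 0.050,
                            policy = c("drop", "fail")) {
  policy <- match.arg(policy)
  missing_ch <- setdiff(channels_of_interest, rec$channel_labels)
  if (length(missing_ch))
    stop_ied("channels of interest not in recording: ",
             paste(missing_ch, collapse = ", "),
             " (available: ", paste(rec$channel_labels, collapse = ", "), ")")
  w <- round(search_halfwidth_s * rec$fs)
  n <- ncol(rec$data)
  sub <- rec$data[channels_of_interest, , drop = FALSE]

  lo <- markers$sample - w
  hi <- markers$sample + w
  bad <- lo < 0 | hi > n - 1
  if (any(bad)) {
    msg <- paste0("search window out of bounds for event(s): ",
                  paste(markers$event_id[bad], collapse = ", "))
    if (policy == "fail") stop_ied(msg)
    warning(msg, "; dropped", call. = FALSE)
    markers <- markers[!bad, , drop = FALSE]
    lo <- lo[!bad]; hi <- hi[!bad]
  }
  new_sample <- vapply(seq_len(nrow(markers)), function(i) {
    idx <- (lo[i]:hi[i]) + 1L              # 0-based -> R indices
    g <- gfp_trace(sub[, idx, drop = FALSE])
    lo[i] + (which.max(g) - 1L)            # which.max: earliest on ties
  }, numeric(1))
  markers$sample <- as.integer(new_sample)
  markers
}

#' Epoch container
#'
#' @param data events x channels x samples array (microvolts).
#' @param event_ids,channels dimension labels.
#' @param window `c(pre_s, post_s)`: seconds before/after the aligned peak.
#' @param fs sampling rate in Hz.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, event_ids, channels, window, fs) {
  data <- unclass(data)
  stopifnot(length(dim(data)) == 3)
  n_samp <- round(sum(window) * fs)
  if (dim(data)[3] != n_samp)
    stop_ied("epoch length ", dim(data)[3], " does not match round((pre+post)*fs) = ",
             n_samp)
  dimnames(data) <- list(event_ids, channels, NULL)
  structure(list(event_ids = as.character(event_ids),
                 channels = as.character(channels),
                 window = as.numeric(window), fs = fs, data = data),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d events x %d channels x %d samples @ %g Hz, window [-%g, +%g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Extract peak-aligned epochs
#'
#' Cuts a window of `pre_s` seconds before to `post_s` seconds after each
#' marker out of the selected channels. Sample 0 of each epoch corresponds to
#' t = -pre_s; the aligned peak falls at index `round(pre_s * fs)`. Windows
#' are half-open: `round((pre_s + post_s) * fs)` samples per channel.
#'
#' @inheritParams realign_markers
#' @param channels channel labels to keep (the channels of interest).
#' @param pre_s,post_s window extent in seconds (defaults 100 ms / 200 ms).
#' @return An [epoch_set].
#' @export
extract_epochs <- function(rec, markers, channels, pre_s = 0.100, post_s = 0.200,
                           policy = c("drop", "fail")) {
  policy <- match.arg(policy)
  missing_ch <- setdiff(channels, rec$channel_labels)
  if (length(missing_ch))
    stop_ied("channels not in recording: ", paste(missing_ch, collapse = ", "))
  n_pre <- round(pre_s * rec$fs)
  n_samp <- round((pre_s + post_s) * rec$fs)
  start <- markers$sample - n_pre          # 0-based first sample of epoch
  bad <- start < 0 | start + n_samp > ncol(rec$data)
  if (any(bad)) {
    msg <- paste0("epoch out of bounds for event(s): ",
                  paste(markers$event_id[bad], collapse = ", "))
    if (policy == "fail") stop_ied(msg)
    warning(msg, "; dropped", call. = FALSE)
    markers <- markers[!bad, , drop = FALSE]
    start <- start[!bad]
  }
  sub <- rec$data[channels, , drop = FALSE]
  arr <- array(0, dim = c(nrow(markers), length(channels), n_samp))
  for (i in seq_len(nrow(markers)))
    arr[i, , ] <- sub[, (start[i] + 1):(start[i] + n_samp), drop = FALSE]
  epoch_set(arr, markers$event_id, channels, c(pre_s, post_s), rec$fs)
}

#' Concatenate epochs into meta-IED vectors
#'
#' A meta-IED is the per-event vector formed by concatenating the epoch
#' waveforms of all channels of interest, in the epoch set's channel order:
#' block c of the vector occupies positions `[c * n_samples, (c+1) * n_samples)`.
#' This single vector carries both the morphology and the spatial field of
#' the event, so one clustering pass can separate classes on either.
#'
#' @param epochs an [epoch_set].
#' @return An object of class `meta_ied_set` with `event_ids`, `vectors`
#'   (events x (channels*samples) matrix) and `provenance`.
#' @export
build_meta_ieds <- function(epochs) {
  d <- dim(epochs$data)
  vectors <- matrix(0, nrow = d[1], ncol = d[2] * d[3])
  for (ch in seq_len(d[2]))
    vectors[, ((ch - 1) * d[3] + 1):(ch * d[3])] <- epochs$data[, ch, ]
  rownames(vectors) <- epochs$event_ids
  structure(list(event_ids = epochs$event_ids, vectors = vectors,
                 provenance = list(channels = epochs$channels,
                                   window = epochs$window, fs = epochs$fs)),
            class = "meta_ied_set")
}

#' @export
print.meta_ied_set <- function(x, ...) {
  cat(sprintf("<meta_ied_set> %d events, vector length %d (%d channels x %d samples)\n",
              nrow(x$vectors), ncol(x$vectors), length(x$provenance$channels),
              ncol(x$vectors) / length(x$provenance$channels)))
  invisible(x)
}

#' Reshape meta-IED vectors back into an epoch set
#'
#' Inverse of [build_meta_ieds]; round-tripping is lossless.
#' @param meta a `meta_ied_set`.
#' @return An [epoch_set].
#' @export
meta_to_epochs <- function(meta) {
  n_ch <- length(meta$provenance$channels)
  n_samp <- ncol(meta$vectors) / n_ch
  arr <- array(0, dim = c(nrow(meta$vectors), n_ch, n_samp))
  for (ch in seq_len(n_ch))
    arr[, ch, ] <- meta$vectors[, ((ch - 1) * n_samp + 1):(ch * n_samp)]
  epoch_set(arr, meta$event_ids, meta$provenance$channels,
            meta$provenance$window, meta$provenance$fs)
}

#' Randomly sample events without replacement
#'
#' Uniform sample of `n` markers, preserving their original order;
#' deterministic given `seed`.
#'
#' @param markers marker data frame.
#' @param n number of events to keep.
#' @param seed RNG seed.
#' @return marker data frame with `n` rows.
#' @export
sample_events <- function(markers, n = 100, seed = NULL) {
  if (n > nrow(markers))
    stop_ied("asked for ", n, " events but only ", nrow(markers), " available")
  keep <- with_seed(seed, sort(sample.int(nrow(markers), n)))
  markers[keep, , drop = FALSE]
}
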