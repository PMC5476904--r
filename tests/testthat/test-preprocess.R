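make_rec <- function(data, fs = 250) {
  eeg_recording(data, sprintf("Ch%d", seq_len(nrow(data))), fs)
}

test_that("band-pass filter passes in-band tones and rejects DC", {
  fs <- 250
  t <- (0:(8 * fs - 1)) / fs
  rec <- make_rec(rbind(rep(5, length(t)), sin(2 * pi * 10 * t)), fs)
  out <- bandpass_filter(rec, 2, 70)
  mid <- seq(2 * fs, 6 * fs)                 # central half, past edge effects
  expect_lt(max(abs(out$data[1, mid])), 0.05)      # DC attenuated below 1%
  amp <- max(abs(out$data[2, mid]))
  expect_lt(abs(amp - 1), 0.05)                    # 10 Hz within 5% of unity
  expect_identical(out$channel_labels, rec$channel_labels)
  expect_error(bandpass_filter(rec, 2, 130), "Nyquist")
  expect_error(bandpass_filter(rec, 80, 70), "low_hz")
})

test_that("resampling scales the sample count and preserves amplitude", {
  fs <- 5000
  t <- (0:19999) / fs
  rec <- make_rec(rbind(sin(2 * pi * 10 * t), rep(2.5, length(t))), fs)
  out <- resample_recording(rec, 250)
  expect_equal(ncol(out$data), 1000)               # 20000 * 250 / 5000
  expect_equal(out$fs, 250)
  mid <- 300:700
  expect_lt(abs(max(abs(out$data[1, mid])) - 1), 0.02)
  expect_lt(max(abs(out$data[2, mid] - 2.5)) / 2.5, 1e-6)
  expect_error(resample_recording(rec, 5000), "below")
})

test_that("GFP is the population sd of the instantaneous field", {
  expect_equal(gfp(c(3, 3, 3, 3)), 0)
  expect_equal(gfp(c(1, -1)), 1)
  v <- rnorm(8)
  expect_equal(gfp(5 * v), 5 * gfp(v))
  expect_equal(gfp(-2 * v), 2 * gfp(v))
  expect_error(gfp(1), "2 channels")
})

test_that("markers move to the GFP maximum within the search window", {
  fs <- 250
  n <- 1000
  data <- matrix(0, 4, n)
  tpl <- make_template(60, 0, 0, fs)
  at <- 500 + round(0.020 * fs)                    # true peak 20 ms after marker
  idx <- (at - tpl$peak_index):(at - tpl$peak_index + length(tpl$waveform) - 1)
  for (c in 1:4) data[c, idx + 1] <- tpl$waveform * c(1, -0.5, 0.8, -1)[c]
  rec <- make_rec(data, fs)
  mk <- data.frame(event_id = "e1", sample = 500L)
  out <- realign_markers(rec, mk, rec$channel_labels, 0.050)
  expect_equal(out$sample, 500L + round(0.020 * fs))

  # a marker already at the unique maximum stays put (idempotence)
  out2 <- realign_markers(rec, out, rec$channel_labels, 0.050)
  expect_equal(out2$sample, out$sample)

  # flat recording: GFP is identically zero, tie breaks to the window start
  flat <- make_rec(matrix(1, 3, n), fs)
  w <- round(0.050 * fs)
  out3 <- realign_markers(flat, mk, flat$channel_labels, 0.050)
  expect_equal(out3$sample, 500L - w)

  # out-of-bounds window: dropped with a warning, or an error in strict mode
  edge <- data.frame(event_id = "e9", sample = 3L)
  expect_warning(res <- realign_markers(rec, edge, rec$channel_labels, 0.050),
                 "e9")
  expect_equal(nrow(res), 0)
  expect_error(realign_markers(rec, edge, rec$channel_labels, 0.050,
                               policy = "fail"), "e9")
})

test_that("epochs slice the recording on a peak-aligned grid", {
  fs <- 250
  ramp <- matrix(rep(0:999, each = 2), nrow = 2, byrow = FALSE)
  ramp[2, ] <- ramp[2, ] * -1
  rec <- make_rec(ramp, fs)
  mk <- data.frame(event_id = c("e1", "e2"), sample = c(200L, 400L))
  ep <- extract_epochs(rec, mk, rec$channel_labels)
  expect_equal(dim(ep$data), c(2, 2, 75))          # 0.300 s at 250 Hz
  # sample 0 of the epoch is t = -pre: a ramp restricted to the window
  expect_equal(ep$data[1, 1, ], (200 - 25):(200 + 49))
  expect_equal(ep$data[2, 2, ], -((400 - 25):(400 + 49)))

  near <- data.frame(event_id = "e3", sample = 10L)  # needs sample -15
  expect_error(extract_epochs(rec, near, rec$channel_labels, policy = "fail"),
               "e3")
})

test_that("meta-IED vectors concatenate channel blocks losslessly", {
  set.seed(3)
  arr <- array(rnorm(4 * 10 * 75), dim = c(4, 10, 75))
  ep <- epoch_set(arr, sprintf("e%d", 1:4), sprintf("Ch%02d", 1:10),
                  c(0.1, 0.2), 250)
  meta <- build_meta_ieds(ep)
  expect_equal(ncol(meta$vectors), 750)
  expect_equal(meta$vectors[2, 76:150], arr[2, 2, ])  # block 2 = channel 2

  back <- meta_to_epochs(meta)
  expect_equal(back$data, ep$data, ignore_attr = TRUE)

  # permuting the channel order permutes the blocks correspondingly
  perm <- c(3, 1, 2, 4:10)
  ep_p <- epoch_set(arr[, perm, , drop = FALSE], ep$event_ids,
                    ep$channels[perm], ep$window, ep$fs)
  meta_p <- build_meta_ieds(ep_p)
  expect_equal(meta_p$vectors[, 1:75], meta$vectors[, 151:225])

  one <- epoch_set(arr[, 1, , drop = FALSE], ep$event_ids, "Ch01",
                   c(0.1, 0.2), 250)
  expect_equal(build_meta_ieds(one)$vectors[3, ], arr[3, 1, ])
})

test_that("event sampling is uniform, order-preserving and seeded", {
  mk <- data.frame(event_id = sprintf("e%03d", 1:200), sample = 1:200 * 100L)
  expect_equal(sample_events(mk, 200, seed = 1), mk)
  expect_error(sample_events(mk, 201), "available")
  s1 <- sample_events(mk, 100, seed = 5)
  expect_equal(s1, sample_events(mk, 100, seed = 5))
  expect_false(is.unsorted(s1$sample))             # original order preserved

  counts <- integer(200)
  for (r in 1:1000) {
    sel <- sample_events(mk, 100, seed = 1000 + r)
    counts[match(sel$event_id, mk$event_id)] <-
      counts[match(sel$event_id, mk$event_id)] + 1L
  }
  expect_true(all(abs(counts / 1000 - 0.5) < 0.05))
})
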