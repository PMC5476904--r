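# Synthetic multichannel EEG with known spike classes, artifact events and
# simulated imperfect observers, so the whole pipeline can be exercised
# end-to-end without patient data.

#' Synthetic dataset configuration
#'
#' Defaults describe a 10-channel, 250 Hz recording carrying 3 latent IED
#' classes of 40 events each plus 20 spatially inconsistent artifact events,
#' with an in-band signal-to-noise ratio of 5. Each class has its own
#' biphasic template (sharp component 40-100 ms) and a sparse spatial field
#' (prominent on 2-4 channels); events get multiplicative amplitude jitter
#' and latency jitter; the background is 1/f-shaped noise.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate (Hz).
#' @param K number of IED classes.
#' @param events_per_class events per class.
#' @param n_artifacts number of one-off artifact events.
#' @param amplitude_uv template peak amplitude on the most prominent channel.
#' @param snr ratio of `amplitude_uv` to the background noise standard
#'   deviation inside the 2-70 Hz band.
#' @param sharp_width_ms range of per-class sharp-component FWHM (ms).
#' @param slow_width_ms range of per-class slow-wave width (ms).
#' @param slow_amp range of slow-wave amplitude relative to the sharp peak.
#' @param artifact_amp_factor artifact amplitude relative to `amplitude_uv`
#'   (muscle and electrode artifacts that get marked as candidate events are
#'   typically larger than the discharges themselves).
#' @param artifact_channels `c(min, max)` channels involved per artifact.
#' @param amp_jitter_sd multiplicative amplitude jitter (lognormal sd).
#' @param latency_jitter_ms latency jitter sd around the event grid (ms).
#' @param noise_exponent spectral exponent of the 1/f background.
#' @param spacing_s event grid spacing (s); must exceed the 0.3 s epoch
#'   length plus jitter so events never overlap.
#' @param max_field_cor maximum pairwise correlation allowed between class
#'   field-weight vectors (templates are redrawn until satisfied).
#' @param seed RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_channels = 10, fs = 250, K = 3,
                         events_per_class = 40, n_artifacts = 20,
                         amplitude_uv = 100, snr = 5,
                         sharp_width_ms = c(40, 100),
                         slow_width_ms = c(100, 200),
                         slow_amp = c(0.4, 0.7),
                         artifact_amp_factor = 3, artifact_channels = c(4, 8),
                         amp_jitter_sd = 0.15, latency_jitter_ms = 4,
                         noise_exponent = 1, spacing_s = 0.8,
                         max_field_cor = 0.3, seed = 1) {
  cfg <- as.list(environment())
  if (amp_jitter_sd < 0 || latency_jitter_ms < 0)
    stop_ied("jitter standard deviations must be >= 0")
  if (spacing_s < 0.3 + 3 * latency_jitter_ms / 1000)
    stop_ied("spacing_s too small: events could overlap within the 300 ms epoch")
  structure(cfg, class = "synth_config")
}

#' Biphasic spike template
#'
#' A raised-cosine sharp component (full width at half maximum =
#' `sharp_width_ms`) peaking at t = 0, followed by an opposite-polarity
#' raised-cosine slow wave. The waveform is normalized to unit peak
#' amplitude, with the peak magnitude exactly at the t = 0 sample.
#'
#' @param sharp_width_ms sharp-component FWHM in ms (10-500).
#' @param slow_width_ms slow-wave width in ms (10-500); 0 disables it.
#' @param slow_amp slow-wave amplitude relative to the sharp peak (< 0.8).
#' @param fs sampling rate in Hz.
#' @return list with `waveform` (numeric), `peak_index` (0-based sample of
#'   t = 0) and `fs`.
#' @export
make_template <- function(sharp_width_ms = 60, slow_width_ms = 150,
                          slow_amp = 0.4, fs = 250) {
  if (sharp_width_ms < 10 || sharp_width_ms > 500)
    stop_ied("sharp_width_ms must lie in [10, 500], got ", sharp_width_ms)
  if (slow_width_ms != 0 && (slow_width_ms < 10 || slow_width_ms > 500))
    stop_ied("slow_width_ms must be 0 or in [10, 500], got ", slow_width_ms)
  if (slow_amp < 0 || slow_amp >= 0.8)
    stop_ied("slow_amp must lie in [0, 0.8), got ", slow_amp)
  H <- sharp_width_ms / 1000
  S <- slow_width_ms / 1000
  t0 <- H + S / 2                     # slow-wave centre, after the sharp lobe
  t_end <- if (S > 0) t0 + S else H
  # sample grid aligned so t = 0 falls exactly on a sample
  t <- seq(-ceiling(H * fs), ceiling(t_end * fs)) / fs
  sharp <- ifelse(abs(t) <= H, 0.5 * (1 + cos(pi * t / H)), 0)
  slow <- if (S > 0)
    ifelse(abs(t - t0) <= S, -slow_amp * 0.5 * (1 + cos(pi * (t - t0) / S)), 0)
  else 0
  w <- sharp + slow
  peak_index <- which.min(abs(t))     # sample closest to t = 0
  w <- w / abs(w[peak_index])
  if (which.max(abs(w)) != peak_index)
    stop_ied("template peak not at t = 0; parameters too extreme")
  list(waveform = w, peak_index = peak_index - 1L, fs = fs)
}

# 1/f^alpha-shaped Gaussian noise of length n (unit variance before shaping).
.pink_noise <- function(n, alpha) {
  white <- rnorm(n)
  if (alpha == 0) return(white)
  sp <- fft(white)
  f <- c(1, seq_len(n - 1))                     # guard DC
  f <- pmin(f, n - f + 1)                       # symmetric frequency index
  shaped <- sp / f^(alpha / 2)
  x <- Re(fft(shaped, inverse = TRUE)) / n
  x / sd(x)
}

# Sparse spatial field profiles with pairwise correlation < max_cor.
.draw_fields <- function(K, n_channels, max_cor) {
  for (attempt in 1:200) {
    W <- t(vapply(seq_len(K), function(k) {
      n_prom <- sample(2:4, 1)
      prom <- sample(n_channels, n_prom)
      w <- runif(n_channels, 0, 0.08)
      w[prom] <- runif(n_prom, 0.6, 1)
      w / max(w)
    }, numeric(n_channels)))
    if (K < 2) return(W)
    cors <- cor(t(W))
    if (max(abs(cors[upper.tri(cors)])) < max_cor) return(W)
  }
  stop_ied("could not draw ", K, " field profiles with pairwise correlation < ",
           max_cor, " on ", n_channels, " channels")
}

#' Simulate a multichannel recording with known IED classes
#'
#' Places `K * events_per_class` spike events and `n_artifacts` artifact
#' events on a jittered time grid (guaranteed non-overlapping at the 300 ms
#' epoch scale) inside 1/f background noise. Spike events are their class
#' template scaled by the class's per-channel field weights and a
#' multiplicative amplitude jitter; artifacts get one-off random multi-bump
#' templates and spatially inconsistent random fields. The noise is scaled so
#' that its standard deviation inside the 2-70 Hz band equals
#' `amplitude_uv / snr`.
#'
#' @param cfg a [synth_config].
#' @return list with `recording` (an [eeg_recording]), `markers` (true peak
#'   samples, 0-based), `labels` (the ground-truth [classification] with
#'   classes `"1"..."K"` and `NON_IED` for artifacts), `fields` (K x channels
#'   weight matrix), `templates` (per-class [make_template] results).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n_events <- cfg$K * cfg$events_per_class + cfg$n_artifacts
    n_samples <- ceiling((n_events + 2) * cfg$spacing_s * cfg$fs)
    chans <- sprintf("Ch%02d", seq_len(cfg$n_channels))

    # background: independent 1/f noise per channel, scaled to in-band sd
    noise_sd <- cfg$amplitude_uv / cfg$snr
    data <- t(vapply(seq_len(cfg$n_channels), function(c)
      .pink_noise(n_samples, cfg$noise_exponent), numeric(n_samples)))
    bf <- signal::butter(2, c(2, 70) / (cfg$fs / 2), type = "pass")
    inband_sd <- mean(apply(data, 1, function(ch)
      sd(signal::filtfilt(bf, ch))))
    data <- data * (noise_sd / inband_sd)

    templates <- lapply(seq_len(cfg$K), function(k)
      make_template(runif(1, cfg$sharp_width_ms[1], cfg$sharp_width_ms[2]),
                    runif(1, cfg$slow_width_ms[1], cfg$slow_width_ms[2]),
                    runif(1, cfg$slow_amp[1], cfg$slow_amp[2]), cfg$fs))
    fields <- .draw_fields(cfg$K, cfg$n_channels, cfg$max_field_cor)

    class_seq <- sample(c(rep(as.character(seq_len(cfg$K)), cfg$events_per_class),
                          rep(NON_IED, cfg$n_artifacts)))
    grid <- round((seq_len(n_events) + 0.5) * cfg$spacing_s * cfg$fs)
    jitter <- round(rnorm(n_events, 0, cfg$latency_jitter_ms / 1000 * cfg$fs))
    peaks <- grid + jitter

    # peak_sample is 0-based; element peak_index of wave lands on it exactly
    add_event <- function(data, wave, peak_index, peak_sample, weights, amp) {
      idx <- (peak_sample - peak_index) + seq_along(wave)
      for (c in which(weights > 0))
        data[c, idx] <- data[c, idx] + amp * weights[c] * wave
      data
    }

    for (i in seq_len(n_events)) {
      amp <- cfg$amplitude_uv * exp(rnorm(1, 0, cfg$amp_jitter_sd))
      if (class_seq[i] == NON_IED) {
        # one-off artifact with low field consistency: a random subset of
        # channels, each with its own random bumps (own widths, signs,
        # latencies) at muscle/electrode-artifact amplitude — no coherent
        # spatial template the way a cortical discharge has
        span <- round(0.3 * cfg$fs)               # fill the whole epoch window
        art_amp <- amp * cfg$artifact_amp_factor
        involved <- sample(cfg$n_channels,
                           sample(cfg$artifact_channels[1]:cfg$artifact_channels[2], 1))
        for (c in involved) {
          wave <- numeric(2 * span + 1)
          for (b in seq_len(sample(2:5, 1))) {
            tpl <- make_template(runif(1, 30, 200), 0, 0, cfg$fs)
            at <- sample.int(length(wave) - length(tpl$waveform), 1)
            seg <- at:(at + length(tpl$waveform) - 1)
            wave[seg] <- wave[seg] +
              tpl$waveform * sample(c(-1, 1), 1) * runif(1, 0.5, 1)
          }
          data <- add_event(data, wave, span, peaks[i],
                            replace(numeric(cfg$n_channels), c, 1), art_amp)
        }
      } else {
        k <- as.integer(class_seq[i])
        tpl <- templates[[k]]
        data <- add_event(data, tpl$waveform, tpl$peak_index, peaks[i],
                          fields[k, ], amp)
      }
    }

    markers <- data.frame(event_id = sprintf("e%03d", seq_len(n_events)),
                          sample = as.integer(peaks))
    labels <- classification("truth", setNames(class_seq, markers$event_id))
    list(recording = eeg_recording(data, chans, cfg$fs, reference = "synthetic"),
         markers = markers, labels = labels, fields = fields,
         templates = templates)
  })
}

#' Simulate an imperfect human observer
#'
#' Degrades the ground-truth labels the way human reviewers disagree: each
#' event independently is relabelled `NON_IED` with probability `nonied_rate`;
#' otherwise, with probability `relabel_rate`, it is moved to a uniformly
#' chosen different label (among the labels present in the truth). Optional
#' class merges and splits then emulate observers working at a different
#' class granularity.
#'
#' @param truth the ground-truth [classification].
#' @param relabel_rate probability of moving an event to a wrong class.
#' @param nonied_rate probability of calling an event `NON_IED`.
#' @param merge optional list of character vectors of class labels to fuse
#'   (each vector becomes one merged class).
#' @param split optional character vector of class labels to split in two
#'   (events divided at random).
#' @param observer_id identifier of the simulated observer.
#' @param seed RNG seed.
#' @return A [classification].
#' @export
simulate_observer <- function(truth, relabel_rate = 0, nonied_rate = 0,
                              merge = NULL, split = NULL,
                              observer_id = "sim", seed = NULL) {
  e <- relabel_rate; m <- nonied_rate
  if (e < 0 || m < 0 || e + m > 1)
    stop_ied("need relabel_rate >= 0, nonied_rate >= 0 and their sum <= 1")
  with_seed(seed, {
    labels <- truth$labels
    pool <- unique(labels)
    u <- runif(length(labels))
    to_non <- u < m
    to_other <- !to_non & u < m + e
    labels[to_non] <- NON_IED
    for (i in which(to_other)) {
      alt <- setdiff(pool, labels[i])
      if (length(alt)) labels[i] <- sample(alt, 1)
    }
    if (!is.null(merge)) {
      for (grp in merge) {
        merged <- paste(grp, collapse = "+")
        labels[labels %in% grp] <- merged
      }
    }
    if (!is.null(split)) {
      for (cl in split) {
        members <- which(labels == cl)
        if (length(members) >= 2) {
          half <- sample(members, floor(length(members) / 2))
          labels[half] <- paste0(cl, "b")
          labels[setdiff(members, half)] <- paste0(cl, "a")
        }
      }
    }
    classification(observer_id, labels)
  })
}

#' Accuracy after optimal class matching
#'
#' Fraction of events on which two classifications agree after the classes
#' of `pred` are optimally matched (one-to-one) to the classes of `truth`;
#' `NON_IED` is matched to `NON_IED`. Used to score recovery of known
#' synthetic classes, where class names are arbitrary.
#'
#' @param pred,truth [classification] objects over the same events.
#' @return scalar accuracy in `[0, 1]`.
#' @export
match_partition_accuracy <- function(pred, truth) {
  ct <- contingency(pred, truth)
  counts <- ct$counts
  pc <- setdiff(rownames(counts), NON_IED)
  tc <- setdiff(colnames(counts), NON_IED)
  base <- if (NON_IED %in% rownames(counts) && NON_IED %in% colnames(counts))
    counts[NON_IED, NON_IED] else 0
  if (length(pc) == 0 || length(tc) == 0) return(base / ct$n)
  sub <- counts[pc, tc, drop = FALSE]
  # exhaustive assignment over the smaller side (class counts are small)
  if (length(pc) <= length(tc)) {
    perms <- .permutations(seq_along(tc), length(pc))
    best <- max(vapply(seq_len(nrow(perms)), function(r)
      sum(sub[cbind(seq_along(pc), perms[r, ])]), numeric(1)))
  } else {
    perms <- .permutations(seq_along(pc), length(tc))
    best <- max(vapply(seq_len(nrow(perms)), function(r)
      sum(sub[cbind(perms[r, ], seq_along(tc))]), numeric(1)))
  }
  (base + best) / ct$n
}

# All ordered selections of k elements from v (small inputs only).
.permutations <- function(v, k) {
  if (k == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- .permutations(v[-i], k - 1)
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}
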