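# Shared test fixtures and independent oracles.

# Classification from a plain label vector; event ids e001, e002, ...
cls <- function(labels, observer = "X") {
  classification(observer,
                 stats::setNames(as.character(labels),
                                 sprintf("e%03d", seq_along(labels))))
}

# Independent oracle for the counts-weighted variation of information:
# N * (H(X) + H(Y) - 2 I(X;Y)) computed from normalized entropies, written
# against the textbook definitions rather than the package's counts formula.
vi_entropy_oracle <- function(counts) {
  n <- sum(counts)
  px <- rowSums(counts) / n
  py <- colSums(counts) / n
  pxy <- counts / n
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  mi <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    if (pxy[i, j] > 0)
      mi <- mi + pxy[i, j] * log2(pxy[i, j] / (px[i] * py[j]))
  }
  n * (ent(px) + ent(py) - 2 * mi)
}

# Random contingency table with 2-5 classes a side and ~n events.
random_table <- function(n = 100) {
  kx <- sample(2:5, 1)
  ky <- sample(2:5, 1)
  x <- sample.int(kx, n, replace = TRUE)
  y <- sample.int(ky, n, replace = TRUE)
  unclass(table(x, y))
}

# Random partition of n events into k classes, as a classification.
random_partition <- function(n, k, observer = "X") {
  cls(sample.int(k, n, replace = TRUE), observer)
}

# A small default-condition synthetic dataset run through the full pipeline.
# Cached per seed within a test run to keep the suite fast.
.pipeline_cache <- new.env()
run_pipeline <- function(data_seed, wc_seed = 42) {
  key <- paste0("s", data_seed, "_", wc_seed)
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  ds <- simulate_dataset(synth_config(seed = data_seed))
  rec <- bandpass_filter(ds$recording, 2, 70)
  mk <- realign_markers(rec, ds$markers, rec$channel_labels)
  ep <- extract_epochs(rec, mk, rec$channel_labels)
  meta <- build_meta_ieds(ep)
  fit <- wc_classify(meta, seed = wc_seed)
  out <- list(ds = ds, rec = rec, markers = mk, epochs = ep, meta = meta,
              fit = fit)
  .pipeline_cache[[key]] <- out
  out
}
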