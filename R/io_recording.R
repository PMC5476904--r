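#' Multichannel EEG recording container
#'
#' Bundles a channels-by-samples data matrix (microvolts) with its channel
#' labels, sampling rate and a free-text montage descriptor. All pipeline
#' operations consume and return this container.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channel_labels character vector, one unique label per row of `data`.
#' @param fs sampling rate in Hz (> 0).
#' @param reference free-text montage descriptor (e.g. `"referential"`).
#'
#' @return An object of class `eeg_recording` with fields `data`,
#'   `channel_labels`, `fs`, `reference`.
#' @export
eeg_recording <- function(data, channel_labels, fs, reference = "unknown") {
  data <- as.matrix(data)
  channel_labels <- as.character(channel_labels)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_ied("fs must be a single positive number, got ", fs)
  if (nrow(data) != length(channel_labels))
    stop_ied("data has ", nrow(data), " rows but ", length(channel_labels),
             " channel labels were given")
  if (anyDuplicated(channel_labels))
    stop_ied("duplicate channel labels: ",
             paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  rownames(data) <- channel_labels
  structure(list(data = data, channel_labels = channel_labels,
                 fs = as.numeric(fs), reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s), reference: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference))
  cat("  channels:", paste(head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Read an EEG recording
#'
#' Reads a BrainVision triplet (`.vhdr` header plus its referenced binary
#' `.eeg` file) or an EDF file into an [eeg_recording]. Data are returned in
#' microvolts, scaled using the per-channel resolution (BrainVision) or the
#' physical/digital calibration fields (EDF). Channel order follows the file
#' header.
#'
#' Only the common BrainVision dialect is supported: binary data, multiplexed
#' orientation, `INT_16` or `IEEE_FLOAT_32` sample format. Other dialects are
#' rejected with an error naming the offending header field.
#'
#' @param path path to the `.vhdr` header (BrainVision) or `.edf` file.
#' @param format `"brainvision"` or `"edf"`; guessed from the file extension
#'   when omitted.
#' @return An [eeg_recording].
#' @export
read_recording <- function(path, format = c("auto", "brainvision", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vhdr = "brainvision", edf = "edf",
                     stop_ied("cannot guess format from extension '.", ext,
                              "'; pass format explicitly"))
  }
  switch(format,
         brainvision = read_brainvision(path),
         edf = read_edf(path))
}

# ---- BrainVision ----------------------------------------------------------

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub(";.*$", "", lines)
  section <- ""
  kv <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      kv[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(section)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      kv[[section]][[key]] <- val
    }
  }
  kv
}

read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path))
    stop_ied("BrainVision header not found: ", vhdr_path)
  hdr <- parse_vhdr(vhdr_path)
  ci <- hdr[["Common Infos"]]
  bi <- hdr[["Binary Infos"]]
  chi <- hdr[["Channel Infos"]]
  if (is.null(ci)) stop_ied("missing [Common Infos] section in ", vhdr_path)

  fmt <- ci[["DataFormat"]] %||% "BINARY"
  if (toupper(fmt) != "BINARY")
    stop_ied("unsupported DataFormat '", fmt, "' (only BINARY is supported)")
  orient <- ci[["DataOrientation"]] %||% "MULTIPLEXED"
  if (toupper(orient) != "MULTIPLEXED")
    stop_ied("unsupported DataOrientation '", orient,
             "' (only MULTIPLEXED is supported)")
  n_ch <- as.integer(ci[["NumberOfChannels"]] %||%
                       stop_ied("missing NumberOfChannels in [Common Infos]"))
  si_us <- as.numeric(ci[["SamplingInterval"]] %||%
                        stop_ied("missing SamplingInterval in [Common Infos]"))
  fs <- 1e6 / si_us
  bin_fmt <- toupper(bi[["BinaryFormat"]] %||% "INT_16")
  if (!bin_fmt %in% c("INT_16", "IEEE_FLOAT_32"))
    stop_ied("unsupported BinaryFormat '", bin_fmt,
             "' (only INT_16 and IEEE_FLOAT_32 are supported)")

  if (length(chi) < n_ch)
    stop_ied("[Channel Infos] lists ", length(chi), " channels but ",
             "NumberOfChannels=", n_ch)
  labels <- character(n_ch)
  resolution <- numeric(n_ch)
  for (i in seq_len(n_ch)) {
    entry <- chi[[paste0("Ch", i)]]
    if (is.null(entry)) stop_ied("missing Ch", i, " in [Channel Infos]")
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[i] <- trimws(parts[1])
    resolution[i] <- if (length(parts) >= 3 && nzchar(trimws(parts[3])))
      as.numeric(parts[3]) else 1
  }

  eeg_file <- file.path(dirname(vhdr_path), ci[["DataFile"]] %||%
                          stop_ied("missing DataFile in [Common Infos]"))
  if (!file.exists(eeg_file))
    stop_ied("binary data file referenced by DataFile not found: ", eeg_file)

  sz <- file.info(eeg_file)$size
  bytes_per <- if (bin_fmt == "INT_16") 2L else 4L
  n_total <- sz %/% bytes_per
  if (n_total %% n_ch != 0)
    stop_ied(eeg_file, " holds ", n_total, " samples, not a multiple of ",
             "NumberOfChannels=", n_ch)
  con <- file(eeg_file, "rb")
  on.exit(close(con))
  raw_vals <- if (bin_fmt == "INT_16") {
    readBin(con, "integer", n = n_total, size = 2L, signed = TRUE,
            endian = "little")
  } else {
    readBin(con, "double", n = n_total, size = 4L, endian = "little")
  }
  data <- matrix(raw_vals, nrow = n_ch) * resolution
  eeg_recording(data, labels, fs, reference = "as recorded")
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `.vhdr`, `.vmrk` and `.eeg` files in the multiplexed binary dialect.
#' With `binary_format = "INT_16"` data are quantized by the per-channel
#' `resolution` (microvolts per bit).
#'
#' @param rec an [eeg_recording].
#' @param basepath output path without extension; the three files are
#'   `basepath.vhdr`, `basepath.vmrk`, `basepath.eeg`.
#' @param binary_format `"INT_16"` or `"IEEE_FLOAT_32"`.
#' @param resolution microvolts per integer step for `INT_16` (scalar or one
#'   value per channel); ignored for float output.
#' @return `basepath`, invisibly.
#' @export
write_recording_brainvision <- function(rec, basepath,
                                        binary_format = c("INT_16", "IEEE_FLOAT_32"),
                                        resolution = 0.1) {
  binary_format <- match.arg(binary_format)
  n_ch <- nrow(rec$data)
  resolution <- rep_len(resolution, n_ch)
  stem <- basename(basepath)

  ch_lines <- vapply(seq_len(n_ch), function(i) {
    res <- if (binary_format == "INT_16") format(resolution[i]) else "1"
    sprintf("Ch%d=%s,,%s,µV", i, rec$channel_labels[i], res)
  }, character(1))
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", stem),
    sprintf("MarkerFile=%s.vmrk", stem),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", n_ch),
    sprintf("SamplingInterval=%s", format(1e6 / rec$fs)),
    "",
    "[Binary Infos]",
    sprintf("BinaryFormat=%s", binary_format),
    "",
    "[Channel Infos]",
    ch_lines)
  writeLines(hdr, paste0(basepath, ".vhdr"))
  writeLines(c("BrainVision Data Exchange Marker File Version 1.0",
               "",
               "[Common Infos]",
               sprintf("DataFile=%s.eeg", stem),
               "",
               "[Marker Infos]",
               sprintf("Mk1=New Segment,,1,1,%d", n_ch)),
             paste0(basepath, ".vmrk"))

  con <- file(paste0(basepath, ".eeg"), "wb")
  on.exit(close(con))
  if (binary_format == "INT_16") {
    ints <- round(rec$data / resolution)
    if (any(abs(ints) > 32767))
      stop_ied("data exceed INT_16 range at resolution ",
               paste(format(resolution), collapse = ","),
               " µV/bit; increase resolution")
    writeBin(as.integer(ints), con, size = 2L, endian = "little")
  } else {
    writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  }
  invisible(basepath)
}

# ---- EDF ------------------------------------------------------------------

.edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  if (nchar(s) > width) stop_ied("EDF header field too wide: '", x, "'")
  s
}

.edf_num <- function(x, width) {
  s <- formatC(format(x, digits = 7, scientific = FALSE, trim = TRUE),
               width = -width)
  if (nchar(s) > width) s <- formatC(signif(x, 4), width = -width)
  if (nchar(s) > width) stop_ied("numeric EDF field does not fit: ", x)
  s
}

#' Write a recording as EDF
#'
#' Minimal EDF writer: one data record spanning the whole recording, 16-bit
#' samples, symmetric per-channel physical range. Values are quantized to the
#' 16-bit grid (the round-trip error is at most half a quantization step).
#'
#' @param rec an [eeg_recording].
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  n_ch <- nrow(rec$data)
  ns <- ncol(rec$data)
  dur <- ns / rec$fs
  pmax <- pmax(apply(abs(rec$data), 1, max), 1e-6)
  pmax <- signif(pmax * 1.0000001, 6)  # keep extremes inside the range

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  put(.edf_field("0", 8))
  put(.edf_field("synthetic", 80))
  put(.edf_field("iedclust export", 80))
  put(.edf_field("01.01.26", 8))
  put(.edf_field("00.00.00", 8))
  put(.edf_field(256 + 256 * n_ch, 8))
  put(.edf_field("", 44))
  put(.edf_field(1, 8))
  put(.edf_num(dur, 8))
  put(.edf_field(n_ch, 4))
  for (i in seq_len(n_ch)) put(.edf_field(rec$channel_labels[i], 16))
  for (i in seq_len(n_ch)) put(.edf_field("", 80))
  for (i in seq_len(n_ch)) put(.edf_field("uV", 8))
  for (i in seq_len(n_ch)) put(.edf_num(-pmax[i], 8))
  for (i in seq_len(n_ch)) put(.edf_num(pmax[i], 8))
  for (i in seq_len(n_ch)) put(.edf_field(-32768, 8))
  for (i in seq_len(n_ch)) put(.edf_field(32767, 8))
  for (i in seq_len(n_ch)) put(.edf_field("", 80))
  for (i in seq_len(n_ch)) put(.edf_field(ns, 8))
  for (i in seq_len(n_ch)) put(.edf_field("", 32))
  for (i in seq_len(n_ch)) {
    scale <- (2 * pmax[i]) / (32767 - (-32768))
    dig <- round(rec$data[i, ] / scale)
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  if (!file.exists(path)) stop_ied("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  grab <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  grab(8)                       # version
  grab(80); grab(80)            # patient / recording id
  grab(8); grab(8)              # date / time
  grab(8)                       # header bytes
  grab(44)                      # reserved
  n_rec <- as.integer(grab(8))
  dur <- as.numeric(grab(8))
  n_ch <- as.integer(grab(4))
  if (is.na(n_ch) || n_ch < 1) stop_ied("invalid EDF channel count field")
  labels <- vapply(seq_len(n_ch), function(i) grab(16), character(1))
  for (i in seq_len(n_ch)) grab(80)
  for (i in seq_len(n_ch)) grab(8)   # physical dimension
  pmin_ <- vapply(seq_len(n_ch), function(i) as.numeric(grab(8)), numeric(1))
  pmax_ <- vapply(seq_len(n_ch), function(i) as.numeric(grab(8)), numeric(1))
  dmin <- vapply(seq_len(n_ch), function(i) as.numeric(grab(8)), numeric(1))
  dmax <- vapply(seq_len(n_ch), function(i) as.numeric(grab(8)), numeric(1))
  for (i in seq_len(n_ch)) grab(80)
  spr <- vapply(seq_len(n_ch), function(i) as.integer(grab(8)), integer(1))
  for (i in seq_len(n_ch)) grab(32)

  if (length(unique(spr)) != 1L)
    stop_ied("per-channel samples-per-record differ; only uniform-rate EDF is supported")
  fs <- spr[1] / dur
  data <- matrix(0, nrow = n_ch, ncol = spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_ch)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[i])
        stop_ied("EDF data truncated in record ", r, ", signal ", i)
      phys <- (dig - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) + pmin_[i]
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  eeg_recording(data, labels, fs, reference = "as recorded")
}
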