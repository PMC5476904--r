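#' An observer's partition of the event set
#'
#' Holds one classifier's labelling of the analyzed events: a mapping from
#' event id to class label. Class labels are opaque strings, except the
#' reserved label `NON_IED` which means "not an epileptiform discharge".
#' Common synonyms (`non-IED`, `nonied`, `artifact`, case-insensitive) are
#' normalized to `NON_IED` on construction.
#'
#' @param observer_id identifier of the classifier (e.g. `"WC"`, `"H2"`).
#' @param labels named character vector (names = event ids) or a data frame
#'   with columns `event_id` and `label`.
#' @return An object of class `ied_classification` with fields `observer_id`
#'   and `labels` (named character vector).
#' @export
classification <- function(observer_id, labels) {
  if (is.data.frame(labels)) {
    lab <- as.character(labels$label)
    names(lab) <- as.character(labels$event_id)
    labels <- lab
  }
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop_ied("labels must be named by event_id")
  if (anyDuplicated(names(labels))) {
    dups <- unique(names(labels)[duplicated(names(labels))])
    stop_ied("event(s) labelled more than once: ", paste(dups, collapse = ", "))
  }
  structure(list(observer_id = as.character(observer_id),
                 labels = normalize_label(labels)),
            class = "ied_classification")
}

#' @export
print.ied_classification <- function(x, ...) {
  sizes <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("<ied_classification> observer %s: %d events, %d classes\n",
              x$observer_id, length(x$labels), length(sizes)))
  print(sizes)
  invisible(x)
}

#' Event ids of a classification
#' @param x an `ied_classification`.
#' @return character vector of event ids.
#' @export
event_ids <- function(x) names(x$labels)

#' Read event markers from CSV
#'
#' The file must have header columns `event_id,sample`; `sample` is a 0-based
#' index into the recording at its current sampling rate. Lines starting with
#' `#` (such as the `# fs=...` header written by [write_markers]) are ignored.
#'
#' @param path CSV path.
#' @return data frame with character `event_id` and integer `sample`, in file
#'   order.
#' @export
read_markers <- function(path) {
  df <- read.csv(path, comment.char = "#", strip.white = TRUE,
                 colClasses = "character")
  if (!all(c("event_id", "sample") %in% names(df)))
    stop_ied("marker CSV must have columns event_id,sample; found: ",
             paste(names(df), collapse = ","))
  df$sample <- as.integer(df$sample)
  if (anyDuplicated(df$event_id)) {
    dups <- unique(df$event_id[duplicated(df$event_id)])
    stop_ied("duplicate event_id in marker file: ", paste(dups, collapse = ", "))
  }
  if (nrow(df) > 0 && any(df$sample < 0))
    stop_ied("negative sample index for event(s): ",
             paste(df$event_id[df$sample < 0], collapse = ", "))
  df[, c("event_id", "sample")]
}

#' Write event markers to CSV
#'
#' @param markers data frame with columns `event_id`, `sample` (0-based).
#' @param path output path.
#' @param fs sampling rate the sample indices refer to; recorded as a
#'   `# fs=...` comment line so the file is self-describing.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path, fs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(fs)) writeLines(sprintf("# fs=%g", fs), con)
  writeLines("event_id,sample", con)
  if (nrow(markers) > 0)
    writeLines(paste(markers$event_id, markers$sample, sep = ","), con)
  invisible(path)
}

#' Read an observer's labels from TSV
#'
#' Expects tab-separated columns `event_id` and `label`. Non-IED synonyms are
#' normalized to the reserved `NON_IED` label.
#'
#' @param path TSV path.
#' @param observer_id identifier recorded on the returned classification.
#' @return An [classification] object.
#' @export
read_labels <- function(path, observer_id) {
  df <- read.delim(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("event_id", "label") %in% names(df)))
    stop_ied("label TSV must have columns event_id<TAB>label; found: ",
             paste(names(df), collapse = ","))
  classification(observer_id, df)
}

#' Write an observer's labels to TSV
#' @param c an [classification] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(c, path) {
  df <- data.frame(event_id = names(c$labels), label = unname(c$labels))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
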