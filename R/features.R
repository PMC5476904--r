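# Wavelet features and deviation-from-normality feature selection.

# One Haar analysis step: returns approximation and detail halves.
.haar_step <- function(x) {
  odd <- x[seq(1, length(x), by = 2)]
  even <- x[seq(2, length(x), by = 2)]
  list(a = (odd + even) / sqrt(2), d = (odd - even) / sqrt(2))
}

# Multilevel Haar DWT; returns c(a_L, d_L, d_{L-1}, ..., d_1), length = length(x)
# (x must already be a multiple of 2^levels).
haar_dwt <- function(x, levels) {
  if (length(x) %% 2^levels != 0)
    stop_ied("length ", length(x), " is not a multiple of 2^", levels)
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- .haar_step(a)
    a <- s$a
    details[[l]] <- s$d
  }
  c(a, unlist(rev(details)))
}

#' Wavelet features of meta-IEDs
#'
#' Computes a multilevel discrete Haar wavelet decomposition of every
#' meta-IED vector. Vectors are padded to the next multiple of `2^levels` by
#' edge replication (repeating the last sample), which avoids the spurious
#' boundary coefficients zero-padding would create. Every coefficient is kept
#' as a feature; the informative subset is chosen later by
#' [select_features]. The wavelet transform concentrates spike morphology
#' into few coefficients at matched scales, which is what makes the
#' subsequent small feature set sufficient for clustering.
#'
#' @param meta a `meta_ied_set` (or any events x length numeric matrix).
#' @param wavelet wavelet family; only `"haar"` is implemented.
#' @param levels decomposition depth.
#' @return An object of class `feature_matrix` with `event_ids`, `features`
#'   (events x padded-length matrix) and an empty `selected` slot.
#' @export
wavelet_features <- function(meta, wavelet = "haar", levels = 4) {
  if (wavelet != "haar")
    stop_ied("unsupported wavelet '", wavelet, "'; only 'haar' is implemented")
  vectors <- if (inherits(meta, "meta_ied_set")) meta$vectors else as.matrix(meta)
  if (ncol(vectors) < 1) stop_ied("empty meta-IED vectors")
  block <- 2^levels
  if (ncol(vectors) < block)
    stop_ied("vector length ", ncol(vectors), " too short for ", levels,
             " decomposition levels (needs >= ", block, ")")
  padded_len <- block * ceiling(ncol(vectors) / block)
  n_pad <- padded_len - ncol(vectors)
  feats <- t(apply(vectors, 1, function(v) {
    haar_dwt(c(v, rep(v[length(v)], n_pad)), levels)
  }))
  ids <- rownames(vectors) %||% as.character(seq_len(nrow(vectors)))
  structure(list(event_ids = ids, features = feats, selected = integer(0),
                 wavelet = wavelet, levels = levels),
            class = "feature_matrix")
}

#' Select clustering features by deviation from normality
#'
#' Scores every wavelet coefficient across events with the Lilliefors
#' (Kolmogorov-Smirnov with estimated mean/sd) statistic and keeps the
#' `n_select` coefficients that deviate most from a normal distribution.
#' The rationale: a coefficient that separates event classes is multimodal
#' across events, while a coefficient carrying only noise is approximately
#' normal — so deviation from normality is a class-agnostic usefulness score.
#' Zero-variance coefficients are excluded first; score ties break to the
#' lower coefficient index, making the selection deterministic.
#'
#' @param fm a [wavelet_features] result.
#' @param n_select number of features to keep.
#' @return `fm` with the `selected` slot filled (ordered indices).
#' @export
select_features <- function(fm, n_select = 10) {
  feats <- fm$features
  usable <- which(apply(feats, 2, function(col) var(col) > 0))
  if (length(usable) == 0) {
    warning("all features are constant; empty selection", call. = FALSE)
    fm$selected <- integer(0)
    return(fm)
  }
  score <- vapply(usable, function(j) {
    col <- feats[, j]
    # bounded outlier trim before scoring: drop values beyond 3 robust sd
    # (median/MAD), but never more than 10% of events. Rare extreme
    # outliers (artifacts) cannot then make a noise-only coefficient look
    # non-normal, while a genuine class mode — typically holding far more
    # than 10% of events — can never be trimmed away, so class-driven
    # multimodality keeps its high score.
    dev <- abs(col - median(col))
    s <- stats::mad(col)
    if (s == 0) s <- sd(col)
    out <- which(dev > 3 * s)
    cap <- ceiling(0.1 * length(col))
    if (length(out) > cap) out <- out[order(dev[out], decreasing = TRUE)[seq_len(cap)]]
    col <- if (length(out)) col[-out] else col
    if (length(col) >= 5 && sd(col) > 0)
      unname(nortest::lillie.test(col)$statistic)
    else 0
  }, numeric(1))
  ord <- usable[order(-score, usable)]
  if (length(ord) < n_select) {
    warning("only ", length(ord), " usable features (< ", n_select,
            " requested); selecting all", call. = FALSE)
    fm$selected <- ord
  } else {
    fm$selected <- ord[seq_len(n_select)]
  }
  fm
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d events x %d %s coefficients (%d levels), %d selected\n",
              nrow(x$features), ncol(x$features), x$wavelet, x$levels,
              length(x$selected)))
  invisible(x)
}
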