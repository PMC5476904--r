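# Agreement statistics between classifications: contingency tables,
# counts-weighted variation of information with bootstrap and a
# surrogate-observer null, Bhattacharyya histogram overlap, silver standard,
# sensitivity/specificity, Cohen's kappa, classification-overlap matrices.

.aligned_labels <- function(x, y) {
  ex <- event_ids(x); ey <- event_ids(y)
  if (!setequal(ex, ey)) {
    diff <- c(setdiff(ex, ey), setdiff(ey, ex))
    stop_ied("classifications cover different events; symmetric difference: ",
             paste(diff, collapse = ", "))
  }
  list(x = unname(x$labels[ex]), y = unname(y$labels[ex]), events = ex)
}

#' Contingency table of two classifications
#'
#' Joint counts `r_ij` of events labelled class i by `x` and class j by `y`,
#' over their (identical) event sets. `NON_IED` is counted as an ordinary
#' class here: each classifier's partition includes its non-IED class.
#'
#' @param x,y [classification] objects over the same events.
#' @return Object of class `contingency_table`: integer matrix `counts` with
#'   row/column labels, `row_marginals` (p_i), `col_marginals` (q_j), `n`.
#' @export
contingency <- function(x, y) {
  al <- .aligned_labels(x, y)
  counts <- unclass(table(al$x, al$y))
  structure(list(counts = counts,
                 row_marginals = rowSums(counts),
                 col_marginals = colSums(counts),
                 n = sum(counts)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %d events, %d x %d classes\n", x$n,
              nrow(x$counts), ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

# VI on a raw counts matrix (the workhorse; no container overhead).
.vi_counts <- function(counts) {
  p <- rowSums(counts)
  q <- colSums(counts)
  idx <- which(counts > 0, arr.ind = TRUE)
  r <- counts[idx]
  # the trailing + 0 normalizes IEEE negative zero to plain zero
  -sum(r * (log2(r / p[idx[, 1]]) + log2(r / q[idx[, 2]]))) + 0
}

#' Variation of information between two classifications
#'
#' Counts-weighted variation of information
#' `VI(X,Y) = -sum_ij r_ij * (log2(r_ij/p_i) + log2(r_ij/q_j))`
#' where `r_ij` are joint counts and `p_i`, `q_j` the marginals — note the
#' counts enter unnormalized, so the value scales with the number of events
#' (it equals `N * (H(X) + H(Y) - 2 I(X;Y))` in bits). Zero cells contribute
#' zero. VI is 0 exactly when the two partitions agree perfectly (up to class
#' relabelling), is symmetric, and satisfies the triangle inequality.
#'
#' @param ct a [contingency] table, or a counts matrix.
#' @param normalized if `TRUE`, divide by N to get per-event bits. The
#'   normalized variant is provided for convenience only; all agreement
#'   statistics in this package use the counts-weighted form.
#' @return scalar VI (event-weighted bits, or bits per event if normalized).
#' @export
variation_of_information <- function(ct, normalized = FALSE) {
  counts <- if (inherits(ct, "contingency_table")) ct$counts else as.matrix(ct)
  if (sum(counts) < 1) stop_ied("contingency table is empty")
  vi <- .vi_counts(counts)
  if (normalized) vi / sum(counts) else vi
}

#' Bootstrap distribution of the variation of information
#'
#' Non-parametric bootstrap over events: each replicate resamples the N
#' events with replacement, rebuilds the contingency table (multiplicities
#' respected) and recomputes the counts-weighted VI. Compensates for the
#' small event sample behind each pairwise comparison.
#'
#' @param x,y [classification] objects over the same events.
#' @param n_boot number of replicates.
#' @param seed RNG seed.
#' @param pair_id identifier stored on the result (default "x_id-y_id").
#' @return Object of class `vi_distribution`: `pair_id`, `values` (length
#'   `n_boot`), `n_boot`, `seed`, `point` (the unresampled VI).
#' @export
bootstrap_vi <- function(x, y, n_boot = 1000, seed = NULL, pair_id = NULL) {
  al <- .aligned_labels(x, y)
  n <- length(al$x)
  if (n < 2) stop_ied("need at least 2 shared events")
  xi <- as.integer(factor(al$x))
  yi <- as.integer(factor(al$y))
  kx <- max(xi); ky <- max(yi)
  point <- .vi_counts(matrix(tabulate((yi - 1L) * kx + xi, nbins = kx * ky), kx, ky))
  values <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    .vi_counts(matrix(tabulate((yi[idx] - 1L) * kx + xi[idx], nbins = kx * ky),
                      kx, ky))
  }, numeric(1)))
  structure(list(pair_id = pair_id %||% paste0(x$observer_id, "-", y$observer_id),
                 values = values, n_boot = n_boot, seed = seed, point = point),
            class = "vi_distribution")
}

#' @export
print.vi_distribution <- function(x, ...) {
  cat(sprintf("<vi_distribution> %s: %d values, mean %.2f (sd %.2f)\n",
              x$pair_id, length(x$values), mean(x$values), sd(x$values)))
  invisible(x)
}

#' Surrogate-observer null model for VI
#'
#' Calibrates what VI values arise between classifications that share no
#' structure: each of `n_observers` artificial observers assigns each of
#' `n_events` events independently and uniformly to one of k classes, with k
#' drawn per observer uniformly from `k_range`. VI is computed for every
#' observer pair; two real classifications are called similar when their VI
#' falls below `mean - 2*sd` of this surrogate sample.
#'
#' @param n_events number of events per surrogate classification.
#' @param n_observers number of artificial observers.
#' @param k_range `c(min, max)` class counts to draw from.
#' @param seed RNG seed.
#' @return Object of class `null_model`: `surrogate_vi` (length
#'   `choose(n_observers, 2)`), `mean`, `sd`, `similarity_threshold`,
#'   `n_observers`, `k_range`, `seed`.
#' @export
surrogate_null <- function(n_events = 100, n_observers = 50, k_range = c(2, 9),
                           seed = NULL) {
  if (n_observers < 2) stop_ied("need at least 2 surrogate observers")
  if (k_range[1] < 1 || k_range[2] < k_range[1])
    stop_ied("invalid k_range [", k_range[1], ", ", k_range[2], "]")
  vi <- with_seed(seed, {
    ks <- sample(seq(k_range[1], k_range[2]), n_observers, replace = TRUE)
    obs <- lapply(ks, function(k) sample.int(k, n_events, replace = TRUE))
    pairs <- combn(n_observers, 2)
    vapply(seq_len(ncol(pairs)), function(p) {
      a <- obs[[pairs[1, p]]]; b <- obs[[pairs[2, p]]]
      ka <- max(a); kb <- max(b)
      .vi_counts(matrix(tabulate((b - 1L) * ka + a, nbins = ka * kb), ka, kb))
    }, numeric(1))
  })
  m <- mean(vi); s <- sd(vi)
  structure(list(surrogate_vi = vi, mean = m, sd = s,
                 similarity_threshold = m - 2 * s,
                 n_observers = n_observers, k_range = k_range, seed = seed),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model> %d surrogate pairs: VI mean %.2f, sd %.2f, similarity threshold %.2f\n",
              length(x$surrogate_vi), x$mean, x$sd, x$similarity_threshold))
  invisible(x)
}

#' Test an observed VI against the surrogate null
#'
#' @param observed_vi scalar VI.
#' @param null a [surrogate_null] model.
#' @return list with `similar` (`observed_vi < mean - 2*sd` of the null) and
#'   `empirical_p`, the add-one smoothed one-sided fraction of surrogate
#'   values at or below the observed VI, `(r + 1) / (n + 1)`.
#' @export
similarity_test <- function(observed_vi, null) {
  r <- sum(null$surrogate_vi <= observed_vi)
  list(similar = observed_vi < null$similarity_threshold,
       empirical_p = (r + 1) / (length(null$surrogate_vi) + 1))
}

#' Pool bootstrap VI distributions
#'
#' Concatenates per-pair bootstrap distributions into one (e.g. all WC-H
#' pairs into `WC_all`, all H-H pairs into `H_all`), retaining the source
#' pair ids.
#'
#' @param dists list of `vi_distribution` objects.
#' @param pool_id identifier for the pooled distribution.
#' @return A `vi_distribution` whose `values` is the concatenation.
#' @export
pool_distributions <- function(dists, pool_id) {
  if (length(dists) < 1) stop_ied("nothing to pool")
  structure(list(pair_id = pool_id,
                 values = unlist(lapply(dists, `[[`, "values"), use.names = FALSE),
                 n_boot = sum(vapply(dists, function(d) length(d$values), integer(1))),
                 seed = NULL, point = NA_real_,
                 sources = vapply(dists, `[[`, character(1), "pair_id")),
            class = "vi_distribution")
}

#' Bhattacharyya overlap of two VI distributions
#'
#' Bins both samples on shared equal-width bins spanning their pooled range
#' and returns `100 * sum_b sqrt(p_b * q_b)` over the normalized bin
#' frequencies: 100 means identical histograms, 0 disjoint support.
#'
#' @param a,b `vi_distribution` objects or numeric vectors.
#' @param n_bins number of shared histogram bins.
#' @return overlap percentage in `[0, 100]`.
#' @export
bhattacharyya_overlap <- function(a, b, n_bins = 50) {
  va <- if (inherits(a, "vi_distribution")) a$values else as.numeric(a)
  vb <- if (inherits(b, "vi_distribution")) b$values else as.numeric(b)
  if (length(va) == 0 || length(vb) == 0) stop_ied("empty distribution")
  rng <- range(c(va, vb))
  if (diff(rng) == 0) return(100)         # all values identical in both
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  pa <- tabulate(findInterval(va, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins) / length(va)
  pb <- tabulate(findInterval(vb, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins) / length(vb)
  100 * sum(sqrt(pa * pb))
}

#' Majority-vote silver standard for IED identity
#'
#' In the absence of a gold standard, an event counts as a true IED when at
#' least `min_votes` of the human reviewers gave it a non-`NON_IED` label
#' (default: 2 of 3).
#'
#' @param h_labels list of [classification] objects over the same events
#'   (canonically exactly 3; any odd count works with the majority rule).
#' @param min_votes votes needed to call an event an IED; default the
#'   majority `ceiling((n + 1) / 2)` (= 2 for 3 observers).
#' @return named character vector event_id -> `"IED"` / `"NON_IED"`.
#' @export
silver_standard <- function(h_labels, min_votes = NULL) {
  n_obs <- length(h_labels)
  if (n_obs < 2) stop_ied("need at least 2 observers")
  if (is.null(min_votes)) {
    if (n_obs %% 2 == 0)
      stop_ied("even observer count (", n_obs, ") needs an explicit min_votes")
    min_votes <- (n_obs + 1) / 2
  }
  ev <- event_ids(h_labels[[1]])
  for (h in h_labels[-1]) {
    if (!setequal(event_ids(h), ev))
      stop_ied("observer ", h$observer_id, " covers a different event set")
  }
  votes <- rowSums(vapply(h_labels, function(h) h$labels[ev] != NON_IED,
                          logical(length(ev))))
  setNames(ifelse(votes >= min_votes, "IED", NON_IED), ev)
}

.as_positive <- function(x, events = NULL) {
  if (inherits(x, "ied_classification")) {
    v <- x$labels != NON_IED
    names(v) <- names(x$labels)
  } else if (is.character(x)) {
    v <- normalize_label(x) != NON_IED
    names(v) <- names(x)
  } else v <- as.logical(x)
  if (!is.null(events)) {
    if (!setequal(names(v), events))
      stop_ied("event sets differ: ",
               paste(c(setdiff(names(v), events), setdiff(events, names(v))),
                     collapse = ", "))
    v <- v[events]
  }
  v
}

#' Sensitivity and specificity against a binary truth
#'
#' A classifier calls an event positive when it assigns any non-`NON_IED`
#' class. Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP); a statistic
#' whose denominator is zero (e.g. specificity when the truth contains no
#' non-IED events) is undefined and returned as `NA`.
#'
#' @param c a [classification] (or named logical/character vector).
#' @param truth named vector event_id -> `"IED"`/`"NON_IED"` (e.g. from
#'   [silver_standard]), or named logical.
#' @return list with `sensitivity` and `specificity` (each scalar or `NA`).
#' @export
sensitivity_specificity <- function(c, truth) {
  tpos <- .as_positive(truth)
  cpos <- .as_positive(c, events = names(tpos))
  tp <- sum(cpos & tpos); fn <- sum(!cpos & tpos)
  tn <- sum(!cpos & !tpos); fp <- sum(cpos & !tpos)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Cohen's kappa for binary IED / non-IED agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the
#' marginals of the 2x2 IED/non-IED table. The conventional interpretive cut
#' in this context is `kappa > 0.4` for high inter-rater agreement. When both
#' raters are constant (`p_e = 1`) kappa is defined as 1 if they agree
#' everywhere and 0 otherwise.
#'
#' @param x,y [classification] objects (reduced to IED vs `NON_IED`), named
#'   logical vectors, or `x` may be a 2x2 count matrix (then `y` is omitted).
#' @return scalar kappa.
#' @export
cohens_kappa <- function(x, y = NULL) {
  if (is.matrix(x) && is.null(y)) {
    tab <- x
    if (!all(dim(tab) == c(2, 2))) stop_ied("count matrix must be 2x2")
  } else {
    xp <- .as_positive(x)
    yp <- .as_positive(y, events = names(xp))
    tab <- matrix(c(sum(xp & yp), sum(xp & !yp),
                    sum(!xp & yp), sum(!xp & !yp)), 2, 2, byrow = TRUE)
  }
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 8) {
    return(if (po == 1) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Classification overlap matrix
#'
#' For each reference class i (rows) and comparison class j (columns),
#' `A_ij = r_ij / |ref_i| * 100` with `r_ij` the joint event count — the
#' percentage of reference-class-i events that the other classifier put in
#' class j. Each row sums to 100. The best match per row is the column (or
#' columns, on ties) with the greatest overlap.
#'
#' @param ref,other [classification] objects over the same events; `ref`
#'   defines the rows.
#' @return list with `matrix` (percentages) and `best_match` (named list of
#'   best-matching `other` classes per `ref` class).
#' @export
overlap_matrix <- function(ref, other) {
  ct <- contingency(ref, other)
  sizes <- ct$row_marginals
  empty <- sizes == 0
  if (any(empty)) {
    warning("empty reference class(es) omitted: ",
            paste(names(sizes)[empty], collapse = ", "), call. = FALSE)
  }
  counts <- ct$counts[!empty, , drop = FALSE]
  pct <- counts / rowSums(counts) * 100
  best <- lapply(seq_len(nrow(pct)), function(i) {
    colnames(pct)[pct[i, ] == max(pct[i, ])]
  })
  names(best) <- rownames(pct)
  list(matrix = pct, best_match = best)
}
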