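# Wave_clus-style unsupervised classification: superparamagnetic clustering
# over selected wavelet features, automatic class-count selection, forced
# assignment of leftovers, non-IED rejection.

#' Superparamagnetic clustering of events
#'
#' Runs a q-state Potts model on the K-nearest-neighbour graph of the
#' selected features. Neighbouring events i, j interact with strength
#' `J_ij = (1/Khat) * exp(-d_ij^2 / (2 a^2))` where `d_ij` is their Euclidean
#' distance in selected-feature space, `a` is the mean nearest-neighbour
#' distance and `Khat` the mean graph degree. At each temperature on the grid
#' the model is simulated with Swendsen-Wang sweeps; events whose spin-spin
#' coincidence frequency exceeds 0.5 are linked, and connected components of
#' the linked graph are the clusters at that temperature. In the
#' low-temperature (ferromagnetic) phase everything fuses into one cluster;
#' in the superparamagnetic regime natural groups appear as stable spin
#' domains; at high temperature the system dissolves into fragments. The
#' working temperature is chosen afterwards by [select_classes].
#'
#' @param fm a [select_features] result (non-empty `selected`).
#' @param k_neighbours neighbours per event in the interaction graph.
#' @param t_min,t_max,t_step temperature grid.
#' @param sweeps Swendsen-Wang sweeps per temperature (the first 20% are
#'   burn-in and excluded from the coincidence estimate).
#' @param q number of Potts states.
#' @param corr_threshold spin coincidence frequency above which two
#'   neighbours are linked.
#' @param seed RNG seed; runs are bit-reproducible given the seed.
#' @return An object of class `temperature_map`: `temperatures`,
#'   `assignments` (one integer vector per temperature), `cluster_sizes`
#'   (per temperature, descending).
#' @export
spc_cluster <- function(fm, k_neighbours = 11, t_min = 0.0, t_max = 0.25,
                        t_step = 0.01, sweeps = 500, q = 20,
                        corr_threshold = 0.5, seed = NULL) {
  if (length(fm$selected) == 0) stop_ied("no selected features; run select_features first")
  X <- fm$features[, fm$selected, drop = FALSE]
  n <- nrow(X)
  if (n < 2) stop_ied("need at least 2 events to cluster")
  temps <- seq(t_min, t_max, by = t_step)

  dmat <- as.matrix(dist(X))
  if (max(dmat) == 0) {
    # all events identical in feature space: one cluster at every temperature
    assignments <- rep(list(rep(1L, n)), length(temps))
    return(.temperature_map(temps, assignments, fm$event_ids))
  }

  k <- min(k_neighbours, n - 1)
  # union of directed k-nearest-neighbour edges
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(dmat[i, ])[2:(k + 1)]
    cbind(pmin(i, nb), pmax(i, nb))
  }))
  pairs <- unique(pairs)
  nnd <- vapply(seq_len(n), function(i) min(dmat[i, -i]), numeric(1))
  a <- mean(nnd)
  if (a == 0) a <- 0.1 * mean(dmat[dmat > 0])
  khat <- 2 * nrow(pairs) / n
  J <- (1 / khat) * exp(-dmat[pairs]^2 / (2 * a^2))

  burnin <- floor(sweeps * 0.2)
  assignments <- with_seed(seed,
    .spc_run(n, pairs[, 1] - 1L, pairs[, 2] - 1L, J, temps,
             as.integer(sweeps), as.integer(burnin), as.integer(q),
             corr_threshold))
  .temperature_map(temps, assignments, fm$event_ids)
}

.temperature_map <- function(temps, assignments, event_ids) {
  sizes <- lapply(assignments, function(a) sort(unname(table(a)), decreasing = TRUE))
  structure(list(temperatures = temps, assignments = assignments,
                 cluster_sizes = sizes, event_ids = event_ids),
            class = "temperature_map")
}

#' @export
print.temperature_map <- function(x, ...) {
  cat(sprintf("<temperature_map> %d events, %d temperatures [%g..%g]\n",
              length(x$event_ids), length(x$temperatures),
              min(x$temperatures), max(x$temperatures)))
  n_cl <- vapply(x$cluster_sizes, length, integer(1))
  cat("  clusters per temperature:", paste(n_cl, collapse = " "), "\n")
  invisible(x)
}

#' Plot cluster sizes against temperature
#'
#' The classic diagnostic: size of the largest clusters as a function of
#' temperature. Stable plateaus in the superparamagnetic regime correspond
#' to the natural classes.
#' @param x a `temperature_map`.
#' @param n_clusters how many of the largest clusters to trace.
#' @param min_cluster_size optional horizontal reference line.
#' @param ... passed to [graphics::matplot].
#' @export
plot.temperature_map <- function(x, n_clusters = 5, min_cluster_size = NULL, ...) {
  sz <- t(vapply(x$cluster_sizes, function(s) {
    out <- rep(0, n_clusters)
    out[seq_len(min(n_clusters, length(s)))] <- s[seq_len(min(n_clusters, length(s)))]
    out
  }, numeric(n_clusters)))
  graphics::matplot(x$temperatures, sz, type = "l", lty = 1,
                    xlab = "temperature", ylab = "cluster size (events)", ...)
  if (!is.null(min_cluster_size))
    graphics::abline(h = min_cluster_size, lty = 3)
  invisible(x)
}

#' Choose the working temperature and name the classes
#'
#' Scans the temperature map for the temperature that maximizes the number
#' of clusters holding at least `min_cluster_size` events (the lowest such
#' temperature when several attain the maximum). Accepted clusters become
#' IED classes named `"A"`, `"B"`, ... in descending size order; all other
#' events are left unassigned (empty label) for [force_assign] to resolve.
#'
#' @param tm a `temperature_map`.
#' @param min_cluster_size smallest event count that makes a cluster a class.
#' @return A partial [classification] (observer `"WC"`) where unassigned
#'   events carry `NA`.
#' @export
select_classes <- function(tm, min_cluster_size = max(5, ceiling(0.05 * length(tm$event_ids)))) {
  n_accept <- vapply(tm$cluster_sizes, function(s) sum(s >= min_cluster_size),
                     integer(1))
  if (max(n_accept) == 0) {
    warning("no cluster ever reaches min_cluster_size = ", min_cluster_size,
            "; all events unassigned", call. = FALSE)
    labels <- rep(NA_character_, length(tm$event_ids))
    names(labels) <- tm$event_ids
    return(structure(list(observer_id = "WC", labels = labels,
                          t_star = NA_real_, min_cluster_size = min_cluster_size),
                     class = c("wc_partial", "ied_classification")))
  }
  i_star <- max(which(n_accept == max(n_accept)))  # highest-T maximizer
  assign <- tm$assignments[[i_star]]
  tab <- sort(table(assign), decreasing = TRUE)
  accepted <- as.integer(names(tab)[tab >= min_cluster_size])
  class_names <- setNames(LETTERS[seq_along(accepted)], accepted)
  labels <- class_names[as.character(assign)]   # NA for unaccepted clusters
  names(labels) <- tm$event_ids
  structure(list(observer_id = "WC", labels = labels,
                 t_star = tm$temperatures[i_star],
                 min_cluster_size = min_cluster_size),
            class = c("wc_partial", "ied_classification"))
}

#' Force-assign leftover events or reject them as non-IED
#'
#' Every event left unassigned by [select_classes] is compared with the
#' accepted classes in selected-feature space: it joins the class with the
#' nearest centroid if its distance is at most `radius_factor` times that
#' class's median event-to-centroid distance, and is labelled `NON_IED`
#' otherwise. This mirrors the template-matching step of spike sorting:
#' stragglers of a genuine class sit near its centroid, artifacts do not.
#'
#' @param fm the [select_features] result the clustering ran on.
#' @param partial the [select_classes] output.
#' @param radius_factor acceptance radius in units of the class's median
#'   event-to-centroid distance.
#' @return A complete [classification] (no `NA` labels).
#' @export
force_assign <- function(fm, partial, radius_factor = 3.0) {
  labels <- partial$labels
  X <- fm$features[, fm$selected, drop = FALSE]
  un <- which(is.na(labels))
  classes <- setdiff(unique(labels[!is.na(labels)]), NON_IED)
  if (length(un) > 0 && length(classes) > 0) {
    cent <- t(vapply(classes, function(cl) colMeans(X[labels %in% cl, , drop = FALSE]),
                     numeric(ncol(X))))
    radius <- vapply(classes, function(cl) {
      members <- X[labels %in% cl, , drop = FALSE]
      d <- sqrt(rowSums((members - matrix(cent[cl, ], nrow(members),
                                          ncol(X), byrow = TRUE))^2))
      median(d)
    }, numeric(1))
    for (i in un) {
      d <- sqrt(rowSums((cent - matrix(X[i, ], nrow(cent), ncol(X), byrow = TRUE))^2))
      j <- which.min(d)
      labels[i] <- if (d[j] <= radius_factor * radius[j]) classes[j] else NON_IED
    }
  } else if (length(un) > 0) {
    labels[un] <- NON_IED
  }
  out <- classification(partial$observer_id, labels)
  out$t_star <- partial$t_star
  out
}

#' Apply manual review edits
#'
#' File-driven stand-in for visual verification of the automatic classes:
#' replaces the labels of the listed events and keeps an audit log of the
#' changes on the result (`attr(, "audit")`).
#'
#' @param c a [classification].
#' @param edits data frame with columns `event_id`, `new_label` (or a list of
#'   such pairs).
#' @return The edited [classification].
#' @export
apply_manual_review <- function(c, edits) {
  if (!is.data.frame(edits))
    edits <- do.call(rbind, lapply(edits, function(e)
      data.frame(event_id = e[[1]], new_label = e[[2]])))
  if (is.null(edits) || nrow(edits) == 0) return(c)
  unknown <- setdiff(edits$event_id, names(c$labels))
  if (length(unknown))
    stop_ied("edit refers to unknown event(s): ", paste(unknown, collapse = ", "))
  audit <- data.frame(event_id = edits$event_id,
                      old = unname(c$labels[edits$event_id]),
                      new = normalize_label(edits$new_label))
  c$labels[edits$event_id] <- normalize_label(edits$new_label)
  attr(c, "audit") <- rbind(attr(c, "audit"), audit)
  c
}

#' Per-class average waveforms
#'
#' Arithmetic mean waveform of each class, per channel, restricted to a
#' window around the aligned peak (default 50 ms before to 150 ms after,
#' i.e. 200 ms). The `NON_IED` class is included for inspection; empty
#' classes are omitted with a warning.
#'
#' @param epochs an [epoch_set].
#' @param c a [classification] over the same events.
#' @param window_s `c(start, end)` in seconds relative to the aligned peak;
#'   must lie inside the epoch window.
#' @return Named list of channels x samples matrices, one per class.
#' @export
class_average <- function(epochs, c, window_s = c(-0.050, 0.150)) {
  if (window_s[1] < -epochs$window[1] || window_s[2] > epochs$window[2])
    stop_ied("window_s [", window_s[1], ", ", window_s[2],
             "] exceeds the epoch window [-", epochs$window[1], ", ",
             epochs$window[2], "]")
  peak_idx <- round(epochs$window[1] * epochs$fs)    # 0-based
  i0 <- peak_idx + round(window_s[1] * epochs$fs)
  n_out <- round((window_s[2] - window_s[1]) * epochs$fs)
  idx <- (i0 + 1):(i0 + n_out)                       # R indices

  labs <- c$labels[epochs$event_ids]
  out <- list()
  for (cl in unique(labs)) {
    members <- which(labs == cl)
    if (length(members) == 0) next
    sub <- epochs$data[members, , idx, drop = FALSE]
    avg <- apply(sub, c(2, 3), mean)
    rownames(avg) <- epochs$channels
    out[[cl]] <- avg
  }
  empties <- setdiff(unique(c$labels), names(out))
  if (length(empties))
    warning("empty class(es) omitted: ", paste(empties, collapse = ", "),
            call. = FALSE)
  out
}

#' Classify meta-IEDs
#'
#' The one-call fitting interface over the full unsupervised chain:
#' [wavelet_features] -> [select_features] -> [spc_cluster] ->
#' [select_classes] -> [force_assign]. The number of classes is determined
#' automatically from the temperature map; events that fit no class are
#' labelled `NON_IED`.
#'
#' @param meta a `meta_ied_set` from [build_meta_ieds].
#' @param wavelet,levels passed to [wavelet_features].
#' @param n_select passed to [select_features].
#' @param k_neighbours,t_min,t_max,t_step,sweeps,q,corr_threshold passed to
#'   [spc_cluster].
#' @param min_cluster_size passed to [select_classes]; default
#'   `max(5, ceiling(0.05 * n_events))`.
#' @param radius_factor passed to [force_assign].
#' @param observer_id label recorded on the resulting classification.
#' @param seed RNG seed; the whole fit is a deterministic function of
#'   (meta-IED matrix, parameters, seed).
#' @return An object of class `wc_fit`: `classification`, `features`
#'   (`feature_matrix`), `temperature_map`, `t_star`, `params`.
#' @export
wc_classify <- function(meta, wavelet = "haar", levels = 4, n_select = 10,
                        k_neighbours = 11, t_min = 0.0, t_max = 0.25,
                        t_step = 0.01, sweeps = 500, q = 20,
                        corr_threshold = 0.5,
                        min_cluster_size = NULL, radius_factor = 3.0,
                        observer_id = "WC", seed = NULL) {
  fm <- wavelet_features(meta, wavelet = wavelet, levels = levels)
  fm <- select_features(fm, n_select = n_select)
  tm <- spc_cluster(fm, k_neighbours = k_neighbours, t_min = t_min,
                    t_max = t_max, t_step = t_step, sweeps = sweeps, q = q,
                    corr_threshold = corr_threshold, seed = seed)
  if (is.null(min_cluster_size))
    min_cluster_size <- max(5, ceiling(0.05 * length(meta$event_ids)))
  partial <- select_classes(tm, min_cluster_size = min_cluster_size)
  partial$observer_id <- observer_id
  cls <- force_assign(fm, partial, radius_factor = radius_factor)
  structure(list(classification = cls, features = fm, temperature_map = tm,
                 t_star = cls$t_star,
                 params = list(wavelet = wavelet, levels = levels,
                               n_select = n_select, k_neighbours = k_neighbours,
                               t_min = t_min, t_max = t_max, t_step = t_step,
                               sweeps = sweeps, q = q,
                               corr_threshold = corr_threshold,
                               min_cluster_size = min_cluster_size,
                               radius_factor = radius_factor, seed = seed)),
            class = "wc_fit")
}

#' @export
print.wc_fit <- function(x, ...) {
  sizes <- sort(table(x$classification$labels), decreasing = TRUE)
  cat(sprintf("<wc_fit> %d events -> %d classes at T* = %s\n",
              length(x$classification$labels),
              sum(names(sizes) != NON_IED),
              format(x$t_star)))
  print(sizes)
  invisible(x)
}

#' @export
summary.wc_fit <- function(object, ...) {
  sizes <- sort(table(object$classification$labels), decreasing = TRUE)
  out <- list(n_events = length(object$classification$labels),
              n_classes = sum(names(sizes) != NON_IED),
              class_sizes = sizes, t_star = object$t_star,
              n_features = length(object$features$selected),
              params = object$params)
  class(out) <- "summary.wc_fit"
  out
}

#' @export
print.summary.wc_fit <- function(x, ...) {
  cat(sprintf("Wave_clus-style classification of %d events\n", x$n_events))
  cat(sprintf("  %d IED classes at working temperature %s (%d selected features)\n",
              x$n_classes, format(x$t_star), x$n_features))
  print(x$class_sizes)
  invisible(x)
}

#' @export
plot.wc_fit <- function(x, ...) {
  plot(x$temperature_map, min_cluster_size = x$params$min_cluster_size,
       main = "Cluster sizes vs temperature", ...)
}
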