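#' Run the full agreement analysis
#'
#' Orchestrates the comparison of one automated classification against a
#' panel of human classifications of the same events: point and bootstrap VI
#' for every automated-human and human-human pair, pooling into `WC_all` and
#' `H_all`, a surrogate-observer null with its `mean - 2*sd` similarity
#' threshold, the Bhattacharyya overlap of the two pooled distributions,
#' and — when the panel has an odd number (canonically 3) of humans — the
#' majority-vote silver standard with per-classifier sensitivity/specificity
#' and pairwise Cohen's kappa, plus classification-overlap matrices of the
#' automated classes against each human. Deterministic given `seed`.
#'
#' @param wc the automated [classification].
#' @param humans list of at least two human [classification]s (same events).
#' @param n_boot bootstrap replicates per pair.
#' @param n_observers,k_range surrogate null parameters.
#' @param n_bins shared histogram bins for the Bhattacharyya overlap.
#' @param kappa_threshold interpretive cut reported next to each kappa.
#' @param seed RNG seed for bootstrap and surrogates.
#' @return Object of class `agreement_report`.
#' @export
run_validation <- function(wc, humans, n_boot = 1000, n_observers = 50,
                           k_range = c(2, 9), n_bins = 50,
                           kappa_threshold = 0.4, seed = NULL) {
  if (length(humans) < 2) stop_ied("need at least 2 human classifications")
  all_cls <- c(list(wc), humans)
  ev <- event_ids(wc)
  for (h in humans)
    if (!setequal(event_ids(h), ev))
      stop_ied("observer ", h$observer_id, " covers a different event set; ",
               "symmetric difference: ",
               paste(c(setdiff(event_ids(h), ev), setdiff(ev, event_ids(h))),
                     collapse = ", "))

  pair_idx <- combn(length(all_cls), 2)
  n_pairs <- ncol(pair_idx)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_pairs + 1))

  null <- surrogate_null(n_events = length(ev), n_observers = n_observers,
                         k_range = k_range, seed = seeds[n_pairs + 1])

  pairs <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    a <- all_cls[[pair_idx[1, p]]]
    b <- all_cls[[pair_idx[2, p]]]
    dist_p <- bootstrap_vi(a, b, n_boot = n_boot, seed = seeds[p])
    sim <- similarity_test(dist_p$point, null)
    pairs[[p]] <- list(pair_id = dist_p$pair_id,
                       type = if (pair_idx[1, p] == 1) "WC-H" else "H-H",
                       point_vi = dist_p$point,
                       boot = dist_p,
                       boot_mean = mean(dist_p$values),
                       boot_sd = sd(dist_p$values),
                       similar = sim$similar,
                       empirical_p = sim$empirical_p)
  }
  names(pairs) <- vapply(pairs, `[[`, character(1), "pair_id")

  wc_all <- pool_distributions(lapply(Filter(function(p) p$type == "WC-H", pairs),
                                      `[[`, "boot"), "WC_all")
  h_all <- pool_distributions(lapply(Filter(function(p) p$type == "H-H", pairs),
                                     `[[`, "boot"), "H_all")
  overlap_pct <- bhattacharyya_overlap(wc_all, h_all, n_bins = n_bins)

  silver <- sens_spec <- kappas <- NULL
  if (length(humans) %% 2 == 1) {
    silver <- silver_standard(humans)
    sens_spec <- lapply(all_cls, sensitivity_specificity, truth = silver)
    names(sens_spec) <- vapply(all_cls, `[[`, character(1), "observer_id")
    kappas <- lapply(seq_len(n_pairs), function(p) {
      a <- all_cls[[pair_idx[1, p]]]; b <- all_cls[[pair_idx[2, p]]]
      k <- cohens_kappa(a, b)
      list(pair_id = paste0(a$observer_id, "-", b$observer_id),
           kappa = k, high_agreement = k > kappa_threshold)
    })
    names(kappas) <- vapply(kappas, `[[`, character(1), "pair_id")
  }

  overlaps <- lapply(humans, function(h) overlap_matrix(wc, h))
  names(overlaps) <- vapply(humans, `[[`, character(1), "observer_id")

  structure(list(schema_version = "1.0",
                 n_events = length(ev),
                 observers = vapply(all_cls, `[[`, character(1), "observer_id"),
                 pairs = pairs,
                 wc_all = wc_all, h_all = h_all,
                 bhattacharyya_overlap_pct = overlap_pct,
                 null = null,
                 silver_standard = silver,
                 sensitivity_specificity = sens_spec,
                 kappa = kappas,
                 overlap_matrices = overlaps,
                 params = list(n_boot = n_boot, n_observers = n_observers,
                               k_range = k_range, n_bins = n_bins,
                               kappa_threshold = kappa_threshold, seed = seed)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d events, observers: %s\n", x$n_events,
              paste(x$observers, collapse = ", ")))
  cat(sprintf("  null: VI mean %.2f (sd %.2f), similarity threshold %.2f\n",
              x$null$mean, x$null$sd, x$null$similarity_threshold))
  for (p in x$pairs)
    cat(sprintf("  %-8s VI %8.2f  boot %8.2f (sd %6.2f)  %s\n", p$pair_id,
                p$point_vi, p$boot_mean, p$boot_sd,
                if (p$similar) "similar" else "not similar"))
  cat(sprintf("  WC_all / H_all Bhattacharyya overlap: %.1f%%\n",
              x$bhattacharyya_overlap_pct))
  invisible(x)
}

#' @export
summary.agreement_report <- function(object, ...) {
  print(object)
  if (!is.null(object$sensitivity_specificity)) {
    cat("  sensitivity / specificity vs silver standard:\n")
    for (id in names(object$sensitivity_specificity)) {
      ss <- object$sensitivity_specificity[[id]]
      cat(sprintf("    %-4s sens %s  spec %s\n", id,
                  format(ss$sensitivity, digits = 3),
                  format(ss$specificity, digits = 3)))
    }
  }
  if (!is.null(object$kappa)) {
    cat("  Cohen's kappa (binary IED/non-IED):\n")
    for (k in object$kappa)
      cat(sprintf("    %-8s %6.3f%s\n", k$pair_id, k$kappa,
                  if (k$high_agreement) " (high agreement)" else ""))
  }
  invisible(object)
}

#' Plot pooled VI distributions
#'
#' Overlaid histograms of the pooled automated-human (`WC_all`) and
#' human-human (`H_all`) bootstrap VI distributions, with the surrogate null
#' threshold marked.
#' @param x an `agreement_report`.
#' @param ... passed to [graphics::hist].
#' @export
plot.agreement_report <- function(x, ...) {
  vals <- c(x$wc_all$values, x$h_all$values)
  breaks <- seq(min(vals), max(vals), length.out = x$params$n_bins + 1)
  h1 <- graphics::hist(x$wc_all$values, breaks = breaks, plot = FALSE)
  h2 <- graphics::hist(x$h_all$values, breaks = breaks, plot = FALSE)
  ylim <- c(0, max(h1$counts, h2$counts))
  graphics::plot(h1, col = grDevices::rgb(0, 0, 1, 0.5), ylim = ylim,
                 xlab = "VI (event-weighted bits)",
                 main = "Pooled VI: WC_all vs H_all", ...)
  graphics::plot(h2, col = grDevices::rgb(1, 0.6, 0, 0.5), add = TRUE)
  graphics::abline(v = x$null$similarity_threshold, lty = 2)
  graphics::legend("topright", c("WC_all", "H_all", "null mean - 2 sd"),
                   fill = c(grDevices::rgb(0, 0, 1, 0.5),
                            grDevices::rgb(1, 0.6, 0, 0.5), NA),
                   border = c("black", "black", NA),
                   lty = c(NA, NA, 2))
  invisible(x)
}

# Canonical (fixed key order, NA -> null) list form of a report for JSON.
.report_to_list <- function(report) {
  num <- function(x) if (length(x) == 0 || is.na(x)) NULL else unname(x)
  pairs <- lapply(report$pairs, function(p) list(
    pair_id = p$pair_id, type = p$type, point_vi = num(p$point_vi),
    boot_mean = num(p$boot_mean), boot_sd = num(p$boot_sd),
    n_boot = p$boot$n_boot, similar = p$similar,
    empirical_p = num(p$empirical_p)))
  ss <- if (is.null(report$sensitivity_specificity)) NULL else
    lapply(report$sensitivity_specificity, function(s)
      list(sensitivity = num(s$sensitivity), specificity = num(s$specificity)))
  kp <- if (is.null(report$kappa)) NULL else
    lapply(report$kappa, function(k)
      list(kappa = num(k$kappa), high_agreement = k$high_agreement))
  # note: multi-valued fields are emitted as lists (not atomic vectors) so
  # that a parsed report re-serializes byte-identically
  om <- lapply(report$overlap_matrices, function(o) list(
    rows = as.list(rownames(o$matrix)), cols = as.list(colnames(o$matrix)),
    percent = apply(o$matrix, 1, function(r) as.list(unname(r)),
                    simplify = FALSE),
    best_match = lapply(o$best_match, function(b)
      if (length(b) > 1) as.list(b) else b)))
  list(schema_version = report$schema_version,
       n_events = report$n_events,
       observers = as.list(report$observers),
       null = list(mean = num(report$null$mean), sd = num(report$null$sd),
                   similarity_threshold = num(report$null$similarity_threshold),
                   n_observers = report$null$n_observers,
                   k_range = as.list(report$null$k_range)),
       pairs = pairs,
       pooled = list(
         wc_all = list(n = length(report$wc_all$values),
                       mean = num(mean(report$wc_all$values)),
                       sd = num(sd(report$wc_all$values))),
         h_all = list(n = length(report$h_all$values),
                      mean = num(mean(report$h_all$values)),
                      sd = num(sd(report$h_all$values)))),
       bhattacharyya_overlap_pct = num(report$bhattacharyya_overlap_pct),
       silver_standard = if (is.null(report$silver_standard)) NULL else
         as.list(report$silver_standard),
       sensitivity_specificity = ss,
       kappa = kp,
       overlap_matrices = om,
       params = list(n_boot = report$params$n_boot,
                     n_observers = report$params$n_observers,
                     k_range = as.list(report$params$k_range),
                     n_bins = report$params$n_bins,
                     kappa_threshold = report$params$kappa_threshold,
                     seed = report$params$seed))
}

#' Write an agreement report as JSON
#'
#' Serializes all per-pair and pooled statistics with a fixed, canonical key
#' order; undefined statistics (e.g. specificity with no negative events)
#' become JSON `null`, never 0. Re-serializing a parsed report is
#' byte-identical.
#'
#' @param report an `agreement_report` (or a list parsed from one by
#'   [jsonlite::fromJSON]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  lst <- if (inherits(report, "agreement_report")) .report_to_list(report)
         else report
  json <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
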