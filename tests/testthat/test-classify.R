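test_that("Haar features: padding, counts and coefficient structure", {
  # constant vector: every detail coefficient is zero
  fm <- wavelet_features(matrix(7, 1, 64), levels = 4)
  expect_equal(ncol(fm$features), 64)
  expect_true(all(abs(fm$features[1, -(1:4)]) < 1e-12))
  expect_true(all(abs(fm$features[1, 1:4] - 7 * 4) < 1e-12))  # a4 = 7*sqrt(16)

  # length 750 pads by edge replication to the next multiple of 16
  fm2 <- wavelet_features(matrix(rnorm(750), 1), levels = 4)
  expect_equal(ncol(fm2$features), 752)

  # a single Haar step (-1 first half, +1 second half, length 16):
  # exactly one dominant coefficient, at the coarsest detail level
  x <- matrix(c(rep(-1, 8), rep(1, 8)), 1)
  fm3 <- wavelet_features(x, levels = 4)
  co <- fm3$features[1, ]
  expect_equal(which(abs(co) > 1e-12), 2L)         # d4 slot, right after a4
  expect_equal(co[2], -4)                          # hand Haar: -16/sqrt(16)

  expect_error(wavelet_features(matrix(1, 1, 8), levels = 4), "levels")
})

test_that("feature selection ranks multimodal coefficients first", {
  set.seed(10)
  n <- 200
  feats <- matrix(rnorm(n * 20), n, 20)
  feats[, 7] <- c(rnorm(n / 2, -6), rnorm(n / 2, 6))   # clearly bimodal
  fm <- structure(list(event_ids = as.character(1:n), features = feats,
                       selected = integer(0), wavelet = "haar", levels = 4),
                  class = "feature_matrix")
  sel <- select_features(fm, 10)
  expect_equal(sel$selected[1], 7L)
  expect_length(sel$selected, 10)
  expect_identical(sel$selected, select_features(fm, 10)$selected)

  const <- fm
  const$features <- matrix(3, n, 5)
  expect_warning(out <- select_features(const, 10), "constant")
  expect_length(out$selected, 0)

  few <- fm
  few$features <- feats[, 1:4]
  expect_warning(out2 <- select_features(few, 10), "selecting all")
  expect_length(out2$selected, 4)
})

test_that("superparamagnetic clustering resolves two well-separated blobs", {
  set.seed(20)
  X <- rbind(matrix(rnorm(200), 100, 2),
             matrix(rnorm(200, mean = 10), 100, 2))
  fm <- structure(list(event_ids = sprintf("e%03d", 1:200), features = X,
                       selected = 1:2, wavelet = "haar", levels = 4),
                  class = "feature_matrix")
  tm <- spc_cluster(fm, seed = 1)

  # ferromagnetic limit: at T = 0 each connected component of the neighbour
  # graph fuses into one cluster (the 10-sigma gap disconnects the blobs)
  expect_lte(length(tm$cluster_sizes[[1]]), 2)
  expect_equal(tm$cluster_sizes[[1]][1], 100)

  km <- kmeans(X, centers = 2, nstart = 5)$cluster   # independent oracle
  ok <- vapply(seq_along(tm$temperatures), function(i) {
    a <- tm$assignments[[i]]
    sizes <- sort(table(a), decreasing = TRUE)
    if (length(sizes) != 2 || any(abs(sizes - 100) > 5)) return(FALSE)
    agree <- max(mean((a == a[1]) == (km == km[1])),
                 mean((a == a[1]) != (km == km[1])))
    agree >= 0.98
  }, logical(1))
  expect_true(any(ok))

  expect_identical(spc_cluster(fm, seed = 1)$assignments, tm$assignments)
})

test_that("identical points collapse to a single cluster at every temperature", {
  fm <- structure(list(event_ids = sprintf("e%d", 1:30),
                       features = matrix(1, 30, 3), selected = 1:3),
                  class = "feature_matrix")
  tm <- spc_cluster(fm, seed = 2)
  expect_true(all(vapply(tm$cluster_sizes,
                         function(s) length(s) == 1 && s[1] == 30,
                         logical(1))))
})

test_that("a connected cloud is one cluster in the ferromagnetic limit", {
  set.seed(21)
  fm <- structure(list(event_ids = sprintf("e%d", 1:80),
                       features = matrix(rnorm(160), 80, 2), selected = 1:2),
                  class = "feature_matrix")
  tm <- spc_cluster(fm, t_min = 0, t_max = 0.02, t_step = 0.01, seed = 3)
  expect_equal(tm$cluster_sizes[[1]][1], 80)
})

test_that("the working temperature maximizes the accepted-cluster count", {
  mk_tm <- function(assignments, temps) {
    iedclust:::.temperature_map(temps, assignments,
                                sprintf("e%02d", seq_along(assignments[[1]])))
  }
  # one all-events cluster everywhere -> a single class holding everything
  tm1 <- mk_tm(list(rep(1L, 40), rep(1L, 40)), c(0, 0.01))
  c1 <- select_classes(tm1, min_cluster_size = 5)
  expect_true(all(c1$labels == "A"))

  # three accepted clusters at one temperature beat one elsewhere
  a3 <- rep(1:3, c(20, 12, 8))
  tm2 <- mk_tm(list(rep(1L, 40), a3, rep(1:8, each = 5)), c(0, 0.05, 0.10))
  c2 <- select_classes(tm2, min_cluster_size = 10)
  expect_equal(c2$t_star, 0.05)
  expect_equal(as.integer(table(c2$labels)[c("A", "B")]), c(20L, 12L))
  expect_true(all(is.na(c2$labels[a3 == 3])))      # below min size: unassigned

  # two temperatures tie on the count: the higher one is the working point
  tm3 <- mk_tm(list(rep(1L, 40), a3, a3), c(0, 0.05, 0.06))
  expect_equal(select_classes(tm3, min_cluster_size = 10)$t_star, 0.06)

  # nothing ever reaches the minimum size -> everything left unassigned
  tm4 <- mk_tm(list(rep(1:20, 2)), 0.1)
  expect_warning(c4 <- select_classes(tm4, min_cluster_size = 30), "unassigned")
  expect_true(all(is.na(c4$labels)))
})

test_that("forced assignment joins near events and rejects far ones", {
  set.seed(30)
  X <- rbind(matrix(rnorm(60 * 2, sd = 1), 60, 2),
             matrix(rnorm(60 * 2, mean = 12), 60, 2),
             c(0, 0),                               # at class-1 centroid
             c(1e4, 1e4))                           # absurdly far
  fm <- structure(list(event_ids = sprintf("e%03d", 1:122), features = X,
                       selected = 1:2), class = "feature_matrix")
  labels <- c(rep("A", 60), rep("B", 60), NA, NA)
  names(labels) <- fm$event_ids
  partial <- structure(list(observer_id = "WC", labels = labels, t_star = 0.05),
                       class = c("wc_partial", "ied_classification"))
  out <- force_assign(fm, partial)
  expect_equal(unname(out$labels["e121"]), "A")
  expect_equal(unname(out$labels["e122"]), "NON_IED")

  full <- partial
  full$labels[121:122] <- c("A", "B")
  expect_equal(force_assign(fm, full)$labels, full$labels)
})

test_that("manual review edits labels and keeps an audit trail", {
  c0 <- cls(c("A", "A", "B"), "WC")
  expect_equal(apply_manual_review(c0, data.frame()), c0)
  c1 <- apply_manual_review(c0, data.frame(event_id = "e002",
                                           new_label = "non-IED"))
  expect_equal(sum(c1$labels != c0$labels), 1L)
  expect_equal(unname(c1$labels["e002"]), "NON_IED")
  expect_equal(attr(c1, "audit")$old, "A")
  expect_error(apply_manual_review(c0, data.frame(event_id = "zz",
                                                  new_label = "A")), "zz")
})

test_that("class averages are per-channel means over the requested window", {
  fs <- 250
  arr <- array(0, dim = c(3, 2, 75))
  arr[1, , ] <- 1
  arr[2, , ] <- matrix(rep(1:75, each = 2), 2, 75, byrow = FALSE) / 10
  arr[3, , ] <- -arr[2, , ]
  ep <- epoch_set(arr, c("e1", "e2", "e3"), c("c1", "c2"), c(0.1, 0.2), fs)
  cl <- classification("WC", c(e1 = "A", e2 = "B", e3 = "B"))
  avg <- class_average(ep, cl)
  expect_equal(dim(avg$A), c(2, 50))               # 200 ms at 250 Hz
  expect_equal(avg$A[1, ], rep(1, 50))             # single event: its own curve
  expect_equal(avg$B, matrix(0, 2, 50), ignore_attr = TRUE)  # v and -v cancel
  expect_error(class_average(ep, cl, window_s = c(-0.2, 0.1)), "window")
})

test_that("the full classification is bit-reproducible under a fixed seed", {
  p <- run_pipeline(3)
  fit2 <- wc_classify(p$meta, seed = 42)
  expect_identical(p$fit$classification$labels, fit2$classification$labels)
  expect_identical(p$fit$t_star, fit2$t_star)
})
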