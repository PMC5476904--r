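test_that("contingency tables count joint labels over the shared events", {
  x <- cls(rep(c("A", "B", "C"), c(20, 30, 50)))
  ct <- contingency(x, x)
  expect_equal(ct$n, 100)
  expect_equal(diag(ct$counts), c(A = 20, B = 30, C = 50))
  expect_equal(sum(ct$counts) - sum(diag(ct$counts)), 0)

  a <- cls(c("A", "A", "B", "B"))
  b <- cls(c("C", "D", "C", "D"))
  ct2 <- contingency(a, b)
  expect_equal(unclass(ct2$counts), matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(ct2$row_marginals, c(A = 2, B = 2))

  short <- classification("Y", c(e001 = "A", e002 = "A", e003 = "B"))
  expect_error(contingency(a, short), "e004")
})

test_that("counts-weighted VI matches its closed forms and invariances", {
  x <- cls(rep(c("A", "B", "C"), c(20, 30, 50)))
  expect_identical(variation_of_information(contingency(x, x)), 0)

  # hand computation: each unit cell contributes -1*(log2(1/2)+log2(1/2)) = 2
  expect_equal(variation_of_information(matrix(1, 2, 2)), 8)

  # label permutation leaves VI unchanged
  m <- matrix(c(30, 5, 2, 40, 10, 13), 2, 3)
  expect_equal(variation_of_information(m),
               variation_of_information(m[, c(3, 1, 2)]))
  expect_equal(variation_of_information(m),
               variation_of_information(m[c(2, 1), ]))

  # the normalized variant is the same quantity per event
  expect_equal(variation_of_information(m, normalized = TRUE),
               variation_of_information(m) / sum(m))
})

test_that("bootstrap VI resamples events with replacement, seeded", {
  set.seed(40)
  x <- random_partition(100, 4, "WC")
  y <- random_partition(100, 3, "H2")
  d <- bootstrap_vi(x, y, n_boot = 250, seed = 8)
  expect_length(d$values, 250)
  expect_equal(d$pair_id, "WC-H2")
  expect_identical(d$values, bootstrap_vi(x, y, n_boot = 250, seed = 8)$values)

  # perfect agreement survives any resampling
  same <- bootstrap_vi(x, x, n_boot = 100, seed = 1)
  expect_true(all(same$values == 0))

  # the bootstrap mean approaches the point VI (within 3 standard errors)
  big <- bootstrap_vi(x, y, n_boot = 1000, seed = 2)
  se <- sd(big$values) / sqrt(1000)
  expect_lt(abs(mean(big$values) - big$point), 3 * se + 0.05 * big$point)
})

test_that("surrogate observers calibrate the similarity threshold", {
  null <- surrogate_null(100, 50, c(2, 9), seed = 11)
  expect_length(null$surrogate_vi, choose(50, 2))
  expect_equal(null$similarity_threshold, null$mean - 2 * null$sd)
  expect_identical(surrogate_null(100, 50, c(2, 9), seed = 11)$surrogate_vi,
                   null$surrogate_vi)

  # single-class observers agree perfectly with each other
  null1 <- surrogate_null(50, 10, c(1, 1), seed = 3)
  expect_true(all(null1$surrogate_vi == 0))
  expect_equal(null1$similarity_threshold, 0)

  st <- similarity_test(0, null)
  expect_true(st$similar)
  expect_equal(st$empirical_p, 1 / (length(null$surrogate_vi) + 1))
  expect_false(similarity_test(null$mean, null)$similar)
  expect_true(similarity_test(null$similarity_threshold - 1e-9, null)$similar)
})

test_that("pooled distributions concatenate values and keep provenance", {
  ds <- lapply(1:3, function(i)
    structure(list(pair_id = paste0("p", i), values = rnorm(1000) + i,
                   n_boot = 1000, seed = i, point = i),
              class = "vi_distribution"))
  pool <- pool_distributions(ds, "WC_all")
  expect_length(pool$values, 3000)
  expect_equal(pool$sources, c("p1", "p2", "p3"))
  expect_equal(sort(pool$values),
               sort(c(ds[[1]]$values, ds[[2]]$values, ds[[3]]$values)))
  expect_equal(pool_distributions(ds[1], "x")$values, ds[[1]]$values)
})

test_that("Bhattacharyya overlap behaves on the closed-form cases", {
  v <- rnorm(500)
  expect_equal(bhattacharyya_overlap(v, v), 100)
  expect_equal(bhattacharyya_overlap(runif(200, 0, 1), runif(200, 10, 11)), 0)

  # two shared bins with masses (.5,.5) vs (.25,.75): 100*(sqrt(.125)+sqrt(.375))
  a <- c(0.1, 0.2, 0.8, 0.9)
  b <- c(0.1, 0.7, 0.8, 0.9)
  expect_equal(bhattacharyya_overlap(a, b, n_bins = 2),
               100 * (sqrt(0.125) + sqrt(0.375)), tolerance = 1e-10)

  x <- rnorm(300); y <- rnorm(300, 1)
  expect_equal(bhattacharyya_overlap(x, y), bhattacharyya_overlap(y, x))
  o <- bhattacharyya_overlap(x, y)
  expect_gte(o, 0); expect_lte(o, 100)
  expect_equal(bhattacharyya_overlap(rep(2, 10), rep(2, 10)), 100)
})

test_that("the silver standard is a majority vote on IED identity", {
  h <- list(cls(c("A", "NON_IED", "NON_IED"), "H2"),
            cls(c("B", "NON_IED", "NON_IED"), "H3"),
            cls(c("NON_IED", "A", "NON_IED"), "H4"))
  truth <- silver_standard(h)
  expect_equal(unname(truth), c("IED", "NON_IED", "NON_IED"))
  expect_error(silver_standard(h[1:2]), "min_votes")
  expect_equal(unname(silver_standard(h[1:2], min_votes = 1)[1]), "IED")
})

test_that("sensitivity and specificity handle undefined denominators", {
  truth <- c(rep("IED", 8), rep("NON_IED", 2))
  names(truth) <- sprintf("e%03d", 1:10)
  hit <- cls(c(rep("A", 7), "NON_IED", "NON_IED", "NON_IED"))
  ss <- sensitivity_specificity(hit, truth)
  expect_equal(ss$sensitivity, 0.875)
  expect_equal(ss$specificity, 1.0)

  perfect <- cls(c(rep("A", 8), "NON_IED", "NON_IED"))
  expect_equal(sensitivity_specificity(perfect, truth),
               list(sensitivity = 1, specificity = 1))

  all_ied <- setNames(rep("IED", 10), names(truth))
  expect_true(is.na(sensitivity_specificity(hit, all_ied)$specificity))
})

test_that("Cohen's kappa matches hand-computed tables", {
  expect_equal(cohens_kappa(matrix(c(45, 5, 5, 45), 2, 2)), 0.8)
  expect_equal(cohens_kappa(matrix(c(25, 25, 25, 25), 2, 2)), 0)
  x <- cls(c("A", "B", "NON_IED", "A"))
  expect_equal(cohens_kappa(x, x), 1)
  # both raters constant and agreeing: kappa 1 by convention; disagreeing: 0
  allpos <- cls(rep("A", 4))
  expect_equal(cohens_kappa(allpos, allpos), 1)
  expect_equal(cohens_kappa(allpos, cls(rep("NON_IED", 4))), 0)
})

test_that("overlap matrices report row percentages and best matches", {
  ref <- cls(rep(c("A", "B"), c(51, 49)), "WC")
  oth_labels <- c(rep("X", 48), rep("Y", 3), rep("Y", 49))
  oth <- cls(oth_labels, "H3")
  om <- overlap_matrix(ref, oth)
  expect_equal(om$matrix["A", "X"], 48 / 51 * 100, tolerance = 1e-12)
  expect_equal(unname(rowSums(om$matrix)), c(100, 100))
  expect_equal(om$best_match$A, "X")
  expect_equal(om$best_match$B, "Y")

  inside <- cls(rep("Z", 100), "H2")
  om2 <- overlap_matrix(ref, inside)
  expect_true(all(om2$matrix[, "Z"] == 100))
})

test_that("run_validation orchestrates every pair deterministically", {
  set.seed(50)
  wc <- random_partition(60, 3, "WC")
  hs <- list(random_partition(60, 3, "H2"), random_partition(60, 4, "H3"),
             random_partition(60, 2, "H4"))
  rep1 <- run_validation(wc, hs, n_boot = 100, n_observers = 10, seed = 77)
  expect_length(rep1$pairs, 6)                     # 3 WC-H + C(3,2) H-H
  expect_equal(sum(vapply(rep1$pairs, function(p) p$type == "WC-H",
                          logical(1))), 3)
  expect_length(rep1$wc_all$values, 300)
  expect_length(rep1$h_all$values, 300)

  rep2 <- run_validation(wc, hs, n_boot = 100, n_observers = 10, seed = 77)
  d1 <- file.path(withr::local_tempdir(), "a.json")
  d2 <- file.path(withr::local_tempdir(), "b.json")
  write_report(rep1, d1); write_report(rep2, d2)
  expect_identical(readLines(d1), readLines(d2))

  same <- run_validation(wc, list(wc, wc, wc), n_boot = 50, n_observers = 10,
                         seed = 1)
  expect_true(all(vapply(same$pairs, function(p) p$point_vi == 0, logical(1))))
  expect_equal(same$bhattacharyya_overlap_pct, 100)
  expect_true(all(vapply(same$kappa, function(k) k$kappa == 1, logical(1))))
})

test_that("VI is a metric on partitions (randomized)", {
  set.seed(60)
  for (r in 1:100) {
    n <- 100
    x <- random_partition(n, sample(2:6, 1))
    y <- random_partition(n, sample(2:6, 1))
    z <- random_partition(n, sample(2:6, 1))
    vxy <- variation_of_information(contingency(x, y))
    vyx <- variation_of_information(contingency(y, x))
    vxz <- variation_of_information(contingency(x, z))
    vzy <- variation_of_information(contingency(z, y))
    expect_equal(vxy, vyx)
    expect_gte(vxy, 0)
    expect_lte(vxy, vxz + vzy + 1e-9)
  }
})
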