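test_that("PCA recovers degenerate and isotropic structure", {
  # data on a line: one component carries all variance
  base <- unit_core(1, 1) + unit_core(2, 0.5)
  W <- t(sapply(seq(0.1, 1, length.out = 20), function(s) s * base))
  co <- expression_cohort(W, sprintf("P%02d", 1:20), rep(EMOS, 5))
  p <- run_pca(co, n_components = 2, representation = "core")
  expect_gt(p$variance_fraction[1], 1 - 1e-10)
  expect_true(p$rank_deficient)
  # variance fractions are non-increasing and sum to 1
  co2 <- random_cohort(30, seed = 3)
  p2 <- run_pca(co2, n_components = 10, representation = "core")
  expect_true(all(diff(p2$variance_fraction) <= 1e-12))
  expect_equal(sum(p2$variance_fraction), 1)
  # isotropic data: each fraction ~ 1/d
  with_seed(5, {
    Wi <- matrix(runif(2000 * 46), 2000, 46)
    coi <- expression_cohort(Wi, sprintf("P%04d", 1:2000),
                             rep(EMOS, length.out = 2000))
    pi_ <- run_pca(coi, n_components = 5, representation = "core")
    expect_true(all(abs(pi_$variance_fraction - 1 / 46) < 0.01))
  })
})

test_that("PCA scores reconstruct the centered data", {
  co <- random_cohort(10, seed = 7)
  p <- run_pca(co, n_components = 39, representation = "core")  # full rank
  X <- co$weights
  recon <- p$scores %*% p$loadings + matrix(p$center, nrow(X), 46, byrow = TRUE)
  expect_equal(recon, X, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("rig-space PCA expands core cohorts through the coupling map", {
  co <- random_cohort(8, seed = 8)
  p <- run_pca(co, n_components = 5)
  expect_equal(ncol(p$loadings), 149)
  expect_equal(nrow(p$scores), 32)
})

test_that("cluster-to-emotion matching maximises the diagonal", {
  expect_equal(nrow(unique(gaexpr:::permutations_k(4))), 24)
  tab <- matrix(c(10, 0, 0, 0,
                  0, 1, 9, 0,
                  0, 8, 2, 0,
                  0, 0, 0, 10), 4, 4, byrow = TRUE)
  # optimal bijection swaps clusters 2 and 3
  expect_equal(gaexpr:::best_cluster_assignment(tab), c(1L, 3L, 2L, 4L))
})

test_that("the Gaussian mixture recovers well-separated clusters exactly", {
  with_seed(11, {
    centers <- matrix(c(0, 0, 20, 0, 0, 20, 20, 20), 4, 2, byrow = TRUE)
    scores <- centers[rep(1:4, each = 25), ] + matrix(rnorm(200), 100, 2)
    labels <- rep(EMOS, each = 25)
    g <- fit_gmm_confusion(scores, labels, seed = 1)
    expect_equal(unname(g$confusion), diag(4))
    expect_true(all(abs(rowSums(g$posteriors) - 1) < 1e-8))
    expect_setequal(unname(g$cluster_to_emotion), EMOS)  # bijection
    # shuffled labels: expected diagonal ~ chance (0.25)
    diags <- sapply(1:5, function(i) {
      mean(diag(fit_gmm_confusion(scores, sample(labels), seed = i)$confusion))
    })
    expect_gt(mean(diags), 0.12)
    expect_lt(mean(diags), 0.40)
  })
})

test_that("confusion rows always sum to one", {
  co <- ga_cohort(n_participants = 8, seed = 13)
  p <- run_pca(co, 10)
  g <- suppressWarnings(fit_gmm_confusion(p$scores, co$emotion, seed = 2))
  expect_equal(unname(rowSums(g$confusion)), rep(1, 4))
})

test_that("fingerprints equal brute-force column statistics", {
  co <- random_cohort(10, seed = 17)
  f <- fingerprint(co, "angry")
  W <- co$weights[co$emotion == "angry", ]
  expect_equal(f$mean_weights, colMeans(W), ignore_attr = TRUE)
  sd_pop <- apply(W, 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(f$sd_weights, sd_pop, ignore_attr = TRUE)
  expect_equal(f$mean_sd, mean(sd_pop))
  expect_equal(f$top_peaks$value,
               sort(f$mean_weights, decreasing = TRUE)[1:5], ignore_attr = TRUE)
  # hand arithmetic: weights 0.2 and 0.4 -> mean 0.3, population sd 0.1
  W2 <- matrix(0, 2, 46); W2[, 7] <- c(0.2, 0.4); W2[, 1] <- 0.5
  co2 <- expression_cohort(W2, c("a", "b"), c("happy", "happy"))
  f2 <- fingerprint(co2, "happy")
  expect_equal(f2$mean_weights[7], 0.3)
  expect_equal(f2$sd_weights[7], 0.1)
  # sample convention is switchable
  f2s <- fingerprint(co2, "happy", sd_type = "sample")
  expect_equal(f2s$sd_weights[7], sd(c(0.2, 0.4)))
  # identical participants: zero variability
  W3 <- matrix(rep(W2[1, ], 3), 3, byrow = TRUE)
  co3 <- expression_cohort(W3, c("a", "b", "c"), rep("sad", 3))
  f3 <- fingerprint(co3, "sad")
  expect_equal(f3$sd_weights, rep(0, 46), ignore_attr = TRUE)
  expect_equal(f3$mean_sd, 0)
})

test_that("synthetic cohorts built from a fixture mean peak on its top unit", {
  means <- default_category_means()
  co <- ga_cohort(n_participants = 6, between_subject_sd = 0, seed = 19)
  f <- fingerprint(co, "happy")
  expect_equal(f$top_peaks$core_index[1], unname(which.max(means["happy", ])))
  # the ranked peak AUs carry the category's signature action units
  expect_true(12 %in% f$top_peaks$au_number)
})

test_that("the SVM separates separable categories and not shuffled ones", {
  means <- separated_means()
  with_seed(23, {
    W <- means[rep(1:4, each = 15), ] +
      matrix(runif(60 * 46, 0, 0.05), 60, 46)
    W <- pmin(W, 1)
    co <- expression_cohort(W, sprintf("P%02d", rep(1:15, times = 4)),
                            rep(EMOS, each = 15))
    cv <- svm_category_cv(co, seed = 1)
    expect_gte(cv$overall, 0.95)
    # duplication invariance under stratified folds
    co2 <- expression_cohort(rbind(W, W), rep(sprintf("P%02d", 1:30), 4),
                             rep(rep(EMOS, each = 15), 2))
    cv2 <- svm_category_cv(co2, seed = 1)
    expect_lt(abs(cv2$overall - cv$overall), 0.05)
    # label shuffle: chance-level performance
    cos <- expression_cohort(W, sprintf("P%02d", rep(1:15, times = 4)),
                             sample(rep(EMOS, each = 15)))
    cvs <- svm_category_cv(cos, seed = 1)
    expect_lt(cvs$overall, 0.45)
  })
})

test_that("fold reduction triggers when a class is too small", {
  co <- random_cohort(3, seed = 29)   # 3 per class < 5 folds
  expect_warning(cv <- svm_category_cv(co, folds = 5, seed = 1),
                 "reducing folds")
  expect_equal(cv$folds, 3)
})
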