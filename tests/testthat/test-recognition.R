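test_that("a noiseless responder labels its own preferred expressions", {
  perc <- toy_perceivers(1)
  rec <- simulate_recognition(perc, perc, temperature = 0, seed = 1)
  expect_true(all(rec$trials$correct))
  expect_equal(nrow(rec$trials), 4)
})

test_that("the trial count is perceivers x stimuli", {
  stim <- random_cohort(10, seed = 2)      # 40 stimuli
  perc <- toy_perceivers(5)
  rec <- simulate_recognition(stim, perc, temperature = 0.1, seed = 3)
  expect_equal(nrow(rec$trials), 200)
})

test_that("infinite decision noise yields chance accuracy", {
  stim <- random_cohort(10, seed = 4)
  perc <- toy_perceivers(5)
  rec <- simulate_recognition(stim, perc, temperature = Inf, seed = 5)
  n <- nrow(rec$trials)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(rec$trials$correct) - 0.25), 4 * se)
})

test_that("a perceiver lacking a preferred expression is rejected", {
  perc <- toy_perceivers(2)
  broken <- expression_cohort(perc$weights[-1, ], perc$participant_id[-1],
                              perc$emotion[-1])
  expect_error(simulate_recognition(random_cohort(3, seed = 6), broken),
               "lacks a preferred expression")
})

test_that("binning matches a hand-computed quartile assignment", {
  # 8 happy stimuli at increasing angle from the perceiver's happy
  # preferred expression: CDs are strictly increasing, so quartile bins
  # are just consecutive pairs in presentation order
  angles <- seq(0.1, 0.8, by = 0.1)
  W <- t(sapply(angles, function(a) {
    v <- numeric(46); v[1] <- cos(a * pi / 2); v[2] <- sin(a * pi / 2); v
  }))
  stim <- expression_cohort(W, sprintf("M%02d", 1:8), rep("happy", 8))
  perc <- toy_perceivers(1)  # happy preferred = units 1..8 high
  perc$weights[1, ] <- unit_core(1)  # exactly unit 1
  # craft responses: correct pattern T T | T F | F T | F F per bin
  correct_pattern <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  trials <- data.frame(
    perceiver_id = "V01",
    stimulus_id = sprintf("S%03d_happy", 1:8),
    true_emotion = "happy",
    response_emotion = ifelse(correct_pattern, "happy", "sad"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(trials, path, row.names = FALSE, quote = FALSE)
  rec <- read_trials(path, stim, perc)
  b <- bin_by_cd(rec, n_bins = 4)
  expect_equal(b$counts, rep(2L, 4))
  expect_equal(b$prob_correct, c(1, 0.5, 0.5, 0))
  expect_equal(b$bin, rep(1:4, each = 2))
  # degenerate binning: one bin = overall accuracy
  b1 <- bin_by_cd(rec, n_bins = 1)
  expect_equal(b1$prob_correct, mean(correct_pattern))
  # all-correct trials: every bin at probability 1
  rec2 <- rec; rec2$trials$response_emotion <- "happy"
  rec2$trials$correct <- TRUE
  b2 <- bin_by_cd(rec2, n_bins = 4)
  expect_equal(b2$prob_correct, rep(1, 4))
})

test_that("bins depend only on the ranks of the distances", {
  x <- with_seed(7, runif(40))
  expect_equal(gaexpr:::quantile_bins(x, 4), gaexpr:::quantile_bins(x^2, 4))
  expect_equal(gaexpr:::quantile_bins(x, 4),
               gaexpr:::quantile_bins(rank(x, ties.method = "first"), 4))
})

test_that("the permutation test is deterministic and preserves accuracy", {
  stim <- random_cohort(6, seed = 8)
  perc <- toy_perceivers(4, jitter = 0.2)
  rec <- simulate_recognition(stim, perc, temperature = 0.1, seed = 9)
  p1 <- permutation_test(rec, n_perm = 100, seed = 10)
  p2 <- permutation_test(rec, n_perm = 100, seed = 10)
  expect_identical(p1$table$p_value, p2$table$p_value)
  # equal-count bins: the bin-count-weighted mean of every null row equals
  # the (invariant) overall accuracy
  acc <- mean(rec$trials$correct)
  expect_true(all(abs(rowMeans(p1$null) - acc) < 1e-10))
  expect_warning(permutation_test(rec, n_perm = 50, seed = 1), "unstable")
})

test_that("identical preferred expressions give a degenerate, centred null", {
  perc <- toy_perceivers(1)
  clones <- expression_cohort(
    perc$weights[rep(1:4, 3), ],
    rep(sprintf("V%02d", 1:3), each = 4), rep(EMOS, 3))
  stim <- random_cohort(6, seed = 11)
  rec <- simulate_recognition(stim, clones, temperature = 0.2, seed = 12)
  p <- permutation_test(rec, n_perm = 100, seed = 13)
  # swapping identical sets changes nothing: observed sits exactly on its null
  expect_true(all(abs(sweep(p$null, 2, p$table$observed)) < 1e-12))
  expect_equal(p$table$p_value, rep(1, 4))
})

test_that("self-matched perceivers lose accuracy in the far bin", {
  # responses driven by each perceiver's own distinct preferred set: the
  # highest-CD bin's observed accuracy falls in its null's lower tail
  stim <- ga_cohort(n_participants = 8, seed = 140)
  perc <- ga_cohort(n_participants = 6, seed = 141)
  rec <- simulate_recognition(stim, perc, temperature = 0.1, seed = 15)
  p <- permutation_test(rec, n_perm = 300, seed = 16)
  expect_lt(p$table$observed[4], p$table$null_mean[4])
  expect_lt(p$table$p_value[4], 0.1)
})
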