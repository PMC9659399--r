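test_that("initialization trial yields a valid, reproducible population", {
  cfg <- ga_config(seed = 5)
  g1 <- with_seed(5, init_population(cfg))
  g2 <- with_seed(5, init_population(cfg))
  expect_identical(g1, g2)
  expect_equal(g1$index, 0L)
  expect_equal(nrow(g1$candidates), 10)
  expect_true(all(g1$candidates >= 0 & g1$candidates <= 1))
  expect_null(g1$selected)
  # Monte-Carlo oracle: per-dimension activation matches the generation law
  with_seed(6, {
    acts <- replicate(300, mean(init_population(cfg)$candidates > 0))
    se <- sqrt(0.3 * 0.7 / (300 * 10 * 46))
    expect_lt(abs(mean(acts) - 0.3), 3 * se)
  })
})

test_that("breeding respects elitism and degenerates correctly", {
  parent <- with_seed(1, random_expression())
  cand <- with_seed(2, t(replicate(10, random_expression())))
  cand[3, ] <- parent
  g <- ga_generation(0L, cand, selected = 3L, best_index = 3L)
  # no variation operators: every offspring is the lone parent
  frozen <- ga_config(mutation_prob = 0, mutation_sd = 0)
  off <- with_seed(3, next_generation(g, frozen))
  expect_true(all(apply(off$candidates, 1, identical, y = parent)))
  expect_equal(off$index, 1L)
  # elitism contract: slot 1 is the previous best, bitwise
  g2 <- ga_generation(0L, cand, selected = c(2L, 3L, 7L), best_index = 7L)
  off2 <- with_seed(4, next_generation(g2, ga_config()))
  expect_identical(off2$candidates[1, ], cand[7, ])
  expect_error(next_generation(ga_generation(0L, cand), ga_config()),
               "select at least one")
})

test_that("mutation follows the clipped-Gaussian law", {
  parent <- rep(0.5, 46)
  cand <- matrix(rep(parent, 10), 10, byrow = TRUE)
  g <- ga_generation(0L, cand, selected = 1L, best_index = 1L)
  cfg <- ga_config(mutation_prob = 1, mutation_sd = 2, elitism = FALSE)
  with_seed(9, {
    off <- do.call(rbind, lapply(1:100, function(i)
      next_generation(g, cfg)$candidates))
  })
  w <- as.vector(off)
  # oracle: X = clip(0.5 + 2 Z); P(X = 0) = P(Z < -0.25), P(X = 1) = P(Z > 0.25)
  p_lo <- pnorm(-0.25); n <- length(w)
  se <- sqrt(p_lo * (1 - p_lo) / n)
  expect_lt(abs(mean(w == 0) - p_lo), 4 * se)
  expect_lt(abs(mean(w == 1) - p_lo), 4 * se)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("a session logs every trial and reproduces bit-for-bit", {
  target <- default_category_means()["fear", ]
  obs <- observer_model(target)
  s1 <- run_session(obs, ga_config(n_generations = 1, seed = 31))
  expect_length(s1$generations, 2)
  s2 <- run_session(obs, ga_config(seed = 77))
  s3 <- run_session(obs, ga_config(seed = 77))
  expect_identical(s2, s3)
  expect_length(s2$generations, 11)
  # final-trial single choice defines the preferred expression
  last <- s2$generations[[11]]
  expect_length(last$selected, 1)
  expect_identical(s2$preferred, last$candidates[last$best_index, ])
  # weights stay valid everywhere: clipping is never bypassed
  for (g in s2$generations)
    expect_true(all(g$candidates >= 0 & g$candidates <= 1))
})

test_that("zeroed variation operators freeze the selected genotypes", {
  target <- default_category_means()["sad", ]
  obs <- observer_model(target, decision_noise_sd = 0)
  s <- run_session(obs, ga_config(mutation_prob = 0, mutation_sd = 0,
                                  seed = 13))
  # without mutation, every gene value in every generation is one of the
  # values present in the initial population's corresponding column
  init <- s$generations[[1]]$candidates
  final <- s$generations[[11]]$candidates
  for (j in seq_len(ncol(final)))
    expect_true(all(final[, j] %in% init[, j]))
  # the elite chain is exactly preserved
  expect_identical(final[1, ],
                   s$generations[[10]]$candidates[s$generations[[10]]$best_index, ])
})

test_that("convergence profile and plateau rule behave as defined", {
  prof <- structure(
    data.frame(generation = 0:5, n_selected = 3,
               dispersion = c(0.6, 0.3, 0.1, 0.1, 0.1, 0.1),
               single_selection = FALSE),
    class = c("convergence_profile", "data.frame"))
  # strictly shrinking then flat: plateau at the first flat index
  expect_equal(plateau_generation(prof), 2)
  prof$dispersion <- rep(0.4, 6)            # all generations identical
  expect_equal(plateau_generation(prof), 0)
  prof$dispersion <- c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1)  # never settles
  expect_equal(plateau_generation(prof), 5)
  # single-selection generations are flagged and excluded from the rule
  prof2 <- structure(
    data.frame(generation = 0:3, n_selected = c(3, 3, 3, 1),
               dispersion = c(0.5, 0.25, 0.25, 0),
               single_selection = c(FALSE, FALSE, FALSE, TRUE)),
    class = c("convergence_profile", "data.frame"))
  expect_equal(plateau_generation(prof2), 1)
})

test_that("plateau rule agrees with an independent re-implementation", {
  # oracle: explicit loop over candidate plateau indices
  plateau_oracle <- function(d, gen, tol = 0.05) {
    scale <- max(d[1], .Machine$double.eps)
    for (i in seq_along(d)) {
      flat <- TRUE
      j <- i
      while (j < length(d)) {
        if (abs(d[j + 1] - d[j]) / scale >= tol) { flat <- FALSE; break }
        j <- j + 1
      }
      if (flat) return(gen[i])
    }
    gen[length(gen)]
  }
  means <- default_category_means()
  plats <- with_seed(55, sapply(1:20, function(i) {
    obs <- observer_model(means[(i %% 4) + 1, ])
    prof <- convergence_profile(run_session(obs, ga_config(seed = 400 + i)))
    use <- !prof$single_selection
    c(plateau_generation(prof),
      plateau_oracle(prof$dispersion[use], prof$generation[use]))
  }))
  expect_equal(plats[1, ], plats[2, ])
})

test_that("session logging round-trips through JSON", {
  obs <- observer_model(default_category_means()["angry", ])
  s <- run_session(obs, ga_config(seed = 99))
  path <- withr::local_tempfile(fileext = ".json")
  write_session(s, path)
  s2 <- read_session(path)
  expect_equal(s2$preferred, s$preferred)
  expect_equal(length(s2$generations), length(s$generations))
  for (i in seq_along(s$generations)) {
    expect_equal(s2$generations[[i]]$candidates, s$generations[[i]]$candidates)
    expect_equal(s2$generations[[i]]$selected, s$generations[[i]]$selected)
    expect_equal(s2$generations[[i]]$best_index, s$generations[[i]]$best_index)
  }
  expect_equal(s2$config$mutation_sd, s$config$mutation_sd)
})
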