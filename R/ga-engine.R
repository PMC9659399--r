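#' Interactive-genetic-algorithm engine
#'
#' The evolution loop an experiment participant would drive: on every trial
#' ten candidate expressions are shown, the observer marks any number of
#' them as resembling the target emotion and flags the single best match;
#' the next generation is bred from the selections by uniform crossover and
#' Gaussian mutation, with the flagged best carried over unchanged
#' (elitism). One session is one initialization trial plus
#' `n_generations` evolved trials; on the final trial the observer picks a
#' single expression, the "preferred expression".
#'
#' @name ga_engine
NULL

#' GA configuration
#'
#' @param population_size candidates per generation (>= 2).
#' @param n_generations number of evolved generations after initialization.
#' @param mutation_prob per-core-unit probability of mutating an offspring
#'   weight. The default 1 perturbs every unit every breeding
#'   (evolution-strategy style); because weights clip at 0, ubiquitous
#'   small kicks also act as a ratchet that strips spuriously active units
#'   inherited from initialization, keeping the algorithm's stochastic
#'   noise floor well below typical between-individual differences.
#' @param mutation_sd standard deviation of the Gaussian mutation, in
#'   weight-fraction units; mutated weights are clipped to [0, 1].
#' @param crossover crossover operator; `"uniform"` picks each offspring
#'   unit from either parent with probability 1/2.
#' @param elitism if `TRUE`, the flagged best candidate is copied unchanged
#'   into the next generation.
#' @param activation_prob,magnitude_law passed to [random_expression()] for
#'   the initialization trial.
#' @param seed optional session seed for full reproducibility.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 10L, n_generations = 10L,
                      mutation_prob = 1, mutation_sd = 0.1,
                      crossover = "uniform", elitism = TRUE,
                      activation_prob = 0.3, magnitude_law = "uniform",
                      seed = NULL) {
  stopifnot(population_size >= 2, n_generations >= 1,
            mutation_prob >= 0, mutation_prob <= 1, mutation_sd >= 0)
  crossover <- match.arg(crossover, "uniform")
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 mutation_prob = mutation_prob, mutation_sd = mutation_sd,
                 crossover = crossover, elitism = isTRUE(elitism),
                 activation_prob = activation_prob,
                 magnitude_law = magnitude_law, seed = seed),
            class = "ga_config")
}

#' One GA generation
#'
#' @param index generation index; 0 is the initialization trial.
#' @param candidates population_size x 46 matrix of core weights.
#' @param selected integer indices of observer-selected candidates (may be
#'   `NULL` before the observer has responded).
#' @param best_index the flagged best match; must be one of `selected`.
#' @return an object of class `ga_generation`.
#' @export
ga_generation <- function(index, candidates, selected = NULL,
                          best_index = NULL) {
  stopifnot(is.matrix(candidates), ncol(candidates) == N_CORE)
  apply(candidates, 1L, validate_core)
  if (!is.null(selected)) {
    stopifnot(length(selected) >= 1,
              all(selected %in% seq_len(nrow(candidates))))
    if (!is.null(best_index) && !(best_index %in% selected))
      stop("best_index must be one of the selected candidates", call. = FALSE)
  }
  structure(list(index = as.integer(index), candidates = candidates,
                 selected = selected, best_index = best_index),
            class = "ga_generation")
}

#' Initialization trial: a population of procedurally generated expressions
#'
#' @param config a [ga_config()].
#' @return a `ga_generation` with index 0 and no selections.
#' @export
init_population <- function(config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  cand <- t(replicate(config$population_size,
                      random_expression(config$activation_prob,
                                        config$magnitude_law)))
  ga_generation(0L, cand)
}

#' Breed the next generation from an observed one
#'
#' With elitism, slot 1 receives the flagged best candidate unchanged. Every
#' other slot draws two parents uniformly with replacement from the selected
#' set (a single selection degenerates to mutate-clone), combines them by
#' per-unit uniform crossover, then mutates each unit with probability
#' `mutation_prob` by adding Gaussian noise (sd `mutation_sd`) and clipping
#' to [0, 1].
#'
#' @param current a `ga_generation` carrying `selected` and `best_index`.
#' @param config a [ga_config()].
#' @return a new `ga_generation` with incremented index.
#' @export
next_generation <- function(current, config = ga_config()) {
  stopifnot(inherits(current, "ga_generation"), inherits(config, "ga_config"))
  if (is.null(current$selected) || length(current$selected) == 0)
    stop("cannot breed from a generation without selections: ",
         "select at least one candidate first", call. = FALSE)
  pop <- config$population_size
  parents <- current$candidates[current$selected, , drop = FALSE]
  out <- matrix(0, pop, N_CORE)
  slot <- 1L
  if (config$elitism) {
    if (is.null(current$best_index))
      stop("elitism requires a flagged best_index", call. = FALSE)
    out[1L, ] <- current$candidates[current$best_index, ]
    slot <- 2L
  }
  np <- nrow(parents)
  for (i in slot:pop) {
    p1 <- parents[sample.int(np, 1L), ]
    p2 <- parents[sample.int(np, 1L), ]
    take1 <- runif(N_CORE) < 0.5
    child <- ifelse(take1, p1, p2)
    mut <- runif(N_CORE) < config$mutation_prob
    if (any(mut))
      child[mut] <- clip01(child[mut] + rnorm(sum(mut), 0, config$mutation_sd))
    out[i, ] <- child
  }
  ga_generation(current$index + 1L, out)
}

#' Run a full evolution session against a simulated observer
#'
#' Alternates observer selection and breeding for `n_generations`
#' generations; on the final trial the observer makes a single choice,
#' stored as the session's preferred expression. The complete log —
#' candidates, selection masks and best flags of every generation — is
#' retained, and the whole session is reproducible from `config$seed`.
#'
#' @param observer an [observer_model()].
#' @param config a [ga_config()].
#' @return an object of class `ga_session` with elements `config`,
#'   `generations` (length `n_generations + 1`) and `preferred` (core
#'   vector).
#' @export
run_session <- function(observer, config = ga_config()) {
  stopifnot(inherits(observer, "observer_model"), inherits(config, "ga_config"))
  with_seed(config$seed, {
    gens <- vector("list", config$n_generations + 1L)
    g <- init_population(config)
    for (step in seq_len(config$n_generations)) {
      sel <- observe(observer, g$candidates)
      g$selected <- sel$selected
      g$best_index <- sel$best_index
      gens[[step]] <- g
      g <- next_generation(g, config)
    }
    # final trial: one face only
    final_obs <- observer
    final_obs$selection_rule <- "topk"
    final_obs$k <- 1L
    sel <- observe(final_obs, g$candidates)
    g$selected <- sel$selected
    g$best_index <- sel$best_index
    gens[[config$n_generations + 1L]] <- g
    structure(list(config = config, generations = gens,
                   preferred = g$candidates[sel$best_index, ]),
              class = "ga_session")
  })
}

#' @export
print.ga_session <- function(x, ...) {
  ng <- length(x$generations)
  cat("GA session:", ng, "generations (1 initialization +", ng - 1L,
      "evolved),", x$config$population_size, "candidates each\n")
  nsel <- vapply(x$generations, function(g) length(g$selected), 1L)
  cat("  selections per trial:", paste(nsel, collapse = " "), "\n")
  cat("  preferred expression: ", sum(x$preferred > 0.05),
      " units above 5% activation\n", sep = "")
  invisible(x)
}

#' Per-generation convergence diagnostics
#'
#' For every generation, the mean pairwise cosine distance among the
#' candidates the observer selected (the within-trial dispersion whose
#' stabilisation signals convergence), and optionally the mean distance of
#' the selected candidates to a known target.
#'
#' @param session a [run_session()] result.
#' @param target optional core vector (e.g. a simulated observer's latent
#'   target).
#' @return data.frame of class `convergence_profile` with columns
#'   `generation`, `n_selected`, `dispersion` (0, flagged by
#'   `single_selection`, when only one candidate was selected) and, when a
#'   target is given, `cd_to_target`.
#' @export
convergence_profile <- function(session, target = NULL) {
  stopifnot(inherits(session, "ga_session"))
  if (length(session$generations) < 2)
    stop("need a session with at least 2 generations", call. = FALSE)
  rows <- lapply(session$generations, function(g) {
    sel <- g$candidates[g$selected, , drop = FALSE]
    disp <- if (nrow(sel) >= 2) mean(pairwise_cd(sel)) else 0
    r <- data.frame(generation = g$index, n_selected = nrow(sel),
                    dispersion = disp,
                    single_selection = nrow(sel) < 2)
    if (!is.null(target))
      r$cd_to_target <- mean(apply(sel, 1L, cosine_distance, b = target))
    r
  })
  out <- do.call(rbind, rows)
  class(out) <- c("convergence_profile", "data.frame")
  out
}

#' Plateau generation of a convergence profile
#'
#' The first generation index g such that the change of the mean
#' selected-candidate dispersion between every later pair of consecutive
#' generations stays below `tol` of the session's dispersion scale (its
#' initialization-trial dispersion). Normalising by the initial scale,
#' rather than by the current value, keeps the rule meaningful at the
#' converged floor, where the dispersion is tiny and its *proportional*
#' wobble under mutation noise never settles. Generations flagged as
#' single-selection (dispersion identically 0 by construction, e.g. the
#' final one-choice trial) carry no dispersion information and are
#' excluded. If no generation qualifies the last usable index is returned.
#'
#' @param profile a [convergence_profile()].
#' @param tol relative-change tolerance (default 0.05, i.e. 5% of the
#'   initial dispersion).
#' @return integer generation index (0 = initialization trial).
#' @export
plateau_generation <- function(profile, tol = 0.05) {
  stopifnot(inherits(profile, "convergence_profile"), tol > 0)
  use <- !profile$single_selection
  d <- profile$dispersion[use]
  gen <- profile$generation[use]
  if (length(d) < 2) return(gen[length(gen)])
  scale <- max(d[1L], .Machine$double.eps)
  rel <- abs(diff(d)) / scale
  ok <- rev(cumprod(rev(rel < tol))) == 1   # all later changes below tol
  if (any(ok)) gen[which(ok)[1L]] else gen[length(gen)]
}

#' @export
plot.convergence_profile <- function(x, ...) {
  plot(x$generation, x$dispersion, type = "b", pch = 19,
       xlab = "generation (0 = initialization)",
       ylab = "mean pairwise CD among selected", ...)
  if ("cd_to_target" %in% names(x))
    lines(x$generation, x$cd_to_target, type = "b", pch = 1, lty = 2)
  invisible(x)
}
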