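#' Simulated observers and synthetic cohorts
#'
#' A simulated observer replaces the human participant: it holds a latent
#' target expression (what it "thinks" the emotion should look like), scores
#' each candidate by negative cosine distance to that target plus Gaussian
#' decision noise, and selects according to a top-k or distance-threshold
#' rule. Cohort generation runs one full GA session per participant x
#' emotion, with latent targets jittered around per-emotion category means,
#' yielding a dataset with the same structure as a human study: N
#' participants x 4 emotions x one preferred expression each.
#'
#' @name observers
NULL

#' Simulated observer
#'
#' @param target core vector: the observer's latent preferred expression.
#' @param selection_rule `"topk"` (select the k best-scoring candidates) or
#'   `"threshold"` (select all candidates whose noisy distance falls below
#'   `threshold`; the best-scoring one if none do).
#' @param k number of selections under the top-k rule (1-10).
#' @param threshold distance threshold for the threshold rule.
#' @param decision_noise_sd sd of the Gaussian noise added to each
#'   candidate's score (score = -CD to target); 0 gives an ideal observer.
#' @return an object of class `observer_model`.
#' @export
observer_model <- function(target, selection_rule = c("topk", "threshold"),
                           k = 3L, threshold = 0.3,
                           decision_noise_sd = 0.05) {
  validate_core(target)
  selection_rule <- match.arg(selection_rule)
  stopifnot(k >= 1, k <= 10, decision_noise_sd >= 0, threshold > 0)
  structure(list(target = target, selection_rule = selection_rule,
                 k = as.integer(k), threshold = threshold,
                 decision_noise_sd = decision_noise_sd),
            class = "observer_model")
}

#' Observer response to one trial's candidates
#'
#' @param observer an [observer_model()].
#' @param candidates population x 46 matrix of core weights.
#' @return list with `selected` (integer indices, always nonempty),
#'   `best_index` (the flagged best match, an element of `selected`) and
#'   `scores`.
#' @export
observe <- function(observer, candidates) {
  stopifnot(inherits(observer, "observer_model"), is.matrix(candidates))
  n <- nrow(candidates)
  cd <- apply(candidates, 1L, cosine_distance, b = observer$target)
  scores <- -cd
  if (observer$decision_noise_sd > 0)
    scores <- scores + rnorm(n, 0, observer$decision_noise_sd)
  if (observer$selection_rule == "topk") {
    k <- min(observer$k, n)
    selected <- order(scores, decreasing = TRUE)[seq_len(k)]
  } else {
    selected <- which(-scores < observer$threshold)
    if (length(selected) == 0) selected <- which.max(scores)
  }
  best <- selected[which.max(scores[selected])]
  list(selected = sort(selected), best_index = best, scores = scores)
}

#' Cohort specification
#'
#' @param n_participants number of simulated participants (>= 2).
#' @param category_means 4 x 46 matrix of per-emotion mean core vectors
#'   (rownames = emotions); defaults to the shipped prototype fixtures.
#' @param between_subject_sd per-unit Gaussian jitter (weight fraction) of
#'   each participant's latent target around its category mean; 0 makes all
#'   participants share the category mean exactly.
#' @param observer_args list of arguments passed to [observer_model()]
#'   (everything but `target`).
#' @param seed cohort seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 24L,
                        category_means = default_category_means(),
                        between_subject_sd = 0.15,
                        observer_args = list(), seed = NULL) {
  stopifnot(n_participants >= 2, is.matrix(category_means),
            ncol(category_means) == N_CORE, between_subject_sd >= 0)
  if (!all(EMOTIONS %in% rownames(category_means)))
    stop("category_means must have rows named ",
         paste(EMOTIONS, collapse = ", "), call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 category_means = category_means[EMOTIONS, , drop = FALSE],
                 between_subject_sd = between_subject_sd,
                 observer_args = observer_args, seed = seed),
            class = "cohort_spec")
}

#' Shipped per-emotion prototype expressions
#'
#' Four hand-authored core vectors whose top-activated units carry the
#' action units most associated with each emotion in the FACS literature
#' (e.g. lip corner puller and cheek raiser for happy, upper lid raiser and
#' brow raisers for fear), so synthetic cohorts inherit a realistic
#' fingerprint structure. Stored as a fixture table under `extdata`.
#'
#' @param path optional alternative expression table (core representation,
#'   one row per emotion).
#' @return 4 x 46 numeric matrix with emotion rownames.
#' @export
default_category_means <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "category_means.csv", package = "gaexpr",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, sprintf("c%02d", seq_len(N_CORE))])
  rownames(m) <- tab$emotion
  m[EMOTIONS, , drop = FALSE]
}

#' Generate a synthetic cohort of preferred expressions
#'
#' For every participant x emotion cell: draw a latent target by jittering
#' the category mean (Gaussian per core unit, sd `between_subject_sd`,
#' clipped to [0, 1]), build an observer with that target, run a full GA
#' session, and store the session's preferred expression. Each cell gets a
#' child seed derived from the cohort seed, so the dataset is reproducible
#' and insensitive to evaluation order.
#'
#' @param spec a [cohort_spec()].
#' @param config a [ga_config()] shared by all sessions.
#' @param keep_sessions if `TRUE`, retain every full `ga_session` log
#'   (memory-heavy for large cohorts).
#' @return an `expression_cohort`: list with `weights` (n x 46 matrix, one
#'   row per participant-emotion), `participant_id`, `emotion`, `targets`
#'   (the latent targets actually used), `spec`, `config`.
#' @export
generate_cohort <- function(spec = cohort_spec(), config = ga_config(),
                            keep_sessions = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "ga_config"))
  n <- spec$n_participants
  rows <- n * length(EMOTIONS)
  W <- matrix(NA_real_, rows, N_CORE)
  Tg <- matrix(NA_real_, rows, N_CORE)
  pid <- character(rows); emo <- character(rows)
  sessions <- if (keep_sessions) vector("list", rows) else NULL
  seed0 <- if (is.null(spec$seed)) NULL else spec$seed
  r <- 0L
  for (p in seq_len(n)) {
    for (e in EMOTIONS) {
      r <- r + 1L
      cell_seed <- if (is.null(seed0)) NULL else
        derive_seed(seed0, paste0("cohort/", p, "/", e))
      mu <- spec$category_means[e, ]
      target <- with_seed(cell_seed, {
        tg <- if (spec$between_subject_sd > 0)
          clip01(mu + rnorm(N_CORE, 0, spec$between_subject_sd)) else mu
        if (all(tg == 0)) tg[which.max(mu)] <- 0.5  # degenerate jitter guard
        tg
      })
      obs <- do.call(observer_model, c(list(target = target),
                                       spec$observer_args))
      cfg <- config
      cfg$seed <- if (is.null(cell_seed)) NULL else
        derive_seed(cell_seed, "session")
      s <- run_session(obs, cfg)
      W[r, ] <- s$preferred
      Tg[r, ] <- target
      pid[r] <- sprintf("P%03d", p)
      emo[r] <- e
      if (keep_sessions) sessions[[r]] <- s
    }
  }
  structure(list(weights = W, participant_id = pid, emotion = emo,
                 targets = Tg, spec = spec, config = config,
                 representation = "core", sessions = sessions),
            class = "expression_cohort")
}

#' Assemble a cohort from an existing weight matrix
#'
#' @param weights n x 46 (core) or n x 149 (rig) matrix, entries in [0, 1].
#' @param participant_id,emotion character vectors of length n.
#' @return an `expression_cohort`.
#' @export
expression_cohort <- function(weights, participant_id, emotion) {
  stopifnot(is.matrix(weights),
            ncol(weights) %in% c(N_CORE, N_RIG),
            nrow(weights) == length(participant_id),
            nrow(weights) == length(emotion))
  if (anyNA(weights) || any(weights < 0) || any(weights > 1))
    stop("weights must all lie in [0, 1]", call. = FALSE)
  bad <- setdiff(unique(emotion), EMOTIONS)
  if (length(bad))
    stop("unknown emotion label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(weights = weights, participant_id = as.character(participant_id),
                 emotion = as.character(emotion), targets = NULL,
                 spec = NULL, config = NULL,
                 representation = if (ncol(weights) == N_CORE) "core" else "rig",
                 sessions = NULL),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("expression cohort: ", length(unique(x$participant_id)),
      " participants x ", length(unique(x$emotion)), " emotions (",
      nrow(x$weights), " preferred expressions, ",
      x$representation, " representation)\n", sep = "")
  print(table(x$emotion))
  invisible(x)
}

#' @export
summary.expression_cohort <- function(object, ...) {
  act <- rowSums(object$weights > 0.05)
  cat("per-expression active units (>5% activation): median",
      stats::median(act), "range", min(act), "-", max(act), "\n")
  for (e in intersect(EMOTIONS, unique(object$emotion))) {
    w <- object$weights[object$emotion == e, , drop = FALSE]
    if (nrow(w) >= 2)
      cat(sprintf("  %-6s mean within-category pairwise CD = %.3f\n",
                  e, mean(pairwise_cd(w))))
  }
  invisible(object)
}

#' Per-emotion centroid expressions of a cohort
#'
#' @param cohort an `expression_cohort`.
#' @return matrix, one row per emotion present.
#' @export
cohort_centroids <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  emos <- intersect(EMOTIONS, unique(cohort$emotion))
  t(vapply(emos, function(e)
    colMeans(cohort$weights[cohort$emotion == e, , drop = FALSE]),
    numeric(ncol(cohort$weights))))
}
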