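#' GA stochastic-noise thresholds and exceedance
#'
#' Two expressions evolved toward the *same* target still differ, because
#' initialization, crossover, mutation and the observer's decision noise
#' are stochastic. The noise simulation quantifies this floor: it evolves
#' many independent sessions toward one fixed target and takes the mean of
#' the pairwise cosine distances among the resulting preferred expressions
#' as the noise threshold. Observed between-participant distances above the
#' threshold reflect genuine individual differences, not algorithm noise.
#'
#' @name noise_sim
NULL

#' Simulate the GA noise distribution for one fixed target
#'
#' @param target core vector all sessions aim at (typically a cohort's
#'   per-emotion centroid).
#' @param n_iter number of independent sessions (>= 2; the study-scale
#'   default is 500).
#' @param config a [ga_config()].
#' @param observer_args arguments for [observer_model()] besides `target`.
#' @param threshold_type `"mean"` (default: threshold = mean of the
#'   simulated pairwise-CD distribution) or `"percentile"`.
#' @param percentile percentile used when `threshold_type = "percentile"`.
#' @param seed simulation seed; each iteration derives its own child seed.
#' @param emotion optional label carried into the result.
#' @return object of class `noise_distribution`: `final_expressions`
#'   (n_iter x 46), `cds` (all n_iter(n_iter-1)/2 pairwise distances),
#'   `threshold`, `emotion`.
#' @export
simulate_noise <- function(target, n_iter = 500L, config = ga_config(),
                           observer_args = list(),
                           threshold_type = c("mean", "percentile"),
                           percentile = 0.95, seed = NULL, emotion = NA) {
  validate_core(target)
  stopifnot(n_iter >= 2)
  threshold_type <- match.arg(threshold_type)
  finals <- matrix(NA_real_, n_iter, N_CORE)
  obs <- do.call(observer_model, c(list(target = target), observer_args))
  for (i in seq_len(n_iter)) {
    cfg <- config
    cfg$seed <- if (is.null(seed)) NULL else
      derive_seed(seed, paste0("noise-iter/", i))
    finals[i, ] <- run_session(obs, cfg)$preferred
  }
  cds <- pairwise_cd(finals)
  thr <- if (threshold_type == "mean") mean(cds) else
    unname(stats::quantile(cds, percentile))
  structure(list(emotion = emotion, final_expressions = finals, cds = cds,
                 threshold = thr, threshold_type = threshold_type,
                 n_iter = as.integer(n_iter)),
            class = "noise_distribution")
}

#' @export
print.noise_distribution <- function(x, ...) {
  cat("GA stochastic-noise distribution",
      if (!is.na(x$emotion)) paste0(" (", x$emotion, ")"), ":\n", sep = "")
  cat(sprintf("  %d iterations, %d pairwise CDs; threshold (%s) = %.4f\n",
              x$n_iter, length(x$cds), x$threshold_type, x$threshold))
  print(summary(x$cds))
  invisible(x)
}

#' Fraction of observed distances exceeding a noise threshold
#'
#' @param observed_cds nonempty numeric vector of observed pairwise cosine
#'   distances.
#' @param threshold noise threshold (see [simulate_noise()]).
#' @return fraction in [0, 1] of observed values strictly above the
#'   threshold.
#' @export
exceedance <- function(observed_cds, threshold) {
  if (length(observed_cds) == 0)
    stop("observed_cds must be nonempty", call. = FALSE)
  stopifnot(is.numeric(observed_cds), is.numeric(threshold),
            length(threshold) == 1L)
  mean(observed_cds > threshold)
}

#' Per-emotion and pooled exceedance of a cohort over its noise floor
#'
#' Each emotion's observed pairwise CDs are compared against that emotion's
#' own threshold; the pooled fraction counts every observed CD against its
#' emotion's threshold.
#'
#' @param cohort an `expression_cohort` with >= 2 expressions per emotion.
#' @param noise named list of `noise_distribution` objects, one per emotion
#'   present in the cohort (e.g. from [ga_noise_thresholds()]).
#' @return object of class `exceedance_report`: data.frame `per_emotion`
#'   (emotion, n_pairs, threshold, exceedance) plus `pooled`.
#' @export
exceedance_report <- function(cohort, noise) {
  stopifnot(inherits(cohort, "expression_cohort"), is.list(noise))
  emos <- intersect(EMOTIONS, unique(cohort$emotion))
  missing <- setdiff(emos, names(noise))
  if (length(missing))
    stop("no noise distribution for emotion(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  above <- 0L; total <- 0L
  rows <- lapply(emos, function(e) {
    w <- cohort$weights[cohort$emotion == e, , drop = FALSE]
    if (nrow(w) < 2)
      stop("need >= 2 expressions for emotion ", e, call. = FALSE)
    cds <- pairwise_cd(w)
    thr <- noise[[e]]$threshold
    above <<- above + sum(cds > thr)
    total <<- total + length(cds)
    data.frame(emotion = e, n_pairs = length(cds), threshold = thr,
               exceedance = exceedance(cds, thr))
  })
  structure(list(per_emotion = do.call(rbind, rows),
                 pooled = above / total),
            class = "exceedance_report")
}

#' @export
print.exceedance_report <- function(x, ...) {
  cat("exceedance of between-participant CDs over GA noise thresholds:\n")
  df <- x$per_emotion
  df$exceedance <- sprintf("%.1f%%", 100 * df$exceedance)
  df$threshold <- sprintf("%.4f", df$threshold)
  print(df, row.names = FALSE)
  cat(sprintf("pooled: %.1f%%\n", 100 * x$pooled))
  invisible(x)
}

#' Full noise-threshold analysis of a cohort
#'
#' Computes the per-emotion centroid expressions ("average happy / fear /
#' angry / sad"), simulates the GA noise distribution toward each centroid,
#' and reports per-emotion and pooled exceedance.
#'
#' The null observer is deterministic by default
#' (`decision_noise_sd = 0`): the threshold is meant to capture the noise
#' of the *algorithm* — initialization, crossover, mutation — not of the
#' selector, so variability below it is attributable to the GA procedure
#' itself. Pass different `observer_args` to fold selector noise into the
#' null as well.
#'
#' @inheritParams simulate_noise
#' @param cohort an `expression_cohort`.
#' @param targets optional matrix of fixed target expressions (rownames =
#'   emotions). The default uses the cohort's own per-emotion centroids;
#'   supplying known generating means instead gives an exactly matched
#'   null for cohorts built without between-subject dispersion.
#' @return list with `noise` (per-emotion `noise_distribution`) and
#'   `report` (an `exceedance_report`).
#' @export
ga_noise_thresholds <- function(cohort, n_iter = 500L, config = ga_config(),
                                observer_args = list(decision_noise_sd = 0),
                                seed = NULL, threshold_type = "mean",
                                targets = NULL) {
  cen <- if (is.null(targets)) cohort_centroids(cohort) else targets
  stopifnot(is.matrix(cen),
            all(intersect(EMOTIONS, unique(cohort$emotion)) %in% rownames(cen)))
  emos <- intersect(EMOTIONS, unique(cohort$emotion))
  noise <- lapply(emos, function(e)
    simulate_noise(cen[e, ], n_iter = n_iter, config = config,
                   observer_args = observer_args,
                   threshold_type = threshold_type,
                   seed = if (is.null(seed)) NULL else
                     derive_seed(seed, paste0("noise/", e)),
                   emotion = e))
  names(noise) <- emos
  list(noise = noise, report = exceedance_report(cohort, noise))
}
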