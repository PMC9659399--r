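#' End-to-end simulation pipeline
#'
#' Runs the whole stack from one configuration and one seed: synthetic
#' cohort generation, GA stochastic-noise thresholds and exceedance, PCA +
#' Gaussian-mixture clustering, blendshape fingerprints, SVM category
#' prediction, a simulated recognition experiment, CD binning and the
#' permutation test. Every stage draws its randomness from a child seed
#' derived from the global seed and the stage label, so adding a stage
#' never changes another stage's results.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param seed global seed; every stage derives its own child seed from it.
#' @param ga a [ga_config()] (its `seed` field is ignored in favour of
#'   derived seeds).
#' @param cohort a [cohort_spec()] for the stimulus-maker cohort.
#' @param n_perceivers size of the separate perceiver cohort for the
#'   recognition experiment.
#' @param n_iter GA noise-simulation iterations per emotion.
#' @param n_perm permutations for the recognition test.
#' @param n_bins CD bins.
#' @param pcs principal components kept for clustering.
#' @param k Gaussian-mixture components.
#' @param svm_folds cross-validation folds.
#' @param temperature recognition softmax noise.
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L, ga = ga_config(), cohort = cohort_spec(),
                       n_perceivers = 8L, n_iter = 100L, n_perm = 1000L,
                       n_bins = 4L, pcs = 10L, k = 4L, svm_folds = 5L,
                       temperature = 0.1) {
  stopifnot(inherits(ga, "ga_config"), inherits(cohort, "cohort_spec"))
  structure(list(seed = as.integer(seed), ga = ga, cohort = cohort,
                 n_perceivers = as.integer(n_perceivers),
                 n_iter = as.integer(n_iter), n_perm = as.integer(n_perm),
                 n_bins = as.integer(n_bins), pcs = as.integer(pcs),
                 k = as.integer(k), svm_folds = as.integer(svm_folds),
                 temperature = temperature),
            class = "run_config")
}

#' Run the full pipeline
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, every stage's tables are
#'   written there as CSV plus a `summary.json` stamped with the config
#'   hash and seed. Created (recursively) if missing.
#' @return a list of class `pipeline_result` with elements `cohort`,
#'   `noise`, `pca`, `gmm`, `fingerprints`, `svm`, `recognition`, `binned`,
#'   `permutation`, `summary`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(label) derive_seed(config$seed, label)
  fail <- function(name, e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)

  spec <- config$cohort; spec$seed <- stage("cohort")
  cohort <- tryCatch(generate_cohort(spec, config$ga),
                     error = function(e) fail("generate_cohort", e))

  noise <- tryCatch(
    ga_noise_thresholds(cohort, n_iter = config$n_iter, config = config$ga,
                        seed = stage("noise")),
    error = function(e) fail("noise_sim", e))

  pca <- tryCatch(run_pca(cohort, n_components = config$pcs),
                  error = function(e) fail("run_pca", e))
  gmm <- tryCatch(
    fit_gmm_confusion(pca$scores, cohort$emotion, k = config$k,
                      seed = stage("gmm")),
    error = function(e) fail("fit_gmm_confusion", e))
  fps <- tryCatch(fingerprints(cohort),
                  error = function(e) fail("fingerprints", e))
  svm <- tryCatch(
    svm_category_cv(cohort, folds = config$svm_folds, seed = stage("svm")),
    error = function(e) fail("svm_category_cv", e))

  pspec <- config$cohort
  pspec$n_participants <- config$n_perceivers
  pspec$seed <- stage("perceivers")
  perceivers <- tryCatch(generate_cohort(pspec, config$ga),
                         error = function(e) fail("perceiver_cohort", e))
  rec <- tryCatch(
    simulate_recognition(cohort, perceivers,
                         temperature = config$temperature,
                         seed = stage("recognition")),
    error = function(e) fail("simulate_recognition", e))
  binned <- tryCatch(bin_by_cd(rec, n_bins = config$n_bins),
                     error = function(e) fail("bin_by_cd", e))
  perm <- tryCatch(
    permutation_test(rec, n_bins = config$n_bins, n_perm = config$n_perm,
                     seed = stage("permutation")),
    error = function(e) fail("permutation_test", e))

  summary <- list(
    config_hash = config_hash(config), seed = config$seed,
    n_expressions = nrow(cohort$weights),
    noise_thresholds = lapply(noise$noise, function(x) x$threshold),
    exceedance = c(as.list(stats::setNames(noise$report$per_emotion$exceedance,
                                           noise$report$per_emotion$emotion)),
                   list(pooled = noise$report$pooled)),
    pca_varexp_3 = sum(pca$variance_fraction[1:3]),
    pca_varexp_10 = sum(pca$variance_fraction[seq_len(min(10, length(pca$variance_fraction)))]),
    gmm_diagonal = as.list(stats::setNames(diag(gmm$confusion),
                                           rownames(gmm$confusion))),
    mean_blendshape_sd = lapply(fps, function(f) f$mean_sd),
    svm_overall = svm$overall,
    recognition_accuracy = mean(rec$trials$correct),
    bin_prob_correct = binned$prob_correct,
    bin_p_values = perm$table$p_value)

  out <- structure(list(cohort = cohort, noise = noise, pca = pca,
                        gmm = gmm, fingerprints = fps, svm = svm,
                        recognition = rec, binned = binned,
                        permutation = perm, summary = summary),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(out, config, out_dir)
  out
}

#' @keywords internal
write_pipeline <- function(result, config, out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  stamp <- function(df) {
    attr(df, "provenance") <- NULL
    df
  }
  prov <- c(sprintf("# config_hash: %s", result$summary$config_hash),
            sprintf("# seed: %d", result$summary$seed))
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(prov, path)
    suppressWarnings(utils::write.table(stamp(df), path, append = TRUE,
                                        sep = ",", row.names = FALSE,
                                        quote = FALSE))
    path
  }
  write_expression_table(result$cohort, file.path(out_dir, "cohort.csv"))
  wr(result$noise$report$per_emotion, "exceedance.csv")
  conf <- as.data.frame(result$gmm$confusion)
  conf <- cbind(true_emotion = rownames(result$gmm$confusion), conf)
  wr(conf, "confusion.csv")
  fp <- do.call(rbind, lapply(result$fingerprints, function(f)
    data.frame(emotion = f$emotion, core_index = seq_along(f$mean_weights),
               mean_weight = f$mean_weights, sd_weight = f$sd_weights)))
  wr(fp, "fingerprints.csv")
  write_trials(result$recognition, file.path(out_dir, "trials.csv"))
  wr(result$permutation$table, "permutation.csv")
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result (config ", x$summary$config_hash, ", seed ",
      x$summary$seed, ")\n", sep = "")
  cat(sprintf("  %d expressions; pooled exceedance %.1f%%; GMM diagonal %.2f\n",
              x$summary$n_expressions, 100 * x$summary$exceedance$pooled,
              mean(unlist(x$summary$gmm_diagonal))))
  cat(sprintf("  recognition accuracy %.1f%%; far-bin p = %.4f\n",
              100 * x$summary$recognition_accuracy,
              x$summary$bin_p_values[length(x$summary$bin_p_values)]))
  invisible(x)
}
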