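#' Category structure of a cohort: PCA, Gaussian-mixture clustering,
#' fingerprints and SVM prediction
#'
#' @name category_stats
NULL

#' Principal component analysis of a cohort's expressions
#'
#' Weights are centered but, by default, not variance-scaled: every
#' blendshape dimension already shares the same unit (fraction of maximal
#' activation), and correlation-mode scaling would inflate near-constant
#' units. By default the analysis runs in the rendered 149-dimensional rig
#' space (core cohorts are expanded through `map`); set
#' `representation = "core"` to stay in the 46 independent units.
#'
#' @param cohort an `expression_cohort`.
#' @param n_components number of components to retain in the scores.
#' @param representation `"rig"` (default) or `"core"`.
#' @param scale. logical; variance-scale the dimensions before PCA.
#' @param map a [core_map()] used when expanding a core cohort to the rig.
#' @return object of class `expression_pca`: `loadings` (components x
#'   dims), `scores` (expressions x components), `variance_fraction` (all
#'   components, non-increasing), `n_components`, `rank_deficient` flag.
#' @export
run_pca <- function(cohort, n_components = 10L,
                    representation = c("rig", "core"), scale. = FALSE,
                    map = default_core_map()) {
  stopifnot(inherits(cohort, "expression_cohort"))
  representation <- match.arg(representation)
  X <- cohort$weights
  if (representation == "rig" && cohort$representation == "core")
    X <- t(apply(X, 1L, expand_core, map = map))
  if (representation == "core" && cohort$representation == "rig")
    stop("cannot reduce a rig cohort to core weights", call. = FALSE)
  if (nrow(X) <= n_components)
    stop("need more expressions than components", call. = FALSE)
  p <- stats::prcomp(X, center = TRUE, scale. = scale.)
  vf <- p$sdev^2 / sum(p$sdev^2)
  rank <- sum(p$sdev > max(p$sdev) * 1e-8)
  k <- min(n_components, rank)
  structure(list(loadings = t(p$rotation[, seq_len(k), drop = FALSE]),
                 scores = p$x[, seq_len(k), drop = FALSE],
                 variance_fraction = vf,
                 center = p$center,
                 n_components = k,
                 rank_deficient = rank < min(nrow(X) - 1L, ncol(X)),
                 emotion = cohort$emotion),
            class = "expression_pca")
}

#' @export
print.expression_pca <- function(x, ...) {
  cat("expression-space PCA:", nrow(x$scores), "expressions,",
      x$n_components, "components retained\n")
  k <- x$n_components
  cat(sprintf("  variance explained: first 3 = %.1f%%, first %d = %.1f%%\n",
              100 * sum(x$variance_fraction[1:min(3, k)]), k,
              100 * sum(x$variance_fraction[seq_len(k)])))
  if (x$rank_deficient) cat("  (rank deficient: fewer informative components than dims)\n")
  invisible(x)
}

# best of the 24 cluster->emotion bijections by total diagonal count
#' @keywords internal
best_cluster_assignment <- function(tab) {
  stopifnot(nrow(tab) == ncol(tab))
  k <- nrow(tab)
  perms <- permutations_k(k)
  diag_count <- apply(perms, 1L, function(p) sum(tab[cbind(seq_len(k), p)]))
  perms[which.max(diag_count), ]
}

#' @keywords internal
permutations_k <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_k(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out <- rbind(out, block)
  }
  dimnames(out) <- NULL
  out
}

#' Gaussian-mixture clustering with an emotion confusion matrix
#'
#' Fits a k-component Gaussian mixture with full covariances to the
#' PCA scores (via \pkg{mclust}, model "VVV", deterministic model-based
#' hierarchical initialisation), maps clusters to emotions by the bijection
#' maximising the total diagonal count over all k! assignments, and reports
#' the row-stochastic confusion matrix: row = true emotion, column =
#' emotion label of the assigned cluster.
#'
#' @param scores expressions x components numeric matrix (e.g. the first 10
#'   PC scores).
#' @param labels true emotion label per expression; all four must appear.
#' @param k number of mixture components (default 4, one per emotion).
#' @param n_restarts EM restarts: one from mclust's default model-based
#'   hierarchical initialisation plus `n_restarts - 1` from hierarchical
#'   initialisations on random data subsets; the fit with the best
#'   log-likelihood is kept.
#' @importFrom mclust Mclust mclustBIC priorControl
#' @param seed RNG seed controlling the restart subsets.
#' @return object of class `gmm_confusion`: `assignments` (per-expression
#'   emotion-mapped cluster), `posteriors`, `cluster_to_emotion`,
#'   `confusion` (k x k row-stochastic), `regularized` flag, `model`.
#' @export
fit_gmm_confusion <- function(scores, labels, k = 4L, n_restarts = 10L,
                              seed = NULL) {
  stopifnot(is.matrix(scores), nrow(scores) == length(labels),
            nrow(scores) >= k, n_restarts >= 1)
  labels <- as.character(labels)
  if (!all(EMOTIONS %in% labels))
    stop("all four emotion labels must be present", call. = FALSE)
  n <- nrow(scores)
  # Mclust() re-evaluates mclustBIC() in the caller frame, hence the
  # namespace import rather than :: qualification
  mfit <- function(...)
    suppressWarnings(Mclust(scores, G = k, modelNames = "VVV",
                            verbose = FALSE, ...))
  regularized <- FALSE
  fit <- with_seed(seed, {
    best <- mfit()
    if (is.null(best)) {  # singular covariance: regularize with a prior
      regularized <- TRUE
      best <- mfit(prior = priorControl())
    }
    for (r in seq_len(n_restarts - 1L)) {
      sub <- sample.int(n, max(k + 1L, ceiling(n / 2)))
      cand <- if (regularized)
        mfit(initialization = list(subset = sub), prior = priorControl())
      else mfit(initialization = list(subset = sub))
      if (!is.null(cand) &&
          (is.null(best) || cand$loglik > best$loglik)) best <- cand
    }
    best
  })
  if (is.null(fit)) stop("Gaussian mixture fit failed", call. = FALSE)
  if (regularized)
    warning("Gaussian mixture needed covariance regularization (prior)")
  cl <- fit$classification
  tab <- matrix(0, k, k, dimnames = list(EMOTIONS[seq_len(k)], NULL))
  for (i in seq_len(k))
    for (j in seq_len(k))
      tab[i, j] <- sum(labels == EMOTIONS[i] & cl == j)
  perm <- best_cluster_assignment(tab)  # cluster shown in column perm[i] <-> emotion i
  # cluster j maps to emotion which has perm[e] == j
  cl2emo <- EMOTIONS[order(perm)[seq_len(k)]]
  names(cl2emo) <- as.character(seq_len(k))
  conf <- tab[, perm, drop = FALSE]
  conf <- conf / rowSums(conf)
  dimnames(conf) <- list(true = EMOTIONS[seq_len(k)],
                         assigned = EMOTIONS[seq_len(k)])
  post <- fit$z[, perm, drop = FALSE]
  colnames(post) <- EMOTIONS[seq_len(k)]
  structure(list(assignments = cl2emo[as.character(cl)],
                 posteriors = post, cluster_to_emotion = cl2emo,
                 confusion = conf, regularized = regularized,
                 loglik = fit$loglik),
            class = "gmm_confusion")
}

#' @export
print.gmm_confusion <- function(x, ...) {
  cat("Gaussian-mixture confusion matrix (rows = true emotion):\n")
  print(round(x$confusion, 3))
  cat(sprintf("mean diagonal = %.3f\n", mean(diag(x$confusion))))
  if (x$regularized) cat("(covariance regularization was applied)\n")
  invisible(x)
}

#' Blendshape fingerprint of one emotion category
#'
#' Per-core-unit mean and SD of weights across participants, plus the
#' top-activated and most-variable units with their FACS/AU labels. The SD
#' convention is the population SD (divide by n): the summary is
#' descriptive over the whole cohort, not an inference to a larger
#' population. `mean_sd` (the mean SD across all 46 units) is the overall
#' between-participant variability, in weight-fraction units — multiply by
#' 100 to quote it as "% of the maximum extent of motion".
#'
#' @param cohort an `expression_cohort` (core representation).
#' @param emotion one of `"happy"`, `"fear"`, `"angry"`, `"sad"`.
#' @param au_table AU lookup from [default_au_table()].
#' @param top_k how many peak / most-variable units to rank.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return object of class `fingerprint`: `emotion`, `mean_weights`,
#'   `sd_weights`, `top_peaks`, `top_variable`, `mean_sd`, `n`.
#' @export
fingerprint <- function(cohort, emotion, au_table = default_au_table(),
                        top_k = 5L, sd_type = c("population", "sample")) {
  stopifnot(inherits(cohort, "expression_cohort"),
            cohort$representation == "core")
  emotion <- match.arg(emotion, EMOTIONS)
  sd_type <- match.arg(sd_type)
  W <- cohort$weights[cohort$emotion == emotion, , drop = FALSE]
  if (nrow(W) < 2)
    stop("need >= 2 expressions for emotion ", emotion, call. = FALSE)
  mw <- colMeans(W)
  sdw <- apply(W, 2L, if (sd_type == "population") population_sd else stats::sd)
  rank_tab <- function(v) {
    idx <- order(v, decreasing = TRUE)[seq_len(top_k)]
    cbind(au_label(idx, au_table), value = v[idx])
  }
  structure(list(emotion = emotion, mean_weights = mw, sd_weights = sdw,
                 top_peaks = rank_tab(mw), top_variable = rank_tab(sdw),
                 mean_sd = mean(sdw), n = nrow(W)),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("%s fingerprint (n = %d): mean weight SD = %.1f%% of full activation\n",
              x$emotion, x$n, 100 * x$mean_sd))
  cat("  top activated units:\n")
  p <- x$top_peaks
  for (i in seq_len(nrow(p)))
    cat(sprintf("    AU%-3d %-28s mean = %.2f\n",
                p$au_number[i], p$facs_name[i], p$value[i]))
  cat("  most variable units:\n")
  v <- x$top_variable
  for (i in seq_len(nrow(v)))
    cat(sprintf("    AU%-3d %-28s sd   = %.2f\n",
                v$au_number[i], v$facs_name[i], v$value[i]))
  invisible(x)
}

#' @export
plot.fingerprint <- function(x, ...) {
  u <- seq_along(x$mean_weights)
  plot(u, x$mean_weights, type = "h", lwd = 3, ylim = c(0, 1),
       xlab = "core blendshape unit", ylab = "weight (fraction of max)",
       main = paste(x$emotion, "fingerprint"), ...)
  polygon(c(u, rev(u)),
          c(x$mean_weights + x$sd_weights,
            rev(pmax(x$mean_weights - x$sd_weights, 0))),
          border = NA, col = grDevices::adjustcolor("red", 0.25))
  invisible(x)
}

#' Fingerprints for every emotion in a cohort
#'
#' @inheritParams fingerprint
#' @return named list of [fingerprint()] objects.
#' @export
fingerprints <- function(cohort, au_table = default_au_table(), top_k = 5L,
                         sd_type = "population") {
  emos <- intersect(EMOTIONS, unique(cohort$emotion))
  out <- lapply(emos, fingerprint, cohort = cohort, au_table = au_table,
                top_k = top_k, sd_type = sd_type)
  names(out) <- emos
  out
}

#' Cross-validated SVM prediction of emotion from blendshape weights
#'
#' Stratified k-fold cross-validation of a multiclass support vector
#' machine (linear kernel by default) on the core weights: can the targeted
#' emotion be read off the evolved expression alone?
#'
#' @param cohort an `expression_cohort`.
#' @param folds number of folds (reduced, with a warning, if an emotion has
#'   fewer members than folds).
#' @param kernel,cost passed to [e1071::svm()].
#' @param seed fold-assignment seed.
#' @return object of class `svm_cv`: `overall` accuracy, `per_class`
#'   accuracies, `fold_accuracy` (per-fold overall rates), `folds`.
#' @export
svm_category_cv <- function(cohort, folds = 5L, kernel = "linear", cost = 1,
                            seed = NULL) {
  stopifnot(inherits(cohort, "expression_cohort"))
  y <- factor(cohort$emotion, levels = intersect(EMOTIONS, unique(cohort$emotion)))
  X <- cohort$weights
  min_class <- min(table(y))
  if (min_class < folds) {
    warning("smallest emotion class has ", min_class,
            " members; reducing folds to ", min_class)
    folds <- min_class
  }
  stopifnot(folds >= 2)
  fold_id <- with_seed(seed, {
    id <- integer(length(y))
    for (lev in levels(y)) {
      idx <- which(y == lev)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    # weights share the [0, 1] unit already; scaling would also warn on
    # units that happen to be constant in a small training fold
    fit <- e1071::svm(x = X[!test, , drop = FALSE], y = y[!test],
                      kernel = kernel, cost = cost, scale = FALSE)
    pred[test] <- stats::predict(fit, X[test, , drop = FALSE])
  }
  per_class <- vapply(levels(y), function(lev)
    mean(pred[y == lev] == lev), numeric(1))
  fold_acc <- vapply(seq_len(folds), function(f)
    mean((pred == y)[fold_id == f]), numeric(1))
  structure(list(overall = mean(pred == y), per_class = per_class,
                 fold_accuracy = fold_acc, folds = folds,
                 predictions = pred, truth = y),
            class = "svm_cv")
}

#' @export
print.svm_cv <- function(x, ...) {
  cat(sprintf("SVM %d-fold CV: overall accuracy = %.1f%% (fold SD %.1f%%)\n",
              x$folds, 100 * x$overall, 100 * stats::sd(x$fold_accuracy)))
  for (lev in names(x$per_class))
    cat(sprintf("  %-6s %.1f%%\n", lev, 100 * x$per_class[lev]))
  invisible(x)
}
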