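#' Expression space: blendshape vectors, the core-to-rig coupling and the
#' cosine-distance metric
#'
#' The avatar face is driven by a 149-dimensional blendshape rig; only 46
#' "core" blendshape units can move independently during evolution, and the
#' remaining rig dimensions follow them through a nonnegative coupling map.
#' Every weight is a fraction of maximal activation, so lives in [0, 1].
#'
#' @name blendspace
NULL

N_RIG  <- 149L
N_CORE <- 46L

#' Validate a core blendshape vector
#'
#' @param x numeric vector of 46 weights in [0, 1].
#' @return `x`, invisibly, after validation.
#' @export
validate_core <- function(x) {
  if (!is.numeric(x) || length(x) != N_CORE)
    stop("a core vector must have exactly ", N_CORE, " numeric entries, got ",
         length(x), call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x > 1))
    stop("core weights must all lie in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Validate a full rig expression vector
#'
#' @param x numeric vector of 149 weights in [0, 1].
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  if (!is.numeric(x) || length(x) != N_RIG)
    stop("an expression vector must have exactly ", N_RIG,
         " numeric entries, got ", length(x), call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x > 1))
    stop("rig weights must all lie in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Cosine distance between two expression vectors
#'
#' `1 - a.b / (|a||b|)`: the dissimilarity measure used throughout the
#' package. Because blendshape weights are nonnegative the distance lies in
#' [0, 1]; it is 0 exactly when the vectors are positively collinear, so it
#' ignores overall expression intensity and compares only the *pattern* of
#' activation.
#'
#' @param a,b numeric weight vectors of equal length, entries in [0, 1],
#'   neither all-zero.
#' @return a single number in [0, 1].
#' @examples
#' a <- c(1, 1, rep(0, 44)); b <- c(1, rep(0, 45))
#' cosine_distance(a, b)  # 1 - 1/sqrt(2)
#' @export
cosine_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("vectors differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    stop("cosine distance is undefined for an all-zero expression vector",
         call. = FALSE)
  # clamp: rounding can push the ratio a hair outside [0, 1]
  min(max(1 - sum(a * b) / (na * nb), 0), 1)
}

#' All unordered pairwise cosine distances
#'
#' Pairs are enumerated in column-major lower-triangle order, i.e.
#' (2,1), (3,1), ..., (n,1), (3,2), ... — the order `stats::dist` uses —
#' so element k of the result is reproducible across calls.
#'
#' @param vectors a list of weight vectors, or a matrix with one row per
#'   expression.
#' @return numeric vector of length n(n-1)/2.
#' @export
pairwise_cd <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  stopifnot(is.matrix(vectors))
  n <- nrow(vectors)
  if (n < 2) stop("need at least 2 vectors for pairwise distances", call. = FALSE)
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0))
    stop("cosine distance is undefined for an all-zero expression vector",
         call. = FALSE)
  g <- (vectors %*% t(vectors)) / outer(norms, norms)
  d <- 1 - g[lower.tri(g)]
  pmin(pmax(d, 0), 1)
}

#' Procedurally generate a random core expression
#'
#' Each core unit is independently switched on with probability
#' `activation_prob`; active units draw a magnitude from `magnitude_law`.
#' This sparse-activation scheme mimics the procedurally generated faces
#' shown on the initialization trial: most units at rest, a plausible
#' scatter of active muscle groups.
#'
#' @param activation_prob probability in (0, 1] that a unit is active.
#' @param magnitude_law either `"uniform"` (default, Uniform(0,1)) or a
#'   function `f(n)` returning `n` magnitudes in [0, 1].
#' @return a core vector (length 46 numeric in [0, 1]).
#' @export
random_expression <- function(activation_prob = 0.3, magnitude_law = "uniform") {
  if (!is.numeric(activation_prob) || length(activation_prob) != 1L ||
      activation_prob <= 0 || activation_prob > 1)
    stop("activation_prob must be a single number in (0, 1]", call. = FALSE)
  law <- magnitude_law
  if (is.character(law)) {
    law <- switch(match.arg(law, "uniform"), uniform = function(n) runif(n))
  }
  stopifnot(is.function(law))
  active <- runif(N_CORE) < activation_prob
  w <- numeric(N_CORE)
  if (any(active)) w[active] <- clip01(law(sum(active)))
  w
}

# ---- core-to-rig coupling ---------------------------------------------------

#' Construct a core-to-rig coupling map
#'
#' @param coupling 149 x 46 matrix of nonnegative coefficients; rig weights
#'   are `clip(coupling %*% core, 0, 1)`.
#' @param names character vector of 46 human-readable core unit names.
#' @return an object of class `core_map`.
#' @export
core_map <- function(coupling, names = NULL) {
  stopifnot(is.matrix(coupling), nrow(coupling) == N_RIG,
            ncol(coupling) == N_CORE)
  if (any(coupling < 0)) stop("coupling coefficients must be nonnegative",
                              call. = FALSE)
  if (any(rowSums(coupling) == 0))
    stop("every rig dimension must be driven by at least one core unit",
         call. = FALSE)
  if (is.null(names)) names <- sprintf("core%02d", seq_len(N_CORE))
  stopifnot(length(names) == N_CORE)
  structure(list(coupling = coupling, names = names,
                 format_version = 1L),
            class = "core_map")
}

#' Default block-diagonal coupling map
#'
#' The published rig's true coupling coefficients live in an archived
#' technical report, not in a form this package can ship; the default map
#' partitions the 149 rig dimensions into 46 contiguous groups, each driven
#' identically (coefficient 1) by its core unit. This preserves the
#' 46-independent / 149-rendered structure without inventing facial
#' anatomy; a measured rig loads through [read_core_map()].
#'
#' @return a `core_map`.
#' @export
default_core_map <- function() {
  sizes <- rep(3L, N_CORE)
  sizes[seq_len(N_RIG - 3L * N_CORE)] <- 4L   # 149 = 11*4 + 35*3
  m <- matrix(0, N_RIG, N_CORE)
  row <- 1L
  for (j in seq_len(N_CORE)) {
    m[row:(row + sizes[j] - 1L), j] <- 1
    row <- row + sizes[j]
  }
  core_map(m, default_au_table()$facs_name)
}

#' Expand a core vector to the full rig
#'
#' @param core length-46 core weight vector.
#' @param map a [core_map()]; defaults to [default_core_map()].
#' @return length-149 rig expression vector (clipped to [0, 1]).
#' @export
expand_core <- function(core, map = default_core_map()) {
  validate_core(core)
  stopifnot(inherits(map, "core_map"))
  clip01(drop(map$coupling %*% core))
}

#' @export
print.core_map <- function(x, ...) {
  cat("core-to-rig coupling map:", N_RIG, "rig dims <-", N_CORE,
      "core units\n")
  nz <- sum(x$coupling > 0)
  cat("  nonzero coefficients:", nz, "\n")
  invisible(x)
}

# ---- AU labels --------------------------------------------------------------

#' Action-unit lookup table for the 46 core blendshape units
#'
#' Maps each core unit to a FACS (Facial Action Coding System) name and
#' action-unit number. Units 1-23 are bilateral actions; 24-46 are the
#' left/right split variants a symmetric rig exposes. Shipped as a plain
#' CSV under `extdata` so a measured rig's table can be dropped in.
#'
#' @param path optional path to an alternative CSV with columns
#'   `core_index, facs_name, au_number`.
#' @return data.frame with columns `core_index`, `facs_name`, `au_number`.
#' @export
default_au_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "au_table.csv", package = "gaexpr",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("core_index", "facs_name", "au_number")
  if (!all(need %in% names(tab)))
    stop("AU table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tab
}

#' Label core units with their AU names
#'
#' @param units integer core-unit indices.
#' @param au_table an AU lookup table from [default_au_table()].
#' @return data.frame with `core_index`, `facs_name`, `au_number`; unknown
#'   units get the placeholder name `"unlabelled"` and `NA` AU, with a
#'   warning.
#' @export
au_label <- function(units, au_table = default_au_table()) {
  i <- match(units, au_table$core_index)
  out <- data.frame(core_index = units,
                    facs_name = au_table$facs_name[i],
                    au_number = au_table$au_number[i],
                    stringsAsFactors = FALSE)
  if (anyNA(i)) {
    warning("no AU label for core unit(s) ",
            paste(units[is.na(i)], collapse = ", "))
    out$facs_name[is.na(i)] <- "unlabelled"
  }
  out
}
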