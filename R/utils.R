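#' @keywords internal
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state, so library code never clobbers a user's
#' random stream. A `NULL` seed evaluates `expr` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive a child seed from a global seed and an operation label
#'
#' Hashes the label (FNV-1a, 32-bit) and mixes it with the global seed so
#' that every pipeline stage gets an independent, reproducible stream and
#' adding a new stage never perturbs the randomness of existing ones.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the operation.
#' @return integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- fnv1a(paste0(label, ":", format(seed)))
  as.integer((h + as.double(seed)) %% 2147483647)
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, returned as a double
# (R has no native unsigned 32-bit integer).
#' @keywords internal
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

#' @keywords internal
bitwXor32 <- function(a, b) {
  # xor of two doubles holding 32-bit unsigned values
  r <- 0
  p <- 1
  for (i in 1:32) {
    ab <- a %% 2; bb <- b %% 2
    if (ab != bb) r <- r + p
    a <- (a - ab) / 2; b <- (b - bb) / 2
    p <- p * 2
  }
  r
}

#' Short provenance hash of an R object
#'
#' FNV-1a hash of the object's deparsed form, printed as 8 hex digits.
#' Used to stamp pipeline outputs with the configuration they came from.
#'
#' @param x any R object.
#' @return character scalar, 8 hex digits.
#' @export
config_hash <- function(x) {
  h <- fnv1a(paste(deparse(x), collapse = "\n"))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @keywords internal
population_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @keywords internal
EMOTIONS <- c("happy", "fear", "angry", "sad")
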