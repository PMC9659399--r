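# Shared fixture builders. Everything is generated in code at test time.

EMOS <- c("happy", "fear", "angry", "sad")

# four strongly separated category means: disjoint 8-unit blocks at 0.9
separated_means <- function(weight = 0.9) {
  m <- matrix(0, 4, 46, dimnames = list(EMOS, NULL))
  for (i in 1:4) m[i, ((i - 1) * 8 + 1):(i * 8)] <- weight
  m
}

# a cohort of sparse random expressions (no GA), one shared distribution
random_cohort <- function(n_participants, seed) {
  with_seed(seed, {
    rows <- n_participants * 4
    W <- t(replicate(rows, random_expression()))
    W[rowSums(W) == 0, 1] <- 0.5
    expression_cohort(W,
                      rep(sprintf("P%03d", seq_len(n_participants)), each = 4),
                      rep(EMOS, n_participants))
  })
}

# small GA-generated cohort with package defaults
ga_cohort <- function(n_participants = 6, between_subject_sd = 0.15,
                      seed = 1, means = default_category_means(),
                      observer_args = list()) {
  generate_cohort(cohort_spec(n_participants = n_participants,
                              category_means = means,
                              between_subject_sd = between_subject_sd,
                              observer_args = observer_args, seed = seed))
}

# a unit vector along core dimension i
unit_core <- function(i, value = 1) {
  v <- numeric(46); v[i] <- value; v
}

# a perceiver cohort whose four preferred expressions sit on disjoint units
toy_perceivers <- function(n = 2, jitter = 0) {
  W <- NULL; pid <- NULL; emo <- NULL
  for (p in seq_len(n)) {
    m <- separated_means()
    if (jitter > 0)
      m <- pmin(pmax(m + matrix(runif(length(m), -jitter, jitter),
                                nrow(m)), 0), 1)
    W <- rbind(W, m)
    pid <- c(pid, rep(sprintf("V%02d", p), 4))
    emo <- c(emo, EMOS)
  }
  expression_cohort(W, pid, emo)
}
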