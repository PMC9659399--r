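#' Readers and writers for expression tables, coupling maps, session logs
#' and trial tables
#'
#' @name io
NULL

#' Write a cohort as a delimited expression table
#'
#' Header is `participant_id,emotion,c01..c46` for core cohorts or
#' `participant_id,emotion,w001..w149` for rig cohorts; weights are
#' decimals in [0, 1], UTF-8, comma-separated.
#'
#' @param cohort an `expression_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "expression_cohort"))
  W <- cohort$weights
  cols <- if (ncol(W) == N_CORE) sprintf("c%02d", seq_len(N_CORE))
          else sprintf("w%03d", seq_len(N_RIG))
  df <- data.frame(participant_id = cohort$participant_id,
                   emotion = cohort$emotion, W, check.names = FALSE)
  names(df)[-(1:2)] <- cols
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression table into a cohort
#'
#' Accepts both dialects (46 `cXX` columns or 149 `wXXX` columns); the
#' returned cohort is tagged with the detected representation. Malformed
#' rows are reported with their row and column.
#'
#' @param path a CSV written by [write_expression_table()] or following the
#'   same header convention.
#' @return an `expression_cohort`.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("participant_id", "emotion")
  if (!all(need %in% names(tab)))
    stop("expression table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  core_cols <- sprintf("c%02d", seq_len(N_CORE))
  rig_cols <- sprintf("w%03d", seq_len(N_RIG))
  cols <- if (all(core_cols %in% names(tab))) core_cols
          else if (all(rig_cols %in% names(tab))) rig_cols
          else stop("expected weight columns c01..c46 or w001..w149",
                    call. = FALSE)
  W <- as.matrix(tab[, cols])
  if (!is.numeric(W)) stop("weight columns must be numeric", call. = FALSE)
  bad <- which(is.na(W) | W < 0 | W > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("weight out of [0, 1] at row %d, column %s",
                 bad[1, 1], cols[bad[1, 2]]), call. = FALSE)
  bad_emo <- setdiff(unique(tab$emotion), EMOTIONS)
  if (length(bad_emo))
    stop("unknown emotion label(s): ", paste(bad_emo, collapse = ", "),
         call. = FALSE)
  expression_cohort(W, tab$participant_id, tab$emotion)
}

#' Write / read a core-to-rig coupling map
#'
#' YAML with a `format_version` field, per-core names, and the 149 x 46
#' coefficient matrix stored row-wise.
#'
#' @param map a [core_map()].
#' @param path file path.
#' @return `path` / a `core_map`.
#' @export
write_core_map <- function(map, path) {
  stopifnot(inherits(map, "core_map"))
  obj <- list(format_version = map$format_version, names = map$names,
              n_rig = nrow(map$coupling), n_core = ncol(map$coupling),
              coupling = apply(map$coupling, 1L, function(r)
                paste(format(r, trim = TRUE), collapse = " ")))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_core_map
#' @export
read_core_map <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$format_version))
    stop("coupling map file lacks a format_version field", call. = FALSE)
  rows <- lapply(obj$coupling, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
  m <- do.call(rbind, rows)
  core_map(m, unlist(obj$names))
}

#' Write / read a GA session log (JSON)
#'
#' One JSON object per session: config, per-generation candidate matrices,
#' selection masks, best indices, and the preferred expression. The round
#' trip is lossless up to numeric printing precision (17 significant
#' digits, i.e. exact for doubles).
#'
#' @param session a `ga_session`.
#' @param path file path.
#' @return `path` / a `ga_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "ga_session"))
  cfg <- session$config[setdiff(names(session$config), "magnitude_law")]
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  obj <- list(
    config = cfg,
    generations = lapply(session$generations, function(g)
      list(index = g$index, candidates = g$candidates,
           selected = g$selected, best_index = g$best_index)),
    preferred = session$preferred)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- do.call(ga_config, obj$config)
  gens <- lapply(obj$generations, function(g) {
    cand <- do.call(rbind, lapply(g$candidates, as.numeric))
    ga_generation(g$index, cand, unlist(g$selected), g$best_index)
  })
  structure(list(config = cfg, generations = gens,
                 preferred = as.numeric(unlist(obj$preferred))),
            class = "ga_session")
}

#' Write / read a recognition-trials table
#'
#' Delimited text `perceiver_id,stimulus_id,true_emotion,response_emotion`;
#' the stimulus expressions and perceiver preferred expressions travel as
#' separate expression tables.
#'
#' @param rec a `recognition_trials` object.
#' @param path trials CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(rec, path) {
  stopifnot(inherits(rec, "recognition_trials"))
  utils::write.csv(rec$trials[, c("perceiver_id", "stimulus_id",
                                  "true_emotion", "response_emotion")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a recognition-trials object from its on-disk parts
#'
#' @param trials_path trials CSV (see [write_trials()]).
#' @param stimuli an `expression_cohort` of stimulus expressions whose
#'   rows, in order, carry the ids appearing in `stimulus_id`.
#' @param perceivers an `expression_cohort` of the perceivers' preferred
#'   expressions.
#' @return a `recognition_trials` object.
#' @export
read_trials <- function(trials_path, stimuli, perceivers) {
  t <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  need <- c("perceiver_id", "stimulus_id", "true_emotion", "response_emotion")
  if (!all(need %in% names(t)))
    stop("trials table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(c(t$true_emotion, t$response_emotion)), EMOTIONS)
  if (length(bad))
    stop("unknown emotion label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  t$correct <- t$true_emotion == t$response_emotion
  stim_id <- sprintf("S%03d_%s", seq_len(nrow(stimuli$weights)),
                     stimuli$emotion)
  if (!all(t$stimulus_id %in% stim_id))
    stop("trials reference stimulus ids not present in the stimulus table",
         call. = FALSE)
  structure(list(trials = t, stimulus_weights = stimuli$weights,
                 stimulus_id = stim_id, stimulus_emotion = stimuli$emotion,
                 perceiver_preferred = preferred_map(perceivers)),
            class = "recognition_trials")
}
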