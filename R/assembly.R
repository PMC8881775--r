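#' Study assembly: linkage, inclusion, standardization, aggregation
#'
#' Joins voice- and keyboard-derived feature streams to their ESM surveys,
#' applies the cohort inclusion rules, and produces the two analysis
#' datasets: the momentary dataset (within-person standardized repeated
#' measures) and the trait dataset (per-participant aggregates plus the
#' DASS depression score).
#'
#' @name study_assembly
NULL

EMOTIONS <- c("valence", "arousal", "anger", "anxiety", "sadness",
              "stress", "happiness")

#' Link voice recordings to ESM surveys
#'
#' Exact timestamp matches are linked first; remaining recordings link to
#' the nearest survey of the same participant within `window_s` seconds.
#' Matching is greedy by increasing time difference, so each recording
#' links to at most one survey and vice versa; a recording losing the
#' competition for a survey is reported as unlinked.
#'
#' @param surveys data.frame with `participant_id`, `timestamp` (seconds).
#' @param recordings data.frame with `participant_id`, `timestamp`, plus
#'   any feature columns to carry along.
#' @param window_s maximum separation in seconds (default 300).
#' @return list: `links` (survey timestamp, recording timestamp, delta_s,
#'   exact flag, carried feature columns) and `unlinked` (recordings
#'   without a partner, with a `reason`).
#' @export
link_voice <- function(surveys, recordings, window_s = 300) {
  links <- list(); unlinked <- list()
  for (pid in unique(recordings$participant_id)) {
    sv <- surveys[surveys$participant_id == pid, , drop = FALSE]
    rc <- recordings[recordings$participant_id == pid, , drop = FALSE]
    if (nrow(sv) == 0) {
      rc$reason <- "no surveys for participant"
      unlinked[[length(unlinked) + 1]] <- rc
      next
    }
    # all candidate pairs within the window, nearest first
    cand <- expand.grid(si = seq_len(nrow(sv)), ri = seq_len(nrow(rc)))
    cand$delta <- abs(sv$timestamp[cand$si] - rc$timestamp[cand$ri])
    cand <- cand[cand$delta <= window_s, , drop = FALSE]
    cand <- cand[order(cand$delta, sv$timestamp[cand$si],
                       rc$timestamp[cand$ri]), , drop = FALSE]
    used_s <- logical(nrow(sv)); used_r <- logical(nrow(rc))
    for (k in seq_len(nrow(cand))) {
      si <- cand$si[k]; ri <- cand$ri[k]
      if (used_s[si] || used_r[ri]) next
      used_s[si] <- TRUE; used_r[ri] <- TRUE
      row <- rc[ri, , drop = FALSE]
      row$survey_timestamp <- sv$timestamp[si]
      row$delta_s <- cand$delta[k]
      row$exact <- cand$delta[k] == 0
      links[[length(links) + 1]] <- row
    }
    if (any(!used_r)) {
      lost <- rc[!used_r, , drop = FALSE]
      lost$reason <- "no free survey within window"
      unlinked[[length(unlinked) + 1]] <- lost
    }
  }
  list(links = if (length(links)) do.call(rbind, links) else NULL,
       unlinked = if (length(unlinked)) do.call(rbind, unlinked) else NULL)
}

#' Pre-enrollment participant flow arithmetic
#'
#' Computes the screening and enrollment stages of the cohort accounting:
#' eligible = screened - screening exclusions; enrolled = lab attendees -
#' consent refusals - failed installations.
#'
#' @param screened people completing the screening survey.
#' @param excluded_screening screening-criteria exclusions.
#' @param attended people attending the laboratory session.
#' @param consent_refused,install_failed lab-stage drop-outs.
#' @return data.frame with `stage` and `n` rows for every stage.
#' @export
participant_flow <- function(screened, excluded_screening, attended,
                             consent_refused, install_failed) {
  eligible <- screened - excluded_screening
  enrolled <- attended - consent_refused - install_failed
  data.frame(stage = c("screened", "excluded_screening", "eligible",
                       "attended", "consent_refused", "install_failed",
                       "enrolled"),
             n = c(screened, excluded_screening, eligible, attended,
                   consent_refused, install_failed, enrolled))
}

#' Apply the analysis inclusion rules
#'
#' Retains participants with at least `min_responses` answered surveys and
#' at least one linked observation of the stream under analysis, and emits
#' a stage-by-stage accounting table (retained + excluded = input at every
#' stage).
#'
#' @param surveys answered surveys (`participant_id` per row).
#' @param linked linked observations (`participant_id` per row).
#' @param min_responses response threshold (default 30).
#' @return list: `retained` (participant ids), `accounting` (data.frame).
#' @export
apply_inclusion <- function(surveys, linked, min_responses = 30) {
  if (nrow(surveys) == 0) stopf("empty cohort")
  counts <- table(surveys$participant_id)
  all_ids <- names(counts)
  enough <- all_ids[counts >= min_responses]
  with_stream <- unique(as.character(linked$participant_id))
  retained <- intersect(enough, with_stream)
  acct <- data.frame(
    stage = c("with_surveys", paste0("excluded_lt", min_responses, "_responses"),
              "excluded_no_stream", "retained"),
    n = c(length(all_ids),
          length(all_ids) - length(enough),
          length(enough) - length(retained),
          length(retained)))
  list(retained = retained, accounting = acct)
}

#' Within-person standardization
#'
#' z-scores every variable per participant over that participant's linked
#' observations only (sample SD). Variables with fewer than two
#' observations or zero variance for a participant become NA for that
#' participant and are recorded in the `dropped` attribute.
#'
#' @param data linked-observation data.frame with `participant_id`.
#' @param vars character vector of columns to standardize.
#' @return `data` with `vars` replaced by z-scores; attribute `dropped`
#'   lists (participant, variable) pairs with zero variance.
#' @export
standardize_within <- function(data, vars, id = "participant_id") {
  dropped <- list()
  for (v in vars) {
    for (pid in unique(data[[id]])) {
      sel <- data[[id]] == pid & !is.na(data[[v]])
      x <- data[[v]][sel]
      if (length(x) < 2 || stats::sd(x) == 0) {
        data[[v]][data[[id]] == pid] <- NA_real_
        dropped[[length(dropped) + 1]] <-
          data.frame(participant_id = pid, variable = v)
      } else {
        data[[v]][sel] <- (x - mean(x)) / stats::sd(x)
      }
    }
  }
  attr(data, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  data
}

#' Aggregate to the trait level
#'
#' One row per participant: the mean of every emotion and feature over
#' that participant's linked observations, plus the DASS depression
#' subscale (mean of 7 items on the 0-3 scale). Participants with missing
#' DASS items get NA depression.
#'
#' @param data linked-observation data.frame with `participant_id`.
#' @param vars columns to average.
#' @param dass data.frame with `participant_id` and 7 item columns
#'   `dass1`..`dass7`, or NULL.
#' @return trait-level data.frame, one row per participant.
#' @export
aggregate_traits <- function(data, vars, dass = NULL) {
  ids <- unique(data$participant_id)
  out <- data.frame(participant_id = ids)
  for (v in vars) {
    out[[v]] <- vapply(ids, function(pid) {
      x <- data[[v]][data$participant_id == pid]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
  }
  if (!is.null(dass)) {
    items <- paste0("dass", 1:7)
    stopifnot(all(items %in% names(dass)))
    out$dass_depression <- vapply(ids, function(pid) {
      row <- dass[dass$participant_id == pid, items]
      if (nrow(row) != 1 || anyNA(row)) NA_real_ else mean(as.numeric(row))
    }, numeric(1))
  }
  out
}

#' DASS depression subscale score
#'
#' Mean of the 7 depression items (each rated 0-3).
#'
#' @param items numeric vector of length 7 with values in 0..3.
#' @return the subscale score in [0, 3].
#' @export
dass_depression <- function(items) {
  stopifnot(length(items) == 7)
  if (any(!items %in% 0:3)) stopf("DASS items must be integers 0..3")
  mean(items)
}

#' Compliance summary
#'
#' Per-participant compliance (answered / scheduled) with cohort mean, SD
#' and range.
#'
#' @param answered data.frame with `participant_id` and logical `answered`
#'   per scheduled beep.
#' @return list: `per_participant` data.frame, `mean`, `sd`, `range`.
#' @export
compliance_stats <- function(answered) {
  ids <- unique(answered$participant_id)
  cp <- vapply(ids, function(pid) {
    a <- answered$answered[answered$participant_id == pid]
    mean(a)
  }, numeric(1))
  per <- data.frame(participant_id = ids, compliance = cp)
  list(per_participant = per, mean = mean(cp), sd = stats::sd(cp),
       range = range(cp))
}

#' Within-person day-versus-activity correlation
#'
#' Pools the correlation between study day and a daily activity count
#' after centering both within participants (a declining-compliance
#' check).
#'
#' @param daily data.frame with `participant_id`, `day`, `count`.
#' @return the pooled Pearson correlation.
#' @export
day_activity_correlation <- function(daily) {
  cd <- stats::ave(daily$day, daily$participant_id) # within-person day mean
  cc <- stats::ave(daily$count, daily$participant_id)
  x <- daily$day - cd; y <- daily$count - cc
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
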