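#' Typing-dynamics features from keystroke logs
#'
#' Keystroke event streams (character and backspace keys with press and
#' release timestamps in milliseconds) are summarized per entry (one
#' message or note) and then pooled into one bin per ESM survey covering
#' 30 minutes before to 30 minutes after the survey. Counts and durations
#' are summed over the entries of a bin; typing speed and mean key press
#' duration are averaged (unweighted). Backspaces and typing duration are
#' then expressed relative to the total number of keystrokes in the bin
#' (characters + backspaces).
#'
#' @name keyboard_features
NULL

TYPING_FEATURES <- c("n_characters", "typing_speed", "avg_key_press_duration",
                     "n_entries", "backspaces_rel", "typing_duration_rel")

#' Summarize one keyboard entry
#'
#' @param events data.frame with columns `key_class` ("character" or
#'   "backspace"), `press_ms`, `release_ms` for a single entry.
#' @return list: `n_characters`, `n_backspaces`, `duration_s` (last release
#'   minus first press), `typing_speed` (characters/second; NA when the
#'   duration is zero), `avg_key_press_duration_ms` (over all events),
#'   `first_press_ms`.
#' @export
summarize_entry <- function(events) {
  if (is.null(events) || nrow(events) == 0) stopf("entry has no events")
  if (any(events$release_ms < events$press_ms))
    stopf("release before press in entry")
  n_char <- sum(events$key_class == "character")
  n_back <- sum(events$key_class == "backspace")
  dur <- (max(events$release_ms) - min(events$press_ms)) / 1000
  speed <- if (dur > 0) n_char / dur else NA_real_
  list(n_characters = n_char,
       n_backspaces = n_back,
       duration_s = dur,
       typing_speed = speed,
       avg_key_press_duration_ms = mean(events$release_ms - events$press_ms),
       first_press_ms = min(events$press_ms))
}

#' Summarize all entries of a keystroke log
#'
#' @param events data.frame with `participant_id`, `entry_id`, `key_class`,
#'   `press_ms`, `release_ms`.
#' @return data.frame, one row per (participant, entry).
#' @export
summarize_entries <- function(events) {
  stopifnot(all(c("participant_id", "entry_id", "key_class",
                  "press_ms", "release_ms") %in% names(events)))
  keys <- unique(events[, c("participant_id", "entry_id")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    ev <- events[events$participant_id == keys$participant_id[i] &
                 events$entry_id == keys$entry_id[i], ]
    c(list(participant_id = keys$participant_id[i],
           entry_id = keys$entry_id[i]),
      summarize_entry(ev))
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Pool keyboard entries into one survey bin
#'
#' An entry belongs to the bin iff its first key press lies in
#' `[esm - half_window, esm + half_window)` (closed-left, open-right).
#' Counts and durations are summed; typing speed and key press duration
#' are unweighted means over the bin's entries.
#'
#' @param entries entry-level data.frame from [summarize_entries()].
#' @param esm_ms survey timestamp in milliseconds.
#' @param half_window_min half window width in minutes (default 30).
#' @return one-row data.frame of typing features, or `NULL` for an empty
#'   bin (the survey then has no keyboard observation).
#' @export
bin_keyboard <- function(entries, esm_ms, half_window_min = 30) {
  w <- half_window_min * 60 * 1000
  sel <- entries$first_press_ms >= esm_ms - w & entries$first_press_ms < esm_ms + w
  e <- entries[sel, , drop = FALSE]
  if (nrow(e) == 0) return(NULL)
  n_char <- sum(e$n_characters)
  n_back <- sum(e$n_backspaces)
  keystrokes <- n_char + n_back
  data.frame(
    n_characters = n_char,
    typing_speed = mean(e$typing_speed, na.rm = TRUE),
    avg_key_press_duration = mean(e$avg_key_press_duration_ms),
    n_entries = nrow(e),
    backspaces_rel = if (keystrokes > 0) n_back / keystrokes else NA_real_,
    typing_duration_rel = if (keystrokes > 0) sum(e$duration_s) / keystrokes
                          else NA_real_)
}

#' Bin a participant's keyboard log against all of their surveys
#'
#' @param entries entry-level data.frame (single participant or with a
#'   `participant_id` column matching the surveys).
#' @param surveys data.frame with `participant_id` and `timestamp_ms`.
#' @param half_window_min half window width in minutes.
#' @return data.frame keyed by participant and survey timestamp; surveys
#'   with empty bins are omitted.
#' @export
bin_keyboard_all <- function(entries, surveys, half_window_min = 30) {
  out <- list()
  for (i in seq_len(nrow(surveys))) {
    ent <- entries[entries$participant_id == surveys$participant_id[i], ,
                   drop = FALSE]
    b <- bin_keyboard(ent, surveys$timestamp_ms[i], half_window_min)
    if (!is.null(b)) {
      b$participant_id <- surveys$participant_id[i]
      b$timestamp_ms <- surveys$timestamp_ms[i]
      out[[length(out) + 1]] <- b
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
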