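#' Dataset assembly from a simulated or exported study
#'
#' Convenience wrappers that chain linkage, inclusion, standardization and
#' trait aggregation into the two analysis datasets for one stream
#' (voice or keyboard), mirroring the preprocessing rules: voice
#' recordings link to surveys within 5 minutes, keyboard activity pools
#' into the hour around each survey, participants need at least 30
#' answered surveys and one observation of the stream, and momentary
#' variables are standardized within participants over the linked
#' observations only.
#'
#' @name pipeline
NULL

stream_features <- function(stream = c("voice", "keyboard")) {
  stream <- match.arg(stream)
  fs <- feature_sets()
  if (stream == "voice") c(fs$speech_content, fs$speech_form)
  else c(fs$writing_content, fs$writing_form)
}

#' Assemble momentary and trait analysis datasets for one stream
#'
#' @param study an `emolang_study` (or a compatible list with `surveys`,
#'   `features`, `dass`).
#' @param stream "voice" or "keyboard".
#' @param min_responses inclusion threshold on answered surveys.
#' @param features optional feature data.frame overriding
#'   `study$features` (e.g. features re-extracted from rendered
#'   artifacts); must carry `participant_id`, `beep` and the stream's
#'   feature columns plus `has_voice`/`has_keyboard`.
#' @return list: `momentary` (standardized), `trait`, `accounting`,
#'   `retained`, `n_linked`.
#' @export
assemble_analysis <- function(study, stream = c("voice", "keyboard"),
                              min_responses = 30, features = NULL) {
  stream <- match.arg(stream)
  feats <- features %||% study$features
  fcols <- intersect(stream_features(stream), names(feats))
  present <- if (stream == "voice") feats$has_voice else feats$has_keyboard
  linked <- merge(study$surveys,
                  feats[present, c("participant_id", "beep", fcols)],
                  by = c("participant_id", "beep"))
  linked <- linked[order(linked$participant_id, linked$beep), ]
  inc <- apply_inclusion(study$surveys, linked, min_responses)
  linked <- linked[linked$participant_id %in% inc$retained, , drop = FALSE]
  if (nrow(linked) == 0) stopf("no linked observations after inclusion")
  vars <- c(EMOTIONS, fcols)
  momentary <- standardize_within(linked, vars)
  trait <- aggregate_traits(linked, vars, dass = study$dass)
  list(momentary = momentary, trait = trait, accounting = inc$accounting,
       retained = inc$retained, n_linked = nrow(linked))
}

#' Re-extract features from rendered artifacts
#'
#' Runs the three extractors over a full render: content features from
#' the transcript and message files, acoustic features from the WAV
#' clips (linked to surveys within 5 minutes via [link_voice()]), and
#' typing features from the keystroke log binned into the hour around
#' each survey. Returns a feature table shaped like `study$features`,
#' suitable for [assemble_analysis()]'s `features` argument.
#'
#' @param study a fully rendered `emolang_study`.
#' @param lexicon lexicon for content scoring.
#' @return data.frame keyed by `participant_id` and `beep`.
#' @export
extract_study_features <- function(study, lexicon = demo_lexicon()) {
  man <- study$artifacts
  if (is.null(man)) stopf("study has no rendered artifacts; simulate with render = \"full\"")
  out <- study$features[, c("participant_id", "beep", "day", "timestamp")]
  cats <- LEXICON_CATEGORIES
  for (col in c(paste0("speech_", c("wc", cats)), ACOUSTIC_FEATURES,
                paste0("write_", c("pos_emojis", "neg_emojis", "wc", cats,
                                   "exclam")), TYPING_FEATURES))
    out[[col]] <- NA_real_
  out$has_voice <- FALSE; out$has_keyboard <- FALSE

  voice <- man[man$type == "voice", , drop = FALSE]
  # linkage check: recordings must sit within 5 minutes of their survey
  if (nrow(voice)) {
    lk <- link_voice(study$surveys[, c("participant_id", "timestamp")],
                     data.frame(participant_id = voice$participant_id,
                                timestamp = voice$timestamp,
                                beep = voice$beep))
    linked_keys <- paste(lk$links$participant_id, lk$links$beep)
    for (i in seq_len(nrow(voice))) {
      if (!paste(voice$participant_id[i], voice$beep[i]) %in% linked_keys)
        next
      j <- which(out$participant_id == voice$participant_id[i] &
                 out$beep == voice$beep[i])
      cf <- extract_content_features(paste(readLines(voice$transcript[i],
                                                     warn = FALSE),
                                           collapse = " "), lexicon)
      out[j, paste0("speech_", c("wc", cats))] <- cf[, c("wc", cats)]
      af <- extract_acoustic_features(read_wav(voice$audio[i]))
      out[j, ACOUSTIC_FEATURES] <- af
      out$has_voice[j] <- TRUE
    }
  }

  kb <- man[man$type == "keyboard", , drop = FALSE]
  if (nrow(kb) && !is.null(study$keystrokes)) {
    entries <- summarize_entries(study$keystrokes)
    for (i in seq_len(nrow(kb))) {
      j <- which(out$participant_id == kb$participant_id[i] &
                 out$beep == kb$beep[i])
      ent <- entries[entries$participant_id == kb$participant_id[i], ,
                     drop = FALSE]
      b <- bin_keyboard(ent, out$timestamp[j] * 1000)
      if (is.null(b)) next
      out[j, TYPING_FEATURES] <- b[, TYPING_FEATURES]
      cf <- extract_content_features(paste(readLines(kb$transcript[i],
                                                     warn = FALSE),
                                           collapse = " "), lexicon)
      out[j, paste0("write_", c("wc", cats))] <- cf[, c("wc", cats)]
      out$write_exclam[j] <- cf$exclam
      out$write_pos_emojis[j] <- cf$pos_emojis
      out$write_neg_emojis[j] <- cf$neg_emojis
      out$has_keyboard[j] <- TRUE
    }
  }
  out
}

#' Association tables for every feature family
#'
#' One Holm family per displayed table: level x feature family. At the
#' trait level the outcome grid includes the DASS depression score.
#'
#' @param datasets output of [assemble_analysis()] for the matching stream.
#' @param families named list of feature vectors (defaults to the two
#'   families of the stream present in the data).
#' @param level "momentary" or "trait".
#' @param alpha Holm alpha.
#' @return one data.frame combining the per-family tables.
#' @export
association_tables <- function(datasets, families, level = c("momentary", "trait"),
                               alpha = 0.05) {
  level <- match.arg(level)
  data <- if (level == "momentary") datasets$momentary else datasets$trait
  outcomes <- if (level == "trait") c(EMOTIONS, "dass_depression") else EMOTIONS
  out <- list()
  for (fam in names(families)) {
    feats <- intersect(families[[fam]], names(data))
    if (!length(feats)) next
    out[[fam]] <- correlation_table(data, outcomes, feats, level = level,
                                    family_id = paste(level, fam, sep = "_"),
                                    alpha = alpha)
  }
  do.call(rbind, out)
}
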