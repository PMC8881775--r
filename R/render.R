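# Artifact rendering for the synthetic study: turns ground-truth feature
# values into transcripts, writing messages, voiced waveforms and
# keystroke event streams. Rendering inverts the extractor exactly for
# F0 level, jitter, shimmer, HNR and voicing segmentation; contour-shape
# parameters (slopes, ranges) and loudness are approximated by simple
# triangular contours. Analyses can run either on extracted features
# (full render) or directly on the ground truth (fast path).

FILLER_WORDS <- c("vandaag", "morgen", "school", "werk", "thuis", "gisteren",
                  "straks", "beetje", "veel", "weinig", "uur", "tijd", "dag",
                  "avond", "ochtend", "middag", "eten", "gegeten", "fietsen",
                  "lopen", "praten", "kijken", "televisie", "serie", "boek",
                  "les", "college", "toets", "trein", "bus", "vriend",
                  "vriendin", "moeder", "vader", "broer", "zus", "hond",
                  "kat", "muziek", "spelen", "werken", "studeren", "slapen",
                  "wakker", "douche", "koffie", "thee", "brood", "pasta",
                  "daarna", "toen", "dus", "want", "maar", "ook", "nog",
                  "wel", "even", "gewoon", "daar", "hier", "iets")

# sample a surface form for a lexicon entry (stems get a short suffix)
sample_entry_word <- function(entries) {
  e <- sample(entries, 1)
  if (endsWith(e, "*")) paste0(sub("\\*$", "", e), sample(c("", "e", "en"), 1))
  else e
}

render_text <- function(n_tokens, cat_pct, lexicon, exclam_n = 0,
                        pos_emojis = 0, neg_emojis = 0) {
  cats <- names(cat_pct)
  p <- clamp(as.numeric(cat_pct) / 100, 0, 1)
  p_fill <- max(0.02, 1 - sum(p))
  pr <- c(p, p_fill) / (sum(p) + p_fill)
  counts <- as.vector(stats::rmultinom(1, n_tokens, pr))
  words <- character(0)
  for (k in seq_along(cats)) {
    if (counts[k] > 0)
      words <- c(words, replicate(counts[k],
                                  sample_entry_word(lexicon$categories[[cats[k]]])))
  }
  nf <- counts[length(counts)]
  if (nf > 0) words <- c(words, sample(FILLER_WORDS, nf, replace = TRUE))
  words <- sample(words)
  pieces <- c(words, rep("!", exclam_n),
              if (pos_emojis > 0) sample(lexicon$emoji$positive, pos_emojis,
                                         replace = TRUE),
              if (neg_emojis > 0) sample(lexicon$emoji$negative, neg_emojis,
                                         replace = TRUE))
  paste(sample(pieces), collapse = " ")
}

# Synthesize one voiced clip from an acoustic ground-truth row.
render_waveform <- function(row, duration, sr = 16000) {
  n <- round(duration * sr)
  s <- numeric(n)
  n_seg <- max(1, round(row$voiced_segments_per_second * duration))
  pause <- row$mean_unvoiced_segment_length
  pad <- 0.06
  voiced_total <- duration - 2 * pad - (n_seg - 1) * pause
  if (voiced_total < 0.25 * duration) {      # keep enough voiced material
    pause <- max(0.05, (duration * 0.75 - 2 * pad) / max(1, n_seg - 1))
    voiced_total <- duration - 2 * pad - (n_seg - 1) * pause
  }
  seg_len <- voiced_total / n_seg
  f0_center <- 27.5 * 2^(row$f0_mean / 12)
  sig_j <- row$jitter_mean * sqrt(pi) / 2
  sig_s <- row$shimmer_mean * sqrt(pi) / 2
  a0 <- 0.45
  voiced_mask <- logical(n)
  t0 <- pad
  for (seg in seq_len(n_seg)) {
    t1 <- t0 + seg_len
    # triangular semitone contour: rise then fall at the planted rates,
    # excursion capped at the planted range
    half <- seg_len / 2
    exc <- min(row$f0_range, row$f0_rise_slope * half, 6)
    st_at <- function(t) {
      u <- t - t0
      base <- row$f0_mean - exc / 2
      if (u <= half) base + row$f0_rise_slope * u * (exc / max(row$f0_rise_slope * half, 1e-9))
      else base + exc - row$f0_fall_slope * (u - half) *
        (exc / max(row$f0_fall_slope * half, 1e-9))
    }
    t <- t0
    while (t < t1) {
      f <- 27.5 * 2^(st_at(t) / 12)
      period <- (1 / f) * (1 + stats::rnorm(1, 0, sig_j))
      amp <- a0 * 10^(stats::rnorm(1, 0, sig_s) / 20)
      w <- max(3, round(0.3 * sr / f))
      ctr <- round(t * sr)
      k <- (ctr - w):(ctr + w)
      ok <- k >= 1 & k <= n
      s[k[ok]] <- s[k[ok]] + amp * cos(pi * (k[ok] - t * sr) / (2 * w))^2
      t <- t + period
    }
    i0 <- max(1, round(t0 * sr)); i1 <- min(n, round(t1 * sr))
    voiced_mask[i0:i1] <- TRUE
    t0 <- t1 + pause
    if (t0 >= duration - pad) break
  }
  pwr <- mean(s[voiced_mask]^2)
  if (is.finite(pwr) && pwr > 0) {
    noise_sd <- sqrt(pwr * 10^(-row$hnr_mean / 10))
    s[voiced_mask] <- s[voiced_mask] +
      stats::rnorm(sum(voiced_mask), 0, noise_sd)
  }
  peak <- max(abs(s))
  if (peak > 0.9) s <- s * 0.9 / peak
  audio_clip(s, sr)
}

# Keystroke events for one survey bin.
render_keystrokes <- function(row, pid, beep, esm_s) {
  n_entries <- max(1, round(row$n_entries))
  n_char <- max(n_entries, round(row$n_characters))
  speed <- max(0.3, row$typing_speed)
  br <- clamp(row$backspaces_rel, 0, 0.6)
  chars <- as.vector(stats::rmultinom(1, n_char, rep(1, n_entries)))
  chars <- pmax(chars, 1)
  starts <- sort(stats::runif(n_entries, esm_s - 28 * 60, esm_s + 28 * 60))
  ev <- list()
  for (j in seq_len(n_entries)) {
    nb <- round(chars[j] * br / (1 - br))
    keys <- sample(c(rep("character", chars[j]), rep("backspace", nb)))
    dt <- stats::rexp(length(keys), rate = speed)
    press <- (starts[j] + cumsum(dt)) * 1000
    dur <- pmax(10, stats::rnorm(length(keys), row$avg_key_press_duration, 8))
    ev[[j]] <- data.frame(participant_id = pid,
                          entry_id = sprintf("%s_b%04d_e%02d", pid, beep, j),
                          key_class = keys,
                          press_ms = press,
                          release_ms = press + dur)
  }
  do.call(rbind, ev)
}

#' Render language artifacts for one participant
#'
#' For every answered survey: a voice transcript and a WAV clip when the
#' survey carries a recording, a writing-message text file and keystroke
#' events when it carries keyboard activity. Artifacts land under
#' `out_dir/transcripts`, `out_dir/messages` and `out_dir/audio`.
#'
#' @param config an `emolang_config`.
#' @param profile the participant's profile row.
#' @param feats the participant's ground-truth feature rows (with
#'   `has_voice`/`has_keyboard` flags).
#' @param lexicon lexicon used for word sampling.
#' @param out_dir artifact directory.
#' @return list: `keystrokes` (events data.frame or NULL), `files`
#'   (manifest data.frame).
#' @export
render_language <- function(config, profile, feats, lexicon, out_dir) {
  pid <- profile$participant_id
  set.seed(derive_seed(config$rng_seed, 61L,
                       match(pid, sprintf("P%03d", 1:100000))))
  ks <- list(); files <- list()
  cats <- LEXICON_CATEGORIES
  for (i in seq_len(nrow(feats))) {
    row <- feats[i, ]
    if (isTRUE(row$has_voice)) {
      pct <- stats::setNames(as.numeric(row[paste0("speech_", cats)]), cats)
      txt <- render_text(max(3, round(row$speech_wc)), pct, lexicon)
      tf <- file.path(out_dir, "transcripts",
                      sprintf("%s_b%04d.txt", pid, row$beep))
      writeLines(txt, tf, useBytes = TRUE)
      clipf <- file.path(out_dir, "audio",
                         sprintf("%s_b%04d.wav", pid, row$beep))
      write_wav(render_waveform(row, config$clip_duration), clipf)
      files[[length(files) + 1]] <-
        data.frame(participant_id = pid, beep = row$beep, type = "voice",
                   transcript = tf, audio = clipf,
                   timestamp = row$voice_timestamp)
    }
    if (isTRUE(row$has_keyboard)) {
      pct <- stats::setNames(as.numeric(row[paste0("write_", cats)]), cats)
      nw <- max(3, round(row$write_wc))
      txt <- render_text(nw, pct, lexicon,
                         exclam_n = round(row$write_exclam * nw / 100),
                         pos_emojis = round(pmax(0, row$write_pos_emojis)),
                         neg_emojis = round(pmax(0, row$write_neg_emojis)))
      mf <- file.path(out_dir, "messages",
                      sprintf("%s_b%04d.txt", pid, row$beep))
      writeLines(txt, mf, useBytes = TRUE)
      ks[[length(ks) + 1]] <- render_keystrokes(row, pid, row$beep,
                                                row$timestamp)
      files[[length(files) + 1]] <-
        data.frame(participant_id = pid, beep = row$beep, type = "keyboard",
                   transcript = mf, audio = NA_character_,
                   timestamp = row$timestamp)
    }
  }
  list(keystrokes = if (length(ks)) do.call(rbind, ks) else NULL,
       files = if (length(files)) do.call(rbind, files) else NULL)
}
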