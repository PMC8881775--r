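#' Synthetic ESM study generator
#'
#' Generates a complete synthetic experience-sampling study with known
#' planted effect sizes: beep schedules (10 semirandom beeps per day over
#' two weeks), AR(1) within-person emotion trajectories around
#' between-person trait means with a shared latent factor carrying the
#' valence/happiness versus negative-emotion structure, compliance that
#' declines over the study, and three language streams (transcripts,
#' voiced waveforms, keystroke logs) whose features couple to the
#' standardized emotion states through a configurable loading matrix.
#' Ground-truth feature values are returned alongside the rendered
#' artifacts so every downstream stage can be tested against the planted
#' parameters.
#'
#' @name simulate
NULL

#' Expected emotion-feature correlation directions
#'
#' The literature-derived expected signs for every emotion (plus
#' depression) against the speech-form, content and writing-form
#' features. Signs are `+`, `-`, `±` (direction reported as mixed or
#' positive-or-null) or `0` (no expectation). Used to default the signs
#' of planted simulator loadings: only strict `+`/`-` entries plant a
#' nonzero loading.
#'
#' @return data.frame with `emotion`, `feature`, `sign`.
#' @export
direction_priors <- function() {
  af <- ACOUSTIC_FEATURES
  row <- function(emotion, features, signs) {
    data.frame(emotion = emotion, feature = features, sign = signs,
               stringsAsFactors = FALSE)
  }
  sf <- rbind(
    row("arousal",  af, c("+", "+", "+", "+", "+", "+", "+", "+", "0", "0", "0", "±", "-")),
    row("anger",    af, c("+", "+", "+", "+", "+", "+", "+", "+", "±", "±", "+", "±", "-")),
    row("anxiety",  af, c("+", "±", "+", "±", "±", "+", "0", "0", "+", "+", "-", "±", "±")),
    row("sadness",  af, c("-", "-", "-", "-", "-", "-", "-", "-", "+", "0", "-", "-", "+")),
    row("depression", af, c("-", "-", "-", "-", "-", "-", "-", "-", "+", "0", "-", "-", "+")),
    row("stress",   af, c("+", "+", "+", "+", "+", "+", "+", "+", "0", "0", "0", "+", "-")),
    row("happiness", af, c("+", "+", "+", "+", "+", "+", "+", "+", "±", "±", "+", "+", "-")))
  cc <- c("wc", "i", "we", "you", "negate", "posemo", "negemo", "anx",
          "anger", "sad", "certain", "swear", "exclam")
  ct <- rbind(
    row("valence",  cc, c("+", "-", "0", "0", "0", "0", "0", "0", "0", "+", "0", "+", "+")),
    row("anger",    cc, c("0", "+", "+", "+", "0", "0", "0", "0", "+", "0", "0", "0", "0")),
    row("anxiety",  cc, c("0", "+", "+", "+", "+", "+", "+", "+", "0", "0", "+", "0", "0")),
    row("sadness",  cc, c("0", "+", "+", "0", "+", "0", "0", "+", "0", "0", "0", "0", "0")),
    row("stress",   cc, c("0", "+", "0", "+", "0", "0", "0", "0", "0", "0", "0", "0", "0")),
    row("happiness", cc, c("+", "-", "0", "0", "0", "0", "0", "0", "0", "+", "0", "+", "+")),
    row("depression", cc, c("0", "+", "+", "+", "+", "+", "+", "+", "0", "0", "+", "0", "0")))
  tf <- TYPING_FEATURES
  wf <- rbind(
    row("valence",  tf, c("+", "0", "0", "0", "0", "0")),
    row("arousal",  tf, c("0", "+", "-", "0", "0", "-")),
    row("stress",   tf, c("0", "+", "-", "-", "-", "-")),
    row("happiness", tf, c("+", "0", "0", "0", "0", "0")),
    row("depression", tf, c("0", "0", "-", "0", "0", "0")))
  # content signs apply to both the speech and the writing stream
  speech_ct <- ct[ct$feature != "exclam", ]
  speech_ct$feature <- paste0("speech_", speech_ct$feature)
  write_ct <- ct
  write_ct$feature <- paste0("write_", write_ct$feature)
  pri <- rbind(sf, speech_ct, write_ct, wf)
  pri <- pri[pri$sign != "0", ]
  rownames(pri) <- NULL
  pri
}

#' Default planted loading matrix
#'
#' One standardized loading per directed prior entry: `+` entries get
#' `magnitude`, `-` entries `-magnitude`; `±` entries plant nothing.
#' The default magnitude 0.15 sits in the middle of the small
#' within-person correlations (|r| about 0.05-0.25) the pipeline is
#' designed to detect.
#'
#' @param magnitude absolute loading for directed entries.
#' @return data.frame `feature`, `emotion`, `loading`.
#' @export
default_loadings <- function(magnitude = 0.15) {
  pri <- direction_priors()
  pri <- pri[pri$sign %in% c("+", "-") & pri$emotion != "depression", ]
  data.frame(feature = pri$feature, emotion = pri$emotion,
             loading = ifelse(pri$sign == "+", magnitude, -magnitude),
             stringsAsFactors = FALSE)
}

# Natural-scale location/spread per feature for rendering ground truth.
feature_scales <- function() {
  sc <- function(feature, mu, sd, min = 0, max = Inf)
    data.frame(feature = feature, mu = mu, sd = sd, min = min, max = max)
  rbind(
    sc("speech_wc", 60, 25, min = 3),
    sc("speech_i", 9.4, 3.7), sc("speech_we", 0.6, 0.8),
    sc("speech_you", 0.3, 0.4), sc("speech_negate", 1.3, 0.9),
    sc("speech_posemo", 3.54, 2.04), sc("speech_negemo", 1.0, 0.8),
    sc("speech_anx", 0.4, 0.5), sc("speech_anger", 0.3, 0.4),
    sc("speech_sad", 0.2, 0.25), sc("speech_certain", 1.6, 1.3),
    sc("speech_swear", 0.05, 0.1),
    sc("f0_mean", 0, 1.2, min = -6, max = 6),  # offset from speaker base, st
    sc("f0_sd_norm", 0.022, 0.006, min = 0.004),
    sc("f0_range", 2.2, 0.7, min = 0.3),
    sc("f0_rise_slope", 25, 8, min = 4), sc("f0_fall_slope", 22, 7, min = 4),
    sc("loudness_mean", 0.10, 0.025, min = 0.02),
    sc("loudness_rise_slope", 0.45, 0.15, min = 0.05),
    sc("loudness_fall_slope", 0.40, 0.13, min = 0.05),
    sc("jitter_mean", 0.030, 0.008, min = 0.004, max = 0.08),
    sc("shimmer_mean", 1.3, 0.3, min = 0.15, max = 4),
    sc("hnr_mean", 10, 2.5, min = 2, max = 25),
    sc("voiced_segments_per_second", 2.0, 0.45, min = 0.6, max = 3.4),
    sc("mean_unvoiced_segment_length", 0.30, 0.10, min = 0.08, max = 1.2),
    sc("write_pos_emojis", 1.2, 1.2), sc("write_neg_emojis", 0.2, 0.35),
    sc("write_wc", 80, 35, min = 3),
    sc("write_i", 3.2, 1.2), sc("write_we", 0.6, 0.35),
    sc("write_you", 2.2, 0.8), sc("write_negate", 1.4, 0.8),
    sc("write_posemo", 1.5, 0.9), sc("write_negemo", 1.8, 1.0),
    sc("write_anx", 0.8, 0.4), sc("write_anger", 0.3, 0.3),
    sc("write_sad", 0.3, 0.25), sc("write_certain", 0.6, 0.4),
    sc("write_swear", 1.0, 0.7), sc("write_exclam", 1.6, 1.5),
    sc("n_characters", 480, 200, min = 5),
    sc("typing_speed", 0, 0.5, min = -1.5, max = 2),  # offset from base
    sc("avg_key_press_duration", 80, 15, min = 25, max = 160),
    sc("n_entries", 15, 7, min = 1),
    sc("backspaces_rel", 0.15, 0.05, min = 0, max = 0.6),
    sc("typing_duration_rel", 0.55, 0.15, min = 0.1, max = 2))
}

EMOTION_MEANS <- c(valence = 56.21, arousal = 44.7, anger = 10.63,
                   anxiety = 12.47, sadness = 13.06, stress = 27.58,
                   happiness = 56.44)
EMOTION_BETWEEN_SD <- c(valence = 11.3, arousal = 11.35, anger = 9.08,
                        anxiety = 12.62, sadness = 9.38, stress = 15.15,
                        happiness = 11.32)
# shared-factor loadings: positive pole = feeling good
EMOTION_FACTOR <- c(valence = 0.8, arousal = 0.2, anger = -0.5,
                    anxiety = -0.5, sadness = -0.6, stress = -0.5,
                    happiness = 0.8)

#' Build a simulation configuration
#'
#' Defaults reproduce the study protocol: 60 participants, 14 days x 10
#' beeps; compliance averaging about 0.78 and declining through the study
#' (base per-beep probability 0.89 at day 1 for the average participant,
#' person-level log-odds SD 1, log-odds decrement 0.08/day); AR(1)
#' emotion dynamics (coefficient 0.4) with a within-person SD of 12 VAS
#' units around between-person trait means drawn from the observed
#' emotion distributions; voice recordings follow 19% and keyboard
#' activity 60% of answered surveys; planted feature-emotion loadings
#' default to the literature direction priors at magnitude 0.15.
#'
#' @param n_participants,n_days,beeps_per_day protocol dimensions.
#' @param compliance_base day-1 per-beep answer probability (average person).
#' @param compliance_person_sd SD of the person-level log-odds offset.
#' @param compliance_decay per-day log-odds decrement (>= 0 declines).
#' @param emotion_ar AR(1) coefficient in [0, 1).
#' @param within_person_sd within-person emotion SD (VAS units), recycled
#'   over the 7 emotions.
#' @param between_person_sd between-person SD per emotion (VAS units).
#' @param emotion_means grand trait means per emotion (VAS units).
#' @param factor_loadings shared-latent-factor loading per emotion in
#'   (-1, 1), inducing the cross-emotion correlation structure.
#' @param loadings planted loading data.frame (`feature`, `emotion`,
#'   `loading`); default [default_loadings()].
#' @param voice_rate,keyboard_rate probability that an answered survey
#'   carries a voice recording / keyboard activity.
#' @param clip_duration rendered voice clip length in seconds.
#' @param rng_seed integer master seed.
#' @return validated `emolang_config` list.
#' @export
simulation_config <- function(n_participants = 60, n_days = 14,
                              beeps_per_day = 10,
                              compliance_base = 0.89,
                              compliance_person_sd = 1.0,
                              compliance_decay = 0.08,
                              emotion_ar = 0.4,
                              within_person_sd = 12,
                              between_person_sd = EMOTION_BETWEEN_SD,
                              emotion_means = EMOTION_MEANS,
                              factor_loadings = EMOTION_FACTOR,
                              loadings = default_loadings(),
                              voice_rate = 0.19, keyboard_rate = 0.60,
                              clip_duration = 1.6,
                              rng_seed = 1L) {
  if (!is_count(n_participants) || !is_count(n_days) || !is_count(beeps_per_day))
    stopf("n_participants, n_days and beeps_per_day must be positive integers")
  if (compliance_base < 0 || compliance_base > 1 ||
      voice_rate < 0 || voice_rate > 1 || keyboard_rate < 0 || keyboard_rate > 1)
    stopf("probabilities must lie in [0, 1]")
  if (emotion_ar < 0 || emotion_ar >= 1)
    stopf("emotion_ar must lie in [0, 1)")
  if (!all(is.finite(loadings$loading)))
    stopf("planted loadings must be finite")
  wps <- rep_len(within_person_sd, length(EMOTIONS))
  names(wps) <- EMOTIONS
  stopifnot(all(EMOTIONS %in% names(emotion_means)),
            all(EMOTIONS %in% names(between_person_sd)),
            all(EMOTIONS %in% names(factor_loadings)))
  known <- feature_scales()$feature
  bad <- setdiff(loadings$feature, known)
  if (length(bad))
    stopf("loading references unknown feature(s): %s",
          paste(bad, collapse = ", "))
  structure(list(n_participants = as.integer(n_participants),
                 n_days = as.integer(n_days),
                 beeps_per_day = as.integer(beeps_per_day),
                 compliance_base = compliance_base,
                 compliance_person_sd = compliance_person_sd,
                 compliance_decay = compliance_decay,
                 emotion_ar = emotion_ar,
                 within_person_sd = wps,
                 between_person_sd = between_person_sd[EMOTIONS],
                 emotion_means = emotion_means[EMOTIONS],
                 factor_loadings = factor_loadings[EMOTIONS],
                 loadings = loadings,
                 voice_rate = voice_rate, keyboard_rate = keyboard_rate,
                 clip_duration = clip_duration,
                 rng_seed = as.integer(rng_seed)),
            class = "emolang_config")
}

#' Draw participant profiles
#'
#' Trait emotion means (clipped to the VAS range), 7 DASS depression
#' items from a right-skewed severity distribution concentrating subscale
#' means below 0.75, a base speaking F0 and a base typing speed.
#'
#' @param config an `emolang_config`.
#' @return data.frame, one row per participant.
#' @export
participant_profiles <- function(config) {
  set.seed(derive_seed(config$rng_seed, 11L))
  n <- config$n_participants
  out <- data.frame(participant_id = sprintf("P%03d", seq_len(n)))
  for (e in EMOTIONS)
    out[[paste0("trait_", e)]] <-
      clamp(stats::rnorm(n, config$emotion_means[[e]],
                         config$between_person_sd[[e]]), 0, 100)
  sev <- stats::rbeta(n, 1.2, 6) * 3        # subscale severity in [0, 3]
  for (k in 1:7)
    out[[paste0("dass", k)]] <- stats::rbinom(n, 3, sev / 3)
  out$base_f0_hz <- exp(stats::rnorm(n, log(165), 0.18))   # mixed-sex span
  out$base_typing_speed <- clamp(stats::rnorm(n, 2.1, 0.5), 0.8, 4.5)
  out$compliance_offset <- stats::rnorm(n, 0, config$compliance_person_sd)
  out
}

#' Beep schedule for one participant
#'
#' Per day: the first beep uniform in [10:00, 11:00); the other nine one
#' per equal block of [11:00, 22:00). Timestamps are seconds from the
#' study start (day 1, 00:00), strictly increasing.
#'
#' @param config an `emolang_config` (beeps_per_day must be 10; other
#'   protocols need an explicit block definition).
#' @param participant_index 1-based participant index (seeds the draw).
#' @return numeric vector of `n_days * 10` timestamps in seconds.
#' @export
build_schedule <- function(config, participant_index = 1L) {
  if (config$beeps_per_day != 10)
    stopf("beeps_per_day other than 10 requires an explicit block definition")
  set.seed(derive_seed(config$rng_seed, 21L, participant_index))
  block_w <- 11 * 3600 / 9
  ts <- c()
  for (d in seq_len(config$n_days)) {
    day0 <- (d - 1) * 86400
    first <- day0 + 10 * 3600 + stats::runif(1, 0, 3600)
    rest <- day0 + 11 * 3600 + (0:8) * block_w + stats::runif(9, 0, block_w)
    ts <- c(ts, first, rest)
  }
  ts
}

#' Simulate one participant's emotion trajectory
#'
#' Latent standardized states follow `z_e = f_e F + sqrt(1 - f_e^2) U_e`
#' with F and U_e independent stationary AR(1) processes; ratings are
#' `trait mean + within-person SD x z`, clipped to [0, 100]. Answer flags
#' are Bernoulli with log-odds declining by `compliance_decay` per day.
#'
#' @param config an `emolang_config`.
#' @param profile one row of [participant_profiles()].
#' @param schedule timestamps from [build_schedule()].
#' @return data.frame per beep: `participant_id`, `beep`, `day`,
#'   `timestamp`, `answered`, rating and latent `z_` columns per emotion.
#' @export
simulate_emotions <- function(config, profile, schedule) {
  n <- length(schedule)
  set.seed(derive_seed(config$rng_seed, 31L,
                       match(profile$participant_id,
                             sprintf("P%03d", 1:100000))))
  ar <- config$emotion_ar
  ar1 <- function(n) {
    x <- numeric(n); x[1] <- stats::rnorm(1)
    if (n > 1) for (t in 2:n)
      x[t] <- ar * x[t - 1] + sqrt(1 - ar^2) * stats::rnorm(1)
    x
  }
  f <- ar1(n)
  day <- floor(schedule / 86400) + 1
  out <- data.frame(participant_id = profile$participant_id,
                    beep = seq_len(n), day = day, timestamp = schedule)
  for (e in EMOTIONS) {
    lam <- config$factor_loadings[[e]]
    z <- lam * f + sqrt(1 - lam^2) * ar1(n)
    out[[paste0("z_", e)]] <- z
    out[[e]] <- clamp(profile[[paste0("trait_", e)]] +
                        config$within_person_sd[[e]] * z, 0, 100)
  }
  logit_p <- stats::qlogis(config$compliance_base) + profile$compliance_offset -
    config$compliance_decay * (day - 1)
  out$answered <- stats::runif(n) < stats::plogis(logit_p)
  out
}

# Ground-truth feature values for the answered beeps of one trajectory.
# Every feature is loading-weighted in the standardized emotion state
# (within-person z plus the standardized between-person trait deviation,
# so planted effects act at both levels) plus unique noise, then mapped
# to its natural scale. f0_mean and typing_speed are person-anchored.
ground_truth_features <- function(config, profile, traj) {
  ans <- traj[traj$answered, , drop = FALSE]
  n <- nrow(ans)
  scales <- feature_scales()
  zb <- vapply(EMOTIONS, function(e) {
    (profile[[paste0("trait_", e)]] - config$emotion_means[[e]]) /
      config$between_person_sd[[e]]
  }, numeric(1))
  out <- data.frame(participant_id = rep(profile$participant_id, n),
                    beep = ans$beep, day = ans$day, timestamp = ans$timestamp)
  if (n == 0) {
    for (f in scales$feature) out[[f]] <- numeric(0)
    return(out)
  }
  set.seed(derive_seed(config$rng_seed, 41L,
                       match(profile$participant_id,
                             sprintf("P%03d", 1:100000))))
  zmat <- as.matrix(ans[, paste0("z_", EMOTIONS)])
  colnames(zmat) <- EMOTIONS
  for (i in seq_len(nrow(scales))) {
    f <- scales$feature[i]
    lam <- config$loadings[config$loadings$feature == f, , drop = FALSE]
    zsum <- numeric(n); zb_sum <- 0; lam2 <- 0
    if (nrow(lam)) {
      for (k in seq_len(nrow(lam))) {
        e <- lam$emotion[k]
        zsum <- zsum + lam$loading[k] * zmat[, e]
        zb_sum <- zb_sum + lam$loading[k] * zb[[e]]
        lam2 <- lam2 + lam$loading[k]^2
      }
    }
    s <- sqrt(max(1 - lam2, 0.01))
    zf <- zsum + zb_sum + s * stats::rnorm(n)
    if (f %in% c("f0_mean", "typing_speed")) {
      # person-anchored features: mu is an offset from the speaker's base;
      # the offset (not the absolute value) is range-limited
      base <- if (f == "f0_mean") hz_to_semitone(profile$base_f0_hz)
              else profile$base_typing_speed
      out[[f]] <- base + clamp(scales$mu[i] + scales$sd[i] * zf,
                               scales$min[i], scales$max[i])
    } else {
      out[[f]] <- clamp(scales$mu[i] + scales$sd[i] * zf,
                        scales$min[i], scales$max[i])
    }
  }
  # count-like features are rounded at rendering, kept continuous here
  out
}

#' Simulate a complete study
#'
#' Generates profiles, schedules, trajectories, answered surveys, DASS
#' items and ground-truth language features for every stream; with
#' `render = "full"` additionally renders transcripts, writing messages,
#' waveforms and keystroke logs (see [render_language()]). Voice and
#' keyboard presence per answered survey follow `voice_rate` and
#' `keyboard_rate`.
#'
#' @param config an `emolang_config`.
#' @param lexicon lexicon used to render transcripts (default
#'   [demo_lexicon()]); only needed for full rendering.
#' @param render "none" (ground-truth features only, fast) or "full".
#' @param out_dir directory for rendered artifacts (required for "full").
#' @return `emolang_study` list: `config`, `profiles`, `trajectories`,
#'   `surveys` (answered, with ratings), `features` (ground truth; voice
#'   columns NA without a recording, writing columns NA without keyboard
#'   activity), `dass`, `recordings` (voice timestamps), and for full
#'   renders `artifacts` (file manifest) and `keystrokes`.
#' @export
simulate_study <- function(config, lexicon = NULL,
                           render = c("none", "full"), out_dir = NULL) {
  render <- match.arg(render)
  if (render == "full") {
    if (is.null(out_dir)) stopf("full rendering requires out_dir")
    if (is.null(lexicon)) lexicon <- demo_lexicon()
    dir.create(file.path(out_dir, "transcripts"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "messages"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "audio"), showWarnings = FALSE)
  }
  profiles <- participant_profiles(config)
  traj_list <- list(); feat_list <- list(); ks_list <- list()
  manifest <- list()
  for (p in seq_len(config$n_participants)) {
    prof <- profiles[p, ]
    sched <- build_schedule(config, p)
    traj <- simulate_emotions(config, prof, sched)
    feats <- ground_truth_features(config, prof, traj)
    # stream presence per answered survey
    set.seed(derive_seed(config$rng_seed, 51L, p))
    n <- nrow(feats)
    has_voice <- stats::runif(n) < config$voice_rate
    has_kb <- stats::runif(n) < config$keyboard_rate
    voice_cols <- c(paste0("speech_", c("wc", LEXICON_CATEGORIES)),
                    ACOUSTIC_FEATURES)
    write_cols <- c(paste0("write_", c("pos_emojis", "neg_emojis", "wc",
                                       LEXICON_CATEGORIES, "exclam")),
                    TYPING_FEATURES)
    feats[!has_voice, voice_cols] <- NA_real_
    feats[!has_kb, write_cols] <- NA_real_
    feats$has_voice <- has_voice
    feats$has_keyboard <- has_kb
    feats$voice_timestamp <- ifelse(has_voice,
                                    feats$timestamp + stats::runif(n, 5, 120),
                                    NA_real_)
    if (render == "full" && n > 0) {
      ra <- render_language(config, prof, feats, lexicon, out_dir)
      if (!is.null(ra$keystrokes)) ks_list[[p]] <- ra$keystrokes
      manifest[[p]] <- ra$files
    }
    traj_list[[p]] <- traj
    feat_list[[p]] <- feats
  }
  traj <- do.call(rbind, traj_list)
  feats <- do.call(rbind, feat_list)
  surveys <- traj[traj$answered,
                  c("participant_id", "beep", "day", "timestamp", EMOTIONS)]
  dass <- profiles[, c("participant_id", paste0("dass", 1:7))]
  structure(list(config = config, profiles = profiles,
                 trajectories = traj, surveys = surveys, features = feats,
                 dass = dass,
                 keystrokes = if (length(ks_list)) do.call(rbind, ks_list)
                              else NULL,
                 artifacts = if (length(manifest)) do.call(rbind, manifest)
                             else NULL),
            class = "emolang_study")
}

#' @export
print.emolang_study <- function(x, ...) {
  cat(sprintf("Synthetic ESM study: %d participants, %d scheduled beeps each, %d answered surveys\n",
              x$config$n_participants,
              x$config$n_days * x$config$beeps_per_day, nrow(x$surveys)))
  invisible(x)
}
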