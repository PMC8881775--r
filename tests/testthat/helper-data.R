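# Shared fixtures, built in code.

# Balanced within-person standardized panel with a known pooled
# within-person correlation r between x and y.
make_panel <- function(n_id = 20, n_obs = 30, r = 0.3, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_id), function(i) {
    x <- rnorm(n_obs)
    y <- r * x + sqrt(1 - r^2) * rnorm(n_obs)
    zx <- (x - mean(x)) / sd(x)
    zy <- (y - mean(y)) / sd(y)
    data.frame(participant_id = sprintf("P%03d", i), x = zx, y = zy)
  })
  do.call(rbind, rows)
}

# A minimal lexicon with the full category structure but few entries,
# for hand-countable content tests.
tiny_lexicon <- function() {
  lex <- structure(list(
    categories = list(
      i = c("ik"), we = c("we"), you = c("jij"),
      negate = c("niet"), posemo = c("blij", "happ*"),
      negemo = c("rot"), anx = c("bang"), anger = c("boos"),
      sad = c("verdriet"), certain = c("zeker"), swear = c("kut")),
    emoji = list(positive = c(":)"), negative = c(":("))),
    class = "emolang_lexicon")
  validate_lexicon(lex)
  lex
}

# Empty loading table (null model).
no_loadings <- function() {
  data.frame(feature = character(0), emotion = character(0),
             loading = numeric(0))
}

# Single planted loading.
one_loading <- function(feature, emotion, loading) {
  data.frame(feature = feature, emotion = emotion, loading = loading)
}

sine_clip <- function(freq = 220, dur = 1, amp = 0.5, sr = 16000) {
  audio_clip(amp * sin(2 * pi * freq * (0:(round(dur * sr) - 1)) / sr), sr)
}
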