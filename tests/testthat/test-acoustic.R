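test_that("semitone conversion anchors at 27.5 Hz with 12 per octave", {
  expect_equal(hz_to_semitone(27.5), 0)
  expect_equal(hz_to_semitone(55), 12)
  expect_equal(hz_to_semitone(220), 36)
  expect_error(hz_to_semitone(0), "positive")
  expect_error(hz_to_semitone(-10), "positive")
})

test_that("pure tone is tracked at its frequency on interior frames", {
  trk <- detect_voicing_and_f0(sine_clip(220))
  interior <- trk[trk$time > 0.05 & trk$time < 0.95, ]
  expect_true(all(interior$voiced))
  expect_true(all(abs(interior$f0_hz - 220) < 1))
})

test_that("low-amplitude white noise yields no voiced frames", {
  set.seed(11)
  trk <- detect_voicing_and_f0(audio_clip(rnorm(16000) * 0.001, 16000))
  expect_equal(sum(trk$voiced), 0)
  # and a silent clip is valid with all frames unvoiced
  trk0 <- detect_voicing_and_f0(audio_clip(rep(0, 16000), 16000))
  expect_equal(sum(trk0$voiced), 0)
})

test_that("a perfectly periodic tone has degenerate variability features", {
  fx <- extract_acoustic_features(sine_clip(220))
  expect_equal(fx$f0_mean, 36, tolerance = 0.05 / 36)
  expect_lt(fx$f0_sd_norm, 0.005)
  expect_lt(fx$f0_range, 0.05)
  expect_lt(fx$jitter_mean, 1e-3)
  expect_lt(fx$shimmer_mean, 0.01)
  expect_gt(fx$hnr_mean, 20)
})

test_that("tone-silence-tone splits into two voiced segments", {
  sr <- 16000
  seg <- 0.5 * sin(2 * pi * 220 * (0:7999) / sr)
  clip <- audio_clip(c(seg, rep(0, 8000), seg), sr)
  fx <- extract_acoustic_features(clip)
  expect_equal(fx$voiced_segments_per_second * clip$duration, 2)
  expect_equal(fx$mean_unvoiced_segment_length, 0.5, tolerance = 0.15)
})

test_that("one-octave-per-second glide has a rising slope near 12 st/s", {
  sr <- 16000
  t <- (0:(sr - 1)) / sr
  phase <- 2 * pi * cumsum(110 + 110 * t) / sr
  fx <- extract_acoustic_features(audio_clip(0.5 * sin(phase), sr))
  expect_equal(fx$f0_rise_slope, 12, tolerance = 0.5 / 12)
})

test_that("amplitude scaling leaves F0, jitter and HNR untouched", {
  clip <- sine_clip(180, dur = 0.8)
  scaled <- audio_clip(clip$samples * 0.25, clip$sample_rate)
  a <- extract_acoustic_features(clip)
  b <- extract_acoustic_features(scaled)
  expect_equal(a$f0_mean, b$f0_mean, tolerance = 1e-9)
  expect_equal(a$jitter_mean, b$jitter_mean, tolerance = 1e-9)
  expect_equal(a$hnr_mean, b$hnr_mean, tolerance = 1e-9)
  expect_equal(b$loudness_mean / a$loudness_mean, 0.25, tolerance = 1e-6)
})

test_that("planted period jitter is recovered within 20 percent", {
  sr <- 16000
  set.seed(7)
  t0 <- sr / 150
  per <- t0 * (1 + rnorm(400, 0, 0.03 * sqrt(pi) / 2))
  pos <- cumsum(per); pos <- pos[pos < sr * 2.4 - 100]
  s <- rep(0, sr * 2.4)
  w <- round(t0 * 0.3)
  for (p in pos) {
    k <- (round(p) - w):(round(p) + w)
    s[k] <- s[k] + 0.6 * cos(pi * (k - p) / (2 * w))^2
  }
  fx <- extract_acoustic_features(audio_clip(s / max(abs(s)) * 0.8, sr))
  expect_equal(fx$jitter_mean, 0.03, tolerance = 0.2)
  expect_equal(fx$f0_mean, hz_to_semitone(150), tolerance = 0.02)
})

test_that("WAV files round-trip through write and read", {
  clip <- sine_clip(300, dur = 0.3)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 16000)
  expect_equal(length(back$samples), length(clip$samples))
  expect_lt(max(abs(back$samples - clip$samples)), 1 / 32000)
})

test_that("clips with no voiced frames keep segment statistics only", {
  set.seed(3)
  fx <- extract_acoustic_features(audio_clip(rnorm(16000) * 0.001, 16000))
  expect_true(is.na(fx$f0_mean))
  expect_true(is.na(fx$jitter_mean))
  expect_true(is.na(fx$hnr_mean))
  expect_equal(fx$voiced_segments_per_second, 0)
})
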