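test_that("schedules follow the beep protocol", {
  cfg <- simulation_config(n_participants = 2, rng_seed = 3)
  ts <- build_schedule(cfg, 1)
  expect_length(ts, 140)
  expect_true(all(diff(ts) > 0))
  # first beep of every day in [10:00, 11:00), others in [11:00, 22:00)
  day <- floor(ts / 86400)
  tod <- ts - day * 86400
  first <- !duplicated(day)
  expect_true(all(tod[first] >= 10 * 3600 & tod[first] < 11 * 3600))
  expect_true(all(tod[!first] >= 11 * 3600 & tod[!first] < 22 * 3600))
  # one beep per equal block of [11:00, 22:00)
  block <- floor((tod[!first] - 11 * 3600) / (11 * 3600 / 9))
  expect_equal(as.vector(table(block)), rep(cfg$n_days, 9))

  expect_identical(build_schedule(cfg, 1), build_schedule(cfg, 1))
  cfg9 <- simulation_config(beeps_per_day = 9)
  expect_error(build_schedule(cfg9, 1), "block definition")
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(compliance_base = 1.4), "\\[0, 1\\]")
  expect_error(simulation_config(emotion_ar = 1), "\\[0, 1\\)")
  expect_error(simulation_config(
    loadings = data.frame(feature = "nope", emotion = "valence",
                          loading = 0.2)), "unknown feature")
  expect_error(simulation_config(
    loadings = data.frame(feature = "speech_posemo", emotion = "valence",
                          loading = Inf)), "finite")
})

test_that("zero within-person noise pins ratings at the trait mean", {
  cfg <- simulation_config(n_participants = 1, n_days = 2,
                           within_person_sd = 0, rng_seed = 7)
  prof <- participant_profiles(cfg)
  traj <- simulate_emotions(cfg, prof[1, ], build_schedule(cfg, 1))
  for (e in c("valence", "sadness"))
    expect_true(all(traj[[e]] == prof[[paste0("trait_", e)]][1]))
})

test_that("compliance declines over days when decay is positive", {
  cfg <- simulation_config(n_participants = 40, n_days = 14,
                           compliance_decay = 0.15, rng_seed = 11)
  st <- simulate_study(cfg)
  daily <- aggregate(answered ~ participant_id + day, st$trajectories, sum)
  names(daily)[3] <- "count"
  expect_lt(day_activity_correlation(daily), 0)
  # and per-participant answered fractions overlap the observed range
  cs <- compliance_stats(st$trajectories)
  expect_gt(max(cs$per_participant$compliance), 0.8)
  expect_lt(min(cs$per_participant$compliance), 0.8)
})

test_that("direction priors are unique, signed and drive default loadings", {
  pri <- direction_priors()
  expect_false(any(duplicated(pri[, c("emotion", "feature")])))
  expect_true(all(pri$sign %in% c("+", "-", "±")))
  ld <- default_loadings(0.2)
  expect_true(all(abs(ld$loading) == 0.2))
  # a known entry: higher arousal with higher F0 mean
  expect_equal(ld$loading[ld$feature == "f0_mean" & ld$emotion == "arousal"],
               0.2)
  # valence carries no speech-form expectation
  expect_false(any(ld$emotion == "valence" & ld$feature %in%
                     c("f0_mean", "jitter_mean")))
})

test_that("the study object is deterministic under its seed", {
  cfg <- simulation_config(n_participants = 3, n_days = 2, rng_seed = 17)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$surveys, b$surveys)
  expect_identical(a$profiles, b$profiles)
})

test_that("full rendering writes linked, re-readable artifacts", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_participants = 2, n_days = 1, rng_seed = 23,
                           voice_rate = 1, keyboard_rate = 1,
                           compliance_base = 0.9, compliance_decay = 0)
  st <- simulate_study(cfg, render = "full", out_dir = dir)
  expect_gt(nrow(st$artifacts), 0)
  expect_true(all(file.exists(st$artifacts$transcript)))
  voice <- st$artifacts[st$artifacts$type == "voice", ]
  expect_true(all(file.exists(voice$audio)))
  # voice recordings sit within the 5-minute linkage window
  sv <- st$surveys[match(paste(voice$participant_id, voice$beep),
                         paste(st$surveys$participant_id, st$surveys$beep)), ]
  expect_true(all(abs(voice$timestamp - sv$timestamp) <= 300))
  # clips decode and carry voiced speech-like material
  fx <- extract_acoustic_features(read_wav(voice$audio[1]))
  expect_gt(fx$voiced_segments_per_second, 0)
  expect_false(is.na(fx$f0_mean))
  # keystroke log is well-formed
  expect_true(all(st$keystrokes$release_ms >= st$keystrokes$press_ms))
})

test_that("null loadings leave features uncorrelated with emotions", {
  cfg <- simulation_config(n_participants = 30, n_days = 6,
                           loadings = no_loadings(), voice_rate = 1,
                           keyboard_rate = 1, rng_seed = 29)
  st <- simulate_study(cfg)
  ds <- assemble_analysis(st, "voice", min_responses = 10)
  r <- momentary_slope(ds$momentary, "valence", "speech_posemo")
  expect_lt(abs(r$estimate), 0.06)
})

test_that("planted loadings are recovered in sign for directed priors", {
  cfg <- simulation_config(n_participants = 40, n_days = 8,
                           voice_rate = 1, keyboard_rate = 1, rng_seed = 31)
  st <- simulate_study(cfg)
  dsv <- assemble_analysis(st, "voice", min_responses = 10)
  # two directed entries with opposite signs
  up <- momentary_slope(dsv$momentary, "arousal", "loudness_mean")
  down <- momentary_slope(dsv$momentary, "sadness", "loudness_mean")
  expect_gt(up$estimate, 0)
  expect_lt(down$estimate, 0)
})
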