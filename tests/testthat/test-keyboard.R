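entry_events <- function(n_char, start_ms, gap_ms, press_ms = 80,
                         n_back = 0, pid = "P001", entry = "e1") {
  n <- n_char + n_back
  press <- start_ms + (0:(n - 1)) * gap_ms
  data.frame(participant_id = pid, entry_id = entry,
             key_class = c(rep("character", n_char), rep("backspace", n_back)),
             press_ms = press, release_ms = press + press_ms)
}

test_that("entry summaries reproduce hand arithmetic", {
  # 10 characters spread over 5 s (first press to last release), 80 ms presses
  ev <- entry_events(10, 0, (5000 - 80) / 9)
  s <- summarize_entry(ev)
  expect_equal(s$n_characters, 10)
  expect_equal(s$duration_s, 5)
  expect_equal(s$typing_speed, 2)
  expect_equal(s$avg_key_press_duration_ms, 80)

  # degenerate single instantaneous key
  one <- data.frame(participant_id = "P001", entry_id = "e1",
                    key_class = "character", press_ms = 100, release_ms = 100)
  s1 <- summarize_entry(one)
  expect_equal(s1$duration_s, 0)
  expect_true(is.na(s1$typing_speed))

  ev2 <- entry_events(9, 0, 100, n_back = 1)
  s2 <- summarize_entry(ev2)
  expect_equal(s2$n_characters, 9)
  expect_equal(s2$n_backspaces, 1)

  expect_error(summarize_entry(data.frame()), "no events")
})

test_that("binning pools counts, averages dynamics and applies relative rates", {
  ev <- rbind(entry_events(10, 0, (5000 - 80) / 9, entry = "e1"),
              entry_events(10, 10000, (2500 - 80) / 9, entry = "e2"))
  ent <- summarize_entries(ev)
  b <- bin_keyboard(ent, esm_ms = 0)
  expect_equal(b$typing_speed, 3)          # unweighted mean of 2 and 4
  expect_equal(b$n_characters, 20)
  expect_equal(b$n_entries, 2)

  ev2 <- rbind(entry_events(90, 0, 50, entry = "e1"),
               entry_events(0, 20000, 50, n_back = 10, entry = "e2"))
  b2 <- bin_keyboard(summarize_entries(ev2), esm_ms = 0)
  expect_equal(b2$backspaces_rel, 0.1)     # 10 / (90 + 10)
})

test_that("the bin window is closed-left open-right at esm +/- 30 min", {
  w <- 30 * 60 * 1000
  at <- function(t) summarize_entries(entry_events(5, t, 100))
  expect_false(is.null(bin_keyboard(at(-w), esm_ms = 0)))       # exactly -30 min
  expect_true(is.null(bin_keyboard(at(w), esm_ms = 0)))         # exactly +30 min
  expect_false(is.null(bin_keyboard(at(w - 1), esm_ms = 0)))
  expect_true(is.null(bin_keyboard(at(-w - 1), esm_ms = 0)))
})

test_that("splitting an entry leaves summed counts unchanged", {
  whole <- entry_events(20, 0, 100, n_back = 4)
  halves <- rbind(entry_events(10, 0, 100, n_back = 2, entry = "a"),
                  entry_events(10, 5000, 100, n_back = 2, entry = "b"))
  b1 <- bin_keyboard(summarize_entries(whole), 0)
  b2 <- bin_keyboard(summarize_entries(halves), 0)
  expect_equal(b1$n_characters, b2$n_characters)
  expect_equal(b1$backspaces_rel, b2$backspaces_rel)
  expect_equal(b2$n_entries, 2)
})

test_that("binning against surveys keys rows by participant and time", {
  ev <- rbind(entry_events(10, 1000, 100, pid = "P001"),
              entry_events(12, 1000, 100, pid = "P002", entry = "e9"))
  surveys <- data.frame(participant_id = c("P001", "P002", "P003"),
                        timestamp_ms = c(0, 0, 0))
  out <- bin_keyboard_all(summarize_entries(ev), surveys)
  expect_equal(nrow(out), 2)
  expect_setequal(out$participant_id, c("P001", "P002"))
})
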