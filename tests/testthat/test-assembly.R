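test_that("voice linkage honours the 5-minute window and nearest-wins rule", {
  sv <- data.frame(participant_id = "P001", timestamp = 1000)
  near <- data.frame(participant_id = "P001", timestamp = 1000 + 4 * 60)
  far <- data.frame(participant_id = "P001", timestamp = 1000 + 6 * 60)
  expect_equal(nrow(link_voice(sv, near)$links), 1)
  expect_null(link_voice(sv, far)$links)
  expect_equal(link_voice(sv, far)$unlinked$reason,
               "no free survey within window")

  both <- data.frame(participant_id = "P001",
                     timestamp = c(1000 + 2 * 60, 1000 + 4 * 60))
  lk <- link_voice(sv, both)
  expect_equal(nrow(lk$links), 1)
  expect_equal(lk$links$timestamp, 1000 + 2 * 60)
  expect_equal(nrow(lk$unlinked), 1)
})

test_that("linkage is injective both ways", {
  set.seed(4)
  sv <- data.frame(participant_id = "P001", timestamp = sort(runif(30, 0, 1e5)))
  rc <- data.frame(participant_id = "P001",
                   timestamp = sort(runif(40, 0, 1e5)))
  lk <- link_voice(sv, rc)
  expect_false(any(duplicated(lk$links$survey_timestamp)))
  expect_false(any(duplicated(lk$links$timestamp)))
  expect_true(all(lk$links$delta_s <= 300))
  n_rec <- nrow(lk$links) + (if (is.null(lk$unlinked)) 0 else nrow(lk$unlinked))
  expect_equal(n_rec, 40)  # conservation
})

test_that("participant flow arithmetic reproduces stage accounting", {
  fl <- participant_flow(screened = 230, excluded_screening = 116,
                         attended = 69, consent_refused = 2,
                         install_failed = 2)
  expect_equal(fl$n[fl$stage == "eligible"], 114)
  expect_equal(fl$n[fl$stage == "enrolled"], 65)
})

test_that("inclusion needs 30 responses and one stream observation", {
  surveys <- data.frame(participant_id = rep(c("A", "B", "C"), c(29, 30, 40)))
  linked <- data.frame(participant_id = c("A", "B"))
  inc <- apply_inclusion(surveys, linked)
  expect_equal(inc$retained, "B")    # A: 29 responses; C: no stream
  acct <- inc$accounting
  expect_equal(acct$n[acct$stage == "with_surveys"], 3)
  # conservation: exclusions plus retained cover the input
  expect_equal(sum(acct$n[grepl("excluded", acct$stage)]) +
                 acct$n[acct$stage == "retained"],
               acct$n[acct$stage == "with_surveys"])
  expect_error(apply_inclusion(surveys[0, , drop = FALSE], linked), "empty")
})

test_that("within-person standardization matches hand arithmetic", {
  d <- data.frame(participant_id = c("A", "A", "B", "B", "B"),
                  v = c(40, 60, 50, 50, 50))
  z <- standardize_within(d, "v")
  expect_equal(z$v[1:2], c(-sqrt(0.5), sqrt(0.5)), tolerance = 1e-9)
  expect_true(all(is.na(z$v[3:5])))            # zero variance
  expect_equal(attr(z, "dropped")$participant_id, "B")
})

test_that("standardization is idempotent and yields mean 0, SD 1", {
  set.seed(9)
  d <- data.frame(participant_id = rep(sprintf("P%02d", 1:6), each = 20),
                  a = rnorm(120, 50, 10), b = runif(120))
  z <- standardize_within(d, c("a", "b"))
  for (pid in unique(z$participant_id)) {
    expect_equal(mean(z$a[z$participant_id == pid]), 0, tolerance = 1e-9)
    expect_equal(sd(z$a[z$participant_id == pid]), 1, tolerance = 1e-9)
  }
  zz <- standardize_within(z, c("a", "b"))
  expect_equal(zz$a, z$a, tolerance = 1e-9)
})

test_that("trait aggregation averages linked observations and scores DASS", {
  expect_equal(dass_depression(rep(0, 7)), 0)
  expect_equal(dass_depression(c(0, 1, 1, 0, 2, 1, 2)), 1)
  expect_error(dass_depression(c(0, 1, 1, 0, 2, 1, 5)), "0..3")

  d <- data.frame(participant_id = c("A", "A", "B"), v = c(10, 30, 7))
  dass <- data.frame(participant_id = c("A", "B"),
                     dass1 = c(0, 1), dass2 = c(1, 1), dass3 = c(1, 1),
                     dass4 = c(0, 1), dass5 = c(2, 1), dass6 = c(1, 1),
                     dass7 = c(2, 1))
  tr <- aggregate_traits(d, "v", dass)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$v[tr$participant_id == "A"], 20)
  expect_equal(tr$dass_depression, c(1, 1))
})

test_that("compliance statistics and day correlation behave at the edges", {
  a <- data.frame(participant_id = rep(c("A", "B"), each = 4),
                  answered = c(rep(TRUE, 4), TRUE, TRUE, FALSE, FALSE))
  cs <- compliance_stats(a)
  expect_equal(cs$per_participant$compliance,
               c(1, 0.5)[match(cs$per_participant$participant_id, c("A", "B"))])
  expect_equal(cs$mean, 0.75)

  daily <- data.frame(participant_id = rep("A", 5), day = 1:5,
                      count = c(5, 4, 3, 2, 1))
  expect_equal(day_activity_correlation(daily), -1)
})
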