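test_that("predictive R2 follows its definition including the sign", {
  expect_equal(predictive_r2(c(1, 2, 3), rep(2, 3)), 0)   # mean predictor
  expect_equal(predictive_r2(c(1, 2, 3), c(1, 2, 3)), 1)  # perfect
  # worked micro-example with the population variance convention
  expect_equal(predictive_r2(c(0, 1, 2), c(0, 0, 0)), -1.5)
})

test_that("splits are disjoint, exhaustive and near 80/20", {
  d <- make_panel(n_id = 13, n_obs = 17, r = 0.2, seed = 8)
  sp <- make_split(d, "momentary", seed = 3)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(nrow(d)))
  expect_lte(abs(length(sp$train_idx) - round(0.8 * nrow(d))), 1)
  # every participant keeps a training observation
  expect_setequal(unique(d$participant_id[sp$train_idx]),
                  unique(d$participant_id))
  # determinism under the seed
  sp2 <- make_split(d, "momentary", seed = 3)
  expect_identical(sp$train_idx, sp2$train_idx)

  tr <- data.frame(participant_id = sprintf("P%02d", 1:20), y = rnorm(20))
  spt <- make_split(tr, "trait", seed = 4)
  expect_equal(length(spt$train_idx), 16)
  expect_length(intersect(spt$train_idx, spt$test_idx), 0)
})

test_that("candidate selection follows flags, top-3 fallback and ties", {
  tab <- data.frame(emotion = "valence",
                    feature = c("f1", "f2", "f3", "f4", "f5"),
                    estimate = c(0.30, -0.25, 0.20, 0.10, 0.05),
                    raw_p = c(0.001, 0.002, 0.01, 0.2, 0.5),
                    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  feats <- paste0("f", 1:5)
  expect_setequal(select_candidates(tab, "valence", feats), feats)

  tab$significant <- FALSE
  expect_equal(select_candidates(tab, "valence", feats), c("f1", "f2", "f3"))

  # tie on |estimate| broken by the fixed feature order
  tab$estimate <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  expect_equal(select_candidates(tab, "valence", feats), c("f1", "f2", "f3"))

  tab$significant <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(select_candidates(tab, "valence", feats), "f4")  # no padding

  expect_equal(select_candidates(tab[1:2, ], "valence", c("f1", "f2")),
               c("f1", "f2"))
})

test_that("cross-validated selection keeps signal and falls back on noise", {
  set.seed(21)
  d <- make_panel(n_id = 12, n_obs = 25, r = 0.6, seed = 21)
  names(d)[names(d) == "x"] <- "signal"
  d$noise1 <- as.vector(scale(rnorm(nrow(d))))
  d$noise2 <- as.vector(scale(rnorm(nrow(d))))
  sel <- cv_feature_select(d, c("signal", "noise1", "noise2"), "y",
                           "momentary", seed = 1)
  expect_true("signal" %in% sel$retained)

  d$y <- as.vector(scale(rnorm(nrow(d))))  # sever the outcome
  sel0 <- cv_feature_select(d, c("noise1", "noise2", "signal"), "y",
                            "momentary", seed = 1)
  expect_length(sel0$retained, 2)          # the "2 best" fallback

  sel1 <- cv_feature_select(d, c("noise1", "noise2", "signal"), "y",
                            "momentary", seed = 1)
  expect_identical(sel0$retained, sel1$retained)  # seeded determinism
})

test_that("final fit scores out of sample at both levels", {
  d <- make_panel(n_id = 15, n_obs = 30, r = 0.5, seed = 31)
  sp <- make_split(d, "momentary", seed = 2)
  sc <- fit_final_and_score(d[sp$train_idx, ], d[sp$test_idx, ], "x", "y",
                            "momentary")
  expect_true(sc$ok)
  expect_gt(sc$r2, 0)     # r = 0.5 planted, must beat the mean predictor

  set.seed(32)
  tr <- data.frame(participant_id = sprintf("P%02d", 1:30), x = rnorm(30))
  tr$y <- 0.8 * tr$x + rnorm(30, 0, 0.4)
  spt <- make_split(tr, "trait", seed = 5)
  sct <- fit_final_and_score(tr[spt$train_idx, ], tr[spt$test_idx, ], "x",
                             "y", "trait")
  # the OLS route must agree with a direct lm prediction
  fit <- lm(y ~ x, tr[spt$train_idx, ])
  r2_direct <- predictive_r2(tr$y[spt$test_idx],
                             predict(fit, tr[spt$test_idx, ]))
  expect_equal(sct$r2, r2_direct, tolerance = 1e-12)
})

test_that("resampling is deterministic and preserves negative R2", {
  d <- make_panel(n_id = 10, n_obs = 20, r = 0, seed = 41)
  d$f1 <- as.vector(scale(rnorm(nrow(d))))
  tab <- correlation_table(d, "y", c("x", "f1"), "momentary")
  a <- resample_splits(d, "y", c("x", "f1"), tab, "momentary",
                       n_splits = 4, seed = 9)
  b <- resample_splits(d, "y", c("x", "f1"), tab, "momentary",
                       n_splits = 4, seed = 9)
  expect_identical(a$splits, b$splits)
  expect_false(any(is.na(a$splits$r2) & a$splits$ok))
})

test_that("feature families combine on their common rows", {
  d <- make_panel(n_id = 6, n_obs = 10, r = 0.3, seed = 51)
  d$a1 <- rnorm(nrow(d)); d$b1 <- rnorm(nrow(d))
  d$a1[1:20] <- NA; d$b1[41:60] <- NA
  cmb <- combine_feature_sets(d, list(A = "a1", B = "b1"))
  expect_equal(nrow(cmb$data), nrow(d) - 40)
  expect_lte(nrow(cmb$data), min(sum(!is.na(d$a1)), sum(!is.na(d$b1))))
  expect_setequal(cmb$features, c("a1", "b1"))

  d$b2 <- NA_real_
  d$b2[1:20] <- 1  # disjoint from a1 rows
  expect_error(combine_feature_sets(d, list(A = "a1", B = "b2")),
               "no observations")
})
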