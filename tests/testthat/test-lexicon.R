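test_that("tokenization segments words, exclamation marks and emoji", {
  lex <- tiny_lexicon()
  tk <- tokenize("Ik ben blij!", lex)
  expect_equal(tk$tokens, c("ik", "ben", "blij"))
  expect_equal(tk$exclam, 1)

  expect_equal(tokenize("", lex)$tokens, character(0))
  expect_equal(tokenize("", lex)$exclam, 0)

  tk2 <- tokenize("top top!!", lex)
  expect_equal(tk2$tokens, c("top", "top"))
  expect_equal(tk2$exclam, 2)

  tk3 <- tokenize("blij :) maar ook :( soms :)", lex)
  expect_equal(tk3$pos_emojis, 2)
  expect_equal(tk3$neg_emojis, 1)
  expect_false(any(grepl("[():]", tk3$tokens)))

  # apostrophes stay inside tokens
  expect_equal(tokenize("m'n fiets", lex)$tokens, c("m'n", "fiets"))
})

test_that("content features reproduce hand counts and percentages", {
  lex <- tiny_lexicon()
  cf <- extract_content_features("ik ben niet blij", lex)
  expect_equal(cf$wc, 4)
  expect_equal(cf$i, 25)
  expect_equal(cf$negate, 25)
  expect_equal(cf$posemo, 25)
  expect_equal(cf$we, 0)
  expect_equal(cf$recognized_fraction, 3 / 4)
  expect_false(cf$degenerate)
})

test_that("unmatched text and empty text degrade gracefully", {
  lex <- tiny_lexicon()
  cf <- extract_content_features("qqq www eee", lex)
  for (cat in c("i", "we", "you", "negate", "posemo", "negemo",
                "anx", "anger", "sad", "certain", "swear"))
    expect_equal(cf[[cat]], 0)
  expect_equal(cf$recognized_fraction, 0)

  cf0 <- extract_content_features("", lex)
  expect_true(cf0$degenerate)
  expect_equal(cf0$wc, 0)
  expect_equal(cf0$posemo, 0)
})

test_that("stems match by prefix and never undershoot the stem", {
  lex <- tiny_lexicon()  # posemo contains happ*
  expect_equal(extract_content_features("happy", lex)$posemo, 100)
  expect_equal(extract_content_features("happiness", lex)$posemo, 100)
  expect_equal(extract_content_features("hap", lex)$posemo, 0)
})

test_that("extraction is idempotent and percentages bounded", {
  lex <- demo_lexicon()
  txt <- "ik ben niet zo blij vandaag maar wel zeker trots op ons werk!"
  a <- extract_content_features(txt, lex)
  b <- extract_content_features(txt, lex)
  expect_identical(a, b)
  pct <- unlist(a[c("i", "we", "you", "negate", "posemo", "negemo",
                    "anx", "anger", "sad", "certain", "swear")])
  expect_true(all(pct >= 0 & pct <= 100))
  expect_true(a$recognized_fraction >= 0 && a$recognized_fraction <= 1)
})

test_that("lexicon validation enforces the category contract", {
  lex <- tiny_lexicon()
  bad <- lex; bad$categories$extra <- "x"
  expect_error(validate_lexicon(bad), "categories")
  bad2 <- lex; bad2$categories$posemo <- c("Blij")
  expect_error(validate_lexicon(bad2), "lowercase")
  bad3 <- lex; bad3$categories$posemo <- c("blij", "blij*")
  expect_error(validate_lexicon(bad3), "stem")
  expect_s3_class(demo_lexicon(), "emolang_lexicon")
})
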