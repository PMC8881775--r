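#' Dictionary-based word-category counting
#'
#' Reimplementation of LIWC-style closed-vocabulary counting for the 12
#' speech categories (word count, first-person singular/plural, second
#' person, negations, positive/negative emotion, anxiety, anger, sadness,
#' certainty, swear words) used throughout the pipeline, plus exclamation
#' marks and positive/negative emoji counts for the writing stream. Each
#' category is scored as the percentage of tokens matching any of its
#' entries; entries are exact lowercase words or trailing-star stems
#' ("happ*" matches "happy" and "happiness" but not "hap").
#'
#' @name lexicon_features
NULL

LEXICON_CATEGORIES <- c("i", "we", "you", "negate", "posemo", "negemo",
                        "anx", "anger", "sad", "certain", "swear")

#' Read a category lexicon from JSON
#'
#' The file must contain a `categories` map (category name to entry array)
#' covering exactly the eleven dictionary categories, and an `emoji` map
#' with `positive` and `negative` arrays.
#'
#' @param path path to a JSON lexicon file.
#' @return A validated `emolang_lexicon` object.
#' @export
read_lexicon <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lex <- structure(list(categories = lapply(raw$categories, as.character),
                        emoji = list(positive = as.character(raw$emoji$positive),
                                     negative = as.character(raw$emoji$negative))),
                   class = "emolang_lexicon")
  validate_lexicon(lex)
  lex
}

#' Built-in demonstration lexicon
#'
#' A small open lexicon (roughly 150 Dutch entries) with the full category
#' structure required by the pipeline. It is a stand-in for a proprietary
#' dictionary and makes no claim of lexical coverage; synthetic transcripts
#' are generated from the same entries, so counting is exercised end to end.
#'
#' @return An `emolang_lexicon` object.
#' @export
demo_lexicon <- function() {
  read_lexicon(system.file("extdata", "demo_lexicon.json", package = "emolang",
                           mustWork = TRUE))
}

#' Validate a lexicon object
#'
#' Checks the category set, lowercase entries, and that no stem coexists
#' with itself as an exact word within one category.
#'
#' @param lex an `emolang_lexicon`.
#' @return `lex`, invisibly; errors on violation.
#' @export
validate_lexicon <- function(lex) {
  if (!setequal(names(lex$categories), LEXICON_CATEGORIES))
    stopf("lexicon categories must be exactly {%s}; got {%s}",
          paste(LEXICON_CATEGORIES, collapse = ", "),
          paste(names(lex$categories), collapse = ", "))
  for (cat in names(lex$categories)) {
    entries <- lex$categories[[cat]]
    if (any(entries != tolower(entries)))
      stopf("lexicon category '%s' contains non-lowercase entries", cat)
    stems <- sub("\\*$", "", entries[endsWith(entries, "*")])
    if (any(stems %in% entries))
      stopf("category '%s': stem and identical exact word both present", cat)
  }
  if (!all(c("positive", "negative") %in% names(lex$emoji)))
    stopf("lexicon must define positive and negative emoji sets")
  invisible(lex)
}

#' Tokenize a transcript or message
#'
#' Lowercases, matches and removes emoji (against the lexicon's emoji
#' sets), counts exclamation marks, and splits the remainder on non-letter
#' boundaries keeping apostrophes inside tokens.
#'
#' @param text a single UTF-8 string.
#' @param lexicon optional lexicon providing the emoji sets; without one,
#'   emoji counts are 0 and no emoji are removed.
#' @return list with `tokens` (lowercase character vector), `exclam`
#'   (count), `pos_emojis`, `neg_emojis` (counts).
#' @export
tokenize <- function(text, lexicon = NULL) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text)) text <- ""
  pos <- 0L; neg <- 0L
  if (!is.null(lexicon)) {
    for (em in lexicon$emoji$positive) {
      n <- length(gregexpr(em, text, fixed = TRUE)[[1]])
      if (n == 1 && gregexpr(em, text, fixed = TRUE)[[1]][1] == -1) n <- 0L
      if (n > 0) { pos <- pos + n; text <- gsub(em, " ", text, fixed = TRUE) }
    }
    for (em in lexicon$emoji$negative) {
      n <- length(gregexpr(em, text, fixed = TRUE)[[1]])
      if (n == 1 && gregexpr(em, text, fixed = TRUE)[[1]][1] == -1) n <- 0L
      if (n > 0) { neg <- neg + n; text <- gsub(em, " ", text, fixed = TRUE) }
    }
  }
  exclam <- sum(strsplit(text, "")[[1]] == "!")
  text <- tolower(text)
  m <- gregexpr("[\\p{L}']+", text, perl = TRUE)[[1]]
  tokens <- character(0)
  if (!(length(m) == 1 && m[1] == -1)) {
    tokens <- regmatches(text, list(m))[[1]]
    tokens <- gsub("^'+|'+$", "", tokens)
    tokens <- tokens[nzchar(tokens)]
  }
  list(tokens = tokens, exclam = exclam, pos_emojis = pos, neg_emojis = neg)
}

# Which tokens match a category's entry list (exact words + stems).
match_category <- function(tokens, entries) {
  if (length(tokens) == 0 || length(entries) == 0)
    return(logical(length(tokens)))
  is_stem <- endsWith(entries, "*")
  exact <- entries[!is_stem]
  stems <- sub("\\*$", "", entries[is_stem])
  hit <- tokens %in% exact
  for (s in stems) hit <- hit | startsWith(tokens, s)
  hit
}

#' Extract content features from text
#'
#' Scores one transcript or pooled message against the lexicon. Each
#' category percentage is `100 * matches / word_count`; a token may count
#' toward several categories. `recognized_fraction` is the share of tokens
#' matching at least one entry anywhere in the lexicon. With zero tokens
#' the vector is flagged degenerate and all percentages are 0.
#'
#' @param text a single string.
#' @param lexicon an `emolang_lexicon`.
#' @param exclam_as report exclamation marks as percent of word count
#'   (default, consistent with the other dimensions) or as a raw count.
#' @return one-row data.frame: `wc`, one percentage per category, `exclam`,
#'   `pos_emojis`, `neg_emojis`, `recognized_fraction`, `degenerate`.
#' @export
extract_content_features <- function(text, lexicon,
                                     exclam_as = c("percent", "count")) {
  exclam_as <- match.arg(exclam_as)
  validate_lexicon(lexicon)
  tk <- tokenize(text, lexicon)
  n <- length(tk$tokens)
  out <- list(wc = n)
  recognized <- logical(n)
  for (cat in LEXICON_CATEGORIES) {
    hit <- match_category(tk$tokens, lexicon$categories[[cat]])
    out[[cat]] <- if (n == 0) 0 else 100 * sum(hit) / n
    recognized <- recognized | hit
  }
  out$exclam <- if (exclam_as == "count") tk$exclam
                else if (n == 0) 0 else 100 * tk$exclam / n
  out$pos_emojis <- tk$pos_emojis
  out$neg_emojis <- tk$neg_emojis
  out$recognized_fraction <- if (n == 0) 0 else sum(recognized) / n
  out$degenerate <- n == 0
  as.data.frame(out)
}
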