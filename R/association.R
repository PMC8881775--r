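#' Emotion-feature association tables
#'
#' Pairwise associations between the seven emotions and each language
#' feature family, at two levels. Momentary: the fixed slope of a
#' two-level linear model (participant random intercept, REML) of the
#' within-person standardized emotion on the standardized feature -- with
#' both variables standardized within persons this slope is a pooled
#' within-person correlation. Trait: Spearman rank correlation over
#' per-participant aggregates. Each displayed table (level x feature
#' family) forms one multiple-testing family corrected by Holm's
#' step-down procedure.
#'
#' @name association
NULL

#' Momentary (within-person) slope for one emotion-feature pair
#'
#' Fits `emotion ~ feature + (1 | participant)` by REML on the
#' within-person standardized momentary dataset and returns the fixed
#' slope with its p-value. P-values use the large-sample normal
#' approximation by default; `method = "satterthwaite"` uses lmerTest's
#' Satterthwaite degrees of freedom when that package is installed.
#'
#' @param data momentary dataset (standardized), with `participant_id`.
#' @param emotion,feature column names.
#' @param method p-value method.
#' @return list: `estimate`, `raw_p`, `n`, `ok` (FALSE when the fit
#'   failed, with `message`).
#' @export
momentary_slope <- function(data, emotion, feature,
                            method = c("normal", "satterthwaite")) {
  method <- match.arg(method)
  d <- data.frame(y = data[[emotion]], x = data[[feature]],
                  g = factor(data$participant_id))
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 4 || length(unique(d$g)) < 2)
    return(list(estimate = NA_real_, raw_p = NA_real_, n = nrow(d),
                ok = FALSE, message = "insufficient data"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ x + (1 | g), data = d, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(estimate = NA_real_, raw_p = NA_real_, n = nrow(d),
                ok = FALSE, message = conditionMessage(fit)))
  co <- summary(fit)$coefficients
  est <- co["x", "Estimate"]; tval <- co["x", "t value"]
  if (method == "satterthwaite" && requireNamespace("lmerTest", quietly = TRUE)) {
    fit2 <- suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ x + (1 | g), data = d, REML = TRUE)))
    co2 <- summary(fit2)$coefficients
    p <- co2["x", "Pr(>|t|)"]
  } else {
    p <- 2 * stats::pnorm(-abs(tval))
  }
  list(estimate = unname(est), raw_p = unname(p), n = nrow(d), ok = TRUE,
       message = NULL)
}

#' Trait-level Spearman correlation
#'
#' Rank correlation with mid-ranks for ties; p-value from the
#' t-approximation.
#'
#' @param data trait dataset, one row per participant.
#' @param x,y column names (emotion/depression and feature).
#' @return list: `estimate` (rho), `raw_p`, `n`, `ok`.
#' @export
trait_spearman <- function(data, x, y) {
  d <- data.frame(a = data[[x]], b = data[[y]])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 5 || stats::sd(d$a) == 0 || stats::sd(d$b) == 0)
    return(list(estimate = NA_real_, raw_p = NA_real_, n = nrow(d),
                ok = FALSE, message = "constant column or too few rows"))
  ct <- suppressWarnings(stats::cor.test(d$a, d$b, method = "spearman",
                                         exact = FALSE))
  list(estimate = unname(ct$estimate), raw_p = unname(ct$p.value),
       n = nrow(d), ok = TRUE, message = NULL)
}

#' Holm step-down significance flags
#'
#' Sorts the family's p-values ascending and flags p_(k) significant iff
#' p_(j) <= alpha / (m - j + 1) for every j <= k (step-down with stop at
#' the first failure). Equivalent to `p.adjust(p, "holm") <= alpha`, which
#' is how it is computed.
#'
#' @param p vector of raw p-values in [0, 1] (NA allowed, never flagged).
#' @param alpha family-wise error level (default 0.05).
#' @return logical vector of flags, same length and order as `p`.
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  if (!length(p)) stopf("empty p-value family")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values outside [0, 1]")
  flags <- rep(FALSE, length(p))
  ok <- !is.na(p)
  flags[ok] <- stats::p.adjust(p[ok], method = "holm") <= alpha
  flags
}

#' Full emotion-by-feature association table for one family
#'
#' Computes every emotion x feature cell at the requested level and
#' applies Holm correction over the whole table as one family. At the
#' trait level the grid can include `dass_depression` among the outcomes.
#'
#' @param data momentary or trait dataset.
#' @param emotions outcome column names.
#' @param features feature column names (one family per call).
#' @param level "momentary" or "trait".
#' @param family_id label recorded on every row (which table this is).
#' @param alpha Holm alpha.
#' @param method momentary p-value method, see [momentary_slope()].
#' @return data.frame: level, emotion, feature, estimate, raw_p,
#'   significant, family_id, n. Failed cells carry NA estimates and are
#'   excluded from the Holm family.
#' @export
correlation_table <- function(data, emotions, features,
                              level = c("momentary", "trait"),
                              family_id = NULL, alpha = 0.05,
                              method = "normal") {
  level <- match.arg(level)
  grid <- expand.grid(emotion = emotions, feature = features,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    if (level == "momentary")
      momentary_slope(data, grid$emotion[i], grid$feature[i], method = method)
    else
      trait_spearman(data, grid$emotion[i], grid$feature[i])
  })
  out <- data.frame(
    level = level,
    emotion = grid$emotion,
    feature = grid$feature,
    estimate = vapply(res, function(r) r$estimate, numeric(1)),
    raw_p = vapply(res, function(r) r$raw_p, numeric(1)),
    n = vapply(res, function(r) r$n, numeric(1)),
    family_id = family_id %||% paste(level, "table"),
    stringsAsFactors = FALSE)
  out$significant <- holm_adjust(out$raw_p, alpha = alpha)
  out
}
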