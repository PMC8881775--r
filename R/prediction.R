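#' Predictive modeling with cross-validated feature selection
#'
#' The predictive stage asks how much of an emotion's variation the
#' language features explain out of sample. For one emotion and feature
#' set: candidate predictors are the Holm-significant features of the
#' association stage (or the 3 most strongly correlated when none is
#' significant); a 10-fold cross-validation on the 80% training set keeps
#' candidates whose coefficient p-value averages below .05 over folds
#' (falling back to the 2 best to prevent overfitting); the final model --
#' a participant random-intercept, random-slope mixed model at the
#' momentary level, ordinary least squares at the trait level -- is fitted
#' on the full training set and scored on the 20% test set by predictive
#' R² = 1 - MSE / Var(test outcomes). The whole chain is repeated over 50
#' resampled train/test splits and summarized by the mean and SD of the
#' per-split R².
#'
#' @name prediction
NULL

#' Feature family name sets
#'
#' Column names of the four feature families as they appear in assembled
#' datasets (speech content prefixed `speech_`, writing content prefixed
#' `write_`; acoustic and typing names are unique already), plus the
#' combined sets.
#'
#' @return named list of character vectors.
#' @export
feature_sets <- function() {
  sc <- paste0("speech_", c("wc", LEXICON_CATEGORIES))
  wc <- paste0("write_", c("pos_emojis", "neg_emojis", "wc",
                           LEXICON_CATEGORIES, "exclam"))
  sets <- list(speech_content = sc,
               speech_form = ACOUSTIC_FEATURES,
               writing_content = wc,
               writing_form = TYPING_FEATURES)
  sets$speech_combined <- c(sets$speech_content, sets$speech_form)
  sets$writing_combined <- c(sets$writing_content, sets$writing_form)
  sets$all <- c(sets$speech_combined, sets$writing_combined)
  sets
}

#' Predictive R-squared
#'
#' `1 - MSE / Var` with the population (n) variance convention for the
#' test outcomes. Negative for models worse than predicting the test
#' mean; exactly 0 when predictions equal the test mean, 1 when perfect.
#'
#' @param y test outcomes.
#' @param yhat predictions.
#' @return the predictive R².
#' @export
predictive_r2 <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) > 0)
  v <- mean((y - mean(y))^2)
  if (v == 0) return(NA_real_)
  1 - mean((y - yhat)^2) / v
}

#' Build one 80/20 train/test split
#'
#' Momentary splits are at the observation level, stratified by
#' participant so that every participant keeps at least one training
#' observation whenever possible; trait splits are at the participant
#' (row) level. Overall proportions land within one row of 80/20.
#'
#' @param data the analysis dataset.
#' @param level "momentary" or "trait".
#' @param train_prop training share (default 0.8).
#' @param seed RNG seed for this split.
#' @param split_id identifier carried in the plan.
#' @return list: `split_id`, `level`, `train_idx`, `test_idx`, `seed`.
#' @export
make_split <- function(data, level = c("momentary", "trait"),
                       train_prop = 0.8, seed = 1, split_id = 1L) {
  level <- match.arg(level)
  n <- nrow(data)
  set.seed(seed)
  if (level == "trait") {
    n_train <- round(train_prop * n)
    train <- sort(sample.int(n, n_train))
  } else {
    ids <- factor(data$participant_id)
    target <- round(train_prop * n)
    per <- table(ids)
    base <- pmax(ifelse(per >= 2, 1L, 0L), floor(train_prop * per))
    base <- pmin(base, per)
    remainder <- target - sum(base)
    frac <- train_prop * as.numeric(per) - floor(train_prop * as.numeric(per))
    ord <- order(-frac, sample.int(length(per)))
    k <- 1
    while (remainder > 0 && k <= 2 * length(per)) {
      j <- ord[(k - 1) %% length(per) + 1]
      if (base[j] < per[j]) { base[j] <- base[j] + 1L; remainder <- remainder - 1 }
      k <- k + 1
    }
    while (remainder < 0) {  # overshoot from the >=1 guarantee
      j <- which.max(base - floor(train_prop * as.numeric(per)))
      if (base[j] > 1) { base[j] <- base[j] - 1L; remainder <- remainder + 1 }
      else break
    }
    train <- integer(0)
    for (j in seq_along(levels(ids))) {
      rows <- which(ids == levels(ids)[j])
      if (base[j] > 0) train <- c(train, sort(sample(rows, base[j])))
    }
    train <- sort(train)
  }
  list(split_id = split_id, level = level, seed = seed,
       train_idx = train, test_idx = setdiff(seq_len(n), train))
}

#' Candidate predictors for one emotion and feature set
#'
#' Holm-flagged features of the association table; when none is flagged,
#' the 3 features with largest absolute estimate (ties broken by the
#' fixed order of `features`); when fewer than 3 features exist, all.
#'
#' @param assoc_table output of [correlation_table()] at the matching level.
#' @param emotion outcome name.
#' @param features the feature set (fixed ordering used for ties).
#' @return character vector of candidate feature names.
#' @export
select_candidates <- function(assoc_table, emotion, features) {
  tb <- assoc_table[assoc_table$emotion == emotion &
                    assoc_table$feature %in% features &
                    !is.na(assoc_table$estimate), , drop = FALSE]
  if (nrow(tb) == 0) return(character(0))
  flagged <- tb$feature[tb$significant]
  if (length(flagged)) return(flagged[order(match(flagged, features))])
  k <- min(3, nrow(tb))
  ord <- order(-abs(tb$estimate), match(tb$feature, features))
  tb$feature[ord][seq_len(k)]
}

# Fit the selection-stage model on a row subset and return named
# coefficient p-values (normal approximation at the momentary level).
fit_selection_model <- function(data, predictors, emotion, level) {
  cols <- c(emotion, predictors,
            if (level == "momentary") "participant_id")
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  if (nrow(d) < length(predictors) + 2) return(NULL)
  rhs <- paste(predictors, collapse = " + ")
  if (level == "momentary") {
    f <- stats::as.formula(paste(emotion, "~", rhs, "+ (1 | participant_id)"))
    fit <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(f, data = d, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    co <- summary(fit)$coefficients
    p <- 2 * stats::pnorm(-abs(co[, "t value"]))
  } else {
    f <- stats::as.formula(paste(emotion, "~", rhs))
    fit <- tryCatch(stats::lm(f, data = d), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    co <- summary(fit)$coefficients
    p <- co[, "Pr(>|t|)"]
  }
  p[setdiff(names(p), "(Intercept)")]
}

#' Cross-validated predictor filtering
#'
#' Ten seeded folds over the training rows; per fold the full candidate
#' model is fitted on the fold's training part and every candidate's
#' coefficient p-value recorded. Candidates with mean p < .05 across
#' folds are retained; when none qualifies, the 2 with smallest mean p
#' (all when fewer than 2 candidates). Failed folds are skipped and the
#' mean taken over the rest.
#'
#' @param train training-rows dataset.
#' @param candidates candidate feature names.
#' @param emotion outcome name.
#' @param level "momentary" or "trait".
#' @param n_folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return list: `retained` (character), `mean_p` (named numeric),
#'   `n_failed_folds`.
#' @export
cv_feature_select <- function(train, candidates, emotion,
                              level = c("momentary", "trait"),
                              n_folds = 10, seed = 1) {
  level <- match.arg(level)
  if (length(candidates) == 0) return(list(retained = character(0),
                                           mean_p = numeric(0),
                                           n_failed_folds = 0L))
  if (length(candidates) == 1)
    return(list(retained = candidates, mean_p = stats::setNames(NA_real_,
                candidates), n_failed_folds = 0L))
  n <- nrow(train)
  if (n < n_folds) stopf("need at least %d training rows", n_folds)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  pmat <- matrix(NA_real_, n_folds, length(candidates),
                 dimnames = list(NULL, candidates))
  failed <- 0L
  for (k in seq_len(n_folds)) {
    p <- fit_selection_model(train[fold != k, , drop = FALSE],
                             candidates, emotion, level)
    if (is.null(p)) { failed <- failed + 1L; next }
    pmat[k, names(p)] <- p
  }
  mean_p <- colMeans(pmat, na.rm = TRUE)
  retained <- candidates[!is.na(mean_p) & mean_p < 0.05]
  if (length(retained) == 0) {
    k <- min(2, length(candidates))
    ord <- order(mean_p, match(candidates, candidates))
    retained <- candidates[ord][seq_len(k)]
  }
  list(retained = retained, mean_p = mean_p, n_failed_folds = failed)
}

#' Final fit and out-of-sample score
#'
#' Momentary level: a mixed model with participant random intercept and
#' per-participant random slopes for every predictor, fitted on the
#' training rows; test predictions use a participant's estimated effects
#' when the participant appears in training and population-level effects
#' otherwise. Boundary (singular) fits are accepted -- within-person
#' standardized outcomes leave essentially no between-person intercept
#' variance, so singularity is the expected geometry, not a failure; when
#' the optimizer errors, random slopes are dropped one at a time in fixed
#' (last-to-first) order. Trait level: ordinary least squares. The score
#' is [predictive_r2()] on the test rows.
#'
#' @param train,test row subsets of the analysis dataset.
#' @param predictors retained predictor names (nonempty).
#' @param emotion outcome name.
#' @param level "momentary" or "trait".
#' @return list: `r2`, `n_test`, `dropped_slopes`, `ok`, `message`.
#' @export
fit_final_and_score <- function(train, test, predictors, emotion,
                                level = c("momentary", "trait")) {
  level <- match.arg(level)
  if (length(predictors) == 0) stopf("no predictors retained")
  cols <- c(emotion, predictors, if (level == "momentary") "participant_id")
  tr <- train[stats::complete.cases(train[, cols, drop = FALSE]), cols,
              drop = FALSE]
  te <- test[stats::complete.cases(test[, cols, drop = FALSE]), cols,
             drop = FALSE]
  if (nrow(tr) < length(predictors) + 2 || nrow(te) < 2)
    return(list(r2 = NA_real_, n_test = nrow(te), dropped_slopes = character(0),
                ok = FALSE, message = "insufficient rows"))
  rhs <- paste(predictors, collapse = " + ")
  if (level == "trait") {
    fit <- stats::lm(stats::as.formula(paste(emotion, "~", rhs)), data = tr)
    pred <- stats::predict(fit, newdata = te)
    return(list(r2 = predictive_r2(te[[emotion]], pred), n_test = nrow(te),
                dropped_slopes = character(0), ok = TRUE, message = NULL))
  }
  slope_terms <- predictors
  dropped <- character(0)
  fit <- NULL
  repeat {
    re <- if (length(slope_terms))
      paste("(1 +", paste(slope_terms, collapse = " + "), "| participant_id)")
    else "(1 | participant_id)"
    f <- stats::as.formula(paste(emotion, "~", rhs, "+", re))
    fit <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(f, data = tr, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (!is.null(fit)) break
    if (length(slope_terms) == 0)
      return(list(r2 = NA_real_, n_test = nrow(te), dropped_slopes = dropped,
                  ok = FALSE, message = "mixed model failed"))
    dropped <- c(dropped, slope_terms[length(slope_terms)])
    slope_terms <- slope_terms[-length(slope_terms)]
  }
  pred <- stats::predict(fit, newdata = te, allow.new.levels = TRUE)
  list(r2 = predictive_r2(te[[emotion]], pred), n_test = nrow(te),
       dropped_slopes = dropped, ok = TRUE, message = NULL)
}

#' Resampled predictive performance for one emotion and feature set
#'
#' Runs the full select / cross-validate / fit / score chain on
#' `n_splits` seeded 80/20 splits and summarizes the per-split predictive
#' R² (negative values preserved). Candidates come from the global
#' association table, mirroring the use of "the significant correlations
#' of the previous analyses".
#'
#' @param data the analysis dataset at `level`.
#' @param emotion outcome name.
#' @param features feature set (character vector of columns).
#' @param assoc_table association table at the matching level.
#' @param level "momentary" or "trait".
#' @param n_splits number of resampled splits (default 50).
#' @param seed global seed; the pair (seed, split id) determines each
#'   split and its folds.
#' @param set_name label for the feature set.
#' @return an `emolang_predictive` list: per-split data.frame `splits`,
#'   `mean_r2`, `sd_r2`, `n_failed`, `unreliable` (more than 20% of
#'   splits failed), `emotion`, `set_name`.
#' @export
resample_splits <- function(data, emotion, features, assoc_table,
                            level = c("momentary", "trait"),
                            n_splits = 50, seed = 1, set_name = "features") {
  level <- match.arg(level)
  candidates <- select_candidates(assoc_table, emotion, features)
  rows <- list()
  for (i in seq_len(n_splits)) {
    sp <- make_split(data, level, seed = derive_seed(seed, i, 1L),
                     split_id = i)
    tr <- data[sp$train_idx, , drop = FALSE]
    te <- data[sp$test_idx, , drop = FALSE]
    sel <- tryCatch(cv_feature_select(tr, candidates, emotion, level,
                                      seed = derive_seed(seed, i, 2L)),
                    error = function(e) NULL)
    if (is.null(sel) || length(sel$retained) == 0) {
      rows[[i]] <- data.frame(split_id = i, r2 = NA_real_, n_predictors = 0,
                              predictors = "", ok = FALSE)
      next
    }
    sc <- fit_final_and_score(tr, te, sel$retained, emotion, level)
    rows[[i]] <- data.frame(split_id = i, r2 = sc$r2,
                            n_predictors = length(sel$retained),
                            predictors = paste(sel$retained, collapse = "+"),
                            ok = sc$ok && is.finite(sc$r2))
  }
  splits <- do.call(rbind, rows)
  okr <- splits$r2[splits$ok]
  n_failed <- sum(!splits$ok)
  structure(list(emotion = emotion, set_name = set_name, level = level,
                 candidates = candidates, splits = splits,
                 mean_r2 = if (length(okr)) mean(okr) else NA_real_,
                 sd_r2 = if (length(okr) > 1) stats::sd(okr) else NA_real_,
                 n_failed = n_failed,
                 unreliable = n_failed > 0.2 * n_splits),
            class = "emolang_predictive")
}

#' @export
print.emolang_predictive <- function(x, ...) {
  cat(sprintf("Predictive R2 (%s level): %s ~ %s\n", x$level, x$emotion,
              x$set_name))
  cat(sprintf("  mean %.4f  sd %.4f  over %d/%d splits%s\n",
              x$mean_r2, x$sd_r2, sum(x$splits$ok), nrow(x$splits),
              if (x$unreliable) "  [UNRELIABLE]" else ""))
  invisible(x)
}

#' Join feature families on their common rows
#'
#' Combined models are fitted on the observations carrying every
#' requested family (a family counts as present when at least one of its
#' features is non-missing in the row); the candidate pool is the union
#' of the per-set candidate lists.
#'
#' @param data the analysis dataset.
#' @param sets named list of feature-name vectors to combine.
#' @return list: `data` (row subset), `features` (union, in set order).
#' @export
combine_feature_sets <- function(data, sets) {
  stopifnot(length(sets) >= 1)
  keep <- rep(TRUE, nrow(data))
  for (fam in sets) {
    fam <- intersect(fam, names(data))
    if (length(fam) == 0) stopf("feature family absent from dataset")
    present <- rowSums(!is.na(data[, fam, drop = FALSE])) > 0
    keep <- keep & present
  }
  if (!any(keep)) stopf("no observations carry all requested families")
  list(data = data[keep, , drop = FALSE],
       features = unique(unlist(sets, use.names = FALSE)))
}
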