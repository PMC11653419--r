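#' Two-stage ANOVA screening of imputation predictors
#'
#' Stage 1 fits a joint linear model of the target on all candidate
#' predictors and computes type-III (partial) F-tests per term under
#' sum-to-zero contrasts; candidates with `p < p1` enter stage 2, which
#' refits on the survivors and keeps those with `p < p2`. Deterministic
#' given the table. Numeric candidates are treated as continuous,
#' character/factor candidates as factors (with `"missing"` as an ordinary
#' level where the schema declares one).
#'
#' @param table A data.frame (typically a `cohort_table`).
#' @param target Name of the numeric target column.
#' @param candidates Character vector of candidate predictor columns.
#' @param p1 Stage-1 inclusion threshold (default 0.15).
#' @param p2 Stage-2 retention threshold (default 0.05).
#' @param min_rows Minimum rows with the target observed.
#' @return A `screening_result`: list with `target`, `stage1` and `stage2`
#'   data.frames (`candidate`, `F`, `p`, `keep`), and `kept` (character
#'   vector of final survivors, possibly empty).
#' @export
screen_predictors <- function(table, target, candidates,
                              p1 = 0.15, p2 = 0.05, min_rows = 10L) {
  stopifnot(target %in% names(table), length(candidates) >= 1L,
            all(candidates %in% names(table)))
  rows <- !is.na(table[[target]])
  for (cand in candidates) rows <- rows & !is.na(table[[cand]])
  if (sum(rows) < min_rows) {
    stop("only ", sum(rows), " complete rows for screening target '",
         target, "'; need >= ", min_rows)
  }
  dat <- prepare_model_frame(table[rows, , drop = FALSE], target, candidates)
  usable <- drop_degenerate_terms(dat, candidates)
  stage1 <- anova_type3(dat, target, usable)
  stage1$keep <- stage1$p < p1
  survivors <- stage1$candidate[stage1$keep]
  if (length(survivors)) {
    stage2 <- anova_type3(dat, target, survivors)
    stage2$keep <- stage2$p < p2
  } else {
    stage2 <- stage1[0, , drop = FALSE]
  }
  structure(
    list(target = target, stage1 = stage1, stage2 = stage2,
         kept = stage2$candidate[stage2$keep], n_rows = sum(rows)),
    class = "screening_result"
  )
}

## coerce candidate columns: character -> factor; leave numerics
prepare_model_frame <- function(df, target, candidates) {
  out <- df[, unique(c(target, candidates)), drop = FALSE]
  for (cand in candidates) {
    if (is.character(out[[cand]]) || is.logical(out[[cand]])) {
      out[[cand]] <- factor(out[[cand]])
    } else if (is.factor(out[[cand]])) {
      out[[cand]] <- droplevels(out[[cand]])
    }
  }
  out
}

## remove constant columns and aliased terms before the type-III fit
drop_degenerate_terms <- function(dat, candidates) {
  keep <- candidates
  for (cand in candidates) {
    v <- dat[[cand]]
    n_distinct <- length(unique(v))
    if (n_distinct < 2L) {
      warning("dropping constant candidate '", cand, "'", call. = FALSE)
      keep <- setdiff(keep, cand)
    }
  }
  if (length(keep) == 0L) return(keep)
  form <- stats::reformulate(keep, response = names(dat)[1L])
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) {
    al <- stats::alias(fit)$Complete
    if (!is.null(al)) {
      terms_lab <- attr(stats::terms(fit), "term.labels")
      asg <- attr(stats::model.matrix(fit), "assign")
      bad_cols <- which(is.na(stats::coef(fit)))
      bad_terms <- unique(terms_lab[asg[bad_cols]])
      warning("dropping aliased candidate term(s): ",
              paste(bad_terms, collapse = ", "), call. = FALSE)
      keep <- setdiff(keep, bad_terms)
    }
  }
  keep
}

## type-III F tests via car::Anova with sum-to-zero contrasts
anova_type3 <- function(dat, target, candidates) {
  if (length(candidates) == 0L) {
    return(data.frame(candidate = character(0), F = numeric(0),
                      p = numeric(0), keep = logical(0),
                      stringsAsFactors = FALSE))
  }
  form <- stats::reformulate(candidates, response = target)
  contr <- lapply(candidates, function(cand) {
    if (is.factor(dat[[cand]])) "contr.sum" else NULL
  })
  names(contr) <- candidates
  contr <- Filter(Negate(is.null), contr)
  fit <- if (length(contr)) {
    stats::lm(form, data = dat, contrasts = contr)
  } else {
    stats::lm(form, data = dat)
  }
  a3 <- tryCatch(car::Anova(fit, type = 3), error = function(e) NULL)
  if (is.null(a3)) {
    # saturated fit (zero residual variance): a candidate whose removal
    # leaves residual variance behind is infinitely significant
    informative <- vapply(candidates, function(cand) {
      others <- setdiff(candidates, cand)
      form_r <- if (length(others)) {
        stats::reformulate(others, response = target)
      } else {
        stats::reformulate("1", response = target)
      }
      tot <- sum((dat[[target]] - mean(dat[[target]]))^2)
      stats::deviance(stats::lm(form_r, data = dat)) > 1e-10 * tot
    }, logical(1))
    return(data.frame(candidate = candidates,
                      F = ifelse(informative, Inf, 0),
                      p = ifelse(informative, 0, 1),
                      stringsAsFactors = FALSE))
  }
  rows <- rownames(a3) %in% candidates
  data.frame(candidate = rownames(a3)[rows],
             F = a3[rows, "F value"],
             p = a3[rows, "Pr(>F)"],
             stringsAsFactors = FALSE)
}

#' Fit a least-squares imputation model
#'
#' Ordinary least squares of the target on the retained predictors, with
#' reference (treatment) coding for categorical terms. Reports adjusted
#' R-squared and the residual RMSE (`sqrt(SSE / df_resid)`), the standard
#' linear-model definitions. An empty predictor set yields the
#' intercept-only model, whose prediction is the observed grand mean.
#'
#' @param table Data.frame with the fitting rows (target observed).
#' @param target Target column name.
#' @param predictors Character vector (may be empty).
#' @return An `imputation_model`: list with `target`, `predictors`, `fit`
#'   (the `lm` object), `coefficients`, `r2_adjusted`, `rmse`, `n_fit`.
#' @export
fit_imputation_model <- function(table, target, predictors = character(0)) {
  rows <- !is.na(table[[target]])
  for (p in predictors) rows <- rows & !is.na(table[[p]])
  dat <- prepare_model_frame(table[rows, , drop = FALSE], target,
                             if (length(predictors)) predictors else character(0))
  form <- if (length(predictors)) {
    stats::reformulate(predictors, response = target)
  } else {
    stats::as.formula(paste(target, "~ 1"))
  }
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) {
    warning("collinear predictors in imputation model for '", target,
            "'; aliased terms contribute nothing to predictions",
            call. = FALSE)
  }
  smry <- summary(fit)
  n_fit <- length(stats::residuals(fit))
  if (n_fit < length(stats::coef(fit)) + 2L) {
    stop("too few rows (", n_fit, ") to fit imputation model for '",
         target, "'")
  }
  structure(
    list(target = target, predictors = predictors, fit = fit,
         coefficients = stats::coef(fit),
         r2_adjusted = smry$adj.r.squared,
         rmse = smry$sigma, n_fit = n_fit),
    class = "imputation_model"
  )
}

#' Sequential single-imputation chain
#'
#' For each target in order: screen candidates with [screen_predictors()],
#' fit an OLS model on the observed rows with [fit_imputation_model()],
#' and fill the missing cells with conditional-mean point predictions
#' (no residual noise by default), clamped to the target's valid score
#' range. Earlier imputed targets are complete by the time later targets
#' are screened, so they can serve as candidates. Observed values are
#' never modified; `imputed_*` flags mark filled cells.
#'
#' Point-prediction single imputation understates downstream uncertainty;
#' `add_noise = TRUE` adds a residual draw (`N(0, rmse)`) for sensitivity
#' checks, but the default reproduces plain conditional-mean imputation.
#'
#' @param table A `cohort_table` (or compatible data.frame).
#' @param chain_config List of steps, each
#'   `list(target =, candidates =, p1 =, p2 =)`; see
#'   [default_chain_config()].
#' @param add_noise Add a residual noise draw to each prediction.
#' @param seed Optional seed (only used when `add_noise = TRUE`).
#' @return The table with missing target cells filled and flags set, with
#'   attribute `"imputation_report"`: per-target list of
#'   `screening_result`, `imputation_model`, `n_imputed`, `clamped`.
#' @export
impute_chain <- function(table, chain_config = default_chain_config(),
                         add_noise = FALSE, seed = NULL) {
  schema <- cohort_schema()
  if (!is.null(seed)) set.seed(seed)
  report <- list()
  for (step in chain_config) {
    target <- step$target
    stopifnot(target %in% names(table))
    miss <- is.na(table[[target]])
    if (!any(miss)) {
      report[[target]] <- list(skipped = TRUE,
                               note = "target fully observed")
      next
    }
    if (all(miss)) stop("target '", target, "' is fully missing; ",
                        "nothing to fit the imputation model on")
    scr <- screen_predictors(table, target, step$candidates,
                             p1 = step$p1 %||% 0.15,
                             p2 = step$p2 %||% 0.05)
    kept <- scr$kept
    if (length(kept) == 0L) {
      message("no predictor survived screening for '", target,
              "'; imputing with the observed grand mean")
    }
    model <- fit_imputation_model(table, target, kept)
    newdata <- prepare_model_frame(table[miss, , drop = FALSE], target,
                                   kept)
    pred <- as.numeric(stats::predict(model$fit, newdata = newdata))
    if (add_noise) pred <- pred + stats::rnorm(length(pred), 0, model$rmse)
    rng <- schema[[target]]$range %||% c(-Inf, Inf)
    clamped <- sum(pred < rng[1] | pred > rng[2])
    pred <- pmin(pmax(pred, rng[1]), rng[2])
    table[[target]][miss] <- pred
    flag_col <- paste0("imputed_", target)
    if (!flag_col %in% names(table)) table[[flag_col]] <- FALSE
    table[[flag_col]][miss] <- TRUE
    report[[target]] <- list(screening = scr, model = model,
                             n_imputed = sum(miss), clamped = clamped)
  }
  attr(table, "imputation_report") <- report
  table
}

#' Default imputation chain for the cohort schema
#'
#' Baseline THI first (screened against the clinical covariates), then
#' baseline GHSI (with the now-complete baseline THI as an additional
#' candidate), then post-treatment THI (with both imputed scores as
#' candidates) — the natural ordering when later scores depend on earlier
#' ones.
#'
#' @param p1,p2 Screening thresholds applied at every step.
#' @return A chain-config list for [impute_chain()].
#' @export
default_chain_config <- function(p1 = 0.15, p2 = 0.05) {
  base_covariates <- c("age", "sex", "hearing_loss", "tinnitus_duration",
                       "non_hearing_problems", "tinnitus_type",
                       "referring_specialty")
  list(
    list(target = "thi_baseline", candidates = base_covariates,
         p1 = p1, p2 = p2),
    list(target = "ghsi_baseline",
         candidates = c(base_covariates, "thi_baseline"),
         p1 = p1, p2 = p2),
    list(target = "thi_post",
         candidates = c(base_covariates, "thi_baseline", "ghsi_baseline"),
         p1 = p1, p2 = p2)
  )
}

#' Flatten an imputation report to a delimited-table-ready data.frame
#'
#' @param table A table returned by [impute_chain()] (carrying the
#'   `"imputation_report"` attribute), or the report list itself.
#' @return Data.frame with one row per (target, stage, candidate) plus the
#'   per-target model fit statistics.
#' @export
imputation_report_table <- function(table) {
  report <- if (is.data.frame(table)) {
    attr(table, "imputation_report")
  } else {
    table
  }
  rows <- list()
  for (target in names(report)) {
    entry <- report[[target]]
    if (isTRUE(entry$skipped)) next
    for (stage in c("stage1", "stage2")) {
      st <- entry$screening[[stage]]
      if (nrow(st) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        target = target, stage = stage, predictor = st$candidate,
        F = st$F, p = st$p, kept = st$keep,
        r2_adjusted = entry$model$r2_adjusted,
        rmse = entry$model$rmse, n_imputed = entry$n_imputed,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(target = character(0), stage = character(0),
                      predictor = character(0), F = numeric(0),
                      p = numeric(0), kept = logical(0),
                      r2_adjusted = numeric(0), rmse = numeric(0),
                      n_imputed = integer(0)))
  }
  do.call(rbind, rows)
}
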