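# the screening and fitting steps are validated against independent
# full-vs-reduced-model F tests and closed-form OLS

test_that("screening keeps a real predictor and drops an independent one", {
  set.seed(42)
  n <- 200
  tab <- data.frame(A = rnorm(n), B = rnorm(n))
  tab$target <- 3 * tab$A + rnorm(n)
  scr <- screen_predictors(tab, "target", c("A", "B"))
  expect_true("A" %in% scr$kept)
  expect_false("B" %in% scr$kept)
  # oracle: full-vs-reduced F test for each candidate (type III partial)
  full <- lm(target ~ A + B, tab)
  for (cand in c("A", "B")) {
    reduced <- lm(reformulate(setdiff(c("A", "B"), cand), "target"), tab)
    p_oracle <- anova(reduced, full)$`Pr(>F)`[2]
    p_pkg <- scr$stage1$p[scr$stage1$candidate == cand]
    expect_equal(p_pkg, p_oracle, tolerance = 1e-8)
  }
})

test_that("a perfect predictor is kept with p ~ 0", {
  set.seed(1)
  tab <- data.frame(A = rnorm(50))
  tab$target <- tab$A
  scr <- screen_predictors(tab, "target", "A")
  expect_equal(scr$kept, "A")
  expect_lt(scr$stage2$p, 1e-12)
})

test_that("pure-noise candidates pass the two stages at the nominal rates", {
  set.seed(314)
  n_rep <- 150
  pass1 <- pass2 <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    tab <- data.frame(A = rnorm(200))
    tab$target <- rnorm(200)
    scr <- screen_predictors(tab, "target", "A")
    pass1[r] <- nrow(scr$stage1) > 0 && scr$stage1$keep[1]
    pass2[r] <- "A" %in% scr$kept
  }
  # binomial 3 SE bands around 15% and 5%
  expect_lt(abs(mean(pass1) - 0.15), 3 * sqrt(0.15 * 0.85 / n_rep))
  expect_lt(abs(mean(pass2) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("categorical screening uses type-III tests under sum contrasts", {
  set.seed(9)
  n <- 240
  g <- factor(sample(c("a", "b", "c"), n, TRUE))
  x <- rnorm(n)
  tab <- data.frame(g = as.character(g), x = x,
                    target = c(a = 0, b = 4, c = 8)[as.character(g)] +
                      0.5 * x + rnorm(n))
  scr <- screen_predictors(tab, "target", c("g", "x"))
  expect_setequal(scr$kept, c("g", "x"))
  # oracle: partial F for the factor from full-vs-reduced fits
  full <- lm(target ~ g + x, tab)
  red <- lm(target ~ x, tab)
  p_oracle <- anova(red, full)$`Pr(>F)`[2]
  expect_equal(scr$stage1$p[scr$stage1$candidate == "g"], p_oracle,
               tolerance = 1e-8)
})

test_that("noiseless linear data give a perfect fit", {
  tab <- data.frame(x = 1:20)
  tab$y <- 2 + 5 * tab$x
  # summary.lm warns about the essentially perfect fit; that is the point
  expect_warning(mod <- fit_imputation_model(tab, "y", "x"),
                 "perfect fit")
  expect_equal(mod$r2_adjusted, 1)
  expect_equal(mod$rmse, 0, tolerance = 1e-10)
})

test_that("OLS recovers slope and noise scale from noisy data", {
  set.seed(11)
  tab <- data.frame(x = runif(500, 0, 10))
  tab$y <- 2 * tab$x + rnorm(500)
  mod <- fit_imputation_model(tab, "y", "x")
  expect_lt(abs(unname(mod$coefficients["x"]) - 2), 0.1)
  expect_lt(abs(mod$rmse - 1), 0.1)
  # closed-form OLS oracle
  b_hat <- cov(tab$x, tab$y) / var(tab$x)
  expect_equal(unname(mod$coefficients["x"]), b_hat, tolerance = 1e-10)
})

test_that("the intercept-only model predicts the observed mean", {
  tab <- data.frame(y = c(1, 2, 3, 4, NA, NA))
  mod <- fit_imputation_model(tab, "y")
  expect_equal(unname(predict(mod$fit, newdata = data.frame(row = 1:2))),
               rep(2.5, 2))
})

test_that("a complete table passes through the chain unchanged", {
  sim <- simulate_cohort(ground_truth(n = 120), seed = 3)
  out <- impute_chain(sim$cohort)
  expect_identical(as.data.frame(out)[names(sim$cohort)],
                   as.data.frame(sim$cohort))
  expect_false(any(out$imputed_thi_post))
  rep <- attr(out, "imputation_report")
  expect_true(all(vapply(rep, function(e) isTRUE(e$skipped), logical(1))))
})

test_that("observed cells are never modified and flags mark filled cells", {
  sim <- simulate_cohort(ground_truth(n = 250), seed = 4)
  coh <- inject_mcar(sim$cohort, seed = 5)
  obs <- !is.na(coh$thi_post)
  out <- impute_chain(coh)
  expect_identical(out$thi_post[obs], coh$thi_post[obs])
  expect_identical(out$imputed_thi_post, !obs)
  expect_false(anyNA(out$thi_post))
  expect_false(anyNA(out$ghsi_baseline))
  expect_true(all(out$thi_post >= 0 & out$thi_post <= 100))
})

test_that("the chain is deterministic for identical inputs", {
  sim <- simulate_cohort(ground_truth(n = 200), seed = 6)
  coh <- inject_mcar(sim$cohort, seed = 7)
  out1 <- impute_chain(coh)
  out2 <- impute_chain(coh)
  expect_identical(as.data.frame(out1), as.data.frame(out2))
})

test_that("MCAR imputation recovers values at the generating noise level", {
  # known linear structure, 30% MCAR missingness
  set.seed(100)
  n <- 500; sigma <- 5
  reps <- 20
  rmse_ratio <- bias <- numeric(reps)
  for (r in seq_len(reps)) {
    A <- runif(n, 0, 10)
    y_full <- 20 + 3 * A + rnorm(n, 0, sigma)
    tab <- data.frame(A = A, target = y_full)
    miss <- runif(n) < 0.3
    tab$target[miss] <- NA
    scr <- screen_predictors(tab, "target", "A")
    mod <- fit_imputation_model(tab, "target", scr$kept)
    pred <- predict(mod$fit, newdata = tab[miss, , drop = FALSE])
    err <- pred - y_full[miss]
    rmse_ratio[r] <- sqrt(mean(err^2)) / sigma
    bias[r] <- mean(err)
  }
  # imputed-vs-realized RMSE within 15% of the generating sigma
  expect_lt(abs(mean(rmse_ratio) - 1), 0.15)
  # mean bias of imputed - truth within 2 SE of zero
  expect_lt(abs(mean(bias)), 2 * sd(bias) / sqrt(reps))
})

test_that("a fully missing target is refused and grand-mean fallback engages", {
  tab <- data.frame(
    thi_baseline = c(NA_real_, NA_real_, NA_real_),
    age = c(50, 60, 70))
  expect_error(
    impute_chain(tab, list(list(target = "thi_baseline",
                                candidates = "age"))),
    "fully missing")
  set.seed(12)
  tab2 <- data.frame(thi_baseline = c(rnorm(40, 50, 5), rep(NA_real_, 10)),
                     noise = rnorm(50))
  out <- suppressMessages(
    impute_chain(tab2, list(list(target = "thi_baseline",
                                 candidates = "noise"))))
  filled <- out$thi_baseline[41:50]
  if (length(attr(out, "imputation_report")$thi_baseline$screening$kept) == 0) {
    expect_equal(filled, rep(mean(tab2$thi_baseline[1:40]), 10))
  }
})
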