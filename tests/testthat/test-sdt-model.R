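test_that("logistic components keep both parameterizations in sync", {
  comp <- logistic_component(mu = 40, s = 20)
  expect_equal(comp$theta1, -2)
  expect_equal(comp$theta2, 0.05)
  back <- component_from_theta(-2, 0.05)
  expect_equal(back$mu, 40)
  expect_equal(back$s, 20)
  expect_error(logistic_component(0, -1), "must be > 0")
  expect_error(component_from_theta(1, 0), "theta2")
})

test_that("cdf and pdf take their textbook values at the mode", {
  std <- logistic_component(0, 1)
  expect_equal(sdt_cdf(std, 0), 0.5)
  expect_equal(sdt_pdf(std, 0), 0.25)  # logistic peak is 1/(4s)
  shifted <- logistic_component(37, 20)
  expect_equal(sdt_cdf(shifted, 37), 0.5)
  expect_equal(sdt_pdf(shifted, 37), 1 / 80)
  # overflow-safe far in the tails
  expect_true(is.finite(sdt_pdf(std, 1e6)))
  expect_equal(sdt_cdf(std, 1e6), 1)
})

test_that("confusion probabilities conserve tp+fn = fp+tn = 1", {
  set.seed(101)
  for (i in 1:1000) {
    m <- random_sdt_model()
    cc <- runif(1, m$x_min, m$x_max)
    conf <- confusion_at_criterion(m, cc)
    expect_lt(abs(conf$tp + conf$fn - 1), 1e-12)
    expect_lt(abs(conf$fp + conf$tn - 1), 1e-12)
    expect_true(all(unlist(conf[c("tp", "fp", "tn", "fn")]) >= 0))
  }
})

test_that("criterion limits and symmetry behave as expected", {
  m <- sdt_model(logistic_component(-1, 1), logistic_component(1, 1), -12, 12)
  lo <- confusion_at_criterion(m, -1e5)
  expect_equal(c(lo$tp, lo$fp, lo$tn, lo$fn), c(1, 1, 0, 0))
  mid <- confusion_at_criterion(m, 0)
  expect_equal(mid$tp, 1 - mid$fp)  # mirror symmetry at the midpoint
})

test_that("confusion probabilities match the quadrature oracle", {
  # expected areas computed by adaptive quadrature of the two densities
  # beyond c = 0.5 for (mu1, s1, mu2, s2) = (-1, 1, 1, 2)
  m <- sdt_model(logistic_component(-1, 1), logistic_component(1, 2), -10, 10)
  conf <- confusion_at_criterion(m, 0.5)
  expect_equal(conf$tp, 0.562176500886, tolerance = 1e-9)
  expect_equal(conf$fp, 0.182425523806, tolerance = 1e-9)
  expect_equal(conf$tn, 0.817574476194, tolerance = 1e-9)
  expect_equal(conf$fn, 0.437823499114, tolerance = 1e-9)
})

test_that("ROC curves are monotone and bounded ranges keep endpoints interior", {
  set.seed(7)
  for (i in 1:20) {
    m <- random_sdt_model()
    roc <- roc_curve(m, 128)
    expect_true(all(diff(roc$fp) >= 0))
    expect_true(all(diff(roc$tp) >= -1e-12))
  }
  # full-support range: endpoints reach the corners
  wide <- sdt_model(logistic_component(-1, 1), logistic_component(1, 1),
                    -1 - 24, 1 + 24)
  roc <- roc_curve(wide, 512)
  expect_lt(roc$fp[1] + roc$tp[1], 1e-5)
  expect_gt(roc$fp[nrow(roc)] + roc$tp[nrow(roc)], 2 - 1e-5)
  # degenerate equal components: chance diagonal
  flat <- sdt_model(logistic_component(0, 5), logistic_component(0, 5),
                    -20, 20)
  roc_flat <- roc_curve(flat, 256)
  expect_equal(roc_flat$tp, roc_flat$fp, tolerance = 1e-12)
})

test_that("AUC is 0.5 on the chance diagonal and nested across closure modes", {
  flat <- sdt_model(logistic_component(0, 5), logistic_component(0, 5),
                    -80, 80)
  expect_equal(roc_auc(roc_curve(flat, 1024), "closed"), 0.5,
               tolerance = 1e-4)
  # a partial curve always encloses less area than its closed completion
  set.seed(21)
  for (i in 1:10) {
    m <- random_sdt_model()
    roc <- m |> roc_curve(256)
    expect_lt(roc_auc(roc, "partial"), roc_auc(roc, "closed"))
  }
})

test_that("closed-mode AUC on full support matches Monte-Carlo P(X2 > X1)", {
  # equal variance, normalized mode distance 2mu/s = 2
  m <- sdt_model(logistic_component(-1, 1), logistic_component(1, 1),
                 -30, 30)
  auc <- roc_auc(roc_curve(m, 4096), "closed")
  set.seed(99)
  mc <- mean(rlogis(2e6, 1, 1) > rlogis(2e6, -1, 1))
  expect_equal(auc, mc, tolerance = 0.005)
})

test_that("logit-ROC line is analytic: slope s1/s2, intercept (mu2-mu1)/s2", {
  # equal variance example with accuracy index 2mu/s = 2
  m <- sdt_model(logistic_component(-1, 1), logistic_component(1, 1),
                 -12, 12)
  lr <- logit_roc(m)
  expect_equal(lr$slope, 1)
  expect_equal(lr$intercept, 2)
  expect_equal(lr$accuracy, 2)
  # pure scale ratio
  m2 <- sdt_model(logistic_component(0, 2), logistic_component(0, 1), -9, 9)
  lr2 <- logit_roc(m2)
  expect_equal(lr2$slope, 2)
  expect_equal(lr2$intercept, 0)
  # property: empirical least-squares line equals the analytic one
  set.seed(31)
  for (i in 1:50) {
    mm <- random_sdt_model()
    ll <- logit_roc(mm)
    expect_lt(abs(ll$empirical_slope - ll$slope), 1e-6)
    expect_lt(abs(ll$empirical_intercept - ll$intercept), 1e-6)
  }
})

test_that("likelihood ratio is the density quotient, evaluated safely", {
  ident <- sdt_model(logistic_component(3, 2), logistic_component(3, 2),
                     -10, 10)
  expect_equal(likelihood_ratio(ident, seq(-5, 5, 1)), rep(1, 11))
  sym <- sdt_model(logistic_component(-1, 1), logistic_component(1, 1),
                   -10, 10)
  expect_equal(likelihood_ratio(sym, 0), 1)
  # direct quotient at x = 3 for (mu1,s1,mu2,s2) = (-1,1,1,2), computed
  # from the explicit density formula
  m <- sdt_model(logistic_component(-1, 1), logistic_component(1, 2),
                 -10, 10)
  expect_equal(likelihood_ratio(m, 3), 5.565736384539, tolerance = 1e-10)
  expect_true(all(likelihood_ratio(m, c(-200, 200)) > 0))
})

test_that("unbiased criterion solves LR = 1 and reports the regime", {
  sym <- sdt_model(logistic_component(-1, 1), logistic_component(1, 1),
                   -5, 5)
  roots <- unbiased_criterion(sym)
  expect_length(roots, 1)
  expect_equal(as.numeric(roots), 0, tolerance = 1e-9)
  expect_equal(attr(roots, "regime"), "crossing")
  # LR > 1 over the whole range: always-strict flag, no roots
  strict <- sdt_model(logistic_component(-40, 30),
                      logistic_component(20, 10), 0, 45)
  r2 <- unbiased_criterion(strict)
  expect_length(r2, 0)
  expect_equal(attr(r2, "regime"), "always strict")
})

test_that("criterion solvers find every grid-scan root to high precision", {
  set.seed(77)
  for (i in 1:25) {
    m <- random_sdt_model()
    beta <- exp(runif(1, -1, 1))
    roots <- criterion_for_beta(m, beta)$criterion
    for (r in roots) {
      expect_lt(abs(likelihood_ratio(m, r) - beta), 1e-8)
    }
    # independent oracle: sign changes of LR - beta on a dense grid
    xs <- seq(m$x_min, m$x_max, length.out = 1e5)
    g <- likelihood_ratio(m, xs) - beta
    n_oracle <- sum(g[-1] * g[-length(g)] < 0) + sum(g == 0)
    expect_equal(length(roots), n_oracle)
  }
})

test_that("unequal scales produce two LR = 1 crossings when bracketed", {
  # s2 < s1: log LR is concave-like with an interior maximum above 1
  m <- sdt_model(logistic_component(0, 20), logistic_component(10, 5),
                 -80, 80)
  roots <- unbiased_criterion(m)
  expect_length(roots, 2)
  xs <- seq(m$x_min, m$x_max, length.out = 1e5)
  g <- likelihood_ratio(m, xs) - 1
  expect_equal(sum(g[-1] * g[-length(g)] < 0), 2)
})

test_that("LR extremum exists iff scales differ, with the right type", {
  eq <- sdt_model(logistic_component(-1, 2), logistic_component(3, 2),
                  -20, 20)
  expect_null(lr_extremum(eq))  # log LR linear for equal scales
  mx <- sdt_model(logistic_component(0, 20), logistic_component(10, 5),
                  -80, 80)
  ext <- lr_extremum(mx)
  expect_equal(ext$type, "maximum")
  xs <- seq(mx$x_min, mx$x_max, length.out = 1e4)
  expect_gte(ext$lr, max(likelihood_ratio(mx, xs)) - 1e-8)
  mn <- sdt_model(logistic_component(0, 5), logistic_component(10, 20),
                  -80, 80)
  expect_equal(lr_extremum(mn)$type, "minimum")
})

test_that("optimal beta follows the payoff equation and its invariances", {
  # equal base rates, all payoffs equal: unbiased
  expect_equal(optimal_beta(utility_context(0.5)), 1)
  # P(T-) = 0.25, P(T+) = 0.75, numerator sum 4, denominator sum 2
  ctx <- utility_context(0.75, b_pp = 1, c_pn = 1, b_nn = 3, c_np = 1)
  expect_equal(optimal_beta(ctx), (1 / 3) * 2)
  # scale invariance under a common rescaling of the utility unit
  ctx2 <- utility_context(0.75, b_pp = 2, c_pn = 2, b_nn = 6, c_np = 2)
  expect_equal(optimal_beta(ctx2), optimal_beta(ctx))
  expect_error(utility_context(0), "between 0 and 1")
})

test_that("criterion_for_beta matches the equal-variance closed form", {
  # beta = 1 reduces to the unbiased criterion
  m <- sdt_model(logistic_component(-1, 1), logistic_component(1, 1),
                 -6, 6)
  expect_equal(criterion_for_beta(m, 1)$criterion,
               as.numeric(unbiased_criterion(m)), tolerance = 1e-9)
  # equal scales s, modes -mu/+mu: with k = exp(2 mu / s) the likelihood
  # ratio is LR(x) = k ((1 + u) / (1 + u k))^2 for u = exp(-(x + mu)/s),
  # so LR = beta solves in closed form via t = sqrt(beta / k):
  # u = (t - 1) / (1 - t k) and x = -mu - s log(u)
  mu <- 3; s <- 2
  m2 <- sdt_model(logistic_component(-mu, s), logistic_component(mu, s),
                  -30, 30)
  closed_root <- function(beta) {
    k <- exp(2 * mu / s)
    t <- sqrt(beta / k)
    -mu - s * log((t - 1) / (1 - t * k))
  }
  sol <- criterion_for_beta(m2, exp(2))
  expect_equal(sol$criterion, closed_root(exp(2)), tolerance = 1e-9)
  # the root sits above the unbiased point, in the strict regime
  expect_equal(sol$class_below, "strict")
  expect_equal(sol$class_above, "strict")
  sol_len <- criterion_for_beta(m2, exp(-2))
  expect_equal(sol_len$criterion, closed_root(exp(-2)), tolerance = 1e-9)
  expect_equal(sol_len$class_below, "lenient")
  expect_equal(sol_len$class_above, "lenient")
  # beta = 1 root straddles the two regimes
  sol_1 <- criterion_for_beta(m2, 1)
  expect_equal(sol_1$class_below, "lenient")
  expect_equal(sol_1$class_above, "strict")
  # beta above the attainable maximum exp(2 mu / s): no solution
  expect_equal(nrow(criterion_for_beta(m2, 1e9)), 0L)
})

test_that("criteria of a reversed model map back to the original frame", {
  m <- sdt_model(logistic_component(-1, 1), logistic_component(1, 2),
                 -10, 10)
  offset <- 25
  m_rev <- sdt_model(
    logistic_component(offset - m$s1$mu, m$s1$s),
    logistic_component(offset - m$s2$mu, m$s2$s),
    offset - m$x_max, offset - m$x_min,
    orientation = "reversed", reversal_offset = offset)
  orig <- sort(as.numeric(unbiased_criterion(m)))
  mapped <- sort(criterion_to_original(m_rev,
                                       as.numeric(unbiased_criterion(m_rev))))
  expect_equal(mapped, orig, tolerance = 1e-9)
})
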