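#' Default prior and sampler configurations for population fits
#'
#' The prior is a vague, proper, independent pair of zero-centered normal
#' distributions on the logistic-regression intercept `theta1` and slope
#' `theta2`. The default scales (100 on the intercept, 10 on the slope)
#' are wide relative to any driver measured on a 0-130 unit scale, where
#' plausible slopes are of order 0.01-0.1 per unit; the posterior is then
#' dominated by the likelihood. Both scales are surfaced in every report
#' so sensitivity checks against alternative widths are one argument away.
#'
#' @param theta1_sd,theta2_sd Prior standard deviations.
#' @return Named list.
#' @export
default_prior <- function(theta1_sd = 100, theta2_sd = 10) {
  list(theta1_sd = theta1_sd, theta2_sd = theta2_sd)
}

#' @rdname default_prior
#' @param n_draws Retained posterior draws.
#' @param n_burn Burn-in iterations (adaptation happens only here).
#' @param target_accept Target acceptance rate for the adaptive scaling.
#' @export
default_sampler <- function(n_draws = 20000L, n_burn = 5000L,
                            target_accept = 0.3) {
  list(n_draws = as.integer(n_draws), n_burn = as.integer(n_burn),
       target_accept = target_accept)
}

## maximum-likelihood fit with separation detection
logistic_mle <- function(x, y) {
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  list(coef = unname(stats::coef(fit)), separated = sep_warn,
       converged = fit$converged)
}

log_posterior_theta <- function(theta, x, y, prior) {
  eta <- theta[1] + theta[2] * x
  lse <- ifelse(eta > 35, eta, log1p(exp(eta)))
  sum(y * eta - lse) -
    0.5 * (theta[1] / prior$theta1_sd)^2 -
    0.5 * (theta[2] / prior$theta2_sd)^2
}

#' Bayesian logistic regression for one outcome population
#'
#' Fits `y ~ Bernoulli(plogis(theta1 + theta2 * x))` for a single
#' population's yes/no decisions against a decision driver. The posterior
#' over `(theta1, theta2)` under the [default_prior()] is explored by
#' adaptive random-walk Metropolis (compiled; proposal shaped by the
#' curvature at the posterior mode). Reported are the posterior mode, the
#' maximum-likelihood estimates, central 95% credible intervals, and the
#' posterior probability that the slope is positive — the quantity the
#' driver-consistency test ([slope_test()]) thresholds. A deterministic
#' grid evaluation (`method = "grid"`) serves as a sampler-free
#' cross-check on the same posterior.
#'
#' @param x Numeric driver values (finite, not all equal).
#' @param y Binary responses (0/1), both classes present unless
#'   `allow_separation = TRUE`.
#' @param prior See [default_prior()].
#' @param sampler See [default_sampler()].
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   summaries.
#' @param method `"metropolis"` (default) or `"grid"`.
#' @param population Optional population tag (`"S1"`/`"S2"`) carried in
#'   the result.
#' @param allow_separation Proceed despite completely separated data (the
#'   prior then regularizes an otherwise degenerate likelihood).
#' @return A `posterior_fit`: point estimates (`theta1_hat`, `theta2_hat`
#'   at the posterior mode; `mle` pair), `bci_theta1`, `bci_theta2`,
#'   `p_slope_positive`, draws or grid, diagnostics, `prior`, `seed`.
#' @export
fit_population <- function(x, y, prior = default_prior(),
                           sampler = default_sampler(), seed = 1L,
                           method = c("metropolis", "grid"),
                           population = NA_character_,
                           allow_separation = FALSE) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), all(is.finite(x)))
  if (!all(y %in% c(0, 1))) stop("responses must be binary 0/1")
  if (length(unique(x)) < 2L) {
    stop("driver column is constant: the slope is unidentifiable")
  }
  if (length(unique(y)) < 2L && !allow_separation) {
    stop("only one response class observed; the likelihood is degenerate ",
         "(set allow_separation = TRUE to rely on the prior)")
  }
  mle <- logistic_mle(x, y)
  if (mle$separated && !allow_separation) {
    stop("complete or quasi-complete separation: the maximum-likelihood ",
         "slope diverges (set allow_separation = TRUE to rely on the prior)")
  }
  neg_lp <- function(theta) -log_posterior_theta(theta, x, y, prior)
  start <- if (mle$separated || !mle$converged) c(0, 0) else mle$coef
  opt <- stats::optim(start, neg_lp, method = "BFGS", hessian = TRUE)
  mode <- opt$par
  hess <- opt$hessian
  cov <- tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov)) || any(diag(cov) <= 0)) {
    cov <- diag(c(1, 1 / stats::sd(x)^2))
  }
  if (method == "grid") {
    res <- posterior_grid_summary(x, y, prior, mode, cov)
    out <- c(res, list(method = "grid", mle = mle$coef,
                       theta1_hat = mode[1], theta2_hat = mode[2],
                       prior = prior, seed = seed,
                       population = population, n = length(x)))
    class(out) <- "posterior_fit"
    return(out)
  }
  chol_prop <- t(chol(cov))
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  mcmc <- rw_metropolis_logistic(
    as.numeric(x), as.numeric(y), as.numeric(mode), chol_prop,
    prior$theta1_sd, prior$theta2_sd,
    sampler$n_draws, sampler$n_burn, sampler$target_accept)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  draws <- mcmc$draws
  out <- list(
    theta1_hat = mode[1], theta2_hat = mode[2], mle = mle$coef,
    bci_theta1 = unname(stats::quantile(draws[, 1], c(0.025, 0.975))),
    bci_theta2 = unname(stats::quantile(draws[, 2], c(0.025, 0.975))),
    p_slope_positive = mean(draws[, 2] > 0),
    draws = draws,
    diagnostics = list(accept_rate = mcmc$accept_rate,
                       proposal_scale = mcmc$scale,
                       separated = mle$separated),
    method = "metropolis", prior = prior, seed = seed,
    population = population, n = length(x))
  class(out) <- "posterior_fit"
  out
}

## deterministic posterior summary on a dense grid around the mode:
## marginal quantiles and P(theta2 > 0) by direct normalized summation
posterior_grid_summary <- function(x, y, prior, mode, cov, n_grid = 201L) {
  sd1 <- sqrt(cov[1, 1]); sd2 <- sqrt(cov[2, 2])
  g1 <- seq(mode[1] - 8 * sd1, mode[1] + 8 * sd1, length.out = n_grid)
  g2 <- seq(mode[2] - 8 * sd2, mode[2] + 8 * sd2, length.out = n_grid)
  lp <- matrix(NA_real_, n_grid, n_grid)
  s_y <- sum(y)
  for (j in seq_len(n_grid)) {
    t2x <- g2[j] * x
    for (i in seq_len(n_grid)) {
      e <- g1[i] + t2x
      lse <- ifelse(e > 35, e, log1p(exp(e)))
      lp[i, j] <- s_y * g1[i] + sum(y * t2x) - sum(lse) -
        0.5 * (g1[i] / prior$theta1_sd)^2 -
        0.5 * (g2[j] / prior$theta2_sd)^2
    }
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  m1 <- rowSums(w); m2 <- colSums(w)
  qfun <- function(grid, mass, probs) {
    cm <- cumsum(mass)
    vapply(probs, function(p) grid[which(cm >= p)[1]], numeric(1))
  }
  list(bci_theta1 = qfun(g1, m1, c(0.025, 0.975)),
       bci_theta2 = qfun(g2, m2, c(0.025, 0.975)),
       p_slope_positive = sum(m2[g2 > 0]),
       diagnostics = list(grid_size = n_grid))
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("posterior fit (%s)%s, n = %d\n", x$method,
              if (!is.na(x$population)) paste0(" for ", x$population) else "",
              x$n))
  cat(sprintf("  theta1: mode %.4g, 95%% BCI [%.4g, %.4g]\n",
              x$theta1_hat, x$bci_theta1[1], x$bci_theta1[2]))
  cat(sprintf("  theta2: mode %.4g, 95%% BCI [%.4g, %.4g]\n",
              x$theta2_hat, x$bci_theta2[1], x$bci_theta2[2]))
  cat(sprintf("  P(theta2 > 0) = %.4f\n", x$p_slope_positive))
  invisible(x)
}

#' Bayesian slope (driver-consistency) test
#'
#' For the data to be consistent with the driver assumption, the yes
#' probability must change with driver magnitude: the slope must be
#' distinguishable from zero. H0: `theta2 = 0` is rejected in favor of
#' H1: `theta2 > 0` when the posterior probability of a positive slope
#' reaches `1 - alpha`.
#'
#' @param fit A `posterior_fit`.
#' @param alpha Significance threshold (default 0.01).
#' @return `"driver_consistent"` or `"not_consistent"`.
#' @export
slope_test <- function(fit, alpha = 0.01) {
  stopifnot(inherits(fit, "posterior_fit"))
  if (fit$p_slope_positive >= 1 - alpha) "driver_consistent"
  else "not_consistent"
}

#' Orient a decision dataset so the pooled decision curve increases
#'
#' The SDT formulation needs the yes probability to increase with the
#' driver (positive slopes, proper densities). A quick pooled
#' maximum-likelihood logistic fit decides the direction; when the pooled
#' slope is negative, the driver is reflected about `offset`
#' (`x -> offset - x`, default the dataset's `x_max`) and the reflection
#' recorded so criteria can be mapped back.
#'
#' @param dataset A `decision_dataset`.
#' @param offset Reflection offset if a reversal is needed.
#' @return The dataset, possibly reversed (see [reverse_driver()]).
#' @export
orient_driver <- function(dataset, offset = NULL) {
  stopifnot(inherits(dataset, "decision_dataset"))
  mle <- logistic_mle(dataset$x, dataset$y)
  if (mle$coef[2] < 0) {
    reverse_driver(dataset, offset %||% attr(dataset, "x_max"))
  } else {
    dataset
  }
}

#' Reflect a decision dataset's driver about an offset
#'
#' The reflection `x -> offset - x` is an involution: applying it twice
#' (with the same offset) restores the original values and orientation
#' exactly.
#'
#' @param dataset A `decision_dataset`.
#' @param offset Reflection offset in driver units.
#' @return The reflected `decision_dataset` with updated `x_min`/`x_max`,
#'   toggled `orientation`, and `reversal_offset` set (or cleared).
#' @export
reverse_driver <- function(dataset, offset = NULL) {
  stopifnot(inherits(dataset, "decision_dataset"))
  was <- attr(dataset, "orientation")
  offset <- offset %||%
    (if (was == "reversed") attr(dataset, "reversal_offset")
     else attr(dataset, "x_max"))
  old_min <- attr(dataset, "x_min"); old_max <- attr(dataset, "x_max")
  dataset$x <- offset - dataset$x
  attr(dataset, "x_min") <- offset - old_max
  attr(dataset, "x_max") <- offset - old_min
  if (was == "reversed") {
    attr(dataset, "orientation") <- "as_is"
    attr(dataset, "reversal_offset") <- NA_real_
  } else {
    attr(dataset, "orientation") <- "reversed"
    attr(dataset, "reversal_offset") <- offset
  }
  dataset
}

#' Assemble an SDT model from two population fits
#'
#' Converts each population's regression coefficients into the logistic
#' distribution parameters (`mu = -theta1/theta2`, `s = 1/theta2`) and
#' couples them with the driver range. Both populations must pass the
#' slope test: when either slope is not distinguishable from zero the
#' data are not consistent with the variable being a decision driver, and
#' the model is refused unless explicitly marked exploratory.
#'
#' @param fit_s1,fit_s2 `posterior_fit` objects for S1 and S2.
#' @param x_min,x_max Driver range for criterion sweeps.
#' @param alpha Slope-test threshold.
#' @param estimate `"mode"` (posterior mode, default) or `"mle"`.
#' @param exploratory Build the model even if a slope test fails.
#' @param orientation,reversal_offset Orientation metadata carried from
#'   the dataset.
#' @return An `sdt_model` (with attribute `exploratory` when forced).
#' @export
build_sdt_model <- function(fit_s1, fit_s2, x_min, x_max, alpha = 0.01,
                            estimate = c("mode", "mle"),
                            exploratory = FALSE,
                            orientation = "as_is",
                            reversal_offset = NA_real_) {
  estimate <- match.arg(estimate)
  verdicts <- c(S1 = slope_test(fit_s1, alpha), S2 = slope_test(fit_s2, alpha))
  failing <- names(verdicts)[verdicts == "not_consistent"]
  if (length(failing) && !exploratory) {
    stop(paste(failing, collapse = " and "),
         " slope not distinguishable from zero (P(theta2 > 0) = ",
         paste(sprintf("%.3f", c(fit_s1$p_slope_positive,
                                 fit_s2$p_slope_positive)[
                                   match(failing, c("S1", "S2"))]),
               collapse = ", "),
         "): data not consistent with this variable being a decision driver")
  }
  pick <- function(fit) {
    if (estimate == "mode") c(fit$theta1_hat, fit$theta2_hat) else fit$mle
  }
  th1 <- pick(fit_s1); th2 <- pick(fit_s2)
  model <- sdt_model(component_from_theta(th1[1], th1[2]),
                     component_from_theta(th2[1], th2[2]),
                     x_min, x_max, orientation = orientation,
                     reversal_offset = reversal_offset)
  attr(model, "estimate") <- estimate
  attr(model, "exploratory") <- length(failing) > 0L
  attr(model, "slope_verdicts") <- verdicts
  model
}

#' Fit the full SDT model for one decision dataset
#'
#' Convenience wrapper running the per-decision pipeline: orient the
#' driver, split by outcome population, fit each population's Bayesian
#' logistic regression, and assemble the SDT model.
#'
#' @param dataset A `decision_dataset`.
#' @param prior,sampler,seed,method Passed to [fit_population()].
#' @param alpha,estimate,exploratory Passed to [build_sdt_model()].
#' @return List with `model` (`sdt_model` or `NULL` if refused),
#'   `fit_s1`, `fit_s2`, `dataset` (as oriented), and `verdicts`.
#' @export
fit_decision_model <- function(dataset, prior = default_prior(),
                               sampler = default_sampler(), seed = 1L,
                               method = "metropolis", alpha = 0.01,
                               estimate = "mode", exploratory = FALSE) {
  dataset <- orient_driver(dataset)
  fits <- lapply(c(S1 = "S1", S2 = "S2"), function(pop) {
    sub <- dataset[dataset$population == pop, , drop = FALSE]
    fit_population(sub$x, sub$y, prior = prior, sampler = sampler,
                   seed = seed + match(pop, c("S1", "S2")),
                   method = method, population = pop)
  })
  verdicts <- vapply(fits, slope_test, character(1), alpha = alpha)
  model <- tryCatch(
    build_sdt_model(fits$S1, fits$S2,
                    attr(dataset, "x_min"), attr(dataset, "x_max"),
                    alpha = alpha, estimate = estimate,
                    exploratory = exploratory,
                    orientation = attr(dataset, "orientation"),
                    reversal_offset = attr(dataset, "reversal_offset")),
    error = function(e) NULL)
  list(model = model, fit_s1 = fits$S1, fit_s2 = fits$S2,
       dataset = dataset, verdicts = verdicts)
}

#' Posterior summary table for export
#'
#' @param fits Named list of `posterior_fit` objects.
#' @return Data.frame with one row per (population, parameter).
#' @export
posterior_summary_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(
      population = rep(f$population %||% NA_character_, 2L),
      parameter = c("theta1", "theta2"),
      mode = c(f$theta1_hat, f$theta2_hat),
      mle = if (!is.null(f$mle)) f$mle else c(NA_real_, NA_real_),
      bci_lower = c(f$bci_theta1[1], f$bci_theta2[1]),
      bci_upper = c(f$bci_theta1[2], f$bci_theta2[2]),
      p_slope_positive = rep(f$p_slope_positive, 2L),
      seed = rep(f$seed %||% NA_integer_, 2L),
      prior_sd = c(f$prior$theta1_sd, f$prior$theta2_sd),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
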