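#' Logistic component of a signal detection model
#'
#' A single logistic distribution describing the internal decision statistic
#' of one outcome population. The location/scale pair `(mu, s)` is
#' interchangeable with the logistic-regression pair
#' `theta1 = -mu/s` (intercept) and `theta2 = 1/s` (slope); both views are
#' stored so fitted regression coefficients map directly onto distribution
#' parameters.
#'
#' @param mu Location (mode) in driver units.
#' @param s Scale in driver units; must be strictly positive.
#' @return An object of class `logistic_component` with elements `mu`, `s`,
#'   `theta1`, `theta2`.
#' @examples
#' comp <- logistic_component(mu = 40, s = 20)
#' comp$theta1  # -2
#' comp$theta2  # 0.05
#' @export
logistic_component <- function(mu, s) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(s), length(s) == 1L, is.finite(s))
  if (s <= 0) stop("scale parameter 's' must be > 0, got ", s)
  structure(
    list(mu = mu, s = s, theta1 = -mu / s, theta2 = 1 / s),
    class = "logistic_component"
  )
}

#' Build a logistic component from intercept/slope coefficients
#'
#' @param theta1 Intercept of the logistic regression (dimensionless).
#' @param theta2 Slope (per driver unit); must be strictly positive.
#' @return A `logistic_component` with `mu = -theta1/theta2`, `s = 1/theta2`.
#' @export
component_from_theta <- function(theta1, theta2) {
  if (theta2 <= 0) {
    stop("slope 'theta2' must be > 0 to define a proper distribution, got ",
         theta2)
  }
  logistic_component(mu = -theta1 / theta2, s = 1 / theta2)
}

#' @export
print.logistic_component <- function(x, ...) {
  cat(sprintf(
    "logistic component: mu = %.4g, s = %.4g (theta1 = %.4g, theta2 = %.4g)\n",
    x$mu, x$s, x$theta1, x$theta2))
  invisible(x)
}

#' Unequal-variance logistic signal detection model
#'
#' Couples two logistic components: `s1` for the population without a
#' clinically important improvement and `s2` for the population with one.
#' The driver range `[x_min, x_max]` bounds every downstream criterion
#' sweep, so ROC curves are in general partial (they do not reach the unit
#' square corners). Orientation metadata records whether the driver was
#' reversed (`x -> offset - x`) before fitting.
#'
#' @param s1,s2 `logistic_component` objects for the no-improvement (S1) and
#'   improvement (S2) populations.
#' @param x_min,x_max Driver bounds, `x_min < x_max`.
#' @param orientation `"as_is"` or `"reversed"`.
#' @param reversal_offset Offset used when `orientation = "reversed"`
#'   (original driver = offset - stored driver), otherwise `NA`.
#' @return Object of class `sdt_model`.
#' @export
sdt_model <- function(s1, s2, x_min, x_max,
                      orientation = c("as_is", "reversed"),
                      reversal_offset = NA_real_) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(s1, "logistic_component"),
            inherits(s2, "logistic_component"),
            is.numeric(x_min), is.numeric(x_max))
  if (!(x_min < x_max)) stop("x_min must be < x_max")
  if (orientation == "reversed" && !is.finite(reversal_offset)) {
    stop("reversed orientation requires a finite reversal_offset")
  }
  structure(
    list(s1 = s1, s2 = s2, x_min = x_min, x_max = x_max,
         orientation = orientation, reversal_offset = reversal_offset),
    class = "sdt_model"
  )
}

#' @export
print.sdt_model <- function(x, ...) {
  cat("unequal-variance logistic SDT model\n")
  cat(sprintf("  S1: mu = %.4g, s = %.4g\n", x$s1$mu, x$s1$s))
  cat(sprintf("  S2: mu = %.4g, s = %.4g\n", x$s2$mu, x$s2$s))
  cat(sprintf("  driver range: [%.4g, %.4g], orientation: %s\n",
              x$x_min, x$x_max, x$orientation))
  invisible(x)
}

#' Logistic CDF and PDF of a component
#'
#' Thin wrappers over [stats::plogis()] / [stats::dlogis()] carrying the
#' component's location and scale; numerically safe for all finite `x`.
#'
#' @param component A `logistic_component`.
#' @param x Numeric vector of driver values.
#' @return `sdt_cdf`: probabilities; `sdt_pdf`: densities per driver unit.
#' @export
sdt_cdf <- function(component, x) {
  stats::plogis(x, location = component$mu, scale = component$s)
}

#' @rdname sdt_cdf
#' @export
sdt_pdf <- function(component, x) {
  stats::dlogis(x, location = component$mu, scale = component$s)
}

#' Confusion probabilities at a decision criterion
#'
#' The yes-region lies above the criterion: sweeping `c` downward moves the
#' criterion from strict toward lenient. True/false positive rates are the
#' S2/S1 upper-tail probabilities beyond `c`; by construction
#' `tp + fn = 1` and `fp + tn = 1`.
#'
#' @param model An `sdt_model`.
#' @param c Criterion, in driver units (may be a vector).
#' @return A data.frame with columns `criterion`, `tp`, `fp`, `tn`, `fn`.
#' @examples
#' m <- sdt_model(logistic_component(-1, 1), logistic_component(1, 1), -5, 5)
#' confusion_at_criterion(m, 0)  # tp = 1 - fp by symmetry
#' @export
confusion_at_criterion <- function(model, c) {
  stopifnot(inherits(model, "sdt_model"), is.numeric(c), all(is.finite(c)))
  fn <- sdt_cdf(model$s2, c)
  tn <- sdt_cdf(model$s1, c)
  data.frame(criterion = c, tp = 1 - fn, fp = 1 - tn, tn = tn, fn = fn)
}

#' ROC curve of an SDT model over its driver range
#'
#' Evaluates the confusion probabilities on a uniform criterion grid over
#' `[x_min, x_max]` and orders points by increasing false-positive rate.
#' Because the driver range is bounded, the curve endpoints are interior to
#' the unit square (a partial ROC) unless the range spans essentially the
#' full support of both components.
#'
#' @param model An `sdt_model`.
#' @param n_grid Number of criterion grid points (>= 2).
#' @return Object of class `roc_curve`: a data.frame with columns
#'   `criterion`, `fp`, `tp` sorted by increasing `fp`.
#' @export
roc_curve <- function(model, n_grid = 512L) {
  stopifnot(inherits(model, "sdt_model"), n_grid >= 2)
  grid <- seq(model$x_max, model$x_min, length.out = n_grid)
  conf <- confusion_at_criterion(model, grid)
  out <- conf[order(conf$fp, conf$tp), c("criterion", "fp", "tp")]
  rownames(out) <- NULL
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under an ROC curve
#'
#' Trapezoidal integral of `tp` over `fp`. The default `"partial"` mode
#' integrates only the observed span of the curve — appropriate when the
#' driver is bounded, and the reason partial-curve AUCs can fall below the
#' 0.5 chance level even for better-than-chance models. `"closed"` appends
#' chords to (0,0) and (1,1) for comparison against full-support quantities
#' such as P(X2 > X1).
#'
#' @param roc A `roc_curve` (or data.frame with `fp`, `tp`).
#' @param mode `"partial"` (default) or `"closed"`.
#' @return AUC as a single number.
#' @export
roc_auc <- function(roc, mode = c("partial", "closed")) {
  mode <- match.arg(mode)
  stopifnot(nrow(roc) >= 2)
  fp <- roc$fp
  tp <- roc$tp
  if (mode == "closed") {
    fp <- c(0, fp, 1)
    tp <- c(0, tp, 1)
  }
  sum(diff(fp) * (utils::head(tp, -1) + utils::tail(tp, -1)) / 2)
}

#' Logit-ROC (linear zROC analogue) of a logistic SDT model
#'
#' In logit-logit coordinates the ROC of a logistic SDT model is exactly
#' linear: `logit(tp) = intercept + slope * logit(fp)` with
#' `slope = s1/s2` and `intercept = (mu2 - mu1)/s2`. For equal variances
#' the slope is 1 and the intercept reduces to the accuracy index `2*mu/s`
#' (the normalized mode separation). Alongside the analytic pair, an
#' empirical least-squares line through logit-transformed ROC grid points
#' is returned as a numerical cross-check; the two agree to near machine
#' precision.
#'
#' @param model An `sdt_model`.
#' @param n_grid Grid size for the empirical fit.
#' @return A list with `slope`, `intercept` (analytic),
#'   `empirical_slope`, `empirical_intercept`, and `accuracy` (the
#'   intercept, i.e. the accuracy index).
#' @export
logit_roc <- function(model, n_grid = 512L) {
  stopifnot(inherits(model, "sdt_model"))
  slope <- model$s1$s / model$s2$s
  intercept <- (model$s2$mu - model$s1$mu) / model$s2$s
  roc <- roc_curve(model, n_grid)
  # logits of probabilities within ~1e-8 of 0 or 1 carry double-precision
  # noise far above the identity tolerance; fit only well-conditioned points
  well <- function(p) p > 1e-8 & p < 1 - 1e-8
  keep <- well(roc$fp) & well(roc$tp)
  if (sum(keep) < 8L) {
    # criterion range sits in the far tails: evaluate on a criterion grid
    # spanning the central mass of both components instead
    span <- 12 * max(model$s1$s, model$s2$s)
    cg <- seq(min(model$s1$mu, model$s2$mu) - span,
              max(model$s1$mu, model$s2$mu) + span, length.out = n_grid)
    conf <- confusion_at_criterion(model, cg)
    roc <- conf[order(conf$fp), c("criterion", "fp", "tp")]
    keep <- well(roc$fp) & well(roc$tp)
  }
  lf <- stats::qlogis(roc$fp[keep])
  lt <- stats::qlogis(roc$tp[keep])
  fit <- stats::lm.fit(cbind(1, lf), lt)
  list(slope = slope, intercept = intercept,
       empirical_slope = unname(fit$coefficients[2L]),
       empirical_intercept = unname(fit$coefficients[1L]),
       accuracy = intercept)
}

## log density ratio log f2(x) - log f1(x); evaluated in log space so that
## extreme tail values do not overflow
log_lr <- function(model, x) {
  stats::dlogis(x, model$s2$mu, model$s2$s, log = TRUE) -
    stats::dlogis(x, model$s1$mu, model$s1$s, log = TRUE)
}

#' Likelihood ratio of the two populations at a driver value
#'
#' `LR(x) = f2(x) / f1(x)`, the ratio of the improvement-population density
#' to the no-improvement-population density. Values above 1 mark driver
#' magnitudes where a yes decision is more likely to be a true positive
#' than a false positive (a strict-criterion region); values below 1 mark
#' lenient-criterion regions.
#'
#' @param model An `sdt_model`.
#' @param x Numeric vector of driver values.
#' @return Strictly positive numeric vector.
#' @export
likelihood_ratio <- function(model, x) {
  stopifnot(inherits(model, "sdt_model"), all(is.finite(x)))
  exp(log_lr(model, x))
}

## roots of log LR(x) = log beta inside [x_min, x_max]:
## dense-grid sign-change bracketing + uniroot refinement
lr_roots <- function(model, beta, n_scan = 4096L, tol = 1e-12) {
  g <- function(x) log_lr(model, x) - log(beta)
  xs <- seq(model$x_min, model$x_max, length.out = n_scan)
  gs <- g(xs)
  roots <- numeric(0)
  exact <- which(gs == 0)
  roots <- c(roots, xs[exact])
  sign_change <- which(gs[-1] * gs[-n_scan] < 0)
  for (i in sign_change) {
    r <- stats::uniroot(g, lower = xs[i], upper = xs[i + 1L], tol = tol)
    roots <- c(roots, r$root)
  }
  sort(unique(roots))
}

#' Unbiased decision criterion(s): driver values where LR(x) = 1
#'
#' Finds all in-range roots of the likelihood ratio equation `LR(x) = 1`
#' by dense-grid sign-change bracketing followed by bisection refinement.
#' An empty result means the criterion never becomes unbiased within the
#' driver range; the attached `regime` attribute then reports whether the
#' criterion is `"always strict"` (LR > 1 everywhere) or
#' `"always lenient"` (LR < 1 everywhere).
#'
#' @param model An `sdt_model`.
#' @param n_scan Dense grid size for bracketing.
#' @return Numeric vector of roots (possibly empty) with attribute
#'   `regime`: `"crossing"`, `"always strict"` or `"always lenient"`.
#' @export
unbiased_criterion <- function(model, n_scan = 4096L) {
  roots <- lr_roots(model, 1, n_scan)
  if (length(roots) == 0L) {
    mid_lr <- log_lr(model, (model$x_min + model$x_max) / 2)
    regime <- if (mid_lr > 0) "always strict" else "always lenient"
  } else {
    regime <- "crossing"
  }
  attr(roots, "regime") <- regime
  roots
}

#' Interior extremum of the likelihood ratio
#'
#' Locates a stationary point of `log LR` inside the driver range by
#' bracketing a sign change of its derivative and bisecting. For equal
#' scales `log LR` is linear, so there is no interior extremum; when
#' `s2 < s1` the extremum is a maximum, when `s2 > s1` a minimum.
#'
#' @param model An `sdt_model`.
#' @param n_scan Dense grid size.
#' @return `NULL` if `log LR` is monotone on the range, else a list with
#'   `x` (driver value), `lr` (likelihood ratio there) and `type`
#'   (`"maximum"` or `"minimum"`).
#' @export
lr_extremum <- function(model, n_scan = 4096L) {
  dlog <- function(x) {
    z1 <- stats::plogis(x, model$s1$mu, model$s1$s)
    z2 <- stats::plogis(x, model$s2$mu, model$s2$s)
    (1 - 2 * z2) / model$s2$s - (1 - 2 * z1) / model$s1$s
  }
  xs <- seq(model$x_min, model$x_max, length.out = n_scan)
  ds <- dlog(xs)
  idx <- which(ds[-1] * ds[-n_scan] < 0)
  if (length(idx) == 0L) return(NULL)
  i <- idx[1L]
  r <- stats::uniroot(dlog, lower = xs[i], upper = xs[i + 1L], tol = 1e-12)
  x_star <- r$root
  type <- if (ds[i] > 0) "maximum" else "minimum"
  list(x = x_star, lr = likelihood_ratio(model, x_star), type = type)
}

#' Utility context: base rates and the payoff matrix of a yes/no decision
#'
#' Captures the prior probabilities of the two truth states (treatment
#' effective, `T+`, or not, `T-`) and the four payoff terms: benefits of
#' the two correct outcomes, `B(T+ & D+)` and `B(T- & D-)`, and costs of
#' the two errors, `C(T+ & D-)` and `C(T- & D+)`, all in a common
#' arbitrary utility unit.
#'
#' @param p_t_plus Base rate P(T+), in (0, 1); P(T-) is its complement.
#' @param b_pp Benefit of a correct yes, B(T+ & D+).
#' @param b_nn Benefit of a correct no, B(T- & D-).
#' @param c_pn Cost of a missed effective treatment, C(T+ & D-).
#' @param c_np Cost of an unnecessary yes, C(T- & D+).
#' @return Object of class `utility_context`.
#' @export
utility_context <- function(p_t_plus, b_pp = 1, b_nn = 1, c_pn = 1, c_np = 1) {
  if (!(p_t_plus > 0 && p_t_plus < 1)) {
    stop("p_t_plus must lie strictly between 0 and 1")
  }
  if (b_pp + c_pn <= 0) {
    stop("b_pp + c_pn must be > 0 (denominator of the optimal criterion)")
  }
  structure(
    list(p_t_plus = p_t_plus, p_t_minus = 1 - p_t_plus,
         b_pp = b_pp, b_nn = b_nn, c_pn = c_pn, c_np = c_np),
    class = "utility_context"
  )
}

#' Expected-value-optimal likelihood-ratio criterion
#'
#' The likelihood-ratio threshold that maximizes expected value:
#' `beta = [P(T-)/P(T+)] * [B(T-&D-) + C(T-&D+)] / [B(T+&D+) + C(T+&D-)]`.
#' With equal base rates and all payoffs equal, `beta = 1` (the unbiased
#' criterion); `beta` is invariant under a common rescaling of the
#' utility unit.
#'
#' @param context A `utility_context`.
#' @return The optimal likelihood-ratio threshold (dimensionless).
#' @export
optimal_beta <- function(context) {
  stopifnot(inherits(context, "utility_context"))
  denom <- context$b_pp + context$c_pn
  if (denom == 0) stop("zero denominator: b_pp + c_pn must be nonzero")
  (context$p_t_minus / context$p_t_plus) *
    (context$b_nn + context$c_np) / denom
}

#' Driver-unit criterion for a target likelihood ratio
#'
#' Maps a likelihood-ratio threshold `beta` back to driver units by solving
#' `LR(x) = beta` within the model's driver range. Each root is annotated
#' with the criterion class immediately below and above it: lenient where
#' LR < 1, strict where LR > 1.
#'
#' @param model An `sdt_model`.
#' @param beta Target likelihood ratio, > 0.
#' @param n_scan Dense grid size for bracketing.
#' @return A data.frame with columns `criterion`, `class_below`,
#'   `class_above` (zero rows if `LR(x) = beta` has no in-range solution).
#' @export
criterion_for_beta <- function(model, beta, n_scan = 4096L) {
  if (!(is.numeric(beta) && length(beta) == 1L && beta > 0)) {
    stop("beta must be a single positive number")
  }
  roots <- lr_roots(model, beta, n_scan)
  side_class <- function(x) {
    llr <- log_lr(model, x)
    ifelse(llr > 0, "strict", ifelse(llr < 0, "lenient", "unbiased"))
  }
  eps <- (model$x_max - model$x_min) * 1e-6
  data.frame(
    criterion = roots,
    class_below = if (length(roots)) side_class(pmax(roots - eps, model$x_min))
                  else character(0),
    class_above = if (length(roots)) side_class(pmin(roots + eps, model$x_max))
                  else character(0),
    stringsAsFactors = FALSE
  )
}

#' Map a criterion between reversed and original driver frames
#'
#' When a model was fitted on reversed driver values
#' (`x_stored = offset - x_original`), criteria found in the stored frame
#' translate back to original driver units as `offset - criterion`.
#'
#' @param model An `sdt_model`.
#' @param criterion Numeric vector of criteria in the model's own frame.
#' @return Criteria in original driver units (unchanged if the model
#'   orientation is `"as_is"`).
#' @export
criterion_to_original <- function(model, criterion) {
  if (model$orientation == "reversed") {
    model$reversal_offset - criterion
  } else {
    criterion
  }
}
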