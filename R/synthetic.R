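#' Ground-truth specification for a synthetic cohort
#'
#' Defines every data-generating assumption the pipeline is tested
#' against: the base rate of the improved (S2) population, per-decision
#' driver distributions with hard bounds, per-population logistic decision
#' curves in intercept/slope form, the membership-conditional distribution
#' of THI change around the MCID boundary, and per-column
#' missing-completely-at-random rates.
#'
#' Defaults emulate a tertiary tinnitus-care cohort: hearing loss spread
#' over [5, 115] dB HL; decisions about the device evaluation period
#' (SEDEP) driven by hearing loss with near-equal population scales;
#' counseling uptake (PCU) driven by baseline THI with distinctly unequal
#' scales (the improved population more concentrated), which produces an
#' interior likelihood-ratio maximum. Missingness defaults are the
#' complements of questionnaire response rates of 97% (baseline THI),
#' 63% (post-treatment THI) and 56% (GHSI).
#'
#' @param n Number of participants.
#' @param p_s2 Base rate of the improved population, in (0, 1).
#' @param mcid Minimal clinically important difference (THI points).
#' @param decisions Per-decision list: `driver`, `bounds`, `theta` (list
#'   `S1`/`S2` of `c(theta1, theta2)`).
#' @param outcome List: `s2_extra_mean` / `s1_extra_mean`, exponential
#'   means (THI points) of the improvement excess beyond the MCID (S2)
#'   and of the shortfall/deterioration above it (S1).
#' @param missing_rates Named per-column MCAR rates.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(
    n = 200L,
    p_s2 = 0.4,
    mcid = 7,
    decisions = list(
      SEDEP = list(driver = "hearing_loss", bounds = c(5, 115),
                   theta = list(S1 = c(-2.0, 0.05), S2 = c(-1.0, 0.05))),
      PCU = list(driver = "thi_baseline", bounds = c(0, 100),
                 theta = list(S1 = c(-1.8, 0.03), S2 = c(-1.8, 0.06)))
    ),
    outcome = list(s2_extra_mean = 15, s1_extra_mean = 12),
    missing_rates = c(thi_baseline = 0.03, thi_post = 0.37,
                      ghsi_baseline = 0.44)) {
  stopifnot(n >= 1, p_s2 > 0, p_s2 < 1, mcid > 0,
            all(missing_rates >= 0), all(missing_rates <= 1))
  if (mcid >= 100) stop("infeasible spec: mcid must leave room in the ",
                        "0-100 score range")
  for (dec in names(decisions)) {
    d <- decisions[[dec]]
    stopifnot(d$driver %in% c("hearing_loss", "thi_baseline"),
              length(d$bounds) == 2L, d$bounds[1] < d$bounds[2])
    for (pop in c("S1", "S2")) {
      if (length(d$theta[[pop]]) != 2L) {
        stop("decision ", dec, " needs theta pairs for both populations")
      }
    }
  }
  structure(list(n = as.integer(n), p_s2 = p_s2, mcid = mcid,
                 decisions = decisions, outcome = outcome,
                 missing_rates = missing_rates),
            class = "ground_truth")
}

## truncated normal / exponential samplers by inverse-CDF, so bounds are
## respected by construction rather than by rejection or clipping
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

rtrunc_exp <- function(n, mean, lo, hi) {
  rate <- 1 / mean
  p_lo <- stats::pexp(lo, rate)
  p_hi <- stats::pexp(hi, rate)
  stats::qexp(stats::runif(n, p_lo, p_hi), rate)
}

#' Simulate a cohort with known ground truth
#'
#' Per participant: draw S1/S2 membership, covariates, a baseline THI
#' (covariate-linked, truncated so an S2-compatible improvement remains
#' feasible), a THI change from the membership-conditional truncated
#' exponential on the appropriate side of the MCID boundary, hearing
#' loss, each decision from its population's logistic curve, and a GHSI
#' score. Scores stay in [0, 100] by construction of the truncation
#' bounds — never by post-hoc clipping that could flip a membership
#' label — so [label_outcome()] applied to the generated scores
#' reproduces the true membership for every row.
#'
#' @param truth A [ground_truth()] spec.
#' @param seed Integer seed.
#' @return List with `cohort` (a complete `cohort_table`, no missingness —
#'   apply [inject_mcar()] for that) and `truth_table` (per-participant
#'   membership and drivers for oracle checks).
#' @export
simulate_cohort <- function(truth = ground_truth(), seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(seed)
  n <- truth$n
  mcid <- truth$mcid

  population <- ifelse(stats::runif(n) < truth$p_s2, "S2", "S1")

  age <- round(rtrunc_norm(n, 55, 12, 18, 88))
  sex <- sample(c("male", "female", "missing"), n, replace = TRUE,
                prob = c(0.50, 0.48, 0.02))
  tinnitus_duration <- sample(c("<=2mo", "2-6mo", ">6mo"), n, replace = TRUE,
                              prob = c(0.10, 0.20, 0.70))
  non_hearing_problems <- sample(c("none", "family", "work", "personality"),
                                 n, replace = TRUE,
                                 prob = c(0.50, 0.20, 0.15, 0.15))
  tinnitus_type <- sample(c("tonal", "noise", "different", "missing"), n,
                          replace = TRUE, prob = c(0.30, 0.30, 0.35, 0.05))
  referring_specialty <- sample(c("GP", "ORL", "missing"), n, replace = TRUE,
                                prob = c(0.45, 0.50, 0.05))

  # baseline THI: linear covariate structure + noise, truncated so that an
  # S2 member can still improve by more than the MCID
  dur_eff <- c("<=2mo" = -5, "2-6mo" = 0, ">6mo" = 5)[tinnitus_duration]
  prob_eff <- c(none = -8, family = 2, work = 2,
                personality = 10)[non_hearing_problems]
  thi_mean <- 45 + dur_eff + prob_eff
  lo <- ifelse(population == "S2", mcid + 1, 0)
  thi_baseline <- rtrunc_norm(n, thi_mean, 18, lo, 100)

  # THI change: S2 improves by mcid + extra (extra > 0), S1 changes by
  # -mcid + extra (extra >= 0, deterioration allowed); the truncation
  # bounds keep post-treatment scores inside [0, 100]
  extra <- numeric(n)
  is_s2 <- population == "S2"
  if (any(is_s2)) {
    extra[is_s2] <- rtrunc_exp(sum(is_s2), truth$outcome$s2_extra_mean,
                               0, thi_baseline[is_s2] - mcid)
  }
  if (any(!is_s2)) {
    extra[!is_s2] <- rtrunc_exp(
      sum(!is_s2), truth$outcome$s1_extra_mean,
      pmax(0, mcid - thi_baseline[!is_s2]),
      100 - thi_baseline[!is_s2] + mcid)
  }
  change <- ifelse(is_s2, -mcid - extra, -mcid + extra)
  thi_post <- thi_baseline + change

  hl_bounds <- truth$decisions$SEDEP$bounds
  hearing_loss <- rtrunc_norm(n, 50, 30, hl_bounds[1], hl_bounds[2])

  drivers <- list(hearing_loss = hearing_loss, thi_baseline = thi_baseline)
  decide <- function(dec) {
    d <- truth$decisions[[dec]]
    x <- drivers[[d$driver]]
    th <- do.call(rbind, d$theta)[population, , drop = FALSE]
    p_yes <- stats::plogis(th[, 1] + th[, 2] * x)
    ifelse(stats::runif(n) < p_yes, "yes", "no")
  }
  decision_sedep <- decide("SEDEP")
  decision_pcu <- decide("PCU")
  decision_sedu <- ifelse(decision_sedep == "yes",
                          ifelse(stats::runif(n) < 0.65, "yes", "no"),
                          "not_applicable")

  ghsi_raw <- 55 - 0.25 * thi_baseline + stats::rnorm(n, 0, 10)
  ghsi_baseline <- pmin(pmax(ghsi_raw, 0), 100)

  cohort <- as_cohort_table(data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = age, sex = sex, hearing_loss = hearing_loss,
    thi_baseline = thi_baseline, thi_post = thi_post,
    ghsi_baseline = ghsi_baseline,
    decision_sedep = decision_sedep, decision_sedu = decision_sedu,
    decision_pcu = decision_pcu,
    tinnitus_duration = tinnitus_duration,
    non_hearing_problems = non_hearing_problems,
    tinnitus_type = tinnitus_type,
    referring_specialty = referring_specialty,
    stringsAsFactors = FALSE))

  truth_table <- data.frame(
    participant_id = cohort$participant_id,
    population = population,
    hearing_loss = hearing_loss,
    thi_baseline = thi_baseline,
    thi_change = change,
    stringsAsFactors = FALSE)
  attr(truth_table, "spec") <- truth
  attr(truth_table, "seed") <- seed

  list(cohort = cohort, truth_table = truth_table)
}

#' Inject missing-completely-at-random cells
#'
#' Each targeted cell is independently blanked with its column's rate;
#' missingness depends on nothing else, so it is MCAR by construction.
#'
#' @param table A `cohort_table` (or data.frame).
#' @param rates Named per-column rates in [0, 1].
#' @param seed Integer seed.
#' @return The table with cells set to `NA` and attribute
#'   `"mcar_counts"`: per-column number of blanked cells.
#' @export
inject_mcar <- function(table, rates = c(thi_baseline = 0.03,
                                         thi_post = 0.37,
                                         ghsi_baseline = 0.44),
                        seed = 1L) {
  stopifnot(all(rates >= 0), all(rates <= 1),
            all(names(rates) %in% names(table)))
  set.seed(seed)
  counts <- integer(0)
  for (col in names(rates)) {
    hit <- stats::runif(nrow(table)) < rates[[col]]
    table[[col]][hit] <- NA
    counts[col] <- sum(hit)
  }
  attr(table, "mcar_counts") <- counts
  table
}
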