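# Shared fixtures built in code: tiny cohorts, random SDT models.

toy_cohort_df <- function() {
  data.frame(
    participant_id = c("P1", "P2", "P3"),
    age = c(60, 45, 70),
    sex = c("male", "female", "male"),
    hearing_loss = c(35, 60, 20),
    thi_baseline = c(48, 20, 70),
    thi_post = c(30, NA, 66),
    ghsi_baseline = c(40, 55, NA),
    decision_sedep = c("yes", "no", "yes"),
    decision_sedu = c("yes", "not_applicable", "no"),
    decision_pcu = c("no", "yes", "yes"),
    tinnitus_duration = c(">6mo", "2-6mo", ">6mo"),
    non_hearing_problems = c("none", "work", "family"),
    tinnitus_type = c("tonal", "noise", "different"),
    referring_specialty = c("GP", "ORL", "GP"),
    stringsAsFactors = FALSE)
}

write_toy_csv <- function(df = toy_cohort_df(), path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  path
}

# cohort built from explicit 2x2 joint decision counts, with outcome
# scores chosen so every participant is S1 or S2 as requested
cohort_from_joint <- function(joint, population = "S1") {
  n <- sum(joint)
  sedep <- rep(c("yes", "yes", "no", "no"),
               joint[c("yy", "yn", "ny", "nn")])
  pcu <- rep(c("yes", "no", "yes", "no"),
             joint[c("yy", "yn", "ny", "nn")])
  pop <- rep(population, length.out = n)
  thi_baseline <- rep(50, n)
  thi_post <- ifelse(pop == "S2", 30, 50)
  as_cohort <- data.frame(
    participant_id = sprintf("J%03d", seq_len(n)),
    age = 50, sex = "male",
    hearing_loss = seq(10, 90, length.out = n),
    thi_baseline = thi_baseline, thi_post = thi_post,
    ghsi_baseline = 50,
    decision_sedep = sedep,
    decision_sedu = ifelse(sedep == "yes", "no", "not_applicable"),
    decision_pcu = pcu,
    tinnitus_duration = ">6mo", non_hearing_problems = "none",
    tinnitus_type = "tonal", referring_specialty = "GP",
    stringsAsFactors = FALSE)
  path <- write_toy_csv(as_cohort)
  read_cohort(path)
}

# random valid SDT model with well-separated but overlapping components
random_sdt_model <- function() {
  mu1 <- runif(1, -20, 20)
  mu2 <- mu1 + runif(1, -30, 30)
  s1 <- runif(1, 2, 25)
  s2 <- runif(1, 2, 25)
  lo <- min(mu1, mu2) - runif(1, 10, 60)
  hi <- max(mu1, mu2) + runif(1, 10, 60)
  sdt_model(logistic_component(mu1, s1), logistic_component(mu2, s2), lo, hi)
}

# binary decision data from a logistic curve
simulate_binary <- function(n, theta1, theta2, x_min = 0, x_max = 100) {
  x <- runif(n, x_min, x_max)
  y <- rbinom(n, 1, plogis(theta1 + theta2 * x))
  list(x = x, y = y)
}

fast_sampler <- function() default_sampler(n_draws = 4000L, n_burn = 1000L)
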