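# Default parameter tables for the synthetic-cohort generator. Slope
# coefficients are the published relative-risk ratios / OLS coefficients of
# the transition and care-utilisation regressions; intercepts are not
# published and are calibrated in closed form so that a reference covariate
# profile has plausible outcome probabilities (see the methods vignette).

# Predictors of the lagged transition model, in design order.
TRANS_TERMS <- c(
  "housing_problems", "state_mild", "state_moderate", "state_severe",
  "age", "female", "rented", "educ_mid", "educ_high", "income"
)

# Predictors of the care-mode and hours models.
CARE_TERMS <- c(
  "dep_mild", "dep_moderate", "dep_severe", "age", "female",
  "func_iadl_only", "func_adl_1_2", "func_adl_3plus"
)

# Relative-risk ratios of the lagged multinomial transition model
# (outcome severity at wave T+1 vs base "none"; predictors at wave T).
default_transition_rrr <- function() {
  m <- rbind(
    mild     = c(1.12, 3.73, 5.54, 4.58, 1.02, 1.36, 1.22, 0.94, 0.86, 0.99),
    moderate = c(1.24, 5.89, 29.96, 46.91, 1.03, 1.48, 1.70, 0.82, 0.70, 0.99),
    severe   = c(1.28, 6.24, 52.06, 267.68, 1.02, 1.85, 2.20, 0.96, 0.97, 0.99)
  )
  colnames(m) <- TRANS_TERMS
  m
}

# Standard errors of those RRRs (RRR scale), used to seed Monte Carlo draws
# when running from a published-style coefficient table.
default_transition_rrr_se <- function() {
  m <- rbind(
    mild     = c(0.02, 0.13, 0.36, 0.64, 0.002, 0.05, 0.07, 0.04, 0.04, 0.0001),
    moderate = c(0.03, 0.37, 2.35, 6.40, 0.003, 0.07, 0.11, 0.05, 0.05, 0.0001),
    severe   = c(0.05, 0.84, 7.11, 45.40, 0.004, 0.15, 0.21, 0.09, 0.10, 0.0002)
  )
  colnames(m) <- TRANS_TERMS
  m
}

# Care-mode multinomial RRRs (base outcome "no care") and the two OLS hours
# models fitted on care recipients.
default_care_rrr <- function() {
  m <- rbind(
    home_only   = c(1.80, 2.44, 2.43, 1.06, 1.78, 43.83, 13.89, 49.91),
    unpaid_only = c(1.56, 2.43, 2.43, 1.15, 2.11, 8.11, 4.81, 22.10),
    both        = c(1.86, 3.00, 2.76, 1.15, 2.27, 39.59, 18.11, 147.75)
  )
  colnames(m) <- CARE_TERMS
  m
}

default_care_rrr_se <- function() {
  m <- rbind(
    home_only   = c(0.11, 0.18, 0.25, 0.004, 0.09, 4.51, 0.77, 5.10),
    unpaid_only = c(0.18, 0.31, 0.43, 0.01, 0.20, 1.53, 0.50, 3.44),
    both        = c(0.23, 0.38, 0.47, 0.01, 0.19, 6.36, 1.98, 20.77)
  )
  colnames(m) <- CARE_TERMS
  m
}

default_hours_coef <- function() {
  m <- rbind(
    home   = c(1.51, -1.17, 0.40, 0.04, 0.20, 5.18, 4.69, 11.15),
    unpaid = c(3.18, 8.11, 6.97, 0.21, -4.99, 4.46, 7.94, 26.25)
  )
  colnames(m) <- CARE_TERMS
  m
}

default_hours_se <- function() {
  m <- rbind(
    home   = c(2.96, 2.85, 3.50, 0.12, 1.76, 4.02, 3.15, 3.18),
    unpaid = c(1.33, 1.45, 2.01, 0.06, 0.97, 1.54, 1.20, 1.44)
  )
  colnames(m) <- CARE_TERMS
  m
}

# P(functional category | depression state), held fixed over the projection.
# The association direction (worse symptoms -> worse function) is supported
# by the care regressions; the exact law is a generator choice.
default_functional_conditional <- function() {
  m <- rbind(
    none     = c(0.80, 0.08, 0.09, 0.03),
    mild     = c(0.68, 0.10, 0.15, 0.07),
    moderate = c(0.52, 0.13, 0.22, 0.13),
    severe   = c(0.38, 0.14, 0.26, 0.22)
  )
  colnames(m) <- FUNC_LEVELS
  m
}

# Closed-form intercept calibration for a multinomial logit: choose
# intercepts so that, at covariate profile x, the outcome distribution
# equals `target` (first element = base outcome).
calibrate_intercepts <- function(log_rrr, x, target) {
  check_prob_vector(target, "calibration target")
  stopifnot(nrow(log_rrr) == length(target) - 1L)
  vapply(seq_len(nrow(log_rrr)), function(j) {
    log(target[j + 1L] / target[1L]) - sum(log_rrr[j, ] * x)
  }, numeric(1))
}

# Mean covariate profile used to calibrate transition intercepts
# (wave-6-like marginals; origin state "none").
transition_calibration_profile <- function(marginals) {
  c(
    housing_problems = 0.42, state_mild = 0, state_moderate = 0,
    state_severe = 0, age = 67,
    female = unname(marginals$female_share),
    rented = unname(marginals$rented_share),
    educ_mid = unname(marginals$education_shares[2]),
    educ_high = unname(marginals$education_shares[3]),
    income = unname(marginals$income_mean)
  )
}

# Two-year transition matrix over living states implied by intercepts `a`
# and slope matrix `b` at mean profile `x` (state dummies toggled per row).
mean_profile_matrix <- function(a, b, x) {
  P <- matrix(0, 4, 4)
  for (s in 1:4) {
    xs <- x
    xs[c("state_mild", "state_moderate", "state_severe")] <-
      as.numeric(s == 2:4)
    eta <- a + drop(b %*% xs)
    e <- c(1, exp(eta - max(eta, 0)))
    e[1] <- exp(-max(eta, 0))
    P[s, ] <- e / sum(e)
  }
  P
}

stationary_distribution <- function(P) {
  A <- rbind(t(P) - diag(nrow(P)), rep(1, nrow(P)))
  drop(qr.solve(A, c(rep(0, nrow(P)), 1)))
}

default_transition_intercepts <- function(rrr, marginals,
                                          target = c(0.480, 0.319, 0.143, 0.058)) {
  # Choose intercepts so the mean-profile chain's stationary distribution
  # reproduces wave-6-like prevalence; deterministic Nelder-Mead solve from
  # a closed-form start.
  b <- log(rrr)
  x <- transition_calibration_profile(marginals)
  start <- calibrate_intercepts(b, x, c(0.60, 0.28, 0.09, 0.03))
  obj <- function(a) {
    pi_hat <- stationary_distribution(mean_profile_matrix(a, b, x))
    sum((pi_hat - target)^2)
  }
  sol <- stats::optim(start, obj, control = list(maxit = 2000,
                                                 reltol = 1e-14))
  sol$par
}

default_care_intercepts <- function(rrr,
                                    functional_conditional =
                                      default_functional_conditional(),
                                    state_weights = c(0.480, 0.319, 0.143, 0.058),
                                    female_share = 0.552,
                                    target = c(home_only = 0.018,
                                               unpaid_only = 0.180,
                                               both = 0.020)) {
  # Choose intercepts so the population-weighted 65+ mode shares are
  # survey-like: about 20% unpaid-care users and 3.8% home-care users.
  b <- log(rrr)
  mix <- expand.grid(state = 1:4, func = 1:4, band = seq_along(BAND_MIDPOINTS),
                     female = 0:1)
  band_w <- exp(-0.045 * 5 * (seq_along(BAND_MIDPOINTS) - 1)) # older bands smaller
  band_w <- band_w / sum(band_w)
  w <- state_weights[mix$state] *
    functional_conditional[cbind(mix$state, mix$func)] *
    band_w[mix$band] *
    ifelse(mix$female == 1, female_share, 1 - female_share)
  X <- cbind(
    dep_mild = as.numeric(mix$state == 2),
    dep_moderate = as.numeric(mix$state == 3),
    dep_severe = as.numeric(mix$state == 4),
    age = unname(BAND_MIDPOINTS[mix$band]),
    female = mix$female,
    func_iadl_only = as.numeric(mix$func == 2),
    func_adl_1_2 = as.numeric(mix$func == 3),
    func_adl_3plus = as.numeric(mix$func == 4)
  )
  eta_slope <- X %*% t(b)
  obj <- function(a) {
    eta <- sweep(eta_slope, 2, a, "+")
    p <- softmax_rows(eta)
    agg <- colSums(p[, 2:4, drop = FALSE] * w)
    sum((agg - target)^2)
  }
  start <- log(target / (1 - sum(target))) -
    drop(b %*% c(0, 0, 0, 75, female_share, 0, 0, 0))
  sol <- stats::optim(start, obj, control = list(maxit = 2000,
                                                 reltol = 1e-14))
  setNames(sol$par, rownames(rrr))
}

default_hours_intercepts <- function(coefs) {
  # Reference weekly hours at (age 65, male, no symptoms, no difficulty):
  # 8 h home care, 10 h unpaid care.
  c(home = 8 - coefs["home", "age"] * 65,
    unpaid = 10 - coefs["unpaid", "age"] * 65)
}

#' Configuration of the synthetic cohort generator
#'
#' Collects every parameter of the synthetic panel, population, mortality and
#' unit-cost generators. Defaults reproduce the wave-6-like marginals and the
#' published regression structure the projection models assume: housing
#' problems 0/1/2/3+ with mass 0.717/0.182/0.063/0.038, baseline depression
#' states 0.480/0.319/0.143/0.058, and transition/care coefficient matrices
#' equal to the published relative-risk ratios (intercepts calibrated, see
#' the methods vignette).
#'
#' @param n_individuals number of panel members (positive).
#' @param n_waves number of biennial waves (at least 2).
#' @param seed integer seed; identical config + seed gives identical output.
#' @param transition_coefficients 3 x 11 matrix of log-RRR coefficients
#'   (rows mild/moderate/severe, columns intercept + `TRANS_TERMS`).
#' @param care_coefficients list with elements `mode` (3 x 9 log-RRR matrix),
#'   `hours` (2 x 9 coefficient matrix) and `hours_sd` (residual SD).
#' @param housing_distribution probability mass on 0/1/2/3+ housing problems.
#' @param baseline_prevalence probability mass on the four living states.
#' @param functional_conditional 4 x 4 matrix, rows = depression state,
#'   columns = functional category, rows summing to 1.
#' @param attrition_rate per-wave missing-at-random dropout probability.
#' @param mortality list of Gompertz parameters `a`, `b` per gender:
#'   annual death probability `min(1, a * exp(b * age))`.
#' @param covariate_marginals list: `female_share`, `rented_share`,
#'   `education_shares` (3 shares), `income_meanlog`, `income_sdlog`,
#'   `income_mean` (calibration only), `age_mean`, `age_sd`.
#' @param population_scale per-gender population count at the youngest
#'   modelled age for [generate_population_table()].
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_individuals = 10000,
                             n_waves = 4,
                             seed = 1L,
                             transition_coefficients = NULL,
                             care_coefficients = NULL,
                             housing_distribution = c(0.717, 0.182, 0.063, 0.038),
                             baseline_prevalence = c(0.480, 0.319, 0.143, 0.058),
                             functional_conditional = default_functional_conditional(),
                             attrition_rate = 0.12,
                             mortality = list(
                               male = c(a = 1.74e-5, b = 0.099),
                               female = c(a = 6.6e-6, b = 0.107)
                             ),
                             covariate_marginals = list(
                               female_share = 0.552,
                               rented_share = 0.160,
                               education_shares = c(0.378, 0.309, 0.313),
                               income_meanlog = log(392) - 0.5 * 0.5^2,
                               income_sdlog = 0.5,
                               income_mean = 392,
                               age_mean = 67,
                               age_sd = 9
                             ),
                             population_scale = 370000) {
  if (n_individuals < 1) stop_depcare("n_individuals must be positive")
  if (n_waves < 2) stop_depcare("n_waves must be at least 2")
  if (attrition_rate < 0 || attrition_rate >= 1) {
    stop_depcare("attrition_rate must lie in [0, 1)")
  }
  check_prob_vector(housing_distribution, "housing_distribution")
  check_prob_vector(baseline_prevalence, "baseline_prevalence")
  check_prob_vector(covariate_marginals$education_shares, "education_shares")
  if (covariate_marginals$female_share < 0 || covariate_marginals$female_share > 1) {
    stop_depcare("female_share must lie in [0, 1]")
  }
  for (g in GENDERS) {
    if (any(mortality[[g]] < 0)) stop_depcare("Gompertz parameters must be nonnegative")
  }
  stopifnot(is.matrix(functional_conditional),
            all(dim(functional_conditional) == c(4, 4)))
  for (i in 1:4) check_prob_vector(functional_conditional[i, ],
                                   "functional_conditional row")

  if (is.null(transition_coefficients)) {
    rrr <- default_transition_rrr()
    transition_coefficients <- cbind(
      `(Intercept)` = default_transition_intercepts(rrr, covariate_marginals),
      log(rrr)
    )
  }
  stopifnot(all(dim(transition_coefficients) == c(3, length(TRANS_TERMS) + 1L)))

  if (is.null(care_coefficients)) {
    crrr <- default_care_rrr()
    hc <- default_hours_coef()
    care_coefficients <- list(
      mode = cbind(`(Intercept)` = default_care_intercepts(crrr), log(crrr)),
      hours = cbind(`(Intercept)` = default_hours_intercepts(hc), hc),
      hours_sd = 3
    )
  }
  stopifnot(all(dim(care_coefficients$mode) == c(3, length(CARE_TERMS) + 1L)),
            all(dim(care_coefficients$hours) == c(2, length(CARE_TERMS) + 1L)),
            care_coefficients$hours_sd >= 0)

  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_waves = as.integer(n_waves),
      seed = as.integer(seed),
      transition_coefficients = transition_coefficients,
      care_coefficients = care_coefficients,
      housing_distribution = housing_distribution,
      baseline_prevalence = setNames(baseline_prevalence, DEP_STATES),
      functional_conditional = functional_conditional,
      attrition_rate = attrition_rate,
      mortality = mortality,
      covariate_marginals = covariate_marginals,
      population_scale = population_scale
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator config\n")
  cat("  individuals:", x$n_individuals, " waves:", x$n_waves,
      " seed:", x$seed, "\n")
  cat("  baseline prevalence:",
      paste(sprintf("%s %.3f", DEP_STATES, x$baseline_prevalence),
            collapse = ", "), "\n")
  cat("  housing problems 0/1/2/3+:",
      paste(sprintf("%.3f", x$housing_distribution), collapse = "/"), "\n")
  invisible(x)
}
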