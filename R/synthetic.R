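# Synthetic cohort generator: seeded panel, population, mortality and
# unit-cost inputs with the statistical structure the projection models
# assume. All randomness flows from the config seed via withr::local_seed,
# so identical config + seed gives byte-identical output.

softmax_rows <- function(eta) {
  # eta: n x k linear predictors for the non-base outcomes; returns n x (k+1)
  # probabilities with the base outcome in column 1.
  m <- pmax(apply(eta, 1, max), 0)
  e <- cbind(exp(-m), exp(eta - m))
  e / rowSums(e)
}

sample_categories <- function(prob, labels) {
  # One draw per row of a row-stochastic matrix.
  cum <- t(apply(prob, 1, cumsum))
  u <- runif(nrow(prob))
  labels[rowSums(u > cum) + 1L]
}

# Vectorised within-row ranks of an n x k matrix of uniforms; used to pick
# which CES-D items are endorsed given a target score.
row_ranks <- function(u) {
  ord <- order(row(u), u)
  rk <- integer(length(u))
  rk[ord] <- rep(seq_len(ncol(u)), nrow(u))
  matrix(rk, nrow(u), ncol(u))
}

# CES-D items consistent with a vector of scores: score = number of
# endorsed negative items + number of non-endorsed positive items.
items_from_scores <- function(score, polarity = default_cesd_polarity()) {
  n <- length(score)
  rk <- row_ranks(matrix(runif(n * 8L), n, 8L))
  contributes <- rk <= score
  items <- matrix(0, n, 8L)
  neg <- polarity == "negative"
  items[, neg] <- contributes[, neg] * 1
  items[, !neg] <- (!contributes[, !neg]) * 1
  colnames(items) <- paste0("cesd_", 1:8)
  items
}

# Draw a CES-D score inside the band of each state.
score_from_state <- function(state) {
  n <- length(state)
  score <- integer(n)
  score[state == "none"] <- 0L
  idx <- state == "mild"
  score[idx] <- sample(1:2, sum(idx), replace = TRUE)
  idx <- state == "moderate"
  score[idx] <- sample(3:5, sum(idx), replace = TRUE)
  idx <- state == "severe"
  score[idx] <- sample(6:8, sum(idx), replace = TRUE)
  score
}

# Functional category conditional on depression state, plus ADL/IADL counts
# consistent with the category.
draw_functional <- function(state, conditional) {
  n <- length(state)
  func <- character(n)
  for (s in DEP_STATES) {
    idx <- which(state == s)
    if (length(idx)) {
      func[idx] <- sample(FUNC_LEVELS, length(idx), replace = TRUE,
                          prob = conditional[s, ])
    }
  }
  adl <- integer(n)
  iadl <- integer(n)
  idx <- func == "iadl_only"
  iadl[idx] <- 1L + rpois(sum(idx), 0.8)
  idx <- func == "adl_1_2"
  adl[idx] <- sample(1:2, sum(idx), replace = TRUE)
  iadl[idx] <- rpois(sum(idx), 0.7)
  idx <- func == "adl_3plus"
  adl[idx] <- pmin(3L + rpois(sum(idx), 1.0), 6L)
  iadl[idx] <- rpois(sum(idx), 1.5)
  list(functional = func, adl = adl, iadl = iadl)
}

care_design <- function(state, age, female, functional) {
  cbind(
    dep_mild = as.numeric(state == "mild"),
    dep_moderate = as.numeric(state == "moderate"),
    dep_severe = as.numeric(state == "severe"),
    age = age,
    female = female,
    func_iadl_only = as.numeric(functional == "iadl_only"),
    func_adl_1_2 = as.numeric(functional == "adl_1_2"),
    func_adl_3plus = as.numeric(functional == "adl_3plus")
  )
}

# Care mode and weekly hours given covariates; care is only generated for
# ages 65+, matching the domain of the care-utilisation models.
draw_care <- function(state, age, female, functional, care_coefficients) {
  n <- length(state)
  mode <- rep("none", n)
  eligible <- which(age >= 65)
  if (length(eligible)) {
    X <- cbind(1, care_design(state[eligible], age[eligible],
                              female[eligible], functional[eligible]))
    prob <- softmax_rows(X %*% t(care_coefficients$mode))
    mode[eligible] <- sample_categories(prob, CARE_MODES)
  }
  unpaid <- mode %in% c("unpaid_only", "both")
  home <- mode %in% c("home_only", "both")
  unpaid_hours <- numeric(n)
  home_hours <- numeric(n)
  Xall <- cbind(1, care_design(state, age, female, functional))
  mu <- Xall %*% t(care_coefficients$hours)
  sd <- care_coefficients$hours_sd
  if (any(unpaid)) {
    unpaid_hours[unpaid] <- pmax(mu[unpaid, "unpaid"] +
                                   rnorm(sum(unpaid), 0, sd), 0.1)
  }
  if (any(home)) {
    home_hours[home] <- pmax(mu[home, "home"] + rnorm(sum(home), 0, sd), 0.1)
  }
  list(unpaid = unpaid, home = home,
       unpaid_hours = unpaid_hours, home_hours = home_hours)
}

trans_design <- function(state, age, female, rented, educ_mid, educ_high,
                         income, housing) {
  cbind(
    housing_problems = housing,
    state_mild = as.numeric(state == "mild"),
    state_moderate = as.numeric(state == "moderate"),
    state_severe = as.numeric(state == "severe"),
    age = age,
    female = female,
    rented = rented,
    educ_mid = educ_mid,
    educ_high = educ_high,
    income = income
  )
}

gompertz_q <- function(age, pars) {
  pmin(1, pars[["a"]] * exp(pars[["b"]] * age))
}

# Two-year death probability spanning ages (age, age + 1).
two_year_death_prob <- function(age, gender, mortality) {
  q <- numeric(length(age))
  for (g in GENDERS) {
    idx <- gender == g
    q[idx] <- 1 - (1 - gompertz_q(age[idx], mortality[[g]])) *
      (1 - gompertz_q(age[idx] + 1, mortality[[g]]))
  }
  q
}

#' Generate a synthetic longitudinal panel
#'
#' Draws a biennial panel of older people with the covariate marginals,
#' baseline depression-state distribution and housing-problem distribution of
#' the config, then evolves depression states wave to wave through the
#' multinomial-logit data-generating process defined by
#' `config$transition_coefficients` (applied to wave-T covariates), applies
#' Gompertz mortality and missing-at-random attrition between waves, and
#' draws care receipt and weekly hours for members aged 65+ from
#' `config$care_coefficients`. Housing problems are drawn once per person and
#' held fixed across waves.
#'
#' @param config a [generator_config()].
#' @return tibble with one row per surviving, retained person-wave:
#'   `person_id`, `wave`, `age`, `gender`, `tenure`, `education`, `income`,
#'   `housing_problems`, `cesd_1`...`cesd_8`, `adl_count`, `iadl_count`,
#'   `unpaid_care`, `home_care`, `unpaid_hours_week`, `home_hours_week`,
#'   `alive`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::local_seed(config$seed)
  n <- config$n_individuals
  cm <- config$covariate_marginals

  gender <- ifelse(runif(n) < cm$female_share, "female", "male")
  tenure <- ifelse(runif(n) < cm$rented_share, "rented", "owner")
  education <- sample(EDU_LEVELS, n, replace = TRUE,
                      prob = cm$education_shares)
  income <- rlnorm(n, cm$income_meanlog, cm$income_sdlog)
  ages0 <- 50:94
  age1 <- sample(ages0, n, replace = TRUE,
                 prob = dnorm(ages0, cm$age_mean, cm$age_sd))

  band <- sample(0:3, n, replace = TRUE, prob = config$housing_distribution)
  housing <- band
  idx3 <- band == 3L
  # expand the open 3+ band onto 3..12 with a truncated geometric tail
  housing[idx3] <- pmin(3L + rgeom(sum(idx3), 0.6), 12L)

  female <- as.numeric(gender == "female")
  rented <- as.numeric(tenure == "rented")
  educ_mid <- as.numeric(education == "nvq_gce_cse")
  educ_high <- as.numeric(education == "degree_or_below")

  state <- sample(DEP_STATES, n, replace = TRUE,
                  prob = config$baseline_prevalence)
  active <- rep(TRUE, n)
  waves <- vector("list", config$n_waves)

  for (w in seq_len(config$n_waves)) {
    age_w <- age1 + 2L * (w - 1L)
    if (w > 1L) {
      prev_age <- age_w - 2L
      idx <- which(active)
      # mortality over the two-year gap, then attrition, then transitions
      q2 <- two_year_death_prob(prev_age[idx], gender[idx], config$mortality)
      died <- runif(length(idx)) < q2
      active[idx[died]] <- FALSE
      idx <- which(active)
      dropped <- runif(length(idx)) < config$attrition_rate
      active[idx[dropped]] <- FALSE
      idx <- which(active)
      if (!length(idx)) break
      X <- cbind(1, trans_design(state[idx], prev_age[idx], female[idx],
                                 rented[idx], educ_mid[idx], educ_high[idx],
                                 income[idx], housing[idx]))
      prob <- softmax_rows(X %*% t(config$transition_coefficients))
      state[idx] <- sample_categories(prob, DEP_STATES)
    }
    idx <- which(active)
    score <- score_from_state(state[idx])
    items <- items_from_scores(score)
    fn <- draw_functional(state[idx], config$functional_conditional)
    care <- draw_care(state[idx], age_w[idx], female[idx], fn$functional,
                      config$care_coefficients)
    waves[[w]] <- tibble::tibble(
      person_id = idx,
      wave = w,
      age = age_w[idx],
      gender = gender[idx],
      tenure = tenure[idx],
      education = education[idx],
      income = income[idx],
      housing_problems = housing[idx],
      tibble::as_tibble(items),
      adl_count = fn$adl,
      iadl_count = fn$iadl,
      unpaid_care = care$unpaid,
      home_care = care$home,
      unpaid_hours_week = care$unpaid_hours,
      home_hours_week = care$home_hours,
      alive = TRUE
    )
  }
  dplyr::arrange(dplyr::bind_rows(waves), .data$person_id, .data$wave)
}

#' Generate a synthetic 65+ cross-section for the care models
#'
#' Convenience generator for testing the care-utilisation fits at full sample
#' size: draws age, gender, depression state and functional category
#' marginally, then care mode and hours from `config$care_coefficients`.
#'
#' @param config a [generator_config()].
#' @param n number of people (default `config$n_individuals`).
#' @param seed seed (default `config$seed`).
#' @return analysis-ready tibble (one row per person) with the columns used
#'   by [fit_care_mode_model()] and [fit_hours_models()].
#' @export
generate_care_cross_section <- function(config, n = config$n_individuals,
                                        seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  withr::local_seed(seed)
  ages <- 65:95
  age <- sample(ages, n, replace = TRUE, prob = dnorm(ages, 75, 8))
  gender <- ifelse(runif(n) < config$covariate_marginals$female_share,
                   "female", "male")
  state <- sample(DEP_STATES, n, replace = TRUE,
                  prob = config$baseline_prevalence)
  fn <- draw_functional(state, config$functional_conditional)
  female <- as.numeric(gender == "female")
  care <- draw_care(state, age, female, fn$functional,
                    config$care_coefficients)
  tibble::tibble(
    person_id = seq_len(n), age = age, gender = gender, female = female,
    state = state, functional = fn$functional,
    adl_count = fn$adl, iadl_count = fn$iadl,
    unpaid_care = care$unpaid, home_care = care$home,
    unpaid_hours_week = care$unpaid_hours,
    home_hours_week = care$home_hours,
    care_mode = derive_care_mode(care$unpaid, care$home)
  )
}

#' Generate a base-year population table
#'
#' Counts by single year of age (45 to an open 100+ group) and gender. The
#' default profile is flat to age 60 and declines exponentially afterwards,
#' scaled so the 65+ total is of the order of a national older population;
#' a small seeded lognormal jitter makes regeneration checks meaningful.
#'
#' @param config a [generator_config()]; `config$population_scale` sets the
#'   per-gender count at the youngest ages (0 gives an all-zero table).
#' @param flat_count if non-`NULL`, every age-gender cell gets exactly this
#'   count (must be nonnegative) and no jitter is applied.
#' @return tibble `age`, `gender`, `count`.
#' @export
generate_population_table <- function(config, flat_count = NULL) {
  stopifnot(inherits(config, "generator_config"))
  grid <- expand.grid(age = MODEL_AGES, gender = GENDERS,
                      stringsAsFactors = FALSE)
  if (!is.null(flat_count)) {
    if (flat_count < 0) stop_depcare("population counts must be nonnegative")
    grid$count <- flat_count
    return(tibble::as_tibble(grid))
  }
  withr::local_seed(config$seed)
  shape <- pmin(1, exp(-0.045 * (grid$age - 60)))
  jitter <- exp(rnorm(nrow(grid), 0, 0.02))
  grid$count <- round(config$population_scale * shape * jitter)
  tibble::as_tibble(grid)
}

#' Generate an age-gender annual mortality schedule
#'
#' Annual death probabilities `min(1, a * exp(b * age))` from the config's
#' Gompertz parameters; nondecreasing in age within gender and clipped at 1.
#'
#' @param config a [generator_config()].
#' @return tibble `age`, `gender`, `q`.
#' @export
generate_mortality_schedule <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  grid <- expand.grid(age = MODEL_AGES, gender = GENDERS,
                      stringsAsFactors = FALSE)
  grid$q <- NA_real_
  for (g in GENDERS) {
    idx <- grid$gender == g
    grid$q[idx] <- gompertz_q(grid$age[idx], config$mortality[[g]])
  }
  tibble::as_tibble(grid)
}

#' Generate a per-year unit-cost path
#'
#' Starts from a base-year hourly cost, compounds a real growth rate year on
#' year, and applies a one-off uplift factor at 2024 (the planned
#' living-wage rise).
#'
#' @param base_cost hourly cost in the base year, pounds (nonnegative).
#' @param growth scalar annual real growth rate, or a vector named by year
#'   giving the rate applying from that year to the next.
#' @param uplift_2024 one-off multiplicative uplift applied at 2024.
#' @param base_year first year of the path (default 2022).
#' @param horizon last year of the path.
#' @return tibble `year`, `unit_cost`.
#' @export
#' @examples
#' generate_unit_cost_path(23, growth = 0.01, horizon = 2024)
generate_unit_cost_path <- function(base_cost, growth = 0, uplift_2024 = 1,
                                    base_year = 2022, horizon = 2042) {
  if (base_cost < 0) stop_depcare("unit cost must be nonnegative")
  if (horizon < base_year) stop_depcare("horizon must not precede the base year")
  years <- base_year:horizon
  rate_for <- function(y) {
    if (length(growth) == 1L && is.null(names(growth))) return(growth)
    if (!as.character(y) %in% names(growth)) {
      stop_depcare("no growth rate supplied for year ", y)
    }
    growth[[as.character(y)]]
  }
  cost <- numeric(length(years))
  cost[1] <- base_cost
  for (i in seq_along(years)[-1]) {
    cost[i] <- cost[i - 1] * (1 + rate_for(years[i - 1]))
    if (years[i] == 2024) cost[i] <- cost[i] * uplift_2024
  }
  tibble::tibble(year = years, unit_cost = cost)
}
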