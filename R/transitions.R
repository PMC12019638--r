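# Lagged multinomial transition model: estimation, two-year predicted
# probabilities, annualization, housing scenarios and the assembly of 5x5
# annual transition matrices with an absorbing dead state.

#' Construct a transition-model fit object
#'
#' Holds per-outcome (mild/moderate/severe vs base none) coefficient vectors
#' on the log relative-risk scale, their standard errors, and the stratum
#' means at which tenure, education and income are held when materializing
#' matrices. Normally produced by [fit_transition_model()], but can be built
#' directly from a published-style coefficient table so projections can run
#' without refitting.
#'
#' @param coef 3 x 11 matrix, rows `mild`,`moderate`,`severe`, columns
#'   `(Intercept)` plus `TRANS_TERMS`.
#' @param se matrix of the same shape with standard errors on the log scale
#'   (may be `NULL` when only point projections are needed).
#' @param covariate_means named vector with elements `rented`, `educ_mid`,
#'   `educ_high`, `income`.
#' @param n_used number of person-wave pairs used in estimation.
#' @return object of class `transition_fit`.
#' @export
transition_fit <- function(coef, se = NULL,
                           covariate_means = c(rented = 0.16, educ_mid = 0.309,
                                               educ_high = 0.313, income = 392),
                           n_used = NA_integer_) {
  cols <- c("(Intercept)", TRANS_TERMS)
  coef <- as.matrix(coef)
  if (!all(dim(coef) == c(3L, length(cols)))) {
    stop_depcare("transition coefficient matrix must be 3 x ", length(cols))
  }
  colnames(coef) <- cols
  rownames(coef) <- DEP_STATES[-1]
  if (!is.null(se)) {
    se <- as.matrix(se)
    stopifnot(all(dim(se) == dim(coef)))
    if (any(se < 0)) stop_depcare("standard errors must be nonnegative")
    dimnames(se) <- dimnames(coef)
  }
  if (!all(c("rented", "educ_mid", "educ_high", "income") %in%
             names(covariate_means))) {
    stop_depcare("covariate_means must name rented, educ_mid, educ_high, income")
  }
  structure(list(coef = coef, se = se, covariate_means = covariate_means,
                 n_used = n_used),
            class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat("Lagged multinomial transition model (base outcome: none)\n")
  cat("  n used:", x$n_used, "\n  RRRs:\n")
  print(round(exp(x$coef[, -1]), 3))
  invisible(x)
}

# Build (wave T, wave T+1) pairs from an analysis table; consecutive waves
# only, both states observed, predictors complete.
build_transition_pairs <- function(analysis) {
  cur <- analysis |>
    dplyr::select("person_id", "wave", "state", "housing_problems", "age",
                  "female", "rented", "educ_mid", "educ_high", "income")
  nxt <- analysis |>
    dplyr::transmute(.data$person_id, wave = .data$wave - 1L,
                     next_state = .data$state)
  dplyr::inner_join(cur, nxt, by = c("person_id", "wave")) |>
    dplyr::filter(!is.na(.data$state), !is.na(.data$next_state)) |>
    dplyr::filter(stats::complete.cases(
      dplyr::pick("housing_problems", "age", "female", "rented",
                  "educ_mid", "educ_high", "income")))
}

#' Fit the lagged multinomial transition model
#'
#' Pools all consecutive wave pairs (T, T+1) of the analysis table and fits a
#' multinomial logistic regression of depression severity at T+1 on housing
#' problems, severity, age, gender, tenure, education and equivalised income
#' at T, with "none" as the base outcome. Estimation is unweighted and by
#' maximum likelihood.
#'
#' @param analysis analysis table from [prepare_panel()] (at least 2 waves).
#' @return a [transition_fit()] with coefficients, standard errors and the
#'   estimation-sample means of tenure/education/income.
#' @export
fit_transition_model <- function(analysis) {
  pairs <- build_transition_pairs(analysis)
  if (nrow(pairs) == 0L) stop_depcare("no usable wave pairs in the panel")
  missing_states <- setdiff(DEP_STATES, unique(pairs$next_state))
  if (length(missing_states)) {
    stop_depcare("outcome category never observed: ",
                 paste(missing_states, collapse = ", "))
  }
  dat <- pairs |>
    dplyr::mutate(
      next_state = factor(.data$next_state, levels = DEP_STATES),
      state_mild = as.numeric(.data$state == "mild"),
      state_moderate = as.numeric(.data$state == "moderate"),
      state_severe = as.numeric(.data$state == "severe")
    )
  form <- as.formula(paste("next_state ~", paste(TRANS_TERMS, collapse = " + ")))
  fit <- nnet::multinom(form, data = dat, Hess = TRUE, trace = FALSE,
                        maxit = 300, MaxNWts = 5000)
  if (fit$convergence != 0) {
    stop_depcare("multinomial transition model failed to converge")
  }
  sm <- summary(fit)
  transition_fit(
    coef = sm$coefficients,
    se = sm$standard.errors,
    covariate_means = c(
      rented = mean(dat$rented), educ_mid = mean(dat$educ_mid),
      educ_high = mean(dat$educ_high), income = mean(dat$income)
    ),
    n_used = nrow(dat)
  )
}

# Design rows for the transition model given vectors of (state, age, female,
# housing); tenure/education/income at stratum means unless supplied.
transition_design_rows <- function(fit, state, age, female, housing,
                                   rented = NULL, educ_mid = NULL,
                                   educ_high = NULL, income = NULL) {
  mn <- fit$covariate_means
  n <- length(state)
  cbind(
    `(Intercept)` = rep(1, n),
    housing_problems = housing,
    state_mild = as.numeric(state == "mild"),
    state_moderate = as.numeric(state == "moderate"),
    state_severe = as.numeric(state == "severe"),
    age = age,
    female = female,
    rented = rep(rented %||% mn[["rented"]], length.out = n),
    educ_mid = rep(educ_mid %||% mn[["educ_mid"]], length.out = n),
    educ_high = rep(educ_high %||% mn[["educ_high"]], length.out = n),
    income = rep(income %||% mn[["income"]], length.out = n)
  )
}

#' Predict two-year transition probabilities for a covariate profile
#'
#' Softmax of the fitted linear predictors over the four living destination
#' states. Tenure, education and income default to the stratum means stored
#' in the fit.
#'
#' @param fit a [transition_fit()].
#' @param profile list with `current_state`, `age`, `gender`,
#'   `housing_problems`, and optionally `tenure`, `education`, `income`.
#' @return named probability 4-vector over
#'   `c("none","mild","moderate","severe")`, summing to 1.
#' @export
predict_two_year_probs <- function(fit, profile) {
  stopifnot(inherits(fit, "transition_fit"))
  if (!profile$current_state %in% DEP_STATES) {
    stop_depcare("unknown current_state: ", profile$current_state)
  }
  if (!profile$gender %in% GENDERS) {
    stop_depcare("unknown gender: ", profile$gender)
  }
  rented <- educ_mid <- educ_high <- NULL
  if (!is.null(profile$tenure)) {
    if (!profile$tenure %in% c("owner", "rented")) {
      stop_depcare("unknown tenure: ", profile$tenure)
    }
    rented <- as.numeric(profile$tenure == "rented")
  }
  if (!is.null(profile$education)) {
    if (!profile$education %in% EDU_LEVELS) {
      stop_depcare("unknown education: ", profile$education)
    }
    educ_mid <- as.numeric(profile$education == "nvq_gce_cse")
    educ_high <- as.numeric(profile$education == "degree_or_below")
  }
  X <- transition_design_rows(
    fit, profile$current_state, profile$age,
    as.numeric(profile$gender == "female"), profile$housing_problems,
    rented = rented, educ_mid = educ_mid, educ_high = educ_high,
    income = profile$income
  )
  p <- drop(softmax_rows(X %*% t(fit$coef)))
  setNames(p, DEP_STATES)
}

#' Convert a two-year transition probability to an annual one
#'
#' Under a constant instantaneous transition rate, `p1 = 1 - (1 - p2)^(1/2)`.
#'
#' @param p2 probability (or vector of probabilities) over two years.
#' @return annual probability, monotone in `p2`.
#' @export
annualize_probability <- function(p2) {
  if (any(p2 < 0 | p2 > 1)) stop_depcare("probabilities must lie in [0, 1]")
  1 - sqrt(1 - p2)
}

#' Annualize a row of two-year transition probabilities
#'
#' Applies the constant-rate conversion to each off-diagonal (move) entry and
#' restores the diagonal (stay) entry as the complement. If the annualized
#' moves exceed 1, they are rescaled proportionally and the stay probability
#' set to 0. In the single-destination case this is exact: two annual steps
#' reproduce the two-year probability.
#'
#' @param p2_row probability vector over destination states, summing to 1.
#' @param stay index of the origin (stay) state within the row.
#' @return annual probability vector of the same length, summing to 1.
#' @export
annualize_row <- function(p2_row, stay) {
  check_prob_vector(p2_row, "two-year transition row")
  out <- annualize_probability(p2_row)
  move_sum <- sum(out[-stay])
  if (move_sum > 1) {
    out[-stay] <- out[-stay] / move_sum
    out[stay] <- 0
  } else {
    out[stay] <- 1 - move_sum
  }
  out
}

#' Apply a housing intervention scenario to a housing distribution
#'
#' Relocates all probability mass above the cap onto the cap. `cap = Inf` is
#' the no-intervention identity.
#'
#' @param dist probability vector over housing-problem counts, named by
#'   count (e.g. `"0"` ... `"12"`).
#' @param cap maximum number of problems (`Inf`, 2, 1 or 0).
#' @return capped distribution on the same support.
#' @export
apply_housing_scenario <- function(dist, cap) {
  check_prob_vector(dist, "housing distribution")
  if (is.null(names(dist))) names(dist) <- seq_along(dist) - 1L
  if (cap < 0) stop_depcare("cap must be nonnegative")
  if (is.infinite(cap)) return(dist)
  counts <- as.numeric(names(dist))
  out <- dist
  above <- counts > cap
  out[counts == cap] <- out[counts == cap] + sum(dist[above])
  out[above] <- 0
  out
}

# Differential death probabilities: state multipliers normalized so the
# state-share-weighted death probability equals the stratum marginal rate.
state_death_probs <- function(mortality_rate, multipliers, state_shares) {
  if (mortality_rate < 0 || mortality_rate > 1) {
    stop_depcare("mortality_rate must lie in [0, 1]")
  }
  if (any(multipliers <= 0)) stop_depcare("mortality multipliers must be positive")
  check_prob_vector(state_shares, "state shares")
  pmin(1, mortality_rate * multipliers / sum(state_shares * multipliers))
}

#' Build a 5x5 annual transition matrix for one (age, gender) stratum
#'
#' For each living origin state, death is resolved first at the state's
#' differential mortality probability; the surviving mass is distributed
#' over living destinations according to the housing-distribution mixture of
#' the annualized predicted transition rows. The dead state is absorbing.
#'
#' @param fit a [transition_fit()].
#' @param age single year of age.
#' @param gender `"male"` or `"female"`.
#' @param dist housing-problem distribution for the stratum (named by count).
#' @param mortality_rate stratum marginal annual death probability.
#' @param multipliers mortality multipliers by living state (default
#'   `c(1, 1.1, 1.3, 1.6)`), renormalized against `state_shares` so the
#'   weighted death probability equals `mortality_rate`.
#' @param state_shares state shares used for that normalization.
#' @return 5x5 row-stochastic matrix over
#'   `c("none","mild","moderate","severe","dead")`.
#' @export
build_transition_matrix <- function(fit, age, gender, dist, mortality_rate,
                                    multipliers = c(1, 1.1, 1.3, 1.6),
                                    state_shares = c(0.480, 0.319, 0.143, 0.058)) {
  arr <- materialize_matrices(
    fit, ages = age, dist = dist,
    mortality = tibble::tibble(age = rep(age, 2), gender = GENDERS,
                               q = rep(mortality_rate, 2)),
    multipliers = multipliers, state_shares = state_shares
  )
  m <- arr[1, gender, , ]
  dimnames(m) <- list(ALL_STATES, ALL_STATES)
  m
}

#' Materialize annual transition matrices for all ages and genders
#'
#' Vectorized assembly of the per-stratum matrices used by the cohort
#' projection: one 5x5 matrix per (single year of age, gender) under one
#' housing-problem distribution.
#'
#' @param fit a [transition_fit()].
#' @param ages integer vector of single years of age (default 45-100).
#' @param dist housing-problem distribution (named by count).
#' @param mortality tibble `age`, `gender`, `q` covering `ages`.
#' @param multipliers,state_shares see [build_transition_matrix()].
#' @return array `[age, gender, from, to]` of row-stochastic matrices, with
#'   an attribute `n_rescaled` counting rows whose annualized moves needed
#'   proportional rescaling.
#' @export
materialize_matrices <- function(fit, ages = MODEL_AGES, dist, mortality,
                                 multipliers = c(1, 1.1, 1.3, 1.6),
                                 state_shares = c(0.480, 0.319, 0.143, 0.058)) {
  stopifnot(inherits(fit, "transition_fit"))
  check_prob_vector(dist, "housing distribution")
  if (is.null(names(dist))) names(dist) <- seq_along(dist) - 1L
  hvals <- as.numeric(names(dist))
  keep <- dist > 0
  hvals <- hvals[keep]
  wts <- unname(dist[keep])

  grid <- expand.grid(h = seq_along(hvals), origin = 1:4,
                      age = ages, gender = GENDERS,
                      stringsAsFactors = FALSE)
  X <- transition_design_rows(
    fit,
    state = DEP_STATES[grid$origin],
    age = grid$age,
    female = as.numeric(grid$gender == "female"),
    housing = hvals[grid$h]
  )
  p2 <- softmax_rows(X %*% t(fit$coef)) # n x 4, cols = destination states

  # element-wise annualization with per-row stay index = origin state
  ann <- 1 - sqrt(pmax(1 - p2, 0))
  stay_idx <- cbind(seq_len(nrow(ann)), grid$origin)
  move_sum <- rowSums(ann) - ann[stay_idx]
  rescale <- move_sum > 1
  if (any(rescale)) {
    ann[rescale, ] <- ann[rescale, , drop = FALSE] / move_sum[rescale]
  }
  ann[stay_idx] <- pmax(1 - pmin(move_sum, 1), 0)

  # mix over the housing distribution
  ann_w <- ann * wts[grid$h]
  key <- interaction(grid$origin, grid$age, grid$gender, drop = FALSE)
  mixed <- rowsum(ann_w, key, reorder = FALSE)
  mgrid <- grid[!duplicated(key), c("origin", "age", "gender")]

  qtab <- mortality
  out <- array(0, dim = c(length(ages), 2, 5, 5),
               dimnames = list(ages, GENDERS, ALL_STATES, ALL_STATES))
  for (g in GENDERS) {
    qg <- qtab$q[match(ages, qtab$age[qtab$gender == g])]
    if (any(is.na(qg))) stop_depcare("mortality schedule does not cover all ages")
    for (s in 1:4) {
      rows <- mixed[mgrid$origin == s & mgrid$gender == g, , drop = FALSE]
      ord <- match(ages, mgrid$age[mgrid$origin == s & mgrid$gender == g])
      rows <- rows[ord, , drop = FALSE]
      qs <- state_death_probs_vec(qg, multipliers[s], multipliers, state_shares)
      out[, g, s, 1:4] <- rows * (1 - qs)
      out[, g, s, 5] <- qs
    }
    out[, g, 5, 5] <- 1
  }
  attr(out, "n_rescaled") <- sum(rescale)
  out
}

state_death_probs_vec <- function(q, mult_s, multipliers, state_shares) {
  pmin(1, q * mult_s / sum(state_shares * multipliers))
}
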