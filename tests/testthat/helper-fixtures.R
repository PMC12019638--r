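# Shared fixtures, all built in code at test time.

# Fit objects assembled from the published-style coefficient tables (no
# estimation), with delta-method standard errors on the log scale.
published_fits <- function(zero_se = FALSE) {
  trr <- depcare:::default_transition_rrr()
  tse <- depcare:::default_transition_rrr_se() / trr
  cfg <- generator_config(n_individuals = 10, seed = 1)
  tcoef <- cfg$transition_coefficients
  crr <- depcare:::default_care_rrr()
  cse <- depcare:::default_care_rrr_se() / crr
  ccoef <- cfg$care_coefficients$mode
  hcoef <- cfg$care_coefficients$hours
  hse <- depcare:::default_hours_se()
  z <- function(m) if (zero_se) m * 0 else m
  list(
    transition = transition_fit(
      tcoef, se = z(cbind(`(Intercept)` = rep(0.05, 3), tse))
    ),
    care = care_fit(ccoef, se = z(cbind(`(Intercept)` = rep(0.05, 3), cse))),
    hours = hours_fit(hcoef, se = z(cbind(`(Intercept)` = rep(0.5, 2), hse)),
                      sigma = c(home = 3, unpaid = 3))
  )
}

# Small projection world driven by the published fits.
small_inputs <- function(horizon = 2042, population_scale = 1000) {
  cfg <- generator_config(n_individuals = 10, seed = 7,
                          population_scale = population_scale)
  depcare:::default_projection_inputs(cfg, horizon = horizon)
}

# Intercept-only transition fit: identical two-year row everywhere.
flat_transition_fit <- function(intercepts = c(-1, -2, -3)) {
  coef <- matrix(0, 3, 11)
  coef[, 1] <- intercepts
  transition_fit(coef, se = matrix(0, 3, 11))
}

# Intercept-only care-mode and hours fits.
flat_care_fit <- function(intercepts = c(-2, -1, -3)) {
  coef <- matrix(0, 3, 9)
  coef[, 1] <- intercepts
  care_fit(coef, se = matrix(0, 3, 9))
}

flat_hours_fit <- function(home = 6, unpaid = 9) {
  coef <- matrix(0, 2, 9)
  coef[, 1] <- c(home, unpaid)
  hours_fit(coef, se = matrix(0, 2, 9))
}

# A mid-sized panel reused across estimation tests (generated once).
shared_panel_env <- new.env()
shared_panel <- function() {
  if (is.null(shared_panel_env$panel)) {
    cfg <- generator_config(n_individuals = 20000, n_waves = 3, seed = 2024)
    shared_panel_env$config <- cfg
    shared_panel_env$panel <- generate_panel(cfg)
    shared_panel_env$analysis <- prepare_panel(shared_panel_env$panel)
  }
  shared_panel_env
}

# Independent softmax used as an oracle against the package's predictors.
oracle_softmax <- function(eta) {
  e <- c(1, exp(eta))
  e / sum(e)
}

expect_row_stochastic <- function(arr, tol = 1e-12) {
  rs <- apply(arr, c(1, 2, 3), sum)
  expect_true(all(abs(rs - 1) < tol))
  expect_true(all(arr >= -tol))
}
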