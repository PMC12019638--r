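test_that("identical config and seed give byte-identical panels", {
  cfg <- generator_config(n_individuals = 400, n_waves = 3, seed = 11)
  expect_identical(generate_panel(cfg), generate_panel(cfg))
  cfg2 <- generator_config(n_individuals = 400, n_waves = 3, seed = 12)
  expect_false(identical(generate_panel(cfg), generate_panel(cfg2)))
})

test_that("wave-1 marginals match the config within 3 binomial SEs", {
  env <- shared_panel()
  cfg <- env$config
  w1 <- env$panel[env$panel$wave == 1, ]
  n <- nrow(w1)
  tol <- function(p) 3 * sqrt(p * (1 - p) / n)
  states <- prop.table(table(factor(classify_depression(
    depcare:::score_cesd_matrix(as.matrix(w1[paste0("cesd_", 1:8)]))
  ), levels = c("none", "mild", "moderate", "severe"))))
  for (i in 1:4) {
    expect_lt(abs(states[i] - cfg$baseline_prevalence[i]),
              tol(cfg$baseline_prevalence[i]))
  }
  hb <- pmin(w1$housing_problems, 3)
  hshare <- prop.table(table(factor(hb, levels = 0:3)))
  for (i in 1:4) {
    expect_lt(abs(hshare[i] - cfg$housing_distribution[i]),
              tol(cfg$housing_distribution[i]))
  }
  expect_lt(abs(mean(w1$gender == "female") -
                  cfg$covariate_marginals$female_share), tol(0.552))
  expect_lt(abs(mean(w1$tenure == "rented") -
                  cfg$covariate_marginals$rented_share), tol(0.16))
})

test_that("no attrition and no mortality keeps every member for all waves", {
  cfg <- generator_config(
    n_individuals = 300, n_waves = 4, seed = 5, attrition_rate = 0,
    mortality = list(male = c(a = 0, b = 0.1), female = c(a = 0, b = 0.1))
  )
  panel <- generate_panel(cfg)
  expect_identical(nrow(panel), 300L * 4L)
  per_person <- table(panel$person_id)
  expect_true(all(per_person == 4))
  # age rises by exactly 2 between consecutive waves
  byp <- split(panel$age, panel$person_id)
  expect_true(all(vapply(byp, function(a) all(diff(a) == 2), logical(1))))
})

test_that("care hours are zero exactly when the matching flag is off", {
  env <- shared_panel()
  p <- env$panel
  expect_true(all(p$unpaid_hours_week[!p$unpaid_care] == 0))
  expect_true(all(p$unpaid_hours_week[p$unpaid_care] > 0))
  expect_true(all(p$home_hours_week[!p$home_care] == 0))
  expect_true(all(p$home_hours_week[p$home_care] > 0))
  # care is only generated at ages 65+
  young <- p[p$age < 65, ]
  expect_true(all(!young$unpaid_care & !young$home_care))
})

test_that("intercept-only transitions match a direct multinomial oracle", {
  a <- c(-0.8, -1.6, -2.4)
  coef <- matrix(0, 3, 11)
  coef[, 1] <- a
  cfg <- generator_config(
    n_individuals = 30000, n_waves = 2, seed = 99, attrition_rate = 0,
    mortality = list(male = c(a = 0, b = 0.1), female = c(a = 0, b = 0.1)),
    transition_coefficients = coef
  )
  panel <- generate_panel(cfg)
  an <- prepare_panel(panel)
  w2 <- an[an$wave == 2, ]
  emp <- prop.table(table(factor(w2$state,
                                 levels = c("none", "mild", "moderate",
                                            "severe"))))
  expected <- oracle_softmax(a)
  # independent oracle: direct multinomial sampling at the same n
  direct <- prop.table(drop(withr::with_seed(1,
    stats::rmultinom(1, nrow(w2), expected))))
  tol <- 4 * sqrt(expected * (1 - expected) / nrow(w2))
  expect_true(all(abs(emp - expected) < tol))
  expect_true(all(abs(direct - expected) < tol))
})

test_that("population table supports flat, zero and seeded default profiles", {
  cfg <- generator_config(n_individuals = 10, seed = 3)
  flat <- generate_population_table(cfg, flat_count = 1000)
  expect_identical(sum(flat$count), 1000 * 56 * 2) # 56 ages x 2 genders
  expect_error(generate_population_table(cfg, flat_count = -1), "nonnegative")

  zero <- generate_population_table(
    generator_config(n_individuals = 10, seed = 3, population_scale = 0))
  expect_true(all(zero$count == 0))

  d1 <- generate_population_table(cfg)
  d2 <- generate_population_table(cfg)
  expect_identical(d1, d2)
  expect_true(all(d1$count >= 0))
})

test_that("Gompertz mortality schedule has the closed-form age gradient", {
  cfg <- generator_config(
    n_individuals = 10, seed = 1,
    mortality = list(male = c(a = 1e-4, b = 0.1), female = c(a = 1e-4, b = 0.1))
  )
  q <- generate_mortality_schedule(cfg)
  q65 <- q$q[q$age == 65 & q$gender == "male"]
  q45 <- q$q[q$age == 45 & q$gender == "male"]
  expect_equal(q65 / q45, exp(0.1 * 20), tolerance = 1e-12)

  zero <- generate_mortality_schedule(generator_config(
    n_individuals = 10, seed = 1,
    mortality = list(male = c(a = 0, b = 0.1), female = c(a = 0, b = 0.1))
  ))
  expect_true(all(zero$q == 0))

  # monotone nondecreasing in age within gender, clipped at 1
  dflt <- generate_mortality_schedule(generator_config(n_individuals = 10))
  for (g in c("male", "female")) {
    qs <- dflt$q[dflt$gender == g][order(dflt$age[dflt$gender == g])]
    expect_true(all(diff(qs) >= 0))
    expect_true(all(qs >= 0 & qs <= 1))
  }
})

test_that("unit-cost path compounds growth with a one-off 2024 uplift", {
  flat <- generate_unit_cost_path(23, growth = 0, uplift_2024 = 1)
  expect_true(all(flat$unit_cost == 23))
  grown <- generate_unit_cost_path(23, growth = 0.01, uplift_2024 = 1)
  expect_equal(grown$unit_cost[grown$year == 2024], 23 * 1.01^2,
               tolerance = 1e-12)
  opp <- generate_unit_cost_path(14.8, growth = 0)
  expect_true(all(opp$unit_cost == 14.8))
  uplifted <- generate_unit_cost_path(23, growth = 0, uplift_2024 = 1.05)
  expect_equal(uplifted$unit_cost[uplifted$year == 2023], 23)
  expect_true(all(uplifted$unit_cost[uplifted$year >= 2024] == 23 * 1.05))
  expect_error(generate_unit_cost_path(-1), "nonnegative")
  expect_error(generate_unit_cost_path(23, horizon = 2020), "base year")
})

test_that("config validation rejects out-of-domain parameters", {
  expect_error(generator_config(n_individuals = 0), "positive")
  expect_error(generator_config(n_waves = 1), "at least 2")
  expect_error(generator_config(attrition_rate = 1.2), "\\[0, 1\\)")
  expect_error(generator_config(housing_distribution = c(0.5, 0.5, 0.2, 0.1)),
               "sum to 1")
  expect_error(generator_config(baseline_prevalence = c(0.9, 0.2, 0, -0.1)),
               "probability")
})
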