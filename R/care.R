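# Cross-sectional care-utilisation models: multinomial care mode (no care /
# home only / unpaid only / both) and two OLS weekly-hours models fitted on
# care recipients.

#' Construct a care-mode fit object
#'
#' @param coef 3 x 9 matrix of log-RRR coefficients, rows
#'   `home_only`,`unpaid_only`,`both` (base outcome "none"), columns
#'   `(Intercept)` plus `CARE_TERMS`.
#' @param se matrix of standard errors on the log scale (optional).
#' @param n_used number of rows used in estimation.
#' @return object of class `care_fit`.
#' @export
care_fit <- function(coef, se = NULL, n_used = NA_integer_) {
  cols <- c("(Intercept)", CARE_TERMS)
  coef <- as.matrix(coef)
  if (!all(dim(coef) == c(3L, length(cols)))) {
    stop_depcare("care coefficient matrix must be 3 x ", length(cols))
  }
  colnames(coef) <- cols
  rownames(coef) <- CARE_MODES[-1]
  if (!is.null(se)) {
    se <- as.matrix(se)
    stopifnot(all(dim(se) == dim(coef)))
    if (any(se < 0)) stop_depcare("standard errors must be nonnegative")
    dimnames(se) <- dimnames(coef)
  }
  structure(list(coef = coef, se = se, n_used = n_used), class = "care_fit")
}

#' @export
print.care_fit <- function(x, ...) {
  cat("Care-mode multinomial model (base outcome: no care)\n")
  cat("  n used:", x$n_used, "\n  RRRs:\n")
  print(round(exp(x$coef[, -1]), 3))
  invisible(x)
}

#' Construct an hours fit object
#'
#' Two linear models of weekly care hours (home, unpaid), fitted on the
#' recipients of the respective care type.
#'
#' @param coef 2 x 9 coefficient matrix, rows `home`,`unpaid`, columns
#'   `(Intercept)` plus `CARE_TERMS`.
#' @param se matching standard errors (optional).
#' @param sigma named residual standard deviations (optional).
#' @param n_used named counts of recipient rows per model.
#' @return object of class `hours_fit`.
#' @export
hours_fit <- function(coef, se = NULL, sigma = NULL,
                      n_used = c(home = NA_integer_, unpaid = NA_integer_)) {
  cols <- c("(Intercept)", CARE_TERMS)
  coef <- as.matrix(coef)
  if (!all(dim(coef) == c(2L, length(cols)))) {
    stop_depcare("hours coefficient matrix must be 2 x ", length(cols))
  }
  colnames(coef) <- cols
  rownames(coef) <- c("home", "unpaid")
  if (!is.null(se)) {
    se <- as.matrix(se)
    stopifnot(all(dim(se) == dim(coef)))
    dimnames(se) <- dimnames(coef)
  }
  structure(list(coef = coef, se = se, sigma = sigma, n_used = n_used),
            class = "hours_fit")
}

care_model_frame <- function(cross) {
  need <- c("age", "state", "functional")
  if (!all(need %in% names(cross))) {
    stop_depcare("cross-section must contain ", paste(need, collapse = ", "))
  }
  female <- if ("female" %in% names(cross)) cross$female else
    as.numeric(cross$gender == "female")
  tibble::tibble(
    dep_mild = as.numeric(cross$state == "mild"),
    dep_moderate = as.numeric(cross$state == "moderate"),
    dep_severe = as.numeric(cross$state == "severe"),
    age = cross$age,
    female = female,
    func_iadl_only = as.numeric(cross$functional == "iadl_only"),
    func_adl_1_2 = as.numeric(cross$functional == "adl_1_2"),
    func_adl_3plus = as.numeric(cross$functional == "adl_3plus")
  )
}

#' Fit the care-mode multinomial model
#'
#' Maximum-likelihood multinomial logistic regression of the care mode
#' (none / home only / unpaid only / both, base "none") on depression
#' severity, age, gender and functional difficulty, restricted to people
#' aged 65 and over.
#'
#' @param cross analysis-ready cross-section with columns `age`, `state`,
#'   `functional`, `care_mode` and `gender` (or `female`).
#' @return a [care_fit()].
#' @export
fit_care_mode_model <- function(cross) {
  cross <- dplyr::filter(cross, .data$age >= 65, !is.na(.data$state))
  missing_modes <- setdiff(CARE_MODES, unique(cross$care_mode))
  if (length(missing_modes)) {
    stop_depcare("care mode never observed: ",
                 paste(missing_modes, collapse = ", "))
  }
  dat <- care_model_frame(cross)
  dat$care_mode <- factor(cross$care_mode, levels = CARE_MODES)
  form <- as.formula(paste("care_mode ~", paste(CARE_TERMS, collapse = " + ")))
  fit <- nnet::multinom(form, data = dat, Hess = TRUE, trace = FALSE,
                        maxit = 300)
  if (fit$convergence != 0) stop_depcare("care-mode model failed to converge")
  sm <- summary(fit)
  care_fit(coef = sm$coefficients, se = sm$standard.errors,
           n_used = nrow(dat))
}

#' Fit the weekly-hours linear models on care recipients
#'
#' Ordinary least squares of weekly home-care hours on the recipients of
#' home care, and of weekly unpaid-care hours on the recipients of unpaid
#' care, each on depression severity, age, gender and functional difficulty.
#'
#' @param cross analysis-ready cross-section with care flags and
#'   `home_hours_week` / `unpaid_hours_week`.
#' @return an [hours_fit()].
#' @export
fit_hours_models <- function(cross) {
  cross <- dplyr::filter(cross, .data$age >= 65, !is.na(.data$state))
  fit_one <- function(flag, hours) {
    rec <- cross[cross[[flag]], , drop = FALSE]
    dat <- care_model_frame(rec)
    dat$hours <- rec[[hours]]
    if (nrow(dat) <= length(CARE_TERMS) + 1L) {
      stop_depcare("too few recipient rows to fit the ", hours, " model")
    }
    form <- as.formula(paste("hours ~", paste(CARE_TERMS, collapse = " + ")))
    m <- lm(form, data = dat)
    if (m$rank < length(CARE_TERMS) + 1L) {
      stop_depcare("rank-deficient hours model for ", hours)
    }
    sm <- summary(m)
    list(coef = coef(m), se = sm$coefficients[, "Std. Error"],
         sigma = sm$sigma, n = nrow(dat))
  }
  home <- fit_one("home_care", "home_hours_week")
  unpaid <- fit_one("unpaid_care", "unpaid_hours_week")
  hours_fit(
    coef = rbind(home = home$coef, unpaid = unpaid$coef),
    se = rbind(home = home$se, unpaid = unpaid$se),
    sigma = c(home = home$sigma, unpaid = unpaid$sigma),
    n_used = c(home = home$n, unpaid = unpaid$n)
  )
}

cell_design_rows <- function(cells) {
  if (!all(cells$depression %in% DEP_STATES)) {
    stop_depcare("unknown depression category in cells")
  }
  if (!all(cells$functional %in% FUNC_LEVELS)) {
    stop_depcare("unknown functional category in cells")
  }
  if (!all(cells$gender %in% GENDERS)) {
    stop_depcare("unknown gender in cells")
  }
  age <- if ("age" %in% names(cells)) cells$age else
    unname(BAND_MIDPOINTS[cells$band])
  if (any(is.na(age))) stop_depcare("unknown age band in cells")
  cbind(
    `(Intercept)` = rep(1, nrow(cells)),
    dep_mild = as.numeric(cells$depression == "mild"),
    dep_moderate = as.numeric(cells$depression == "moderate"),
    dep_severe = as.numeric(cells$depression == "severe"),
    age = age,
    female = as.numeric(cells$gender == "female"),
    func_iadl_only = as.numeric(cells$functional == "iadl_only"),
    func_adl_1_2 = as.numeric(cells$functional == "adl_1_2"),
    func_adl_3plus = as.numeric(cells$functional == "adl_3plus")
  )
}

#' Predict care-mode probabilities for population cells
#'
#' Softmax of the fitted linear predictors. Banded cells enter the
#' continuous-age models at their band midpoint (92.5 for 90+). The
#' probability of being an unpaid-care user is `p(unpaid only) + p(both)`;
#' of being a home-care user, `p(home only) + p(both)`.
#'
#' @param fit a [care_fit()].
#' @param cells data frame with columns `gender`, `functional`, `depression`
#'   and either `age` or `band`.
#' @return matrix of probabilities, one row per cell, columns `CARE_MODES`.
#' @export
predict_care_probs <- function(fit, cells) {
  stopifnot(inherits(fit, "care_fit"))
  cells <- tibble::as_tibble(cells)
  X <- cell_design_rows(cells)
  p <- softmax_rows(X %*% t(fit$coef))
  colnames(p) <- CARE_MODES
  p
}

#' Predict weekly care hours for population cells
#'
#' Linear prediction from the recipients-only hours model, floored at 0.
#'
#' @param fit an [hours_fit()].
#' @param cells data frame as in [predict_care_probs()].
#' @param care_type `"home"` or `"unpaid"`.
#' @return numeric vector of weekly hours, one per cell.
#' @export
predict_hours <- function(fit, cells, care_type = c("home", "unpaid")) {
  stopifnot(inherits(fit, "hours_fit"))
  care_type <- match.arg(care_type)
  cells <- tibble::as_tibble(cells)
  X <- cell_design_rows(cells)
  pmax(drop(X %*% fit$coef[care_type, ]), 0)
}
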