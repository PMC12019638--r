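# Delimited-file interfaces: UTF-8, comma separator, period decimal mark,
# LF line endings, header rows. Every writer is round-trippable through the
# matching reader.

write_table_csv <- function(x, path) {
  con <- file(path, open = "wb") # LF endings on every platform
  on.exit(close(con))
  write.csv(x, con, row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

read_table_csv <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                             encoding = "UTF-8"))
}

#' Write / read a synthetic panel
#'
#' @param panel panel tibble from [generate_panel()].
#' @param path CSV file path.
#' @return the path (writer) or the panel tibble (reader).
#' @export
write_panel <- function(panel, path) write_table_csv(panel, path)

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  p <- read_table_csv(path)
  p$unpaid_care <- as.logical(p$unpaid_care)
  p$home_care <- as.logical(p$home_care)
  p$alive <- as.logical(p$alive)
  p
}

#' Export / import fitted coefficients as a long coefficient table
#'
#' Long format `model`, `outcome`, `term`, `estimate`, `se` with estimates
#' on the estimation scale (log-RRR for the multinomial models, linear for
#' hours). A table exported from fits can be re-imported to run projections
#' without refitting.
#'
#' @param fits list with `transition`, `care`, `hours` fit objects.
#' @param path CSV file path.
#' @return the path (writer); the `fits` list (reader).
#' @export
export_coef_table <- function(fits, path) {
  melt <- function(coef, se, model) {
    tibble::tibble(
      model = model,
      outcome = rep(rownames(coef), ncol(coef)),
      term = rep(colnames(coef), each = nrow(coef)),
      estimate = as.vector(coef),
      se = if (is.null(se)) NA_real_ else as.vector(se)
    )
  }
  tab <- dplyr::bind_rows(
    melt(fits$transition$coef, fits$transition$se, "transition"),
    melt(fits$care$coef, fits$care$se, "care_mode"),
    melt(fits$hours$coef, fits$hours$se, "hours")
  )
  means <- fits$transition$covariate_means
  tab <- dplyr::bind_rows(tab, tibble::tibble(
    model = "covariate_means", outcome = "all", term = names(means),
    estimate = unname(means), se = NA_real_
  ))
  write_table_csv(tab, path)
}

#' @rdname export_coef_table
#' @export
import_coef_table <- function(path) {
  tab <- read_table_csv(path)
  unmelt <- function(model, rows, cols) {
    sub <- tab[tab$model == model, ]
    coef <- matrix(NA_real_, length(rows), length(cols),
                   dimnames = list(rows, cols))
    se <- coef
    for (i in seq_len(nrow(sub))) {
      coef[sub$outcome[i], sub$term[i]] <- sub$estimate[i]
      se[sub$outcome[i], sub$term[i]] <- sub$se[i]
    }
    if (any(is.na(coef))) stop_depcare("incomplete coefficient table: ", model)
    list(coef = coef, se = if (all(is.na(se))) NULL else se)
  }
  tcols <- c("(Intercept)", TRANS_TERMS)
  ccols <- c("(Intercept)", CARE_TERMS)
  tr <- unmelt("transition", DEP_STATES[-1], tcols)
  cm <- unmelt("care_mode", CARE_MODES[-1], ccols)
  hr <- unmelt("hours", c("home", "unpaid"), ccols)
  mrows <- tab[tab$model == "covariate_means", ]
  means <- setNames(mrows$estimate, mrows$term)
  list(
    transition = transition_fit(tr$coef, tr$se, covariate_means = means),
    care = care_fit(cm$coef, cm$se),
    hours = hours_fit(hr$coef, hr$se)
  )
}

#' Export a transition-matrix array in long format
#'
#' @param arr array `[age, gender, from, to]` from
#'   [materialize_matrices()].
#' @param path CSV file path.
#' @param scenario scenario label recorded in each row.
#' @return the path.
#' @export
write_matrices_long <- function(arr, path, scenario = "base") {
  dn <- dimnames(arr)
  long <- expand.grid(age = dn[[1]], gender = dn[[2]], origin = dn[[3]],
                      destination = dn[[4]], stringsAsFactors = FALSE)
  long$scenario <- scenario
  long$probability <- as.vector(arr)
  write_table_csv(long[, c("age", "gender", "scenario", "origin",
                           "destination", "probability")], path)
}

#' Write the data dictionary for the generated input files
#'
#' @param dir output directory.
#' @return the file path.
#' @export
write_data_dictionary <- function(dir) {
  lines <- c(
    "depcare synthetic input files: column dictionary",
    "",
    "panel.csv (one row per surviving, retained person-wave)",
    "  person_id        integer person identifier",
    "  wave             wave index (biennial; age rises by 2 between waves)",
    "  age              age in years at the wave",
    "  gender           male | female",
    "  tenure           owner | rented",
    "  education        none | nvq_gce_cse | degree_or_below",
    "  income           equivalised weekly income, pounds",
    "  housing_problems count of reported housing problems, 0-12",
    "  cesd_1..cesd_8   CES-D item responses, 1 = yes (items 7-8 are",
    "                   positive statements, reverse-coded when scoring)",
    "  adl_count        difficulties with activities of daily living",
    "  iadl_count       difficulties with instrumental ADLs",
    "  unpaid_care      receives unpaid care (65+ only)",
    "  home_care        receives formal home care (65+ only)",
    "  unpaid_hours_week / home_hours_week  weekly hours (0 when no care)",
    "  alive            TRUE for every emitted record",
    "",
    "population.csv: age (45-100, 100 = open group), gender, count",
    "mortality.csv:  age, gender, q (annual death probability)",
    "unit_costs.csv: year, unit_cost (pounds/hour, 2022 prices)"
  )
  path <- file.path(dir, "data_dictionary.txt")
  writeLines(lines, path)
  path
}
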