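#' Construct a rate table from age-band counts
#'
#' One row per 1-year age band [a, a+1): mid-year population (person-years;
#' multi-year data are pooled before loading), cancer registrations, deaths
#' from the cancer, and deaths from all causes. Derives piecewise-constant
#' per-year hazards: cancer incidence `lambda_c = cancer_cases / population`
#' and other-cause mortality
#' `lambda_o = (all_cause_deaths - cancer_deaths) / population`.
#' The person-year denominator is used as-is for both hazards (no
#' prevalent-case correction); "aged x to y" ranges are inclusive of both
#' endpoint bands.
#'
#' @param bands data.frame with columns `age`, `population`, `cancer_cases`,
#'   `cancer_deaths`, `all_cause_deaths`; ages ascending, contiguous, 1-year.
#' @param cancer,sex labels carried along for reporting.
#' @return a `rate_table`: validated data.frame with derived `lambda_c`,
#'   `lambda_o` columns and `cancer`/`sex` attributes.
#' @export
rate_table <- function(bands, cancer = "cancer", sex = "all") {
  required <- c("age", "population", "cancer_cases", "cancer_deaths",
                "all_cause_deaths")
  missing_cols <- setdiff(required, names(bands))
  if (length(missing_cols)) {
    stop("rate table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(bands) == 0L) stop("rate table has no age bands")
  bands <- bands[order(bands$age), required]
  if (any(diff(bands$age) != 1L)) {
    gaps <- bands$age[which(diff(bands$age) != 1L)]
    stop("non-contiguous age bands after age ", paste(gaps, collapse = ", "))
  }
  bad <- which(!(bands$population > 0))
  if (length(bad)) stop("non-positive population at age ",
                        paste(bands$age[bad], collapse = ", "))
  counts <- c("cancer_cases", "cancer_deaths", "all_cause_deaths")
  for (cn in counts) {
    bad <- which(!is.finite(bands[[cn]]) | bands[[cn]] < 0)
    if (length(bad)) stop("negative or missing ", cn, " at age ",
                          paste(bands$age[bad], collapse = ", "))
  }
  bad <- which(bands$cancer_deaths > bands$all_cause_deaths)
  if (length(bad)) stop("cancer_deaths exceed all_cause_deaths at age ",
                        paste(bands$age[bad], collapse = ", "))
  bands$lambda_c <- bands$cancer_cases / bands$population
  bands$lambda_o <- (bands$all_cause_deaths - bands$cancer_deaths) /
    bands$population
  attr(bands, "cancer") <- cancer
  attr(bands, "sex") <- sex
  class(bands) <- c("rate_table", "data.frame")
  bands
}

#' Load a rate table from CSV
#'
#' Expects header `age,population,cancer_cases,cancer_deaths,all_cause_deaths`,
#' one row per 1-year band, ages ascending. Synthetic calibrated fixtures
#' `synthetic_prostate_rates.csv` and `synthetic_breast_rates.csv` ship under
#' `system.file("extdata", package = "prscreen")`.
#'
#' @param path CSV path.
#' @param cancer,sex labels; cancer defaults to the file name stem.
#' @return a `rate_table`.
#' @export
load_rate_table <- function(path, cancer = sub("\\.csv$", "", basename(path)),
                            sex = "all") {
  rate_table(utils::read.csv(path), cancer = cancer, sex = sex)
}

#' Write a rate table to CSV
#'
#' Writes only the count columns (hazards are derived on load), so a
#' write/read round trip reproduces hazards bit-for-bit.
#'
#' @param table a `rate_table`.
#' @param path output CSV path.
#' @export
write_rate_table <- function(table, path) {
  stopifnot(inherits(table, "rate_table"))
  utils::write.csv(
    as.data.frame(table)[, c("age", "population", "cancer_cases",
                             "cancer_deaths", "all_cause_deaths")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

age_range_of <- function(table) range(table$age)

band_index <- function(table, age) {
  i <- match(age, table$age)
  if (any(is.na(i))) {
    stop("age ", paste(age[is.na(i)], collapse = ", "),
         " outside table coverage [", table$age[1], ", ",
         table$age[nrow(table)], "]")
  }
  i
}

#' Per-year hazards for one age band
#'
#' @param table a `rate_table`.
#' @param age integer age within the table's coverage.
#' @return named numeric vector `c(lambda_c, lambda_o)`: cancer-incidence and
#'   other-cause mortality hazards for band [age, age+1).
#' @export
hazards <- function(table, age) {
  stopifnot(inherits(table, "rate_table"), length(age) == 1L)
  i <- band_index(table, age)
  c(lambda_c = table$lambda_c[i], lambda_o = table$lambda_o[i])
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate_table> %s (%s): ages %d-%d, %d one-year bands\n",
              attr(x, "cancer"), attr(x, "sex"),
              x$age[1], x$age[nrow(x)], nrow(x)))
  invisible(x)
}
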