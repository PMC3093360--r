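# Core piecewise-exponential competing-risk computation over a run of
# 1-year bands with hazards (rr*lambda_c, lambda_o). Within a band the
# cause-specific decomposition gives P(cancer in band | at risk at entry)
# = lambda/(lambda+delta) * (1 - exp(-(lambda+delta))).
piecewise_risk <- function(lambda_c, lambda_o, rr = 1) {
  lam <- rr * lambda_c
  h <- lam + lambda_o
  surv_entry <- c(1, cumprod(exp(-h)))[seq_along(h)]
  contrib <- ifelse(h > 0, surv_entry * lam / h * (1 - exp(-h)), 0)
  sum(contrib)
}

check_window <- function(table, start_age, end_age) {
  amin <- table$age[1]
  amax <- table$age[nrow(table)]
  if (start_age < amin || end_age > amax + 1 || start_age >= end_age) {
    stop("risk window [", start_age, ", ", end_age,
         ") must satisfy ", amin, " <= x < y <= ", amax + 1)
  }
}

#' Age-conditional absolute risk of cancer diagnosis
#'
#' Probability of being diagnosed with the cancer between ages x and y
#' (window [x, y)), given alive and cancer-free at age x, under the competing
#' risk of death from other causes. Hazards are constant within 1-year bands;
#' the cancer-incidence hazard is scaled by a polygenic relative risk `rr`,
#' other-cause mortality is not. For each band a in [x, y) the contribution is
#' \deqn{S(x,a)\,\frac{\lambda}{\lambda+\delta}\,(1 - e^{-(\lambda+\delta)}),}
#' with \eqn{\lambda = rr\,\lambda_c(a)}, \eqn{\delta = \lambda_o(a)} and
#' S(x,a) the probability of reaching band a alive and cancer-free.
#'
#' @param table a [rate_table()].
#' @param start_age,end_age integer ages, table `age_min <= x < y <= age_max+1`.
#' @param rr positive multiplier on cancer incidence (polygenic relative
#'   risk); default 1 gives the general-population risk.
#' @return probability in [0, 1].
#' @examples
#' # single band, incidence 0.02, no competing mortality:
#' tab <- rate_table(data.frame(age = 50, population = 1e6,
#'   cancer_cases = 2e4, cancer_deaths = 0, all_cause_deaths = 0))
#' age_conditional_risk(tab, 50, 51)  # 1 - exp(-0.02)
#' @export
age_conditional_risk <- function(table, start_age, end_age, rr = 1) {
  stopifnot(inherits(table, "rate_table"))
  if (!is.finite(rr) || rr <= 0) stop("rr must be > 0")
  check_window(table, start_age, end_age)
  i <- band_index(table, start_age:(end_age - 1L))
  piecewise_risk(table$lambda_c[i], table$lambda_o[i], rr = rr)
}

#' Probability of remaining alive and cancer-free
#'
#' S(x, y | rr): probability of reaching age y alive and not diagnosed, given
#' alive and cancer-free at x, with cancer incidence scaled by `rr`. Satisfies
#' the decomposition A(x,z) = A(x,y) + S(x,y) A(y,z).
#'
#' @inheritParams age_conditional_risk
#' @return probability in [0, 1].
#' @export
cancer_free_survival <- function(table, start_age, end_age, rr = 1) {
  stopifnot(inherits(table, "rate_table"))
  if (!is.finite(rr) || rr <= 0) stop("rr must be > 0")
  check_window(table, start_age, end_age)
  i <- band_index(table, start_age:(end_age - 1L))
  exp(-sum(rr * table$lambda_c[i] + table$lambda_o[i]))
}

#' Absolute-risk curve by starting age
#'
#' [age_conditional_risk()] with a fixed window length, evaluated at every
#' start age the table covers. Near the upper end of the table the window is
#' truncated at `age_max + 1` (the reported `window_years` column shrinks
#' accordingly); no extrapolation beyond the table.
#'
#' @param table a [rate_table()].
#' @param window window length in years (default 10).
#' @param rr positive relative-risk multiplier.
#' @return data.frame with columns `start_age`, `window_years`, `rr`,
#'   `absolute_risk`, exportable as CSV.
#' @export
risk_curve <- function(table, window = 10L, rr = 1) {
  stopifnot(inherits(table, "rate_table"))
  if (window < 1) stop("window must be >= 1 year")
  amax1 <- table$age[nrow(table)] + 1L
  starts <- table$age
  ends <- pmin(starts + as.integer(window), amax1)
  data.frame(
    start_age = starts,
    window_years = ends - starts,
    rr = rr,
    absolute_risk = vapply(seq_along(starts), function(k) {
      age_conditional_risk(table, starts[k], ends[k], rr = rr)
    }, numeric(1))
  )
}
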