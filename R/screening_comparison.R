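#' Define a screening eligibility policy
#'
#' Age-based: everyone at or above `age_cutoff` (within `age_range`) is
#' eligible. Personalised: at each age a person is eligible if their 10-year
#' (or `window`-year) absolute risk — baseline incidence scaled by their
#' polygenic relative risk — is at least `risk_threshold`.
#'
#' @param kind "age_based" or "personalised".
#' @param age_range inclusive integer range c(low, high) of ages analysed.
#' @param age_cutoff eligibility age (age_based only), low <= cutoff <= high.
#' @param risk_threshold absolute-risk threshold t in (0, 1) (personalised).
#' @param window risk window in years (default 10).
#' @return a `screening_policy` list.
#' @export
screening_policy <- function(kind = c("age_based", "personalised"),
                             age_range, age_cutoff = NULL,
                             risk_threshold = NULL, window = 10L) {
  kind <- match.arg(kind)
  stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2], window >= 1)
  if (kind == "age_based") {
    if (is.null(age_cutoff) || age_cutoff < age_range[1] ||
        age_cutoff > age_range[2]) {
      stop("age_based policy needs age_range[1] <= age_cutoff <= age_range[2]")
    }
  } else {
    if (is.null(risk_threshold) || risk_threshold <= 0 || risk_threshold >= 1) {
      stop("personalised policy needs risk_threshold in (0, 1)")
    }
  }
  structure(list(kind = kind, age_range = as.integer(age_range),
                 age_cutoff = age_cutoff, risk_threshold = risk_threshold,
                 window = as.integer(window)),
            class = "screening_policy")
}

#' Relative risk putting an age at the eligibility threshold
#'
#' Solves for r* such that the `window`-year absolute risk from `age` at
#' relative risk r* equals the threshold t:
#' `age_conditional_risk(table, age, age + window, r*) = t`.
#' The risk is continuous and strictly increasing in r*, so the root is
#' bracketed and found to within 1e-10 on the risk scale.
#'
#' Ages whose risk exceeds t even as rr -> 0 are "always eligible" (returns
#' 0); ages that cannot reach t at rr = 1000 are "never eligible" (returns
#' `Inf`). These sentinels make every threshold representable without
#' numeric failure.
#'
#' @param table a [rate_table()].
#' @param age integer starting age.
#' @param threshold absolute-risk threshold t in (0, 1).
#' @param window risk window in years.
#' @return positive scalar r*, or 0 / `Inf` sentinels as above.
#' @export
threshold_rr_for_age <- function(table, age, threshold, window = 10L) {
  stopifnot(inherits(table, "rate_table"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  end_age <- age + as.integer(window)
  f <- function(rr) age_conditional_risk(table, age, end_age, rr = rr) - threshold
  lo <- 1e-6
  hi <- 1e3
  if (f(lo) >= 0) return(0)      # always eligible at this age
  if (f(hi) <= 0) return(Inf)    # never eligible at this age
  root <- stats::uniroot(f, interval = c(lo, hi), tol = 1e-13)$root
  # polish until within 1e-10 on the risk scale (Newton on log rr)
  for (k in 1:50) {
    err <- f(root)
    if (abs(err) <= 1e-10) break
    d <- (f(root * (1 + 1e-7)) - err) / (root * 1e-7)
    root <- root - err / d
  }
  root
}

# Per-band eligibility fractions under a personalised policy: for each age a,
# r*(a) and the population / case fractions above it.
band_eligibility <- function(table, model, ages, threshold, window) {
  rstar <- vapply(ages, function(a) {
    threshold_rr_for_age(table, a, threshold, window = window)
  }, numeric(1))
  frac <- function(fun, r) {
    if (r == 0) 1 else if (is.infinite(r)) 0 else fun(model, r)
  }
  data.frame(
    age = ages,
    rstar = rstar,
    pop_eligible = vapply(rstar, function(r) {
      frac(population_fraction_above, r)
    }, numeric(1)),
    case_eligible = vapply(rstar, function(r) {
      frac(case_fraction_above, r)
    }, numeric(1))
  )
}

#' Eligible population and screen-detectable case fractions for a policy
#'
#' Age-based: the fraction of the age-range population at or above the cutoff
#' and the fraction of observed cases arising there. Personalised: per band
#' a, r*(a) from [threshold_rr_for_age()]; the eligible population fraction
#' weights [population_fraction_above()] by band population N(a), and the
#' detectable-case fraction weights [case_fraction_above()] by observed band
#' case counts C(a). "Potentially screen-detectable" means exactly: an
#' incident case arising in the eligible subgroup (no screening-sensitivity
#' model).
#'
#' @param table a [rate_table()].
#' @param model a [polygenic_model()] (ignored for age-based policies).
#' @param policy a [screening_policy()].
#' @return a `strategy_summary` list: `eligible_fraction`,
#'   `detectable_case_fraction`.
#' @export
strategy_summary <- function(table, model, policy) {
  stopifnot(inherits(table, "rate_table"), inherits(policy, "screening_policy"))
  ages <- policy$age_range[1]:policy$age_range[2]
  i <- band_index(table, ages)
  N <- table$population[i]
  C <- table$cancer_cases[i]
  if (policy$kind == "age_based") {
    sel <- ages >= policy$age_cutoff
    out <- list(eligible_fraction = sum(N[sel]) / sum(N),
                detectable_case_fraction = sum(C[sel]) / sum(C))
  } else {
    stopifnot(inherits(model, "polygenic_model"))
    el <- band_eligibility(table, model, ages, policy$risk_threshold,
                           policy$window)
    out <- list(eligible_fraction = sum(N * el$pop_eligible) / sum(N),
                detectable_case_fraction = sum(C * el$case_eligible) / sum(C))
  }
  structure(out, class = "strategy_summary")
}

#' @export
print.strategy_summary <- function(x, ...) {
  cat(sprintf("eligible: %.1f%% of population; %.1f%% of cases potentially screen-detectable\n",
              100 * x$eligible_fraction, 100 * x$detectable_case_fraction))
  invisible(x)
}

#' Reclassification of population and cases between strategies
#'
#' Cross-tabulates eligibility under an age-based and a personalised policy
#' (which must share `age_range` and `window`): a 2x2 table for population
#' counts and one for case counts, each scaled to a standard population of
#' 100,000 over the age range (cases become cases per 100,000 population).
#' Internal arithmetic is unrounded; rounding to integers happens only in
#' the print method.
#'
#' @param table a [rate_table()].
#' @param model a [polygenic_model()].
#' @param age_policy an age-based [screening_policy()].
#' @param risk_policy a personalised [screening_policy()].
#' @return a `reclassification` object: matrices `population` and `cases`
#'   (rows: below / at-or-above risk threshold; columns: below / at-or-above
#'   age cutoff), plus the two policies.
#' @export
reclassification <- function(table, model, age_policy, risk_policy) {
  stopifnot(inherits(age_policy, "screening_policy"),
            age_policy$kind == "age_based",
            inherits(risk_policy, "screening_policy"),
            risk_policy$kind == "personalised")
  if (!identical(age_policy$age_range, risk_policy$age_range) ||
      age_policy$window != risk_policy$window) {
    stop("policies must share age_range and window")
  }
  ages <- age_policy$age_range[1]:age_policy$age_range[2]
  i <- band_index(table, ages)
  N <- table$population[i]
  C <- table$cancer_cases[i]
  el <- band_eligibility(table, model, ages, risk_policy$risk_threshold,
                         risk_policy$window)
  old <- ages >= age_policy$age_cutoff
  scale <- 1e5 / sum(N)
  cell <- function(w, frac, col_sel) sum(w[col_sel] * frac[col_sel]) * scale
  dims <- list(risk = c("below_threshold", "at_or_above_threshold"),
               age = c("below_cutoff", "at_or_above_cutoff"))
  pop <- matrix(c(cell(N, 1 - el$pop_eligible, !old),
                  cell(N, el$pop_eligible, !old),
                  cell(N, 1 - el$pop_eligible, old),
                  cell(N, el$pop_eligible, old)),
                2, 2, dimnames = dims)
  cas <- matrix(c(cell(C, 1 - el$case_eligible, !old),
                  cell(C, el$case_eligible, !old),
                  cell(C, 1 - el$case_eligible, old),
                  cell(C, el$case_eligible, old)),
                2, 2, dimnames = dims)
  structure(list(population = pop, cases = cas,
                 age_policy = age_policy, risk_policy = risk_policy),
            class = "reclassification")
}

#' @export
print.reclassification <- function(x, ...) {
  fmt <- function(m, label) {
    m <- cbind(m, total = rowSums(m))
    m <- rbind(m, total = colSums(m))
    cat(label, "(per 100,000 population, rounded):\n")
    print(round(m))
  }
  cat(sprintf("Reclassification: age cutoff %d vs %.3g%% %d-year risk, ages %d-%d\n",
              x$age_policy$age_cutoff, 100 * x$risk_policy$risk_threshold,
              x$risk_policy$window, x$age_policy$age_range[1],
              x$age_policy$age_range[2]))
  fmt(x$population, "Population")
  fmt(x$cases, "Cases")
  invisible(x)
}

#' Eligibility and case detection across risk thresholds
#'
#' [strategy_summary()] for a personalised policy at each threshold. Both
#' reported fractions are non-increasing in the threshold, and for
#' sigma2 > 0 the detectable-case fraction always exceeds the eligible
#' fraction (cases are enriched at high polygenic risk).
#'
#' @param table a [rate_table()].
#' @param model a [polygenic_model()].
#' @param age_range inclusive integer age range.
#' @param thresholds vector of absolute-risk thresholds in (0, 1).
#' @param window risk window in years.
#' @return data.frame `threshold`, `eligible_fraction`,
#'   `detectable_case_fraction`.
#' @export
threshold_sweep <- function(table, model, age_range, thresholds,
                            window = 10L) {
  rows <- lapply(thresholds, function(t) {
    s <- strategy_summary(table, model,
                          screening_policy("personalised", age_range,
                                           risk_threshold = t,
                                           window = window))
    data.frame(threshold = t, eligible_fraction = s$eligible_fraction,
               detectable_case_fraction = s$detectable_case_fraction)
  })
  do.call(rbind, rows)
}

#' Personalised threshold matching an age-based policy
#'
#' Finds the absolute-risk threshold t at which the personalised strategy
#' screens the same population fraction (`match = "eligible_population"`) or
#' captures the same case fraction (`match = "detected_cases"`) as the given
#' age-based policy. The matched fraction is continuous and strictly
#' decreasing in t (for sigma2 > 0), so bisection converges; the returned t
#' reproduces the target fraction to within 1e-6.
#'
#' @param table a [rate_table()].
#' @param model a [polygenic_model()].
#' @param age_policy an age-based [screening_policy()].
#' @param match which margin to equate.
#' @return threshold t in (0, 1).
#' @export
matched_threshold <- function(table, model, age_policy,
                              match = c("eligible_population",
                                        "detected_cases")) {
  match <- match.arg(match)
  stopifnot(inherits(age_policy, "screening_policy"),
            age_policy$kind == "age_based")
  target <- strategy_summary(table, NULL, age_policy)
  target <- if (match == "eligible_population") {
    target$eligible_fraction
  } else {
    target$detectable_case_fraction
  }
  value_at <- function(t) {
    s <- strategy_summary(table, model,
                          screening_policy("personalised",
                                           age_policy$age_range,
                                           risk_threshold = t,
                                           window = age_policy$window))
    if (match == "eligible_population") s$eligible_fraction else
      s$detectable_case_fraction
  }
  lo <- 1e-8
  hi <- 0.999
  f_lo <- value_at(lo) - target
  f_hi <- value_at(hi) - target
  if (f_lo < 0 || f_hi > 0) {
    stop(sprintf(
      "target fraction %.6f unattainable: personalised %s spans [%.6f, %.6f]",
      target, match, f_hi + target, f_lo + target))
  }
  for (k in 1:80) {
    mid <- (lo + hi) / 2
    fm <- value_at(mid) - target
    if (abs(fm) <= 1e-7) break
    if (fm > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Eligibility savings as known polygenic variance grows
#'
#' Best-case analysis: for each fraction f of the total predicted polygenic
#' variance assumed known, build a model with sigma2 = f * total, solve for
#' the threshold matching the age-based policy on detected cases, and report
#' the relative reduction in the eligible population. With no variance known
#' the strategies coincide (zero reduction); the reduction grows with f as
#' more variance concentrates the cases in fewer people.
#'
#' @param table a [rate_table()].
#' @param total_variance total predicted polygenic variance (> 0).
#' @param fractions vector of fractions in (0, 1].
#' @param age_policy an age-based [screening_policy()]; supplies age range
#'   and window.
#' @return data.frame `fraction_known`, `sigma2`, `matched_threshold`,
#'   `eligible_fraction`, `relative_reduction_eligible` (vs the age-based
#'   eligible fraction, at equal case detection).
#' @export
variance_fraction_sweep <- function(table, total_variance, fractions,
                                    age_policy) {
  stopifnot(total_variance > 0, all(fractions > 0 & fractions <= 1))
  base <- strategy_summary(table, NULL, age_policy)
  rows <- lapply(fractions, function(f) {
    model <- polygenic_model(f * total_variance)
    t_star <- matched_threshold(table, model, age_policy,
                                match = "detected_cases")
    s <- strategy_summary(table, model,
                          screening_policy("personalised",
                                           age_policy$age_range,
                                           risk_threshold = t_star,
                                           window = age_policy$window))
    data.frame(fraction_known = f, sigma2 = f * total_variance,
               matched_threshold = t_star,
               eligible_fraction = s$eligible_fraction,
               relative_reduction_eligible =
                 1 - s$eligible_fraction / base$eligible_fraction)
  })
  do.call(rbind, rows)
}
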