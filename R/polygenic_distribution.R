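#' Log-normal polygenic relative-risk model
#'
#' Population distribution of polygenic relative risk RR at birth:
#' log RR ~ Normal(mu, sigma2) with mu = -sigma2/2, so that E[RR] = 1.
#' Among cases (size-biased sampling) the log-risk distribution has the same
#' variance but is shifted right by sigma2. The degenerate case sigma2 = 0
#' (point mass at RR = 1) is supported; under it personalised screening
#' collapses to age-based screening.
#'
#' @param sigma2 variance of log relative risk, >= 0.
#' @return a `polygenic_model` with elements `sigma2`, `sigma` and `mu`.
#' @examples
#' m <- polygenic_model(0.377)
#' population_fraction_above(m, 1)  # ~0.379
#' case_fraction_above(m, 1)        # ~0.621
#' @export
polygenic_model <- function(sigma2) {
  if (!is.finite(sigma2) || sigma2 < 0) stop("sigma2 must be >= 0")
  structure(list(sigma2 = sigma2, sigma = sqrt(sigma2), mu = -sigma2 / 2),
            class = "polygenic_model")
}

#' @export
print.polygenic_model <- function(x, ...) {
  cat(sprintf("<polygenic_model> log RR ~ N(mu = %.5f, sigma2 = %.5f); E[RR] = 1\n",
              x$mu, x$sigma2))
  invisible(x)
}

check_rr <- function(rr) {
  if (any(!is.finite(rr) | rr <= 0)) stop("relative-risk threshold must be > 0")
}

#' Fraction of the population above a relative-risk threshold
#'
#' P(RR > r) under the population (birth) distribution,
#' \eqn{1 - \Phi((\ln r - \mu)/\sigma)}. For `sigma2 = 0` the distribution is
#' a point mass at 1: the fraction is 1 for r <= 1 and 0 otherwise.
#'
#' @param model a [polygenic_model()].
#' @param rr_threshold positive threshold(s) on the relative-risk scale.
#' @return proportion(s) in [0, 1].
#' @export
population_fraction_above <- function(model, rr_threshold) {
  stopifnot(inherits(model, "polygenic_model"))
  check_rr(rr_threshold)
  if (model$sigma2 == 0) return(as.numeric(rr_threshold <= 1))
  stats::pnorm((log(rr_threshold) - model$mu) / model$sigma, lower.tail = FALSE)
}

#' Fraction of cases above a relative-risk threshold
#'
#' P(RR > r) among incident cases. Cases are a size-biased sample of the
#' population (density r f(r) / E[RR]), which for a log-normal shifts the
#' log-scale mean right by sigma2:
#' \eqn{1 - \Phi((\ln r - \mu - \sigma^2)/\sigma)}.
#'
#' @inheritParams population_fraction_above
#' @return proportion(s) in [0, 1]; always >= the population fraction.
#' @export
case_fraction_above <- function(model, rr_threshold) {
  stopifnot(inherits(model, "polygenic_model"))
  check_rr(rr_threshold)
  if (model$sigma2 == 0) return(as.numeric(rr_threshold <= 1))
  stats::pnorm((log(rr_threshold) - model$mu - model$sigma2) / model$sigma,
               lower.tail = FALSE)
}

#' Relative-risk quantile in the population or among cases
#'
#' Inverse of the corresponding cumulative distribution; round-trips with
#' the fraction-above operations.
#'
#' @param model a [polygenic_model()].
#' @param q probability level(s) in (0, 1).
#' @param which "population" (birth distribution) or "cases" (size-biased).
#' @return positive relative risk(s).
#' @export
rr_quantile <- function(model, q, which = c("population", "cases")) {
  stopifnot(inherits(model, "polygenic_model"))
  which <- match.arg(which)
  if (any(!is.finite(q) | q <= 0 | q >= 1)) stop("q must lie in (0, 1)")
  if (model$sigma2 == 0) return(rep(1, length(q)))
  shift <- if (which == "cases") model$sigma2 else 0
  exp(model$mu + shift + model$sigma * stats::qnorm(q))
}
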