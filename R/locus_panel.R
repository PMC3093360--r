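#' Per-locus contribution to polygenic variance
#'
#' Variance of log relative risk contributed by one biallelic susceptibility
#' locus under Hardy-Weinberg equilibrium and a log-additive model:
#' \eqn{2 p (1-p) [\ln \mathrm{OR}]^2}, where \eqn{p} is the risk-allele
#' frequency and OR the per-allele odds ratio (treated as a relative risk;
#' the diseases modelled are rare per year of age).
#'
#' The value is invariant under allele relabelling: \eqn{(p, \mathrm{OR})}
#' and \eqn{(1-p, 1/\mathrm{OR})} give the same variance, so protective
#' alleles (OR < 1) need no flipping.
#'
#' @param risk_allele_freq risk-allele frequency in (0, 1); vectorised.
#' @param or_per_allele per-allele odds ratio, > 0; vectorised.
#' @param rsid optional identifiers used in validation error messages.
#' @param x_linked logical; with `hemizygous = TRUE`, marks loci to score as
#'   male-hemizygous (one allele copy), contributing \eqn{p(1-p)[\ln OR]^2}.
#' @param hemizygous if TRUE, apply the hemizygous formula to `x_linked`
#'   loci; default FALSE scores every locus biallelically.
#' @return numeric vector of non-negative variance contributions.
#' @examples
#' locus_variance(0.94, 1.30)  # 0.00776, rounds to 0.008
#' @export
locus_variance <- function(risk_allele_freq, or_per_allele, rsid = NULL,
                           x_linked = FALSE, hemizygous = FALSE) {
  p <- risk_allele_freq
  or <- or_per_allele
  if (is.null(rsid)) rsid <- paste0("locus ", seq_along(p))
  bad_p <- !is.finite(p) | p <= 0 | p >= 1
  if (any(bad_p)) {
    stop("risk_allele_freq must lie in (0, 1); offending: ",
         paste(rsid[bad_p], collapse = ", "))
  }
  bad_or <- !is.finite(or) | or <= 0
  if (any(bad_or)) {
    stop("or_per_allele must be > 0; offending: ",
         paste(rsid[bad_or], collapse = ", "))
  }
  copies <- ifelse(hemizygous & x_linked, 1, 2)
  copies * p * (1 - p) * log(or)^2
}

#' Total polygenic variance of a susceptibility panel
#'
#' Sum of [locus_variance()] over all loci, assuming independence (linkage
#' equilibrium) between loci. This is the \eqn{\sigma^2} parameter of the
#' log-normal population risk distribution ([polygenic_model()]).
#'
#' @param panel a `locus_panel` from [load_panel()] or [locus_panel()].
#' @param x_linked_hemizygous if TRUE, X-linked loci contribute
#'   \eqn{p(1-p)[\ln OR]^2} (male hemizygotes carry one allele copy);
#'   default FALSE treats all loci biallelically.
#' @return non-negative scalar variance on the log relative-risk scale.
#' @export
panel_variance <- function(panel, x_linked_hemizygous = FALSE) {
  stopifnot(inherits(panel, "locus_panel"))
  if (nrow(panel) == 0L) stop("empty panel")
  sum(locus_variance(panel$risk_allele_freq, panel$or_per_allele,
                     rsid = panel$rsid,
                     x_linked = panel$chromosome_class == "x_linked",
                     hemizygous = x_linked_hemizygous))
}

#' Fraction of familial risk explained by known variants
#'
#' Ratio of the log-scale polygenic variance attributable to known variants
#' to the total predicted polygenic variance. Under the log-normal polygenic
#' model this equals the fraction of the log familial relative risk explained.
#'
#' @param known_variance variance from known susceptibility loci (>= 0).
#' @param total_variance total predicted polygenic variance (> 0).
#' @return proportion in [0, 1].
#' @examples
#' familial_risk_fraction(0.377, 1.58)  # ~0.239
#' @export
familial_risk_fraction <- function(known_variance, total_variance) {
  if (!is.finite(total_variance) || total_variance <= 0) {
    stop("total_variance must be > 0")
  }
  if (!is.finite(known_variance) || known_variance < 0) {
    stop("known_variance must be >= 0")
  }
  if (known_variance > total_variance) {
    stop("known_variance exceeds total_variance")
  }
  known_variance / total_variance
}

#' Construct a susceptibility-locus panel
#'
#' @param loci data.frame with columns `rsid`, `locus`, `risk_allele_freq`,
#'   `or_per_allele` and optionally `chromosome_class` ("autosomal" or
#'   "x_linked"; defaults to autosomal).
#' @param cancer panel label, e.g. "prostate", "breast" or "custom".
#' @return a `locus_panel`: a validated data.frame with a `cancer` attribute.
#' @export
locus_panel <- function(loci, cancer = "custom") {
  required <- c("rsid", "locus", "risk_allele_freq", "or_per_allele")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols)) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(loci) == 0L) stop("empty panel")
  if (is.null(loci$chromosome_class)) loci$chromosome_class <- "autosomal"
  if (!all(loci$chromosome_class %in% c("autosomal", "x_linked"))) {
    stop("chromosome_class must be 'autosomal' or 'x_linked'")
  }
  dup <- loci$rsid[duplicated(loci$rsid)]
  if (length(dup)) {
    stop("duplicate rsid in panel: ", paste(unique(dup), collapse = ", "))
  }
  bad <- which(!is.finite(loci$risk_allele_freq) |
                 loci$risk_allele_freq <= 0 | loci$risk_allele_freq >= 1 |
                 !is.finite(loci$or_per_allele) | loci$or_per_allele <= 0)
  if (length(bad)) {
    stop("invalid risk_allele_freq or or_per_allele at rows ",
         paste(bad, collapse = ", "), " (rsid: ",
         paste(loci$rsid[bad], collapse = ", "), ")")
  }
  out <- loci[, c(required, "chromosome_class")]
  attr(out, "cancer") <- cancer
  class(out) <- c("locus_panel", "data.frame")
  out
}

#' Load a susceptibility panel from CSV
#'
#' Expects header `rsid,locus,risk_allele_freq,or_per_allele` with an optional
#' `chromosome_class` column. Two transcribed panels ship with the package:
#' `prostate_31.csv` (31 loci) and `breast_18.csv` (18 loci), available via
#' `system.file("extdata", ..., package = "prscreen")`.
#'
#' @param path path to a CSV file.
#' @param cancer panel label; defaults to the file name stem.
#' @return a `locus_panel`.
#' @export
load_panel <- function(path, cancer = sub("\\.csv$", "", basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  locus_panel(df, cancer = cancer)
}

#' @export
print.locus_panel <- function(x, ...) {
  v <- locus_variance(x$risk_allele_freq, x$or_per_allele, rsid = x$rsid)
  cat(sprintf("<locus_panel> %s: %d loci, recomputed polygenic variance %.5f\n",
              attr(x, "cancer"), nrow(x), sum(v)))
  cat("(per-locus variances recomputed as 2p(1-p)ln(OR)^2 from p and OR;\n",
      " published per-locus variance columns are not loaded)\n", sep = "")
  invisible(x)
}

#' Round half away from zero for display
#'
#' Display rounding used for per-locus variance tables (3 decimal places,
#' ties away from zero), matching the convention of published panels.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 3).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
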