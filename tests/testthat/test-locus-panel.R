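# Expected per-locus variances frozen from an independent recomputation of
# 2p(1-p)ln(OR)^2 (hand/SciPy), not from the code under test.
worked_loci <- data.frame(
  rsid = c("rs12621278", "rs1465618", "rs1045485", "rs2981582", "rs2046210"),
  p = c(0.94, 0.23, 0.85, 0.38, 0.36),
  or = c(1.30, 1.08, 1.14, 1.26, 1.29),
  variance = c(0.0077646, 0.0020979, 0.0043779, 0.0251680, 0.0298795),
  display = c(0.008, 0.002, 0.004, 0.025, 0.030)
)

test_that("per-locus variance reproduces worked examples and display rounding", {
  v <- locus_variance(worked_loci$p, worked_loci$or, rsid = worked_loci$rsid)
  expect_equal(v, worked_loci$variance, tolerance = 1e-4)
  expect_identical(round_half_away(v, 3), worked_loci$display)
  expect_equal(locus_variance(0.3, 1.0), 0)  # null effect, no variance
})

test_that("locus variance is relabelling-invariant and maximal at p = 0.5", {
  set.seed(11)
  p <- runif(50, 0.01, 0.99)
  or <- exp(runif(50, -0.5, 0.8))
  expect_equal(locus_variance(p, or), locus_variance(1 - p, 1 / or))
  for (o in c(0.9, 1.1, 1.3, 2)) {
    expect_true(all(locus_variance(0.5, o) >= locus_variance(p, o)))
  }
})

test_that("locus variance validation names the offending locus", {
  expect_error(locus_variance(1.2, 1.1, rsid = "rsBAD"), "rsBAD")
  expect_error(locus_variance(0.5, -1, rsid = "rsNEG"), "rsNEG")
})

test_that("panel variance is additive over any partition", {
  set.seed(42)
  n <- 12
  df <- data.frame(rsid = paste0("rs", 1:n), locus = "chr",
                   risk_allele_freq = runif(n, 0.05, 0.95),
                   or_per_allele = exp(rnorm(n, 0.1, 0.1)))
  full <- panel_variance(locus_panel(df))
  for (k in c(1, 5, 11)) {
    split_sum <- panel_variance(locus_panel(df[1:k, , drop = FALSE])) +
      panel_variance(locus_panel(df[(k + 1):n, , drop = FALSE]))
    expect_equal(split_sum, full, tolerance = 1e-12)
  }
})

test_that("packaged panels load with published sizes; variances recompute from p and OR", {
  pros <- load_panel(extdata("prostate_31.csv"), cancer = "prostate")
  brst <- load_panel(extdata("breast_18.csv"), cancer = "breast")
  expect_equal(nrow(pros), 31L)
  expect_equal(nrow(brst), 18L)
  # independent recomputation (SciPy): 0.38881 and 0.13844
  expect_equal(panel_variance(pros), 0.38881, tolerance = 1e-4)
  expect_equal(panel_variance(brst), 0.13844, tolerance = 1e-4)
})

test_that("the X-linked locus can be scored hemizygously via the config flag", {
  pros <- load_panel(extdata("prostate_31.csv"), cancer = "prostate")
  xrow <- pros[pros$chromosome_class == "x_linked", ]
  expect_equal(xrow$rsid, "rs5945619")
  v_x <- locus_variance(xrow$risk_allele_freq, xrow$or_per_allele)
  expect_equal(panel_variance(pros) - panel_variance(pros, x_linked_hemizygous = TRUE),
               v_x / 2, tolerance = 1e-12)
})

test_that("panel loading rejects malformed input with informative errors", {
  df <- data.frame(rsid = c("rs1", "rs1"), locus = "x",
                   risk_allele_freq = c(0.2, 0.3), or_per_allele = c(1.1, 1.2))
  expect_error(locus_panel(df), "rs1")
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("rsid,locus,risk_allele_freq,or_per_allele", tmp)
  expect_error(load_panel(tmp), "empty panel")
  df2 <- data.frame(rsid = c("rs1", "rs2"), locus = "x",
                    risk_allele_freq = c(0.2, 1.3), or_per_allele = c(1.1, 1.2))
  expect_error(locus_panel(df2), "rs2")
})

test_that("familial risk fraction is the variance ratio with guarded domain", {
  expect_equal(familial_risk_fraction(0.377, 1.58), 0.2386076, tolerance = 1e-6)
  expect_equal(familial_risk_fraction(0, 5), 0)
  expect_equal(familial_risk_fraction(0.7, 0.7), 1)
  expect_error(familial_risk_fraction(0.1, 0), "> 0")
  expect_error(familial_risk_fraction(1.2, 1.0), "exceeds")
})
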