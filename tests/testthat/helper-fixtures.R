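# Shared fixtures, built in code.

extdata <- function(f) system.file("extdata", f, package = "prscreen")

# 3-band toy table with hazards lambda_c = (.01,.02,.03), lambda_o = (.005,.01,.02)
toy_table <- function() {
  rate_table(data.frame(
    age = 50:52,
    population = 1e6,
    cancer_cases = c(10000, 20000, 30000),
    cancer_deaths = c(1000, 2000, 3000),
    all_cause_deaths = c(6000, 12000, 23000)
  ))
}

# single band [50, 51) with lambda_c = lc and lambda_o = lo
one_band_table <- function(lc = 0.02, lo = 0) {
  rate_table(data.frame(
    age = 50, population = 1e6,
    cancer_cases = round(lc * 1e6),
    cancer_deaths = 0,
    all_cause_deaths = round(lo * 1e6)
  ))
}

# flat table: w identical bands, no other-cause mortality
flat_table <- function(lc = 0.002, w = 10, age0 = 50) {
  rate_table(data.frame(
    age = age0 + seq_len(w) - 1,
    population = 1e6,
    cancer_cases = round(lc * 1e6),
    cancer_deaths = 0,
    all_cause_deaths = 0
  ))
}

prostate_rates <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- load_rate_table(extdata("synthetic_prostate_rates.csv"),
                              cancer = "prostate", sex = "male")
    }
    tab
  }
})

breast_rates <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- load_rate_table(extdata("synthetic_breast_rates.csv"),
                              cancer = "breast", sex = "female")
    }
    tab
  }
})
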