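# Small builders shared across test files.

# Two-group structure with simple rates, for focused demography tests.
two_groups <- function(m = c(0.1, 0.05), r = c(0, 2)) {
  make_age_groups(c(0L, 60L), m, r)
}

tiny_nest <- function(nest_id = "t1", counts = c(5, 5), season = 1:12, ...) {
  nest_config(nest_id, species = "test", age_groups = two_groups(),
              initial_counts = counts, reproductive_season = season, ...)
}

# A flat exposure series of given length/value.
const_series <- function(value, days, pesticide = "px", nest_id = "t1") {
  exposure_series(nest_id, pesticide, rep(value, days))
}

# Independent-cause mortality oracle by inclusion-exclusion over cause subsets;
# independent of the survival-product implementation it checks.
mortality_by_inclusion_exclusion <- function(rates) {
  n <- length(rates)
  if (n == 0) return(0)
  total <- 0
  for (mask in 1:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    total <- total + (-1)^(length(sel) + 1) * prod(rates[sel])
  }
  total
}
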