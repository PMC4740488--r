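# Closed-form oracles, written independently of the package internals, used
# to freeze expected values for the simulation paths they check.

# odds-scale favorable-probability transform
oracle_adjust <- function(p, or) {
  o <- or * p / (1 - p)
  o / (1 + o)
}

# band probabilities of treatment-start time for a uniform onset over
# `sleep` minutes plus a fixed delay, bands (0,180], (180,270], tail
oracle_uniform_bands <- function(sleep, delay = 158, edges = c(180, 270)) {
  cdf <- pmin(pmax((edges - delay) / sleep, 0), 1)
  diff(c(0, cdf, 1))
}

# expected mRS0-1 share under the MRI strategy: band-weighted mixture of
# treated (OR-adjusted) and untreated favorable probabilities
oracle_favorable_share <- function(sleep, p0 = 0.451, se = 0.62, sp = 0.78,
                                   ors = c(1.75, 1.26, 1.00)) {
  b <- oracle_uniform_bands(sleep)
  treated_frac <- c(se, se, 1 - sp) # bands 1-2 eligible, tail ineligible
  sum(b * (treated_frac * oracle_adjust(p0, ors) + (1 - treated_frac) * p0))
}

# discounted annuity: sum_{t=1..H} (1+r)^-t
oracle_annuity <- function(H, r) sum((1 + r)^-(1:H))

# parameters tuned for fast deterministic lifetime checks: no background
# mortality, no recurrence unless re-enabled by the caller
params_no_mortality <- function() {
  p <- default_parameters()
  p$life_table <- list(source = "makeham", a = 0, b = 0, c = 1.1,
                       male_multiplier = 1, female_multiplier = 1)
  p$progression$annual_recurrent_stroke_prob <- 0
  p
}
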