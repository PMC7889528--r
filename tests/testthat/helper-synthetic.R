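# Shared fixture builders. Short ramps and small rasters keep unit tests
# quick; acceptance tests use the full study conditions.

short_profile <- function(rate = 1, capture_interval = 5,
                          start_temp = 10, end_temp = -28) {
  cooling_profile(start_temp, end_temp, rate = rate,
                  capture_interval = capture_interval)
}

default_lag <- function(volume = 20) thermal_lag(volume = volume)

random_frame <- function(dims = c(16, 16)) {
  array(sample(0:255, prod(dims) * 3, replace = TRUE), c(dims, 3))
}

bimodal_gray <- function(dims = c(24, 24), lo = 60, hi = 180, sd = 12) {
  n <- prod(dims)
  centers <- sample(c(lo, hi), n, replace = TRUE)
  matrix(pmax(0L, pmin(255L, as.integer(round(centers + rnorm(n, 0, sd))))),
         dims[1], dims[2])
}
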