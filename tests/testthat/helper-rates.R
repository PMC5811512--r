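# Random rate sets: each rate drawn as 10^U(-1, 1), one decade around 1.
random_rate_set <- function(m = 1L, min_log = -1, max_log = 1) {
  v <- 10^stats::runif(4, min_log, max_log)
  rate_set(v[1], v[2], v[3], v[4], m = m)
}

# Closed-form open probability for rates (3, 0, 1, 1), m = 1, all channels
# initially closed: eigenvalues {0, -2, -3}.
o_3011 <- function(t) (1 + 3 * exp(-2 * t) - 4 * exp(-3 * t)) / 2
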