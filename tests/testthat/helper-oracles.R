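# Independent oracles used across the suite. These re-derive expected
# values by brute-force bookkeeping or closed forms, never by calling the
# code paths they check.

# Discrete Bloch recursion for the look-locker readout: saturate, relax
# for the effective saturation delay, then alternate alpha-pulse
# projection and TR relaxation, recording the transverse signal at each
# pulse.
bloch_ll_oracle <- function(r1, s0, protocol) {
  a <- protocol$flip_angle * pi / 180
  relax <- function(mz, t) 1 - (1 - mz) * exp(-r1 * t)
  mz <- relax(0, effective_td(protocol))
  s <- numeric(protocol$n_phases)
  for (n in seq_len(protocol$n_phases)) {
    s[n] <- s0 * sin(a) * mz
    mz <- relax(mz * cos(a), protocol$tr)
  }
  s
}

# Three-segment magnetization bookkeeping for the background-suppressed
# control signal: saturate, relax to BS1, invert, relax to BS2, invert,
# relax to the readout delay.
bloch_bs_oracle <- function(r1, protocol, slice_index = 0) {
  relax <- function(mz, t) 1 - (1 - mz) * exp(-r1 * t)
  mz <- relax(0, protocol$bs1)
  mz <- relax(-mz, protocol$bs2 - protocol$bs1)
  relax(-mz, readout_td(protocol, slice_index) - protocol$bs2)
}

# Closed-form OLS of y on x from raw sums (normal equations).
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  e <- y - intercept - slope * x
  se <- sqrt(sum(e^2) / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept,
       r_squared = stats::cor(x, y)^2,
       p_value = 2 * stats::pt(-abs(tval), n - 2))
}

# Closed-form paired t-test p-value from the t CDF.
paired_t_oracle <- function(d) {
  n <- length(d)
  tval <- mean(d) / (stats::sd(d) / sqrt(n))
  2 * stats::pt(-abs(tval), n - 1)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
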