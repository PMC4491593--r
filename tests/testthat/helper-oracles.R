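# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# Exact mean discriminability of the sum-threshold model at overlap O:
# shared sum + two independent unshared sums, categories compared, all
# probabilities from the binomial pmf.
oracle_microbe_fraction <- function(O, N = 30) {
  n <- N - O
  ps <- stats::dbinom(0:O, O, 0.5)
  svals <- 2 * (0:O) - O
  pu <- stats::dbinom(0:n, n, 0.5)
  uvals <- 2 * (0:n) - n
  sum(vapply(seq_along(svals), function(i) {
    tot <- svals[i] + uvals
    cat3 <- ifelse(tot > 2, 1L, ifelse(tot < -2, -1L, 0L))
    pc <- tapply(pu, cat3, sum)
    ps[i] * (1 - sum(pc^2))
  }, numeric(1)))
}

# Crossing overlap of the exact curve at a level, linear interpolation
# on the integer grid.
oracle_microbe_crossing <- function(N = 30, level = 0.5) {
  v <- vapply(0:N, oracle_microbe_fraction, numeric(1), N = N)
  i <- max(which(v >= level))
  (i - 1) + (v[i] - level) / (v[i] - v[i + 1])
}

# Brute-force Hamming-ball volume: enumerate every N-subset of C and
# count those within replacement distance R of the reference subset 1..N.
oracle_ball_volume_bruteforce <- function(C, N, R) {
  subsets <- utils::combn(C, N)
  ref <- seq_len(N)
  as.double(sum(apply(subsets, 2, function(s) length(setdiff(s, ref)) <= R)))
}

# Single-trial odd-man-out accuracy on a line (valid for the ring when
# sigma << 2*pi so wrap-around is negligible): straight Monte-Carlo,
# written independently of the package's decision code.
oracle_line_omo_p <- function(separation, sigma, n = 2e5) {
  a <- stats::rnorm(n, 0, sigma)
  b <- stats::rnorm(n, 0, sigma)
  s <- separation + stats::rnorm(n, 0, sigma)
  mean(abs(a - b) < abs(a - s) & abs(a - b) < abs(b - s))
}
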