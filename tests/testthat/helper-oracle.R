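# Independent brute-force oracle for the race model.
#
# A response is emitted on a stop trial iff the go finishing time beats
# SSD + stop latency. Writing each finishing time as Gaussian + exponential,
# the Gaussian parts collapse into one normal difference, so
#   p(respond | ssd = d) = E_{Eg, Es}[ Phi(d + Es - Eg; mu_d, sd_d) ]
# with Eg, Es the two exponential components. The expectation is taken by
# trapezoidal quadrature on a wide grid; only base dnorm/pnorm/dexp are
# used, independently of the package's samplers and closed forms.
oracle_p_respond <- function(ssd, go, stop_, n_grid = 2001) {
  mu_d <- go$mu - stop_$mu
  sd_d <- sqrt(go$sigma^2 + stop_$sigma^2)
  grid_of <- function(tau) {
    if (tau == 0) return(list(x = 0, w = 1))
    dx <- 25 * tau / (n_grid - 1)
    x <- seq(dx / 2, 25 * tau, by = dx)  # midpoint rule
    list(x = x, w = dexp(x, rate = 1 / tau) * dx)
  }
  g <- grid_of(go$tau)
  s <- grid_of(stop_$tau)
  vapply(ssd, function(d) {
    # P(Ng - Ns < d + Es - Eg)
    m <- outer(s$x, g$x, function(es, eg) pnorm(d + es - eg, mu_d, sd_d))
    sum((s$w %*% m) * g$w) / (sum(s$w) * sum(g$w))
  }, numeric(1))
}

# brute-force empirical-CDF inversion: smallest order statistic whose
# empirical CDF reaches p (independent cross-check for the rank rule)
oracle_ecdf_rank <- function(n, p) {
  which(seq_len(n) / n >= p - 1e-12)[1L]
}
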