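# Independent numerical oracles used across the suite.

# Monomer concentration by brute-force root solving of the isodesmic mass
# balance L0 = [L]/(1 - Ka*[L])^2 on (0, min(L0, 1/Ka)), independent of the
# closed form used by the package.
oracle_monomer <- function(Ka, L0) {
  if (Ka == 0) return(L0)
  f <- function(L) L / (1 - Ka * L)^2 - L0
  upper <- min(L0, 1 / Ka) * (1 - 1e-12)
  stats::uniroot(f, c(1e-300, upper), tol = 1e-15)$root
}

# Free-duplex concentration by root solving the 1:1 mass balances instead of
# the quadratic formula.
oracle_free_dna <- function(Ka, C_DNA, C_L) {
  if (Ka == 0 || C_DNA == 0) return(C_DNA)
  f <- function(d) Ka * d^2 + (1 + Ka * C_L - Ka * C_DNA) * d - C_DNA
  stats::uniroot(f, c(0, C_DNA), tol = 1e-15)$root
}

# Log-linear half-life estimate: regression of log(fraction) on time.
oracle_loglinear_thalf <- function(data) {
  keep <- data$intact_fraction > 0
  k <- -stats::coef(stats::lm(log(intact_fraction) ~ time_days,
                              data = data[keep, ]))[[2]]
  log(2) / k
}
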