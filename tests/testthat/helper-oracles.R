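# Shared fixtures and independent oracles used across test files.

fish_curve <- function() {
  calibration_curve(0.008, 0.088, 0.095, se = c(0.004, 0.022, 0.009),
                    aberration_class = "dicentric_equivalents")
}

# Expand a count distribution (count -> n cells) into the per-cell vector.
expand_distribution <- function(dist) {
  rep(as.integer(names(dist)), as.integer(dist))
}

# Exact Poisson limits by root-finding on the tail sums themselves:
# lower solves P(K >= x; lambda) = a/2, upper solves P(K <= x; lambda) = a/2.
# Independent of the chi-square quantile identity used by the package.
garwood_oracle <- function(x, confidence = 0.95) {
  a <- 1 - confidence
  upper_max <- max(10, 3 * x + 20)
  lower <- if (x == 0) 0 else {
    stats::uniroot(function(l) 1 - ppois(x - 1, l) - a / 2,
                   c(1e-12, upper_max), tol = 1e-10)$root
  }
  upper <- stats::uniroot(function(l) ppois(x, l) - a / 2,
                          c(1e-12, upper_max), tol = 1e-10)$root
  c(lower = lower, upper = upper)
}

# Poisson LQ log-likelihood written directly from its definition, for
# grid-search and score-equation checks independent of the fitter.
lq_loglik_oracle <- function(theta, D, N, X) {
  lam <- theta[1] + theta[2] * D + theta[3] * D^2
  if (any(lam <= 0 & X > 0) || any(lam < 0)) return(-Inf)
  pos <- X > 0
  sum(X[pos] * log(N[pos] * lam[pos])) - sum(N * lam)
}

# Draw a null preparation-comparison design: the same multinomial spectrum
# in both arms, with dose-dependent composition, and return the Wald p of
# the dicentric dose^2 x G2 interaction.
null_interaction_p <- function() {
  doses <- c(0.5, 1, 3, 5, 7.5)
  a <- c(dicentric_equivalents = 0.0, centric_rings = -2.5,
         acentric_rings = -3.0, compound_fragments = 0.2,
         terminal_fragments = -0.6, interstitial_fragments = -1.2)
  b <- c(dicentric_equivalents = 0.0, centric_rings = 0.01,
         acentric_rings = 0.015, compound_fragments = 0.005,
         terminal_fragments = 0.002, interstitial_fragments = 0.004)
  rows <- list()
  for (donor in c("d1", "d2")) for (g2 in 0:1) for (D in doses) {
    p <- exp(a + b * D^2)
    counts <- as.vector(stats::rmultinom(1, size = 400, prob = p / sum(p)))
    rows[[length(rows) + 1]] <- data.frame(
      dose_gy = D, donor = donor, g2 = g2,
      as.list(stats::setNames(counts, names(a))))
  }
  fit <- fit_spectrum_model(spectrum_design(do.call(rbind, rows)))
  it <- fit$interaction
  it$p[it$category == "dicentric_equivalents"]
}
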