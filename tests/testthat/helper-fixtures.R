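# shared fixtures: the repulsion used throughout the dynamical-transition
# analysis (twice the double-hump threshold) and a few rate tables
VSTAR <- 2 * log(3)
rates_2vstar <- glauber_rates(2 * VSTAR)
rates_v0 <- glauber_rates(0)

random_profile <- function(N, seed = 1) {
  set.seed(seed)
  rho <- stats::runif(N, 0.1, 0.9)
  lo <- pmax(0, rho[-N] + rho[-1] - 1)
  hi <- pmin(rho[-N], rho[-1])
  phi <- lo + (hi - lo) * stats::runif(N - 1, 0.2, 0.8)
  profile_state(rho, phi)
}
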