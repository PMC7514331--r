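test_that("bulk-adapted boundary rates: closed-form V = 0 values and limits", {
  bc <- boundary_conditions(0.5, 0.5, rates_v0)
  br <- boundary_rates(bc)
  expect_equal(br$alpha, c(0.25, 0.25), tolerance = 1e-12)
  expect_equal(br$beta, c(0.25, 0.25), tolerance = 1e-12)
  expect_equal(br$gL, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(br$gR, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(br$hop2, 0.5, tolerance = 1e-12)
  # empty left reservoir injects nothing; full right reservoir blocks exit
  expect_equal(boundary_rates(boundary_conditions(0, 0.5, rates_2vstar))$alpha,
               c(0, 0), tolerance = 1e-9)
  expect_equal(boundary_rates(boundary_conditions(0.5, 1, rates_2vstar))$beta,
               c(0, 0), tolerance = 1e-9)
  # full left reservoir: always a particle behind the injected one
  brL1 <- boundary_rates(boundary_conditions(1, 0.5, rates_2vstar))
  expect_equal(brL1$alpha, unname(rates_2vstar$gamma[2, ]), tolerance = 1e-9)
})

test_that("N = 2 generator reproduces the hand-derived spectrum", {
  gen <- build_generator(2, boundary_conditions(0.5, 0.5, rates_v0))
  ev <- eigen(-as.matrix(gen$Q), only.values = TRUE)$values
  ev <- ev[order(Re(ev))]
  expect_equal(ev[1], 0 + 0i, tolerance = 1e-12)
  expect_equal(sort(Re(ev[2:4])), c(0.25, 0.625, 0.625), tolerance = 1e-12)
  expect_equal(max(abs(Im(ev))), 0.330719, tolerance = 1e-5)
  expect_equal(spectral_gap(gen)$gap, 0.25, tolerance = 1e-12)
})

test_that("generator conservation and stationarity invariants", {
  set.seed(31)
  for (j in 1:6) {
    N <- sample(3:8, 1)
    bc <- boundary_conditions(stats::runif(1, 0.1, 0.9),
                              stats::runif(1, 0.1, 0.9),
                              glauber_rates(stats::runif(1, 0, 4)))
    gen <- build_generator(N, bc)
    expect_lt(max(abs(Matrix::colSums(gen$Q))), 1e-12)
    Qd <- as.matrix(gen$Q)
    expect_true(all(Qd[row(Qd) != col(Qd)] >= 0))
    pi <- stationary_distribution(gen)
    expect_true(all(pi >= 0))
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_lt(max(abs(Qd %*% pi)), 1e-12)
  }
  expect_error(build_generator(25, boundary_conditions(0.5, 0.5, rates_v0)),
               "GiB")
})

test_that("equal reservoirs give an exactly flat finite-size profile", {
  bc <- boundary_conditions(0.5, 0.5, rates_2vstar)
  d <- stationary_densities(build_generator(8, bc))
  expect_lt(max(abs(d - 0.5)), 1e-3)   # in fact machine-flat
  bc3 <- boundary_conditions(0.3, 0.3, rates_2vstar)
  d3 <- stationary_densities(build_generator(6, bc3))
  expect_lt(max(abs(d3 - 0.3)), 1e-12)
})

test_that("stationary state maps onto itself under particle-hole conjugation", {
  # N = 3: occupied/empty exchange plus site reversal maps rho = 0.3 to 0.7
  gA <- build_generator(3, boundary_conditions(0.3, 0.3, rates_2vstar))
  gB <- build_generator(3, boundary_conditions(0.7, 0.7, rates_2vstar))
  piA <- stationary_distribution(gA)
  piB <- stationary_distribution(gB)
  conj <- function(s, N) {
    bits <- as.integer(intToBits(s))[1:N]        # LSB = node N
    sum((1 - rev(bits)) * 2^((N - 1):0))         # flip and reverse
  }
  idx <- vapply(0:7, conj, 0, N = 3) + 1
  expect_equal(piA, piB[idx], tolerance = 1e-12)
})

test_that("spectral gap is particle-hole invariant and solver-independent", {
  bcA <- boundary_conditions(0.2, 0.75, rates_2vstar)
  bcB <- boundary_conditions(0.25, 0.8, rates_2vstar)
  expect_equal(spectral_gap(build_generator(6, bcA))$gap,
               spectral_gap(build_generator(6, bcB))$gap,
               tolerance = 1e-10)
  gen <- build_generator(8, boundary_conditions(0.3, 0.75, rates_2vstar))
  expect_equal(spectral_gap(gen, dense_limit = 9)$gap,
               spectral_gap(gen, dense_limit = 4)$gap,
               tolerance = 1e-9)
  # gap positive across parameters
  for (rl in c(0.2, 0.5, 0.8))
    expect_gt(spectral_gap(build_generator(5,
      boundary_conditions(rl, 0.5, rates_2vstar)))$gap, 0)
})

test_that("gap equals the decay rate of the evolving distribution", {
  for (bc in list(boundary_conditions(0.3, 0.75, rates_2vstar),
                  boundary_conditions(0.6, 0.4, rates_v0))) {
    gen <- build_generator(6, bc)
    sg <- spectral_gap(gen)
    pi <- stationary_distribution(gen)
    Q <- as.matrix(gen$Q)
    p <- rep(0, 64); p[2] <- 1   # point mass: generic overlap with the
    # slowest mode (a symmetric start can be orthogonal to it);
    # exponential-integrator evolution, independent of the eigensolver,
    # fitted over a late window so faster modes have died out
    dt <- 1.5 / sg$gap
    P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
    devs <- numeric(14)
    for (s in 1:14) { p <- as.numeric(P %*% p); devs[s] <- sqrt(sum((p - pi)^2)) }
    fit <- stats::lm(log(devs[9:14]) ~ seq(9, 14))
    rate <- -unname(stats::coef(fit)[2]) / dt
    expect_lt(abs(rate - sg$gap) / sg$gap, 0.01)
  }
})

test_that("BST recursion is exact on pure power-law sequences", {
  for (w in c(1, 2, 3)) {
    Ns <- 4:12
    t <- bst_extrapolate(2 + 3 / Ns^w, Ns, omega = w)
    expect_lt(abs(t$limit - 2), 1e-12)
  }
  tconst <- bst_extrapolate(rep(0.7, 5), 4:8, 2)
  expect_equal(tconst$limit, 0.7)
  expect_equal(tconst$spread, 0)
  # mixed corrections converge to ~1e-5 at these lengths
  Ns <- 4:16
  tm <- bst_extrapolate(1 + 2 / Ns^2 - 5 / Ns^3, Ns, 2)
  expect_lt(abs(tm$limit - 1), 1e-5)
  expect_error(bst_extrapolate(c(1, 2), c(4, 5), 2))
})

test_that("omega scan marks 2 as near-optimal for 1/N^2 sequences", {
  Ns <- 4:12
  scan <- bst_omega_scan(0.1 + 0.7 / Ns^2 + 0.2 / Ns^4, Ns,
                         omegas = c(1, 2, 3))
  expect_equal(scan$omega[which.min(scan$spread)], 2)
})

test_that("gap pipeline: finite-size gaps positive, noise flagged", {
  pipe <- gap_extrapolation_pipeline(
    boundary_conditions(0.4, 0.4, rates_2vstar), N_range = 4:9)
  # on the equal-density diagonal the gap decays toward zero (power-law
  # bulk relaxation): every finite-size gap is positive and the pooled
  # extrapolant sits below all of them
  expect_true(all(pipe$gaps$gap > 0))
  expect_lt(pipe$limit, min(pipe$gaps$gap))
  expect_equal(nrow(pipe$gaps), 6)
  # near the minimal-current phase the extrapolants scatter strongly
  noisy <- gap_extrapolation_pipeline(
    boundary_conditions(0.5, 0.98, rates_2vstar), N_range = 4:11)
  expect_false(noisy$reliable)
})
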