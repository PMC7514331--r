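test_that("equal reservoirs give the exact flat bulk fixed point", {
  ns <- find_ness(boundary_conditions(0.5, 0.5, rates_2vstar), 50)
  expect_lt(max(abs(profile_rho(ns) - 0.5)), 1e-9)
  expect_lt(max(abs(profile_phi(ns) - 0.05)), 1e-9)

  # non-interacting: uncorrelated product state rho_i = rho, phi_i = rho^2
  ns0 <- find_ness(boundary_conditions(0.35, 0.35, rates_v0), 20)
  expect_lt(max(abs(profile_rho(ns0) - 0.35)), 1e-9)
  expect_lt(max(abs(profile_phi(ns0) - 0.35^2)), 1e-9)
})

test_that("stationary solver converges for random parameters", {
  set.seed(99)
  for (j in 1:30) {
    V <- stats::runif(1, 0, 5)
    rl <- stats::runif(1, 0.02, 0.98)
    rr <- stats::runif(1, 0.02, 0.98)
    N <- sample(10:40, 1)
    bc <- boundary_conditions(rl, rr, glauber_rates(V))
    ns <- find_ness(bc, N)
    expect_lt(attr(ns, "residual"), 1e-10)
    Jb <- pa_bond_current(ns, bc)
    expect_lt(diff(range(Jb)), 1e-9)
    klsdyn:::assert_profile(ns$x, N)
  }
})

test_that("interior plateau follows the extremal-current bulk density", {
  # LD phase: bulk at rho_L
  bc <- boundary_conditions(0.05, 0.75, rates_2vstar)
  ns <- find_ness(bc, 100)
  expect_lt(abs(mean(profile_rho(ns)[41:60]) - 0.05), 0.01)
  # minimum-current principle selects rho_L = 0.6 on [0.6, 0.75]
  bc2 <- boundary_conditions(0.6, 0.75, rates_2vstar)
  ns2 <- find_ness(bc2, 100)
  expect_lt(abs(mean(profile_rho(ns2)[41:60]) - 0.6), 0.01)
})

test_that("time integration preserves the probability simplex", {
  bc <- boundary_conditions(0.2, 0.9, rates_2vstar)
  p0 <- profile_flat(15, 0.5, rates_2vstar)
  sol <- pa_integrate(p0, bc, seq(0, 40, by = 4))
  for (row in seq_len(nrow(sol))) {
    x <- as.numeric(sol[row, -1])
    rho <- x[seq(1, 29, by = 2)]
    phi <- x[seq(2, 28, by = 2)]
    expect_true(all(rho >= -1e-8 & rho <= 1 + 1e-8))
    expect_true(all(phi >= pmax(0, rho[-15] + rho[-1] - 1) - 1e-8))
    expect_true(all(phi <= pmin(rho[-15], rho[-1]) + 1e-8))
  }
})

test_that("relaxation matrix has positive spectrum and banded structure", {
  bc <- boundary_conditions(0.3, 0.75, rates_2vstar)
  ns <- find_ness(bc, 20)
  M <- relaxation_matrix(ns, bc)
  ev <- eigen(M, only.values = TRUE)$values
  expect_true(all(Re(ev) > 0))
  nz <- which(M != 0, arr.ind = TRUE)
  expect_lte(max(abs(nz[, 1] - nz[, 2])), 9)
  # rejects a non-fixed-point
  expect_error(relaxation_matrix(profile_flat(20, 0.4, rates_2vstar), bc),
               "not a fixed point")
})

test_that("slow end of the spectrum is real at V = 0, equal reservoirs", {
  bc <- boundary_conditions(0.4, 0.4, rates_v0)
  ns <- find_ness(bc, 18)
  sr <- slowest_rate(ns, bc)
  expect_false(sr$is_complex)
  expect_lt(max(abs(Im(sr$spectrum_head[1:3]))), 1e-8)
})

test_that("slowest eigenvalue matches the decay of a perturbed profile", {
  bc <- boundary_conditions(0.3, 0.75, rates_2vstar)
  ns <- find_ness(bc, 30)
  sr <- slowest_rate(ns, bc)
  fitted <- pa_decay_rate_fit(ns, bc)
  expect_lt(abs(fitted - sr$lambda1) / sr$lambda1, 0.01)
})

test_that("relaxation rate is particle-hole symmetric", {
  a <- pa_lambda1(0.3, 0.75, rates_2vstar, 30)
  b <- pa_lambda1(0.25, 0.7, rates_2vstar, 30)
  expect_lt(abs(a - b), 1e-8)
})

test_that("rate vanishes toward LD/HD coexistence and saturates beyond", {
  # at rhoR = 0.75 the HD phase starts at the coexistence rho_L ~ 0.645
  lam <- vapply(c(0.6465, 0.68, 0.75, 0.9),
                function(rl) pa_lambda1(rl, 0.75, rates_2vstar, 50), 0)
  expect_lt(lam[1], 1e-3)
  expect_true(all(diff(lam[1:3]) > 0))
  expect_lt(abs(lam[4] - lam[3]) / lam[3], 0.25)  # near-plateau in fast phase
})

test_that("size dependence: weak in the slow phase", {
  lam <- vapply(c(25, 50, 100, 200),
                function(N) pa_lambda1(0.1, 0.75, rates_2vstar, N), 0)
  expect_lt(abs(lam[4] - lam[3]), abs(lam[2] - lam[1]) / 10)
})

test_that("transition locator finds one crossing at rhoR = 0.75 and two at 0.45", {
  tr <- pa_transition_locator(0.75, rates_2vstar, N_big = 60,
                              N_seq = c(15, 30, 60))
  expect_equal(tr$status, "ok")
  expect_length(tr$rhoL_star, 1)
  expect_gt(tr$rhoL_star, 0.645)
  expect_lt(tr$rhoL_star, 1)

  tr45 <- pa_transition_locator(0.45, rates_2vstar, N_big = 60,
                                N_seq = c(15, 30, 60))
  expect_equal(tr45$status, "ok")
  expect_length(tr45$rhoL_star, 2)
  # two slow phases flank a central fast phase containing the anchor
  expect_true(tr45$rhoL_star[1] < tr45$anchor)
  expect_true(tr45$rhoL_star[2] > tr45$anchor)

  deg <- pa_transition_locator(0.75, rates_2vstar, N_big = 20,
                               N_seq = c(10, 15, 20),
                               rhoL_range = c(0.8, 0.8))
  expect_equal(deg$status, "degenerate-range")
})
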