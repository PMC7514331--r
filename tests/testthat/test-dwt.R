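test_that("DWT rate reproduces hand-computed values", {
  # V = 0 (rates 1/2): J = rho(1-rho)/2
  d <- dwt_rate(0.1, 0.8, rates_v0)
  expect_equal(d$DL, 0.045 / 0.7, tolerance = 1e-12)
  expect_equal(d$DR, 0.08 / 0.7, tolerance = 1e-12)
  expect_equal(d$lambda1, (sqrt(0.045 / 0.7) - sqrt(0.08 / 0.7))^2,
               tolerance = 1e-12)
  expect_error(dwt_rate(0.3, 0.3, rates_v0), "undefined")
})

test_that("DWT rate vanishes exactly on the coexistence locus", {
  # J(rhoL) = J(rhoR) by particle-hole symmetry
  expect_equal(dwt_lambda1(0.25, 0.75, rates_2vstar), 0, tolerance = 1e-14)
  expect_equal(dwt_lambda1(0.3, 0.3, rates_2vstar), 0)
  # ... and the zero locus matches the phase classifier's LD/HD tie
  rl_star <- max(coexistence_partners(0.75, rates_2vstar))
  expect_lt(dwt_lambda1(rl_star, 0.75, rates_2vstar), 1e-15)
  expect_true(classify_phase(rl_star, 0.75, rates_2vstar)$coexistence)
  # positive away from it
  expect_gt(dwt_lambda1(0.7, 0.75, rates_2vstar), 0)
})

test_that("DWT curve at rhoR = 0.75 rises to a single interior maximum", {
  rng <- hd_phase_rhoL_range(0.75, rates_2vstar)
  expect_equal(rng[1], 0.645, tolerance = 1e-2)
  mx <- dwt_maxima(0.75, rates_2vstar)
  expect_equal(nrow(mx), 1)
  r <- seq(rng[1] + 1e-3, mx[1, "rhoL"], length.out = 50)
  expect_true(all(diff(dwt_lambda1(r, 0.75, rates_2vstar)) > 0))
})

test_that("mDWT max-plateau: DWT left of the maximum, constant beyond", {
  mx <- dwt_maxima(0.75, rates_2vstar)
  rl <- seq(0.65, 0.99, by = 0.005)
  m <- mdwt_rate(rl, 0.75, rates_2vstar)
  left <- rl <= mx[1, "rhoL"]
  expect_equal(m$lambda1[left], dwt_lambda1(rl[left], 0.75, rates_2vstar))
  expect_true(all(m$lambda1[!left] == mx[1, "lambda1"]))
  expect_setequal(unique(m$regime), c("slow", "fast-plateau"))
  # continuity across the join
  expect_lt(max(abs(diff(m$lambda1))), 0.002)
})

test_that("mDWT is a no-op in the slow phase of pure TASEP by construction", {
  m <- mdwt_rate(0.3, 0.8, tasep_rates())
  expect_equal(m$lambda1, dwt_lambda1(0.3, 0.8, tasep_rates()))
  expect_equal(m$regime, "slow")
})

test_that("min-plateau rule replaces the oscillating segment continuously", {
  mx <- dwt_maxima(0.98, rates_2vstar)
  expect_equal(nrow(mx), 2)  # second maximum follows the first
  rl <- seq(0.03, 0.97, by = 0.005)
  m <- mdwt_rate(rl, 0.98, rates_2vstar, rule = "min-plateau")
  expect_setequal(unique(m$regime),
                  c("slow", "oscillating-replaced", "fast-plateau"))
  expect_lt(max(abs(diff(m$lambda1))), 0.006)      # no jumps
  seg <- m$replaced_segment
  inside <- rl > seg[1] & rl < seg[2]
  expect_true(all(m$lambda1[inside] == m$plateau_value))
  # the raw DWT oscillates there, the mDWT does not
  raw <- dwt_lambda1(rl, 0.98, rates_2vstar)
  expect_gt(max(raw[inside]) - min(raw[inside]), 0.02)
  # rule errors out where the shape does not match
  expect_error(mdwt_rate(0.7, 0.75, rates_2vstar, rule = "min-plateau"),
               "oscillate")
})

test_that("lowest-max rule plateaus at the lower of the two maxima", {
  mx <- dwt_maxima(0.45, rates_2vstar)
  m <- mdwt_rate(seq(0.2, 0.5, by = 0.01), 0.45, rates_2vstar,
                 rule = "lowest-max")
  expect_equal(m$plateau_value, min(mx[, "lambda1"]), tolerance = 1e-10)
})

test_that("the two HD-III maxima exchange height near rhoR = 0.43", {
  mx45 <- dwt_maxima(0.45, rates_2vstar)
  expect_equal(nrow(mx45), 2)
  expect_gt(mx45[1, "lambda1"], mx45[2, "lambda1"])  # left higher at 0.45
  mx41 <- dwt_maxima(0.41, rates_2vstar)
  expect_lt(mx41[1, "lambda1"], mx41[2, "lambda1"])  # right higher below
  cr <- dwt_crossover_rhoR(rates_2vstar)
  expect_lt(abs(cr$rhoR - 0.43), 0.01)
  expect_equal(cr$maxima[1, "lambda1"], cr$maxima[2, "lambda1"],
               tolerance = 1e-4)
})

test_that("transition lines are continuous and mirror into the LD phases", {
  grid <- seq(0.72, 0.8, by = 0.02)
  tl <- dwt_transition_lines(rates_2vstar, grid, mirror = TRUE)
  solid <- tl[tl$line_type == "first-maximum", ]
  expect_equal(nrow(solid), length(grid))
  expect_lt(max(abs(diff(solid$rhoL_star))), 0.05)
  mirrored <- tl[tl$line_type == "first-maximum-mirror", ]
  expect_equal(sort(1 - mirrored$rhoR), sort(solid$rhoL_star),
               tolerance = 1e-10)
})

test_that("DWT agrees with the extrapolated exact gap deep in the V=0 slow phase", {
  for (pt in list(c(0.3, 0.8), c(0.3, 0.85), c(0.35, 0.85))) {
    bc <- boundary_conditions(pt[1], pt[2], rates_v0)
    pipe <- gap_extrapolation_pipeline(bc, N_range = 4:13)
    dw <- dwt_lambda1(pt[1], pt[2], rates_v0)
    expect_lt(abs(pipe$limit - dw) / dw, 0.02)
  }
})
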