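test_that("extremal-current classification matches a brute-force scan", {
  # independent oracle: dense grid extremization of J over the interval
  oracle <- function(rhoL, rhoR, rates) {
    lo <- min(rhoL, rhoR); hi <- max(rhoL, rhoR)
    grid <- seq(lo, hi, length.out = 200001)
    J <- bulk_current(grid, rates)
    j <- if (rhoL < rhoR) which.min(J) else which.max(J)
    c(rho = grid[j], J = J[j])
  }
  cases <- list(c(0.05, 0.75), c(0.25, 0.95), c(0.3, 0.5), c(0.8, 0.2),
                c(0.45, 0.3), c(0.9, 0.6), c(0.2, 0.6))
  for (cs in cases) {
    p <- classify_phase(cs[1], cs[2], rates_2vstar)
    o <- oracle(cs[1], cs[2], rates_2vstar)
    expect_equal(p$current, unname(o["J"]), tolerance = 1e-9)
    # the arg-extremum is only unique away from ties (the two maxima of the
    # symmetric diagram share one current)
    if (!p$coexistence)
      expect_equal(p$bulk_density, unname(o["rho"]), tolerance = 1e-4)
  }
})

test_that("reference phase points at V = 2V*", {
  p <- classify_phase(0.05, 0.75, rates_2vstar)
  expect_equal(p$phase_label, "LD")
  expect_equal(p$roman, "I")
  expect_equal(p$bulk_density, 0.05)
  expect_equal(p$current, 0.0237176, tolerance = 1e-5)

  p2 <- classify_phase(0.25, 0.95, rates_2vstar)
  expect_equal(p2$phase_label, "HD")
  expect_equal(p2$bulk_density, 0.95)

  p3 <- classify_phase(0.5, 0.5, rates_2vstar)
  expect_equal(p3$bulk_density, 0.5)

  # maximal/minimal current phases; when only one maximum lies in the scan
  # interval the label is unambiguous
  expect_equal(classify_phase(0.5, 0.1, rates_2vstar)$phase_label,
               "MAX_CURRENT_LOW")
  expect_equal(classify_phase(0.95, 0.5, rates_2vstar)$phase_label,
               "MAX_CURRENT_HIGH")
  expect_equal(classify_phase(0.3, 0.7, rates_2vstar)$phase_label,
               "MIN_CURRENT")
  expect_equal(classify_phase(0.3, 0.7, rates_2vstar)$roman, "IV")
  # both maxima inside the interval: equal currents, coexistence flagged
  pboth <- classify_phase(0.9, 0.1, rates_2vstar)
  expect_true(pboth$phase_label %in% c("MAX_CURRENT_LOW", "MAX_CURRENT_HIGH"))
  expect_true(pboth$coexistence)
})

test_that("particle-hole mirror maps phases LD <-> HD", {
  set.seed(21)
  for (i in 1:25) {
    rl <- stats::runif(1, 0.02, 0.98); rr <- stats::runif(1, 0.02, 0.98)
    a <- classify_phase(rl, rr, rates_2vstar)
    b <- classify_phase(1 - rr, 1 - rl, rates_2vstar)
    expect_equal(a$current, b$current, tolerance = 1e-9)
    if (a$coexistence || b$coexistence) next  # tied extrema: either may win
    expect_equal(a$bulk_density + b$bulk_density, 1, tolerance = 1e-6)
    if (a$phase_label == "LD") expect_equal(b$phase_label, "HD")
    if (a$phase_label == "HD") expect_equal(b$phase_label, "LD")
    if (a$phase_label == "MIN_CURRENT")
      expect_equal(b$phase_label, "MIN_CURRENT")
  }
})

test_that("ties between arg-extrema are flagged as coexistence", {
  # LD/HD coexistence: J(rhoL) = J(rhoR) with no interior extremum between
  # (the upper boundary of the LD phase VI at rhoR = 0.75)
  rl_star <- max(coexistence_partners(0.75, rates_2vstar))
  p <- classify_phase(rl_star, 0.75, rates_2vstar)
  expect_true(p$coexistence)
  expect_false(classify_phase(0.1, 0.75, rates_2vstar)$coexistence)
  # (0.25, 0.75) has equal endpoint currents but the interior minimum wins:
  # minimal-current phase, no coexistence
  p2 <- classify_phase(0.25, 0.75, rates_2vstar)
  expect_equal(p2$phase_label, "MIN_CURRENT")
  expect_false(p2$coexistence)
})

test_that("phase raster covers the seven phases at V = 2V* and mirrors", {
  grid <- seq(0.05, 0.95, by = 0.05)
  ras <- phase_raster(rates_2vstar, grid, grid)
  # Roman identifiers are attached off the diagonal only
  expect_setequal(setdiff(unique(ras$roman), NA),
                  c("I", "II", "III", "IV", "V", "VI", "VII"))
  # mirror invariance of the raster (tied extrema excluded: either of the
  # two equal-current maxima may be selected there)
  key <- function(df) paste(round(df$rhoL, 3), round(df$rhoR, 3))
  m <- ras
  m$rhoL2 <- 1 - ras$rhoR; m$rhoR2 <- 1 - ras$rhoL
  idx <- match(paste(round(m$rhoL2, 3), round(m$rhoR2, 3)), key(ras))
  expect_false(anyNA(idx))
  keep <- !ras$coexistence & !ras$coexistence[idx]
  expect_equal(ras$bulk_density[idx][keep] + ras$bulk_density[keep],
               rep(1, sum(keep)), tolerance = 1e-6)
  expect_gt(sum(keep), 0.7 * nrow(ras))
})
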