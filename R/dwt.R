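#' Domain-wall-theory relaxation rate
#'
#' Domain wall theory (DWT) treats the interface between an LD region fed by
#' the left reservoir and an HD region fed by the right one as a biased
#' random walker with hop rates \eqn{D_{L,R} = J(\rho_{L,R})/|\rho_R-\rho_L|}.
#' Its relaxation rate is the spectral gap of the biased walk,
#' \deqn{\lambda_1 = (\sqrt{D_L} - \sqrt{D_R})^2,}
#' which vanishes exactly on the LD/HD coexistence locus
#' \eqn{J(\rho_L) = J(\rho_R)} and is known to be exact in the slow phase of
#' the pure TASEP.
#'
#' @param rhoL,rhoR reservoir densities (must differ)
#' @param rates a `kls_rates`
#' @return object of class `kls_dwt`: list with `DL`, `DR`, `lambda1`,
#'   `regime` (here always "slow": the raw DWT estimate)
#' @export
dwt_rate <- function(rhoL, rhoR, rates) {
  if (abs(rhoL - rhoR) < .Machine$double.eps * 4)
    stop("DWT is undefined at rhoL = rhoR")
  d <- abs(rhoR - rhoL)
  DL <- bulk_current(rhoL, rates) / d
  DR <- bulk_current(rhoR, rates) / d
  structure(list(DL = DL, DR = DR,
                 lambda1 = (sqrt(DL) - sqrt(DR))^2,
                 regime = "slow"),
            class = "kls_dwt")
}

#' @export
print.kls_dwt <- function(x, ...) {
  cat(sprintf("DWT rate: lambda1 = %.8g (DL = %.6g, DR = %.6g, %s)\n",
              x$lambda1, x$DL, x$DR, x$regime))
  invisible(x)
}

#' @rdname dwt_rate
#' @details `dwt_lambda1()` is a vectorized convenience returning just the
#'   rate; it returns 0 at `rhoL == rhoR` (the continuous limit).
#' @export
dwt_lambda1 <- function(rhoL, rhoR, rates) {
  d <- abs(rhoR - rhoL)
  out <- numeric(length(rhoL))
  ok <- d > .Machine$double.eps * 4
  if (any(ok)) {
    DL <- bulk_current(rhoL[ok], rates) / d[ok]
    DR <- bulk_current(rhoR, rates) / d[ok]
    out[ok] <- (sqrt(DL) - sqrt(DR))^2
  }
  out
}

#' Coexistence partners of a reservoir density
#'
#' Solves J(rho) = J(rhoR) for rho != rhoR on (0, 1): the densities at which
#' an LD phase coexists with the HD phase at `rhoR` (where the DWT rate
#' vanishes).
#'
#' @param rhoR reference density
#' @param rates a `kls_rates`
#' @param grid scan resolution
#' @return sorted numeric vector of partner densities (may be empty)
#' @export
coexistence_partners <- function(rhoR, rates, grid = 4001) {
  JR <- bulk_current(rhoR, rates)
  r <- seq(1e-6, 1 - 1e-6, length.out = grid)
  d <- bulk_current(r, rates) - JR
  sgn <- sign(d)
  idx <- which(sgn[-1] * sgn[-grid] < 0)
  roots <- vapply(idx, function(j) {
    stats::uniroot(function(z) bulk_current(z, rates) - JR,
                   c(r[j], r[j + 1]), tol = 1e-12)$root
  }, 0)
  sort(roots[abs(roots - rhoR) > 1e-7])
}

#' Local maxima of the DWT rate along rhoL
#'
#' Scans \eqn{\lambda_1^{DWT}(\rho_L)} at fixed `rhoR` over the HD-relevant
#' segment between the outer coexistence points, and refines each interior
#' local maximum.  In the HD phase adjacent to a single coexistence line
#' there is one maximum; for an HD phase flanked by two LD phases
#' (a double-humped fundamental diagram with rhoR near the central minimum)
#' there are two, one per slow phase.
#'
#' @param rhoR fixed right-reservoir density
#' @param rates a `kls_rates`
#' @param rhoL_range optional scan interval; defaults to the span of the
#'   coexistence partners of `rhoR` (or (rhoR, 1) if there is a single
#'   partner below rhoR)
#' @param grid scan resolution (step ~1e-3 by default)
#' @return matrix with columns `rhoL`, `lambda1`, one row per maximum,
#'   ordered by rhoL
#' @export
dwt_maxima <- function(rhoR, rates, rhoL_range = NULL, grid = NULL) {
  if (is.null(rhoL_range)) rhoL_range <- hd_phase_rhoL_range(rhoR, rates)
  lo <- rhoL_range[1]; hi <- rhoL_range[2]
  if (is.null(grid)) grid <- max(1000, ceiling((hi - lo) / 1e-3))
  r <- seq(lo, hi, length.out = grid)
  lam <- dwt_lambda1(r, rhoR, rates)
  lam[abs(r - rhoR) < 2e-3] <- 0  # remove the trivial zero-touch at rhoL=rhoR
  out <- NULL
  for (j in 2:(grid - 1)) {
    if (lam[j] > lam[j - 1] && lam[j] >= lam[j + 1] && lam[j] > 0) {
      opt <- stats::optimize(function(z) dwt_lambda1(z, rhoR, rates),
                             c(r[j - 1], r[j + 1]), maximum = TRUE,
                             tol = 1e-10)
      out <- rbind(out, c(rhoL = opt$maximum, lambda1 = opt$objective))
    }
  }
  if (!is.null(out)) out <- out[order(out[, 1]), , drop = FALSE]
  out
}

#' rhoL extent of the HD phase at a given rhoR
#'
#' The HD phase at `rhoR` spans rhoL from the coexistence line with the
#' adjacent LD phase (the largest coexistence partner below rhoR) up to the
#' next coexistence partner above rhoR (the boundary with the upper LD
#' phase), or up to 1 if there is none.
#'
#' @inheritParams dwt_maxima
#' @return length-2 numeric range in rhoL
#' @export
hd_phase_rhoL_range <- function(rhoR, rates) {
  cp <- coexistence_partners(rhoR, rates)
  below <- cp[cp < rhoR]
  if (length(below) == 0)
    stop("rhoR = ", rhoR, " has no coexistence partner below it: ",
         "not in an HD phase")
  above <- cp[cp > rhoR]
  c(max(below), if (length(above)) min(above) else 1)
}

#' Modified DWT rate
#'
#' The modified domain wall theory (mDWT) keeps the DWT rate in the slow
#' phase and replaces the portion of the curve beyond it by a constant
#' plateau:
#' \describe{
#'   \item{`"max-plateau"`}{beyond the first maximum of
#'     \eqn{\lambda_1(\rho_L)} the rate is held at that maximum (the fast
#'     phase); exact by construction for pure TASEP.}
#'   \item{`"min-plateau"`}{when the DWT curve oscillates (a second maximum
#'     followed by a local minimum, near the minimal-current phase), the
#'     curve from the point where the rising slow-phase branch reaches the
#'     minimum value onwards is replaced by that minimum value, removing
#'     the oscillation while keeping the curve continuous.}
#'   \item{`"lowest-max"`}{plateau at the lower of the two maxima
#'     (experimental; yields an unphysical kink in the transition lines
#'     where the two maxima exchange height, so it is not used by
#'     [dwt_transition_lines()]).}
#' }
#'
#' @param rhoL left-reservoir density (scalar or vector)
#' @param rhoR right-reservoir density, in an HD phase
#' @param rates a `kls_rates`
#' @param rule plateau rule
#' @return `kls_dwt` object (vector `lambda1` if `rhoL` is a vector), with
#'   `regime` per entry: "slow" where the raw DWT is kept, "fast-plateau"
#'   or "oscillating-replaced" on the plateau
#' @export
mdwt_rate <- function(rhoL, rhoR, rates,
                      rule = c("max-plateau", "min-plateau", "lowest-max")) {
  rule <- match.arg(rule)
  mx <- dwt_maxima(rhoR, rates)
  if (is.null(mx)) stop("DWT curve has no interior maximum; mDWT rule ",
                        rule, " is inapplicable")
  raw <- dwt_lambda1(rhoL, rhoR, rates)
  if (rule == "max-plateau") {
    cut <- mx[1, "rhoL"]; plateau <- mx[1, "lambda1"]
    lam <- unname(ifelse(rhoL <= cut, raw, plateau))
    regime <- unname(ifelse(rhoL <= cut, "slow", "fast-plateau"))
  } else if (rule == "min-plateau") {
    osc <- dwt_oscillation_minimum(rhoR, rates, mx)
    plateau <- osc$lambda1
    # replaced segment: from the point where the rising slow-phase branch
    # first reaches the oscillation-minimum value up to the minimum itself;
    # after the subsequent (last) maximum the curve is held constant as in
    # the max-plateau rule
    lo <- hd_phase_rhoL_range(rhoR, rates)[1]
    cutL <- stats::uniroot(function(z) dwt_lambda1(z, rhoR, rates) - plateau,
                           c(lo, mx[1, "rhoL"]), tol = 1e-10)$root
    cutR <- osc$rhoL
    last_max <- mx[nrow(mx), ]
    lam <- unname(ifelse(rhoL <= cutL, raw,
                         ifelse(rhoL <= cutR, plateau,
                                ifelse(rhoL <= last_max["rhoL"], raw,
                                       last_max["lambda1"]))))
    regime <- unname(ifelse(rhoL <= cutL, "slow",
                            ifelse(rhoL <= cutR, "oscillating-replaced",
                                   ifelse(rhoL <= last_max["rhoL"], "slow",
                                          "fast-plateau"))))
    return(structure(list(DL = NULL, DR = NULL, lambda1 = lam,
                          regime = regime, rule = rule,
                          replaced_segment = c(cutL, cutR),
                          plateau_value = unname(plateau)),
                     class = "kls_dwt"))
  } else {
    if (nrow(mx) < 2)
      stop("lowest-max rule needs two maxima; curve has ", nrow(mx))
    plateau <- min(mx[, "lambda1"])
    cut <- stats::uniroot(function(z) dwt_lambda1(z, rhoR, rates) - plateau,
                          c(hd_phase_rhoL_range(rhoR, rates)[1],
                            mx[which.min(mx[, "lambda1"]), "rhoL"]),
                          tol = 1e-10)$root
    lam <- unname(ifelse(rhoL <= cut, raw, plateau))
    regime <- unname(ifelse(rhoL <= cut, "slow", "fast-plateau"))
  }
  structure(list(DL = NULL, DR = NULL, lambda1 = lam, regime = regime,
                 rule = rule, plateau_start = unname(cut),
                 plateau_value = unname(plateau)),
            class = "kls_dwt")
}

# interior local minimum of the oscillating DWT curve (between its two
# maxima inside the HD phase)
dwt_oscillation_minimum <- function(rhoR, rates, mx = NULL) {
  if (is.null(mx)) mx <- dwt_maxima(rhoR, rates)
  if (is.null(mx) || nrow(mx) < 2)
    stop("DWT curve does not oscillate at rhoR = ", rhoR,
         " (need a second maximum following the first)")
  opt <- stats::optimize(function(z) dwt_lambda1(z, rhoR, rates),
                         c(mx[1, "rhoL"], mx[nrow(mx), "rhoL"]), tol = 1e-10)
  list(rhoL = opt$minimum, lambda1 = opt$objective)
}

#' Height crossover of the two DWT maxima
#'
#' In the HD phase whose bulk density lies below the central minimum of a
#' double-humped fundamental diagram, the DWT curve
#' \eqn{\lambda_1(\rho_L)} has two local maxima.  Their relative height
#' depends on rhoR; this locates the rhoR at which the two heights are
#' equal (below it the right maximum is the higher one).
#'
#' @param rates a `kls_rates` with a double-humped fundamental diagram
#' @param interval search interval in rhoR
#' @param tol root tolerance
#' @return list with `rhoR` (the crossover) and `maxima` (the two equal
#'   maxima at the crossover)
#' @export
dwt_crossover_rhoR <- function(rates, interval = c(0.40, 0.47), tol = 1e-6) {
  hdiff <- function(rR) {
    mx <- dwt_maxima(rR, rates)
    if (is.null(mx) || nrow(mx) != 2)
      stop("expected exactly two DWT maxima at rhoR = ", rR,
           "; got ", if (is.null(mx)) 0 else nrow(mx))
    mx[1, "lambda1"] - mx[2, "lambda1"]
  }
  root <- stats::uniroot(hdiff, interval, tol = tol)$root
  list(rhoR = root, maxima = dwt_maxima(root, rates))
}

#' DWT/mDWT dynamical-transition lines
#'
#' For each rhoR of a grid inside the HD phases, reports the rhoL of the
#' first maximum of the DWT curve (the mDWT estimate of the dynamical
#' transition; solid-line analogue) and, where the curve oscillates so that
#' the min-plateau rule applies, the rhoL positions bounding the replaced
#' segment (dashed-line analogues).  Lines in the LD phases follow by the
#' particle-hole mirror (rhoL, rhoR) -> (1 - rhoR, 1 - rhoL).
#'
#' @param rates a `kls_rates`
#' @param rhoR_grid densities inside HD phases
#' @param mirror also emit the particle-hole-mirrored LD lines
#' @param file optional CSV output (columns V, rhoR, rhoL_star, line_type)
#' @return data frame with columns `V`, `rhoR`, `rhoL_star`, `line_type`
#' @export
dwt_transition_lines <- function(rates, rhoR_grid, mirror = TRUE,
                                 file = NULL) {
  rows <- list()
  for (rR in rhoR_grid) {
    mx <- tryCatch(dwt_maxima(rR, rates), error = function(e) NULL)
    if (is.null(mx)) next
    rows[[length(rows) + 1]] <-
      data.frame(V = rates$V, rhoR = rR, rhoL_star = mx[1, "rhoL"],
                 line_type = "first-maximum")
    if (nrow(mx) >= 2) {
      osc <- tryCatch(dwt_oscillation_minimum(rR, rates, mx),
                      error = function(e) NULL)
      if (!is.null(osc)) {
        cut <- tryCatch(stats::uniroot(
          function(z) dwt_lambda1(z, rR, rates) - osc$lambda1,
          c(hd_phase_rhoL_range(rR, rates)[1], mx[1, "rhoL"]),
          tol = 1e-10)$root, error = function(e) NA_real_)
        rows[[length(rows) + 1]] <-
          data.frame(V = rates$V, rhoR = rR,
                     rhoL_star = c(cut, osc$rhoL),
                     line_type = c("plateau-start", "oscillation-minimum"))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (mirror && !is.null(out)) {
    m <- out
    m$rhoR2 <- 1 - out$rhoL_star
    m$rhoL_star <- 1 - out$rhoR
    m$rhoR <- m$rhoR2
    m$rhoR2 <- NULL
    m$line_type <- paste0(m$line_type, "-mirror")
    out <- rbind(out, m)
  }
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
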