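#' Extremal-current phase classification
#'
#' For bulk-adapted boundary conditions the stationary bulk density of the
#' open chain follows the extremal-current principles: with left and right
#' reservoir densities rhoL < rhoR the selected current is the minimum of
#' J over [rhoL, rhoR]; with rhoL > rhoR it is the maximum of J over
#' [rhoR, rhoL].  The bulk density is the argument of the winning extremum:
#' an endpoint gives a reservoir-controlled LD (low-density, bulk = rhoL) or
#' HD (high-density, bulk = rhoR) phase, while an interior extremum of the
#' fundamental diagram gives a maximal- or minimal-current phase insensitive
#' to the reservoirs.
#'
#' Above the threshold repulsion V* the double-humped diagram yields seven
#' phases; Roman identifiers I-VII are attached following the geometry of
#' the V = 2V* phase diagram (I/VI the two LD phases, III/V the two HD
#' phases, II/VII the maximal-current phases at the lower/upper maximum,
#' IV the minimal-current phase).  For V <= V* the TASEP-like three-phase
#' labels are used and no Roman identifier is attached.
#'
#' @param rhoL,rhoR reservoir densities in (0,1)
#' @param rates a `kls_rates` object
#' @param grid number of scan points on the closed density interval
#' @param tie_tol currents closer than this are treated as a tie
#'   (phase coexistence)
#' @param fd precomputed [fundamental_diagram_features()] result (an
#'   optimization for rasters); computed on the fly when `NULL`
#' @return object of class `kls_phase`: list with `rhoL`, `rhoR`,
#'   `phase_label`, `roman`, `bulk_density`, `current`, `coexistence`
#' @export
classify_phase <- function(rhoL, rhoR, rates, grid = 20001, tie_tol = 1e-9,
                           fd = NULL) {
  stopifnot(rhoL > 0, rhoL < 1, rhoR > 0, rhoR < 1)
  if (is.null(fd)) fd <- fundamental_diagram_features(rates)
  if (abs(rhoL - rhoR) < .Machine$double.eps * 4) {
    lab <- phase_label_for(rhoL, rhoL, rhoR, fd)
    return(structure(list(rhoL = rhoL, rhoR = rhoR,
                          phase_label = lab$label,
                          roman = NA_character_,
                          bulk_density = rhoL,
                          current = bulk_current(rhoL, rates),
                          coexistence = FALSE),
                     class = "kls_phase"))
  }
  lo <- min(rhoL, rhoR); hi <- max(rhoL, rhoR)
  minimize <- rhoL < rhoR
  # candidates: both endpoints plus interior extrema of the right kind
  cand <- c(lo, hi)
  if (minimize && !is.null(fd$minimum)) {
    r <- fd$minimum["rho"]
    if (r > lo && r < hi) cand <- c(cand, r)
  }
  if (!minimize && !is.null(fd$maxima)) {
    r <- fd$maxima[, "rho"]
    cand <- c(cand, r[r > lo & r < hi])
  }
  # guard against diagram shapes without precomputed extrema: coarse scan
  scan <- seq(lo, hi, length.out = max(grid, 1000))
  Jscan <- bulk_current(scan, rates)
  cand <- c(cand, scan[if (minimize) which.min(Jscan) else which.max(Jscan)])
  Jc <- bulk_current(cand, rates)
  ord <- order(if (minimize) Jc else -Jc)
  best <- cand[ord[1]]; Jbest <- Jc[ord[1]]
  # tie detection among candidates at distinct densities
  coex <- FALSE
  for (j in ord[-1]) {
    if (abs(Jc[j] - Jbest) < tie_tol && abs(cand[j] - best) > 1e-6) {
      coex <- TRUE
      break
    }
  }
  lab <- phase_label_for(best, rhoL, rhoR, fd)
  structure(list(rhoL = rhoL, rhoR = rhoR,
                 phase_label = lab$label,
                 roman = if (rates$V > kls_vstar_exact()) lab$roman
                         else NA_character_,
                 bulk_density = as.numeric(best),
                 current = as.numeric(Jbest),
                 coexistence = coex),
            class = "kls_phase")
}

phase_label_for <- function(bulk, rhoL, rhoR, fd) {
  eps <- 1e-7
  if (!is.null(fd$minimum) && abs(bulk - fd$minimum["rho"]) < eps)
    return(list(label = "MIN_CURRENT", roman = "IV"))
  if (!is.null(fd$maxima)) {
    rm <- sort(fd$maxima[, "rho"])
    if (abs(bulk - rm[1]) < eps)
      return(list(label = "MAX_CURRENT_LOW", roman = "II"))
    if (length(rm) > 1 && abs(bulk - rm[length(rm)]) < eps)
      return(list(label = "MAX_CURRENT_HIGH", roman = "VII"))
  }
  if (abs(bulk - rhoL) < eps)
    return(list(label = "LD", roman = if (rhoL < 0.5) "I" else "VI"))
  list(label = "HD", roman = if (rhoR > 0.5) "V" else "III")
}

#' @export
print.kls_phase <- function(x, ...) {
  cat(sprintf(
    "phase %s%s: bulk density %.6g, current %.6g (rhoL = %g, rhoR = %g)%s\n",
    x$phase_label,
    if (!is.na(x$roman)) paste0(" [", x$roman, "]") else "",
    x$bulk_density, x$current, x$rhoL, x$rhoR,
    if (x$coexistence) " -- coexistence" else ""))
  invisible(x)
}

#' Rasterize the NESS phase diagram
#'
#' Classifies every point of a (rhoL, rhoR) grid and optionally writes the
#' raster as CSV with columns (rhoL, rhoR, phase_label, roman, bulk_density,
#' current, coexistence).
#'
#' @param rates a `kls_rates` object
#' @param rhoL_grid,rhoR_grid density grids in (0,1)
#' @param file optional CSV output path
#' @return data frame raster
#' @export
phase_raster <- function(rates,
                         rhoL_grid = seq(0.02, 0.98, by = 0.02),
                         rhoR_grid = seq(0.02, 0.98, by = 0.02),
                         file = NULL) {
  res <- expand.grid(rhoL = rhoL_grid, rhoR = rhoR_grid)
  fd <- fundamental_diagram_features(rates)
  cls <- mapply(function(l, r) {
    p <- classify_phase(l, r, rates, grid = 2001, fd = fd)
    list(p$phase_label, p$roman, p$bulk_density, p$current, p$coexistence)
  }, res$rhoL, res$rhoR, SIMPLIFY = FALSE)
  res$phase_label <- vapply(cls, `[[`, "", 1)
  res$roman <- vapply(cls, function(z) as.character(z[[2]]), "")
  res$bulk_density <- vapply(cls, `[[`, 0, 3)
  res$current <- vapply(cls, `[[`, 0, 4)
  res$coexistence <- vapply(cls, `[[`, TRUE, 5)
  if (!is.null(file)) utils::write.csv(res, file, row.names = FALSE)
  res
}
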