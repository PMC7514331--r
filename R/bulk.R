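#' Bulk correlator of the KLS stationary state
#'
#' In a bulk nonequilibrium steady state at density rho, the pair marginals
#' factor through a single correlator
#' \eqn{\eta = P[10]/(P[1]P[0])}, fixed by the stationarity condition
#' \deqn{\frac{1}{\eta^2} - \frac{1}{\eta}
#'       + \rho(1-\rho)\left[1 - \frac{\Gamma(0,1)}{\Gamma(1,0)}\right] = 0,}
#' whose physical root is
#' \deqn{\eta(\rho) = \frac{2}{1 + \sqrt{1 - 4\rho(1-\rho)
#'       [1 - \Gamma(0,1)/\Gamma(1,0)]}}.}
#' For non-interacting rates (ratio 1) eta = 1 and the state factorizes;
#' repulsion (V > 0) gives eta > 1 (an excess of particle-hole bonds).
#'
#' @param rho density in (0,1); the endpoints are accepted and give eta = 1.
#' @param rates a `kls_rates` object
#' @return the correlator eta (scalar, vectorized over `rho`)
#' @export
bulk_correlator <- function(rho, rates) {
  stopifnot(all(rho >= 0), all(rho <= 1))
  ratio <- rates$gamma[1, 2] / rates$gamma[2, 1]
  disc <- 1 - 4 * rho * (1 - rho) * (1 - ratio)
  if (any(disc < 0))
    stop("negative discriminant in the bulk correlator ",
         "(attractive rates with 4*rho*(1-rho)*(1-exp(-V)) > 1)")
  2 / (1 + sqrt(disc))
}

#' Bulk stationary state at a given density
#'
#' Returns the 1- and 2-node marginals of the bulk steady state,
#' parameterized by the density and the correlator:
#' P[10] = P[01] = eta*rho*(1-rho), P[00] = (1-eta*rho)(1-rho),
#' P[11] = (1-eta*(1-rho))*rho, together with the bulk current.
#'
#' @inheritParams bulk_correlator
#' @return object of class `kls_bulk` with fields `rho`, `eta`,
#'   `p00`, `p01`, `p10`, `p11`, `current`
#' @export
bulk_state <- function(rho, rates) {
  stopifnot(length(rho) == 1, rho >= 0, rho <= 1)
  eta <- bulk_correlator(rho, rates)
  p10 <- eta * rho * (1 - rho)
  p00 <- (1 - eta * rho) * (1 - rho)
  p11 <- (1 - eta * (1 - rho)) * rho
  ps <- c(p00, p10, p10, p11)
  if (any(ps < -1e-12) || any(ps > 1 + 1e-12))
    stop("bulk pair marginal outside [0,1]; invalid (rho, rates) combination")
  structure(list(rho = rho, eta = eta,
                 p00 = p00, p01 = p10, p10 = p10, p11 = p11,
                 current = bulk_current(rho, rates)),
            class = "kls_bulk")
}

#' @export
print.kls_bulk <- function(x, ...) {
  cat(sprintf(
    "KLS bulk state: rho = %g, eta = %.6g, J = %.6g\n  pair marginals: p00 = %.6g, p01 = p10 = %.6g, p11 = %.6g\n",
    x$rho, x$eta, x$current, x$p00, x$p01, x$p11))
  invisible(x)
}

#' Bulk current (fundamental diagram)
#'
#' \deqn{J(\rho) = \Gamma(1,0)\,\{\eta(\rho)\rho(1-\rho)
#'       + [1-\eta(\rho)](a + b\rho)\}.}
#' For the explicit TASEP constructor (eta = 1) this reduces to
#' \eqn{\rho(1-\rho)}.
#'
#' @inheritParams bulk_correlator
#' @return current per unit time (vectorized over `rho`)
#' @export
bulk_current <- function(rho, rates) {
  eta <- bulk_correlator(rho, rates)
  g <- rates$gamma
  if (abs(g[2, 1] - g[1, 2]) < 1e-14) {
    # non-interacting limit: eta = 1 identically and the (1 - eta) term
    # drops out, so a, b are never needed
    return(g[2, 1] * rho * (1 - rho))
  }
  ab <- ab_coefficients(rates)
  g[2, 1] * (eta * rho * (1 - rho) + (1 - eta) * (ab$a + ab$b * rho))
}

#' Features of the fundamental diagram
#'
#' Locates interior local maxima and minima of J(rho) on (0,1) by a dense
#' grid scan followed by golden-section refinement, and classifies the
#' diagram as single- or double-humped.  For Glauber rates the diagram has a
#' single maximum at rho = 1/2 below the threshold repulsion V* = 2 ln 3 and
#' two maxima symmetric about an interior minimum at rho = 1/2 above it.
#'
#' @param rates a `kls_rates` object
#' @param grid number of grid points (>= 1000)
#' @param find_vstar_too if `TRUE`, also populate the `Vstar` field
#' @return list with `maxima` (matrix with columns rho, J), `minimum`
#'   (NULL or c(rho, J)), `is_double_humped`, and optionally `Vstar`
#' @export
fundamental_diagram_features <- function(rates, grid = 4001,
                                         find_vstar_too = FALSE) {
  stopifnot(grid >= 1000)
  rho <- seq(1 / grid, 1 - 1 / grid, length.out = grid)
  J <- bulk_current(rho, rates)
  dJ <- diff(J)
  refine <- function(lo, hi, maximum) {
    f <- function(r) bulk_current(r, rates)
    opt <- stats::optimize(f, c(lo, hi), maximum = maximum, tol = 1e-12)
    if (maximum) c(rho = opt$maximum, J = opt$objective)
    else c(rho = opt$minimum, J = opt$objective)
  }
  maxima <- NULL
  minimum <- NULL
  for (j in seq_len(grid - 2)) {
    if (dJ[j] > 0 && dJ[j + 1] <= 0)
      maxima <- rbind(maxima, refine(rho[j], rho[j + 2], TRUE))
    if (dJ[j] < 0 && dJ[j + 1] >= 0)
      minimum <- refine(rho[j], rho[j + 2], FALSE)
  }
  out <- list(maxima = maxima, minimum = minimum,
              is_double_humped = !is.null(maxima) && nrow(maxima) == 2)
  if (find_vstar_too) out$Vstar <- find_vstar()
  out
}

# Central second difference of J at rho = 1/2 with two Richardson levels
# (eliminates the h^2 and h^4 error terms; remaining bias O(h^6)).
curvature_at_half <- function(rates, h = 2e-2) {
  d2 <- function(h) {
    (bulk_current(0.5 + h, rates) - 2 * bulk_current(0.5, rates) +
       bulk_current(0.5 - h, rates)) / h^2
  }
  r1 <- function(h) (4 * d2(h / 2) - d2(h)) / 3
  (16 * r1(h / 2) - r1(h)) / 15
}

#' Threshold repulsion of the double-humped fundamental diagram
#'
#' Bisection on the sign of the curvature of the fundamental diagram at
#' rho = 1/2 as a function of V.  The curvature changes sign at
#' V* = 2 ln 3, where the single maximum of J(rho) splits into two.
#'
#' @param lower,upper bracketing interval for V
#' @param tol bisection tolerance in V
#' @return the threshold V*
#' @export
find_vstar <- function(lower = 1, upper = 4, tol = 1e-10) {
  f <- function(V) curvature_at_half(glauber_rates(V))
  flo <- f(lower); fhi <- f(upper)
  if (flo >= 0 || fhi <= 0)
    stop("bracketing interval does not straddle the curvature sign change")
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (f(mid) < 0) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

#' @rdname find_vstar
#' @details `kls_vstar_exact()` returns the closed form 2 ln 3, for use as a
#'   reference value and in constructing rate tables at multiples of V*.
#' @export
kls_vstar_exact <- function() 2 * log(3)

#' Write a fundamental-diagram table to CSV
#'
#' Columns: V, rho, eta, J.
#'
#' @param rates a `kls_rates` object
#' @param file output path
#' @param grid number of density points
#' @return the data frame, invisibly
#' @export
write_fundamental_diagram <- function(rates, file, grid = 1001) {
  rho <- seq(1 / grid, 1 - 1 / grid, length.out = grid)
  df <- data.frame(V = rates$V, rho = rho,
                   eta = bulk_correlator(rho, rates),
                   J = bulk_current(rho, rates))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
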