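#' Rate tables for the 1D KLS exclusion process
#'
#' The model lives on a chain of nodes that are empty or singly occupied.
#' A particle at node i hops to an empty node i+1 with a rate
#' \eqn{\Gamma(k, n)} that depends on the occupation k of node i-1 and the
#' occupation n of node i+2.  A `kls_rates` object stores the four rates
#' together with the repulsion energy V (in units of kT) that parameterizes
#' them.
#'
#' For membership in the KLS class (whose bulk stationary state is the
#' Boltzmann measure of a nearest-neighbour lattice gas) the rates must
#' satisfy
#' \deqn{\Gamma(0,1) = e^{-V}\,\Gamma(1,0), \qquad
#'       \Gamma(0,1)+\Gamma(1,0) = \Gamma(0,0)+\Gamma(1,1).}
#'
#' @param V repulsion energy (dimensionless, kT units).  V > 0 is repulsive;
#'   negative values are accepted but flagged as attractive.
#' @return an object of class `kls_rates` with fields `V` and `gamma`
#'   (a 2x2 matrix, `gamma[k+1, n+1]` = \eqn{\Gamma(k,n)}).
#' @export
#' @examples
#' g <- glauber_rates(2 * kls_vstar_exact())
#' g$gamma
glauber_rates <- function(V) {
  stopifnot(is.numeric(V), length(V) == 1, is.finite(V))
  gam <- matrix(0, 2, 2, dimnames = list(k = c("0", "1"), n = c("0", "1")))
  for (k in 0:1) for (n in 0:1)
    gam[k + 1, n + 1] <- 1 / (1 + exp((n - k) * V))
  new_kls_rates(V, gam, family = "glauber")
}

#' @rdname glauber_rates
#' @details `tasep_rates()` is an explicit constructor for the pure TASEP
#'   limit with unit hop rate, provided for comparison with the TASEP
#'   literature.  (The Glauber table at V = 0 is a TASEP slowed by a factor
#'   2: all four rates equal 1/2.)  By convention the TASEP constructor has
#'   current-expansion coefficients a = b = 0.
#' @export
tasep_rates <- function() {
  gam <- matrix(1, 2, 2, dimnames = list(k = c("0", "1"), n = c("0", "1")))
  new_kls_rates(0, gam, family = "tasep")
}

#' @rdname glauber_rates
#' @details `as_rates()` builds an Antal-Schutz-type table in which the hop
#'   rate is independent of the left neighbour, \eqn{\Gamma(0,n)=\Gamma(1,n)},
#'   adjusted to satisfy the KLS class conditions:
#'   \eqn{\Gamma(1,0)=\Gamma(0,0)=1/(1+e^{-V})} and
#'   \eqn{\Gamma(0,1)=\Gamma(1,1)=e^{-V}\Gamma(1,0)}.
#' @export
as_rates <- function(V) {
  stopifnot(is.numeric(V), length(V) == 1, is.finite(V), V != 0)
  hi <- 1 / (1 + exp(-V))
  lo <- exp(-V) * hi
  gam <- matrix(c(hi, hi, lo, lo), 2, 2,
                dimnames = list(k = c("0", "1"), n = c("0", "1")))
  new_kls_rates(V, gam, family = "as")
}

#' @rdname glauber_rates
#' @param gamma 2x2 matrix of rates, `gamma[k+1, n+1]` = \eqn{\Gamma(k,n)}.
#' @param check if `TRUE`, require the KLS class conditions to hold at V.
#' @export
kls_rates <- function(V, gamma, check = TRUE) {
  stopifnot(is.matrix(gamma), all(dim(gamma) == c(2, 2)))
  dimnames(gamma) <- list(k = c("0", "1"), n = c("0", "1"))
  r <- new_kls_rates(V, gamma, family = "custom")
  if (check) assert_kls_class(r)
  r
}

new_kls_rates <- function(V, gamma, family) {
  if (any(gamma <= 0) || any(gamma > 1))
    stop("all four hop rates must be strictly positive and <= 1")
  structure(list(V = V, gamma = gamma, family = family,
                 attractive = V < 0),
            class = "kls_rates")
}

#' @export
print.kls_rates <- function(x, ...) {
  cat(sprintf("KLS rate table (%s), V = %g%s\n", x$family, x$V,
              if (isTRUE(x$attractive)) " [attractive]" else ""))
  print(x$gamma)
  invisible(x)
}

#' Accessor: rate for left occupation k, right-next occupation n
#' @param rates a `kls_rates` object
#' @param k,n occupations in {0, 1}
#' @export
rate_of <- function(rates, k, n) rates$gamma[k + 1, n + 1]

assert_kls_class <- function(rates, tol = 1e-12) {
  g <- rates$gamma
  d1 <- abs(g[1, 2] - exp(-rates$V) * g[2, 1])
  d2 <- abs(g[1, 2] + g[2, 1] - g[1, 1] - g[2, 2])
  if (d1 > tol || d2 > tol)
    stop(sprintf(
      "rate table violates the KLS class conditions (residuals %.3g, %.3g)",
      d1, d2))
  invisible(rates)
}

#' Coefficients a, b of the bulk current expansion
#'
#' The bulk current of a KLS-class table can be written
#' \eqn{J(\rho) = \Gamma(1,0)\{\eta\rho(1-\rho) + (1-\eta)(a+b\rho)\}} with
#' \deqn{a = \frac{\Gamma(1,0)-\Gamma(0,0)}{\Gamma(1,0)-\Gamma(0,1)}, \qquad
#'       b = \frac{\Gamma(0,0)-\Gamma(1,1)}{\Gamma(1,0)-\Gamma(0,1)}.}
#' Glauber rates give (a, b) = (1/2, 0); an Antal-Schutz-type table gives
#' (0, 1); the pure-TASEP constructor returns (0, 0) by convention (its
#' denominator vanishes, but there eta = 1 and the (1 - eta) term drops out).
#'
#' @param rates a `kls_rates` object
#' @return list with components `a` and `b`
#' @export
ab_coefficients <- function(rates) {
  g <- rates$gamma
  den <- g[2, 1] - g[1, 2]
  if (abs(den) < 1e-14) {
    if (identical(rates$family, "tasep")) return(list(a = 0, b = 0))
    stop("degenerate rates: Gamma(1,0) = Gamma(0,1); ",
         "use tasep_rates() for the pure TASEP limit")
  }
  list(a = (g[2, 1] - g[1, 1]) / den,
       b = (g[1, 1] - g[2, 2]) / den)
}
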