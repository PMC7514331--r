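#' Stationary profile of the pair approximation
#'
#' Solves f(x) = 0 for the open-chain pair-approximation kinetics by damped
#' Newton iteration with the analytic Jacobian, initialized from the
#' extremal-current bulk density with exponential boundary blending toward
#' the reservoir densities.  If Newton fails to converge the solver falls
#' back to stiff time integration (lsoda) until the residual is small, then
#' polishes with Newton again.
#'
#' @param bc a `kls_bc`
#' @param N chain length (>= 3)
#' @param init optional initial `kls_profile`
#' @param tol convergence tolerance on the sup-norm of f
#' @param max_iter Newton iteration cap
#' @param quiet suppress fallback messages
#' @return a `kls_profile` at the stationary state, with attributes
#'   `residual` (sup-norm of f) and `iterations`
#' @export
find_ness <- function(bc, N, init = NULL, tol = 1e-12, max_iter = 60,
                      quiet = TRUE) {
  stopifnot(N >= 3)
  x <- if (is.null(init)) ness_initial_guess(bc, N) else init$x
  res <- newton_solve(x, N, bc, tol, max_iter)
  if (!res$converged) {
    # stiff time integration with geometrically growing horizon, polishing
    # with Newton as soon as its (possibly small) basin is reached; near
    # phase boundaries the stationary profile sits on a slow manifold that
    # pure Newton cannot track from the bulk initial guess
    if (!quiet) message("Newton stalled (residual ", signif(res$resnorm, 3),
                        "); relaxing by stiff time integration")
    prof <- structure(list(N = N, x = res$x, t = 0), class = "kls_profile")
    t_chunk <- 100
    for (ch in 1:40) {
      sol <- pa_integrate(prof, bc, c(0, t_chunk), rtol = 1e-7, atol = 1e-10)
      prof$x <- clip_profile(as.numeric(sol[nrow(sol), -1]), N)
      fn <- max(abs(pa_rhs(prof$x, N, bc)$f))
      if (fn < 1e-4) {
        res <- newton_solve(prof$x, N, bc, tol, max_iter)
        if (res$converged) break
      }
      t_chunk <- min(t_chunk * 2, 1e5)
    }
    if (!res$converged)
      stop(sprintf(
        "find_ness did not converge: residual %.3g after integration fallback (rhoL=%g, rhoR=%g, N=%d)",
        res$resnorm, bc$rhoL, bc$rhoR, N))
  }
  out <- structure(list(N = N, x = res$x, t = Inf), class = "kls_profile")
  attr(out, "residual") <- res$resnorm
  attr(out, "iterations") <- res$iter
  out
}

newton_solve <- function(x, N, bc, tol, max_iter) {
  r <- pa_rhs(x, N, bc, want_grad = TRUE)
  fn <- max(abs(r$f))
  iter <- 0L
  while (fn > tol && iter < max_iter) {
    step <- tryCatch(solve(r$Jf, r$f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    improved <- FALSE
    while (lam > 1e-4) {
      xn <- clip_profile(x - lam * step, N)
      fnn <- max(abs(pa_rhs(xn, N, bc)$f))
      if (is.finite(fnn) && fnn < fn * (1 - 0.1 * lam) || fnn < tol) {
        x <- xn
        r <- pa_rhs(x, N, bc, want_grad = TRUE)
        fn <- fnn
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
    iter <- iter + 1L
  }
  list(x = x, resnorm = fn, iter = iter, converged = fn <= tol)
}

# keep the state inside the probability simplex (all four pair marginals
# nonnegative); used to damp Newton steps near phase boundaries
clip_profile <- function(x, N) {
  nx <- 2L * N - 1L
  ir <- seq(1L, nx, by = 2L)
  rho <- pmin(pmax(x[ir], 1e-12), 1 - 1e-12)
  x[ir] <- rho
  if (N >= 2) {
    ip <- seq(2L, nx - 1L, by = 2L)
    lo <- pmax(0, rho[-N] + rho[-1] - 1) + 1e-14
    hi <- pmin(rho[-N], rho[-1]) - 1e-14
    x[ip] <- pmin(pmax(x[ip], lo), hi)
  }
  x
}

ness_initial_guess <- function(bc, N) {
  ph <- classify_phase(max(min(bc$rhoL, 1 - 1e-6), 1e-6),
                       max(min(bc$rhoR, 1 - 1e-6), 1e-6), bc$rates)
  rb <- ph$bulk_density
  i <- seq_len(N)
  w <- 3
  rho <- rb + (bc$rhoL - rb) * exp(-(i - 1) / w) +
    (bc$rhoR - rb) * exp(-(N - i) / w)
  rho <- pmin(pmax(rho, 1e-9), 1 - 1e-9)
  rmid <- (rho[-N] + rho[-1]) / 2
  phi <- vapply(rmid, function(r) bulk_state(r, bc$rates)$p11, 0)
  x <- numeric(2 * N - 1)
  x[seq(1, 2 * N - 1, by = 2)] <- rho
  x[seq(2, 2 * N - 2, by = 2)] <- phi
  clip_profile(x, N)
}

#' Integrate the pair-approximation kinetics in time
#'
#' Wraps [deSolve::lsoda()] around the closed kinetic equations.  Useful
#' both as a relaxation fallback and as an independent check of the
#' spectral relaxation rate.
#'
#' @param profile starting `kls_profile`
#' @param bc a `kls_bc`
#' @param times output time points (first entry is the initial time)
#' @param ... passed to [deSolve::lsoda()]
#' @return matrix of states, one row per time point (deSolve convention:
#'   first column is time)
#' @export
pa_integrate <- function(profile, bc, times, rtol = 1e-10, atol = 1e-12,
                         ...) {
  N <- profile$N
  rhs <- function(t, y, parms) list(pa_rhs(y, N, bc)$f)
  jac <- function(t, y, parms) -relaxation_matrix_raw(y, N, bc)
  deSolve::lsoda(profile$x, times, rhs, parms = NULL,
                 jacfunc = jac, jactype = "fullusr",
                 rtol = rtol, atol = atol, ...)
}

relaxation_matrix_raw <- function(x, N, bc) {
  -pa_rhs(x, N, bc, want_grad = TRUE)$Jf
}

#' Relaxation matrix of the pair approximation
#'
#' The matrix M with entries \eqn{M_{ab} = -\partial f_a/\partial x_b}
#' evaluated at the stationary profile.  Its eigenvalues have positive real
#' part at a stable stationary state; the smallest real part is the slowest
#' relaxation rate.  M is banded (bandwidth <= 9) because the closure uses
#' a 4-site stencil.
#'
#' @param ness stationary `kls_profile` (from [find_ness()])
#' @param bc a `kls_bc`
#' @param check_fixed_point require the residual of f at `ness` to be small
#' @return dense (2N-1) x (2N-1) matrix
#' @export
relaxation_matrix <- function(ness, bc, check_fixed_point = TRUE) {
  if (check_fixed_point) {
    fn <- max(abs(pa_rhs(ness$x, ness$N, bc)$f))
    if (fn > 1e-8)
      stop("profile is not a fixed point (residual ", signif(fn, 3), ")")
  }
  relaxation_matrix_raw(ness$x, ness$N, bc)
}

#' Slowest relaxation rate of the pair approximation
#'
#' Computes the spectrum of the relaxation matrix and returns the smallest
#' real part, lambda_1, the inverse of the longest relaxation time.  A
#' complex slowest eigenvalue (oscillatory slowest mode) is flagged, and its
#' real part is reported as the rate.
#'
#' @inheritParams relaxation_matrix
#' @param nhead how many smallest-real-part eigenvalues to report
#' @param vectors also compute the eigenvector of the slowest mode
#' @return object of class `kls_relaxation`: list with `lambda1`,
#'   `spectrum_head`, `eigvec`, `is_complex`, `N`
#' @export
slowest_rate <- function(ness, bc, nhead = 6, vectors = FALSE,
                         check_fixed_point = TRUE) {
  M <- relaxation_matrix(ness, bc, check_fixed_point = check_fixed_point)
  ev <- eigen(M, only.values = !vectors)
  ord <- order(Re(ev$values))
  lam <- ev$values[ord[1]]
  if (Re(lam) < -1e-9)
    stop("negative-real-part eigenvalue (", format(lam),
         "): profile is not a stable stationary state")
  structure(list(
    lambda1 = Re(lam),
    spectrum_head = ev$values[ord[seq_len(min(nhead, length(ord)))]],
    eigvec = if (vectors) ev$vectors[, ord[1]] else NULL,
    is_complex = abs(Im(lam)) > 1e-10 * max(abs(Re(lam)), 1e-300),
    N = ness$N), class = "kls_relaxation")
}

#' @export
print.kls_relaxation <- function(x, ...) {
  cat(sprintf("PA relaxation: lambda1 = %.8g (N = %d)%s\n", x$lambda1, x$N,
              if (x$is_complex) " [complex slowest mode]" else ""))
  invisible(x)
}

#' Convenience: lambda1 for given reservoir densities and size
#'
#' @param rhoL,rhoR reservoir densities
#' @param rates a `kls_rates`
#' @param N chain length
#' @param ... passed to [find_ness()]
#' @return the slowest relaxation rate (scalar)
#' @export
pa_lambda1 <- function(rhoL, rhoR, rates, N, ...) {
  bc <- boundary_conditions(rhoL, rhoR, rates)
  ness <- find_ness(bc, N, ...)
  slowest_rate(ness, bc, check_fixed_point = FALSE)$lambda1
}

#' Decay rate from time integration (independent oracle)
#'
#' Perturbs a stationary profile, integrates the kinetics, and fits the
#' exponential tail of \eqn{\|x(t) - x^*\|} to estimate the slowest
#' relaxation rate without using the spectrum.
#'
#' @inheritParams relaxation_matrix
#' @param amplitude perturbation amplitude
#' @param t_end,nt integration horizon and number of sample points
#' @param tail_frac fraction of the latest samples used in the log-linear fit
#' @return fitted decay rate
#' @export
pa_decay_rate_fit <- function(ness, bc, amplitude = 1e-4, t_end = NULL,
                              nt = 60, tail_frac = 0.5) {
  N <- ness$N
  lam_guess <- slowest_rate(ness, bc, check_fixed_point = FALSE)$lambda1
  if (is.null(t_end)) t_end <- 6 / lam_guess
  # perturb along a smooth bulk-like mode, then let fast modes die out
  i <- seq_len(2 * N - 1)
  pert <- amplitude * sin(pi * i / (2 * N))
  x0 <- clip_profile(ness$x + pert, N)
  prof <- structure(list(N = N, x = x0, t = 0), class = "kls_profile")
  times <- seq(0, t_end, length.out = nt)
  sol <- pa_integrate(prof, bc, times)
  dev <- apply(sol[, -1, drop = FALSE], 1,
               function(row) sqrt(sum((row - ness$x)^2)))
  keep <- seq(ceiling(nt * (1 - tail_frac)), nt)
  keep <- keep[dev[keep] > 1e-13]
  fit <- stats::lm(log(dev[keep]) ~ times[keep])
  -as.numeric(stats::coef(fit)[2])
}
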