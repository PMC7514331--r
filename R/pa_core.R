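#' Boundary conditions for the open KLS chain
#'
#' Bulk-adapted boundary conditions couple the chain to reservoirs that
#' behave like semi-infinite systems in their own bulk stationary state at
#' densities `rhoL` and `rhoR`.  The object stores the reservoir 1- and
#' 2-node marginal tables, obtained from the exact bulk solution
#' ([bulk_state()]).  Reservoir densities of exactly 0 and 1 are supported:
#' the reservoir tables are evaluated in the analytic limit (numerically, at
#' a density clamped by 1e-12, which reproduces the limiting conditional
#' probabilities to machine precision; the correlator tends to 1 at both
#' endpoints).
#'
#' @param rhoL,rhoR reservoir densities in [0, 1]
#' @param rates a `kls_rates` object
#' @return object of class `kls_bc`
#' @export
boundary_conditions <- function(rhoL, rhoR, rates) {
  stopifnot(rhoL >= 0, rhoL <= 1, rhoR >= 0, rhoR <= 1)
  eps <- 1e-12
  bl <- bulk_state(min(max(rhoL, eps), 1 - eps), rates)
  br <- bulk_state(min(max(rhoR, eps), 1 - eps), rates)
  pairmat <- function(b) matrix(c(b$p00, b$p10, b$p01, b$p11), 2, 2)
  structure(list(rhoL = rhoL, rhoR = rhoR, rates = rates,
                 PL = bl, PR = br,
                 PLpair = pairmat(bl), PRpair = pairmat(br),
                 PLs = c(1 - bl$rho, bl$rho), PRs = c(1 - br$rho, br$rho)),
            class = "kls_bc")
}

#' @export
print.kls_bc <- function(x, ...) {
  cat(sprintf("KLS boundary conditions: rhoL = %g, rhoR = %g, V = %g\n",
              x$rhoL, x$rhoR, x$rates$V))
  invisible(x)
}

#' Pair-approximation profile state
#'
#' The pair approximation evolves the (2N-1)-component vector
#' x = (rho_1, phi_1, rho_2, phi_2, ..., rho_{N-1}, phi_{N-1}, rho_N),
#' where rho_i is the occupation probability of node i and phi_i the joint
#' occupation probability of nodes i, i+1.
#'
#' @param rho length-N density profile
#' @param phi length-(N-1) nearest-neighbour pair profile
#' @param t time stamp (bookkeeping only)
#' @return object of class `kls_profile` with fields `N`, `x`, `t`
#' @export
profile_state <- function(rho, phi, t = 0) {
  N <- length(rho)
  stopifnot(N >= 2, length(phi) == N - 1)
  x <- numeric(2 * N - 1)
  x[seq(1, 2 * N - 1, by = 2)] <- rho
  x[seq(2, 2 * N - 2, by = 2)] <- phi
  assert_profile(x, N)
  structure(list(N = N, x = x, t = t), class = "kls_profile")
}

#' @rdname profile_state
#' @param N chain length
#' @param rates a `kls_rates` object (used to pick the bulk pair correlator)
#' @details `profile_flat()` builds the spatially uniform profile at density
#'   `rho` with phi from the bulk solution, which is an exact stationary
#'   point when both reservoirs sit at the same density.
#' @export
profile_flat <- function(N, rho, rates) {
  b <- bulk_state(rho, rates)
  profile_state(rep(rho, N), rep(b$p11, N - 1))
}

#' @export
print.kls_profile <- function(x, ...) {
  cat(sprintf("KLS pair-approximation profile, N = %d, t = %g\n", x$N, x$t))
  r <- profile_rho(x)
  cat("  rho: ", paste(sprintf("%.4f", utils::head(r, 6)), collapse = " "),
      if (x$N > 6) "..." else "", "\n")
  invisible(x)
}

#' @rdname profile_state
#' @param profile a `kls_profile`
#' @export
profile_rho <- function(profile) profile$x[seq(1, 2 * profile$N - 1, by = 2)]

#' @rdname profile_state
#' @export
profile_phi <- function(profile) profile$x[seq(2, 2 * profile$N - 2, by = 2)]

assert_profile <- function(x, N, tol = 1e-9) {
  rho <- x[seq(1, 2 * N - 1, by = 2)]
  phi <- x[seq(2, 2 * N - 2, by = 2)]
  if (any(rho < -tol) || any(rho > 1 + tol))
    stop("density out of [0,1]")
  lo <- pmax(0, rho[-N] + rho[-1] - 1)
  hi <- pmin(rho[-N], rho[-1])
  if (any(phi < lo - tol) || any(phi > hi + tol))
    stop("pair marginal out of range (some P[mn] would be negative)")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Right-hand side f(x) of the pair-approximation kinetics and its Jacobian.
#
# Node indices are 1-based as in the profile vector; bond b = 0..N connects
# node b to node b+1 (bonds 0 and N touch the reservoirs).  The 4-node
# marginal P_i[k10n] (sites i..i+3) is closed as
#   P_i[k10n] = p~_i[k1] p~_{i+1}[10] p~_{i+2}[0n] / (s~_{i+1}[1] s~_{i+2}[0])
# with pair tables p~ taken from the left reservoir for i <= 0, the profile
# for 1 <= i <= N-1 and the right reservoir for i >= N, and single-site
# tables s~ from the left reservoir for i <= 1, the profile for
# 2 <= i <= N-1 and the right reservoir for i >= N.  Note that the
# single-site table at node 1 deliberately uses the left reservoir: the
# closure is implemented exactly as its defining equations are written.
# Profile-sourced denominators are floored at 1e-14.
# ---------------------------------------------------------------------------
pa_rhs <- function(x, N, bc, want_grad = FALSE, want_aux = FALSE) {
  if (!want_grad && !want_aux) return(pa_rhs_value(x, N, bc))
  nx <- 2L * N - 1L
  rho <- x[seq(1L, nx, by = 2L)]
  phi <- x[seq(2L, nx - 1L, by = 2L)]
  PLp <- bc$PLpair; PRp <- bc$PRpair
  sL <- bc$PLs; sR <- bc$PRs
  gam <- bc$rates$gamma
  # column order of the 4 (k, n) combinations: (0,0), (0,1), (1,0), (1,1)
  gvec <- c(gam[1, 1], gam[1, 2], gam[2, 1], gam[2, 2])
  dfloor <- 1e-14
  none <- list(ix = integer(0), dv = numeric(0))

  pairf <- function(j, m, n) {
    if (j <= 0) { v <- PLp[m + 1, n + 1]; return(list(v = v, ix = none$ix, dv = none$dv)) }
    if (j >= N) { v <- PRp[m + 1, n + 1]; return(list(v = v, ix = none$ix, dv = none$dv)) }
    irho <- 2L * j - 1L; irho2 <- 2L * j + 1L; iphi <- 2L * j
    if (m == 1L) {
      if (n == 1L) list(v = phi[j], ix = iphi, dv = 1)
      else list(v = rho[j] - phi[j], ix = c(irho, iphi), dv = c(1, -1))
    } else {
      if (n == 1L) list(v = rho[j + 1] - phi[j], ix = c(irho2, iphi), dv = c(1, -1))
      else list(v = 1 - rho[j] - rho[j + 1] + phi[j],
                ix = c(irho, irho2, iphi), dv = c(-1, -1, 1))
    }
  }
  singlef <- function(j, m) {
    if (j <= 1) { v <- sL[m + 1]; return(list(v = v, ix = none$ix, dv = none$dv)) }
    if (j >= N) { v <- sR[m + 1]; return(list(v = v, ix = none$ix, dv = none$dv)) }
    irho <- 2L * j - 1L
    if (m == 1L) list(v = rho[j], ix = irho, dv = 1)
    else list(v = 1 - rho[j], ix = irho, dv = -1)
  }

  nr <- N + 1L                     # closure rows i = -1 .. N-1, r = i + 2
  vals <- matrix(0, nr, 4L)
  if (want_grad) {
    dJb <- matrix(0, nr, nx)       # gradient of bond current r
    dgain <- matrix(0, nr, nx)     # gradient of sum_k P[k,1] Gamma(k,1)
    dloss <- matrix(0, nr, nx)     # gradient of sum_n P[1,n] Gamma(1,n)
  }

  for (r in seq_len(nr)) {
    i <- r - 2L
    F2 <- pairf(i + 1L, 1L, 0L)
    D1 <- singlef(i + 1L, 1L)
    D2 <- singlef(i + 2L, 0L)
    d1v <- max(D1$v, dfloor); d2v <- max(D2$v, dfloor)
    den <- d1v * d2v
    F1 <- list(pairf(i, 0L, 1L), pairf(i, 1L, 1L))
    F3 <- list(pairf(i + 2L, 0L, 0L), pairf(i + 2L, 0L, 1L))
    for (k in 0:1) for (n in 0:1) {
      f1 <- F1[[k + 1L]]; f3 <- F3[[n + 1L]]
      num <- f1$v * F2$v * f3$v
      P <- num / den
      col <- 2L * k + n + 1L
      vals[r, col] <- P
      if (want_grad) {
        g <- gvec[col]
        # accumulate factor by factor: indices repeat across factors, and
        # duplicated indices within one R subassignment would not add up
        add <- function(ix, dv) {
          if (!length(ix)) return(invisible())
          dJb[r, ix] <<- dJb[r, ix] + g * dv
          if (n == 1L) dgain[r, ix] <<- dgain[r, ix] + g * dv
          if (k == 1L) dloss[r, ix] <<- dloss[r, ix] + g * dv
        }
        add(f1$ix, f1$dv * (F2$v * f3$v / den))
        add(F2$ix, F2$dv * (f1$v * f3$v / den))
        add(f3$ix, f3$dv * (f1$v * F2$v / den))
        add(D1$ix, -P / d1v * D1$dv)
        add(D2$ix, -P / d2v * D2$dv)
      }
    }
  }

  Jb <- as.numeric(vals %*% gvec)            # bond currents, bonds 0..N
  gain <- vals[, 2L] * gvec[2L] + vals[, 4L] * gvec[4L]
  loss <- vals[, 3L] * gvec[3L] + vals[, 4L] * gvec[4L]

  f <- numeric(nx)
  irho_idx <- seq(1L, nx, by = 2L)
  f[irho_idx] <- Jb[seq_len(N)] - Jb[seq_len(N) + 1L]
  if (N >= 2) {
    iphi_idx <- seq(2L, nx - 1L, by = 2L)
    f[iphi_idx] <- gain[seq_len(N - 1L)] - loss[seq_len(N - 1L) + 2L]
  }

  out <- list(f = f, Jbond = Jb)
  if (want_aux) out$closure <- vals
  if (want_grad) {
    Jf <- matrix(0, nx, nx)
    Jf[irho_idx, ] <- dJb[seq_len(N), , drop = FALSE] -
      dJb[seq_len(N) + 1L, , drop = FALSE]
    if (N >= 2)
      Jf[iphi_idx, ] <- dgain[seq_len(N - 1L), , drop = FALSE] -
        dloss[seq_len(N - 1L) + 2L, , drop = FALSE]
    out$Jf <- Jf
  }
  out
}

# vectorized value-only evaluation of f(x); identical closure logic to the
# loop in pa_rhs (which also carries gradients), assembled with index shifts
pa_rhs_value <- function(x, N, bc) {
  nx <- 2L * N - 1L
  rho <- x[seq(1L, nx, by = 2L)]
  phi <- x[seq(2L, nx - 1L, by = 2L)]
  PLp <- bc$PLpair; PRp <- bc$PRpair
  sL <- bc$PLs; sR <- bc$PRs
  gam <- bc$rates$gamma
  dfloor <- 1e-14
  nr <- N + 1L                       # rows r = 1..N+1 are i = -1..N-1

  # profile pair tables padded so that index j is row j of the closure:
  # pr_*(j) valid for j = 1..N-1
  prv <- function(m, n) {
    if (m == 1L && n == 1L) phi
    else if (m == 1L) rho[1:(N - 1)] - phi
    else if (n == 1L) rho[2:N] - phi
    else 1 - rho[1:(N - 1)] - rho[2:N] + phi
  }
  # F1[k]: pair(i)[k1], i = -1..N-1
  F1 <- function(k) c(PLp[k + 1L, 2L], PLp[k + 1L, 2L], prv(k, 1L))
  # F2: pair(i+1)[10], i+1 = 0..N
  F2 <- c(PLp[2L, 1L], prv(1L, 0L), PRp[2L, 1L])
  # F3[n]: pair(i+2)[0n], i+2 = 1..N+1
  F3 <- function(n) c(prv(0L, n), PRp[1L, n + 1L], PRp[1L, n + 1L])
  mid <- if (N >= 3) rho[2:(N - 1)] else numeric(0)
  # D1: single(i+1)[1], i+1 = 0..N  (reservoir table at sites <= 1, >= N)
  D1 <- c(sL[2L], sL[2L], mid, sR[2L])
  # D2: single(i+2)[0], i+2 = 1..N+1
  D2 <- c(sL[1L], 1 - mid, sR[1L], sR[1L])
  den <- pmax(D1, dfloor) * pmax(D2, dfloor)

  Jb <- numeric(nr); gain <- numeric(nr); loss <- numeric(nr)
  for (k in 0:1) {
    f1 <- F1(k)
    for (n in 0:1) {
      P <- f1 * F2 * F3(n) / den
      g <- gam[k + 1L, n + 1L]
      Jb <- Jb + g * P
      if (n == 1L) gain <- gain + g * P
      if (k == 1L) loss <- loss + g * P
    }
  }
  f <- numeric(nx)
  f[seq(1L, nx, by = 2L)] <- Jb[seq_len(N)] - Jb[seq_len(N) + 1L]
  f[seq(2L, nx - 1L, by = 2L)] <- gain[seq_len(N - 1L)] -
    loss[seq_len(N - 1L) + 2L]
  list(f = f, Jbond = Jb)
}

#' Closed 4-node marginals of the pair approximation
#'
#' Returns the pair-approximation estimate of P_i[k10n], the joint
#' probability that nodes (i, i+1, i+2, i+3) are in state (k, 1, 0, n),
#' for all four (k, n) combinations.  Index i runs from -1 to N-1; rows
#' i <= 0 and i >= N-2 involve the reservoir tables of the bulk-adapted
#' boundary conditions.
#'
#' @param profile a `kls_profile`
#' @param bc a `kls_bc`
#' @param i marginal index in -1 .. N-1
#' @return 2x2 matrix with `[k+1, n+1]` = P_i[k10n]
#' @export
pa_closure_4site <- function(profile, bc, i) {
  N <- profile$N
  stopifnot(i >= -1, i <= N - 1)
  res <- pa_rhs(profile$x, N, bc, want_aux = TRUE)
  v <- res$closure[i + 2L, ]
  matrix(v, 2, 2, byrow = TRUE,
         dimnames = list(k = c("0", "1"), n = c("0", "1")))
}

#' Bond probability currents of the pair approximation
#'
#' The current across bond i (connecting node i to node i+1; bonds 0 and N
#' touch the reservoirs) is
#' \eqn{J_i = \sum_{k,n} P_{i-1}[k10n]\,\Gamma(k,n)}.
#'
#' @inheritParams pa_closure_4site
#' @param i optional bond index in 0..N; if `NULL` all N+1 bond currents
#'   are returned
#' @return current (scalar, or vector of length N+1)
#' @export
pa_bond_current <- function(profile, bc, i = NULL) {
  res <- pa_rhs(profile$x, profile$N, bc)
  if (is.null(i)) return(res$Jbond)
  stopifnot(i >= 0, i <= profile$N)
  res$Jbond[i + 1L]
}

#' Time derivative of the pair-approximation state vector
#'
#' Right-hand side f(x) of the closed kinetic equations
#' \eqn{\dot\rho_i = J_{i-1} - J_i} and
#' \eqn{\dot\phi_i = \sum_k P_{i-2}[k101]\Gamma(k,1)
#'      - \sum_n P_i[110n]\Gamma(1,n)}, assembled in the state-vector
#' ordering (rho_1, phi_1, ..., rho_N).
#'
#' @inheritParams pa_closure_4site
#' @return numeric vector of length 2N-1
#' @export
pa_time_derivative <- function(profile, bc) {
  pa_rhs(profile$x, profile$N, bc)$f
}
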