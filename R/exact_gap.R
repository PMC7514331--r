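#' Effective boundary rates of the bulk-adapted coupling
#'
#' Derives the injection, extraction and edge-hop rates of the finite-chain
#' master equation from the reservoir marginal tables, as conditional
#' reservoir averages of the bulk hop rate:
#' \itemize{
#'   \item injection at node 1 given n2 = n:
#'     \eqn{\alpha(n) = (P_L[10]/P_L[0]) \sum_k (P_L[k1]/P_L[1]) \Gamma(k,n)};
#'   \item left-edge hop 1 -> 2 given n3 = n:
#'     \eqn{\hat g_L(n) = \sum_k (P_L[k1]/P_L[1]) \Gamma(k,n)};
#'   \item right-edge hop N-1 -> N given n_{N-2} = k:
#'     \eqn{\hat g_R(k) = \sum_n (P_R[0n]/P_R[0]) \Gamma(k,n)};
#'   \item extraction at node N given n_{N-1} = k:
#'     \eqn{\beta(k) = (P_R[10]/P_R[1]) \sum_n (P_R[0n]/P_R[0]) \Gamma(k,n)}.
#' }
#' For N = 2 the single interior hop combines the two edge averages:
#' rate = \eqn{\sum_{k,n} (P_L[k1]/P_L[1])(P_R[0n]/P_R[0]) \Gamma(k,n)}.
#' Reservoir densities of exactly 0 or 1 are handled by the analytic limits
#' of the conditional tables.
#'
#' @param bc a `kls_bc`
#' @return list with `alpha` (length 2, indexed by n2 + 1), `gL` (length 2,
#'   by n3 + 1), `gR` (length 2, by n_{N-2} + 1), `beta` (length 2, by
#'   n_{N-1} + 1), and `hop2` (scalar, the N = 2 interior hop rate)
#' @export
boundary_rates <- function(bc) {
  gam <- bc$rates$gamma
  # conditional reservoir tables, analytic in (rho, eta): the (1-rho) and
  # rho factors of the bulk pair marginals cancel exactly
  rL <- bc$PL$rho; eL <- bc$PL$eta
  rR <- bc$PR$rho; eR <- bc$PR$eta
  condL_k_given_1 <- c(eL * (1 - rL), 1 - eL * (1 - rL))  # P_L[k1]/P_L[1]
  injL <- eL * rL                                         # P_L[10]/P_L[0]
  condR_n_given_0 <- c(1 - eR * rR, eR * rR)              # P_R[0n]/P_R[0]
  extR <- eR * (1 - rR)                                   # P_R[10]/P_R[1]
  gL <- vapply(0:1, function(n) sum(condL_k_given_1 * gam[, n + 1]), 0)
  gR <- vapply(0:1, function(k) sum(condR_n_given_0 * gam[k + 1, ]), 0)
  hop2 <- sum(outer(condL_k_given_1, condR_n_given_0) * gam)
  list(alpha = injL * gL, gL = gL, gR = gR, beta = extR * gR, hop2 = hop2)
}

#' Master-equation generator of the finite open chain
#'
#' Builds the sparse 2^N x 2^N rate matrix Q of the full master equation
#' with bulk-adapted boundary rates (columns indexed by source
#' configuration; every column sums to zero).  Configurations are packed as
#' integers with node 1 in the most significant bit position.
#'
#' @param N chain length (2 <= N; memory grows as ~N 2^N)
#' @param bc a `kls_bc`
#' @return object of class `kls_generator`: list with `N`, `Q`
#'   (a `Matrix::dgCMatrix`), `boundary` (the [boundary_rates()] tables)
#' @export
build_generator <- function(N, bc) {
  stopifnot(N >= 2)
  if (N > 24) stop("N = ", N, " needs more than ~", round(2^N * N * 16 / 2^30, 1),
                   " GiB for the sparse generator; refusing")
  br <- boundary_rates(bc)
  gam <- bc$rates$gamma
  nstates <- 2^N
  states <- 0:(nstates - 1)
  bit <- function(s, i) bitwAnd(bitwShiftR(s, N - i), 1L)  # node i, 1 = MSB

  from <- integer(0); to <- integer(0); rate <- numeric(0)
  add <- function(src, dst, r) {
    keep <- r > 0
    from <<- c(from, src[keep]); to <<- c(to, dst[keep])
    rate <<- c(rate, r[keep])
  }

  # injection at node 1 (requires n1 = 0), rate alpha(n2)
  n1 <- bit(states, 1L)
  sel <- n1 == 0L
  add(states[sel], states[sel] + bitwShiftL(1L, N - 1L),
      br$alpha[bit(states[sel], 2L) + 1L])
  # extraction at node N (requires nN = 1), rate beta(n_{N-1})
  nN <- bit(states, N)
  sel <- nN == 1L
  add(states[sel], states[sel] - 1L, br$beta[bit(states[sel], N - 1L) + 1L])
  # hops i -> i+1
  for (i in seq_len(N - 1)) {
    sel <- bit(states, i) == 1L & bit(states, i + 1L) == 0L
    src <- states[sel]
    dst <- src - bitwShiftL(1L, N - i) + bitwShiftL(1L, N - i - 1L)
    r <- if (N == 2) {
      rep(br$hop2, length(src))
    } else if (i == 1) {
      br$gL[bit(src, 3L) + 1L]
    } else if (i == N - 1) {
      br$gR[bit(src, N - 2L) + 1L]
    } else {
      gam[cbind(bit(src, i - 1L) + 1L, bit(src, i + 2L) + 1L)]
    }
    add(src, dst, r)
  }

  Q <- Matrix::sparseMatrix(i = to + 1L, j = from + 1L, x = rate,
                            dims = c(nstates, nstates))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::colSums(Q)
  structure(list(N = N, Q = Q, boundary = br, bc = bc),
            class = "kls_generator")
}

#' @export
print.kls_generator <- function(x, ...) {
  cat(sprintf("KLS master-equation generator: N = %d (%d states, %d nonzeros)\n",
              x$N, nrow(x$Q), Matrix::nnzero(x$Q)))
  invisible(x)
}

#' Stationary distribution of a finite generator
#'
#' Solves Q pi = 0, sum(pi) = 1 (dense LU on the bordered system for
#' moderate N).
#'
#' @param gen a `kls_generator`
#' @return numeric probability vector over configurations
#' @export
stationary_distribution <- function(gen) {
  n <- nrow(gen$Q)
  A <- as.matrix(gen$Q)
  A[n, ] <- 1  # replace one redundant balance row with normalization
  b <- c(rep(0, n - 1), 1)
  pi <- solve(A, b)
  pi[pi < 0 & pi > -1e-14] <- 0
  pi / sum(pi)
}

#' Per-site stationary densities from a configuration distribution
#'
#' @param gen a `kls_generator`
#' @param pi stationary vector (computed if missing)
#' @return length-N vector of site occupation probabilities
#' @export
stationary_densities <- function(gen, pi = NULL) {
  if (is.null(pi)) pi <- stationary_distribution(gen)
  N <- gen$N
  states <- 0:(2^N - 1)
  vapply(seq_len(N), function(i)
    sum(pi[bitwAnd(bitwShiftR(states, N - i), 1L) == 1L]), 0)
}

#' Spectral gap of the master equation
#'
#' The smallest nonzero decay rate: eigenvalues of -Q have nonnegative real
#' part, with a simple zero mode (the stationary state); the gap is the
#' smallest real part among the rest.  Dense eigendecomposition is used up
#' to `dense_limit` sites; above that a deterministic block subspace
#' iteration on the uniformized chain I + Q/Lambda extracts the dominant
#' modes, which are precisely the zero mode and the slowest decay modes
#' since the whole spectrum of Q lies in the closed left half plane.
#'
#' @param gen a `kls_generator`
#' @param dense_limit largest N solved with the dense eigensolver
#' @param nev number of eigenvalues requested from the sparse path
#' @return list with `gap`, `is_complex`, `eigenvalue` (the full complex
#'   decay rate), `method`
#' @export
spectral_gap <- function(gen, dense_limit = 9, nev = 6) {
  if (gen$N <= dense_limit) {
    dec <- eigen(-as.matrix(gen$Q), only.values = TRUE)$values
    method <- "dense"
  } else {
    dec <- arnoldi_small_decay_rates(gen$Q, nev)
    method <- "shift-invert-arnoldi"
  }
  zero <- abs(dec) < 1e-10
  if (!any(zero))
    stop("no zero mode found among computed eigenvalues")
  if (sum(zero) > 1)
    stop("ambiguous zero-mode separation; near-zero spectrum: ",
         paste(format(dec[abs(dec) < 1e-8]), collapse = ", "))
  rest <- dec[!zero]
  lam <- rest[which.min(Re(rest))]
  if (Re(lam) <= 0)
    stop("nonpositive decay rate ", format(lam), ": generator is not ergodic?")
  list(gap = Re(lam),
       is_complex = abs(Im(lam)) > 1e-10 * max(Re(lam), 1e-300),
       eigenvalue = lam, method = method)
}

# Slowest decay rates of -Q by block subspace iteration on the uniformized
# chain P = I + Q/Lambda (Lambda >= max exit rate): P is substochastic-free
# with spectrum in the unit disk, and the eigenvalues of largest modulus,
# mu ~ 1 - lambda/Lambda, are exactly the zero mode and the slowest decay
# modes.  Rayleigh-Ritz on the iterated block extracts them; the start
# block is deterministic so results are reproducible.
arnoldi_small_decay_rates <- function(Q, nev = 6, tol = 1e-11,
                                      max_outer = 2000) {
  n <- nrow(Q)
  Lam <- max(abs(Matrix::diag(Q))) * 1.05
  b <- min(n, max(2 * nev, 12))
  applyP <- function(V) as.matrix(V + (Q %*% V) / Lam)
  # deterministic, incoherent start block
  V <- qr.Q(qr(outer(seq_len(n), seq_len(b),
                     function(i, j) cos(i * j * 0.7123 + j))))
  prev <- rep(Inf, nev)
  for (it in seq_len(max_outer)) {
    for (s in 1:4) V <- applyP(V)
    V <- qr.Q(qr(V))
    H <- crossprod(V, applyP(V))
    mu <- eigen(H, only.values = TRUE)$values
    lam <- Lam * (1 - mu)
    lam <- lam[order(Re(lam))][seq_len(nev)]
    if (max(abs(lam - prev)) < tol * Lam) break
    prev <- lam
  }
  if (it == max_outer)
    warning("subspace iteration reached the iteration cap; ",
            "smallest decay rates may not be fully converged")
  lam
}

#' Finite-size gap sequence and extrapolation pipeline
#'
#' Computes the spectral gap for a range of chain lengths and extrapolates
#' to infinite size with the Bulirsch-Stoer algorithm applied to trailing
#' subsequences (N = a..max for several a), reporting each extrapolant, a
#' pooled estimate and a spread-based reliability flag.
#'
#' @param bc a `kls_bc`
#' @param N_range integer vector of chain lengths (increasing)
#' @param omega leading finite-size exponent for the extrapolation
#' @param n_subseq number of trailing subsequences to extrapolate
#' @param spread_tol relative spread above which the pooled result is
#'   flagged unreliable
#' @param dense_limit passed to [spectral_gap()]
#' @return object of class `kls_gap_extrapolation`: list with `gaps` (data
#'   frame N, gap, is_complex), `subsequences` (data frame N_min, limit,
#'   spread), `limit`, `spread`, `reliable`
#' @export
gap_extrapolation_pipeline <- function(bc, N_range = 4:12, omega = 2,
                                       n_subseq = 4, spread_tol = 0.05,
                                       dense_limit = 9) {
  N_range <- sort(unique(as.integer(N_range)))
  gaps <- vapply(N_range, function(N) {
    sg <- spectral_gap(build_generator(N, bc), dense_limit = dense_limit)
    c(sg$gap, sg$is_complex)
  }, numeric(2))
  gapdf <- data.frame(N = N_range, gap = gaps[1, ],
                      is_complex = as.logical(gaps[2, ]))
  nmax_start <- length(N_range) - 2  # need >= 3 points per subsequence
  starts <- seq_len(min(n_subseq, nmax_start))
  sub <- do.call(rbind, lapply(starts, function(s) {
    t <- bst_extrapolate(gapdf$gap[s:length(N_range)],
                         N_range[s:length(N_range)], omega)
    data.frame(N_min = N_range[s], limit = t$limit, spread = t$spread)
  }))
  limit <- stats::median(sub$limit)
  spread <- max(max(sub$spread), max(abs(sub$limit - limit)))
  structure(list(gaps = gapdf, subsequences = sub, limit = limit,
                 spread = spread, omega = omega,
                 reliable = spread <= spread_tol * max(abs(limit), 1e-300)),
            class = "kls_gap_extrapolation")
}

#' @export
print.kls_gap_extrapolation <- function(x, ...) {
  cat(sprintf(
    "exact-gap extrapolation (omega = %g): limit = %.8g +- %.2g%s\n",
    x$omega, x$limit, x$spread,
    if (!x$reliable) " [UNRELIABLE: high spread]" else ""))
  print(x$subsequences, row.names = FALSE)
  invisible(x)
}
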