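#' Kinetic Monte Carlo simulation on a ring
#'
#' Rejection-free continuous-time simulation of the KLS dynamics on a
#' periodic lattice at fixed particle number.  Every bond with a particle
#' to its left and a hole to its right carries an exponential clock with
#' rate \eqn{\Gamma(n_{i-1}, n_{i+2})}; events are drawn proportionally to
#' the current rates and the affected neighbourhood rates are updated in
#' place.  Time-averaged current and occupations are accumulated with
#' batch-means standard errors.
#'
#' @param N ring size
#' @param n_particles number of particles (0 < n < N)
#' @param rates a `kls_rates`
#' @param t_max simulated time span
#' @param seed RNG seed (mandatory, for reproducibility)
#' @param burn_in fraction of `t_max` discarded before accumulating
#' @param n_batches number of batches for the standard errors
#' @return object of class `kls_kmc`: list with `current`, `current_se`,
#'   `density` (per-site time averages), `density_se`, `phi` (nearest-
#'   neighbour pair average), `phi_se`, `n_events`, `seed`
#' @export
simulate_ring <- function(N, n_particles, rates, t_max = 1e3, seed,
                          burn_in = 0.2, n_batches = 50) {
  stopifnot(n_particles > 0, n_particles <= N, !missing(seed))
  set.seed(seed)
  occ <- integer(N)
  occ[sample.int(N, n_particles)] <- 1L
  gam <- rates$gamma
  wrap <- function(i) ((i - 1L) %% N) + 1L
  bond_rate <- function(i) {
    # hop i -> i+1 on the ring
    if (occ[i] == 1L && occ[wrap(i + 1L)] == 0L)
      gam[occ[wrap(i - 1L)] + 1L, occ[wrap(i + 2L)] + 1L]
    else 0
  }
  rate <- vapply(seq_len(N), bond_rate, 0)
  kmc_run(occ, rate, t_max, burn_in, n_batches, seed,
          jump = function(b) {
            occ[b] <<- 0L; occ[wrap(b + 1L)] <<- 1L
            for (j in (b - 2L):(b + 2L)) {
              jj <- wrap(j)
              rate[jj] <<- bond_rate(jj)
            }
            b  # crossing counted on bond b
          },
          get_occ = function() occ, get_rate = function() rate,
          n_bonds = N)
}

#' Kinetic Monte Carlo simulation of the open chain
#'
#' Same engine as [simulate_ring()] for the open chain coupled to
#' reservoirs with the bulk-adapted boundary rates of [boundary_rates()]:
#' bond 0 injects at node 1 with rate alpha(n2), bond N extracts from node
#' N with rate beta(n_{N-1}), edge bonds use the reservoir-averaged rates
#' and interior bonds the bare \eqn{\Gamma(n_{i-1}, n_{i+2})}.
#'
#' @param N chain length (>= 3)
#' @param bc a `kls_bc`
#' @param t_max simulated time span
#' @param seed RNG seed (mandatory)
#' @param init optional initial occupation vector (defaults to independent
#'   fill at the mean reservoir density)
#' @inheritParams simulate_ring
#' @return a `kls_kmc` object (bond current averaged over all N+1 bonds;
#'   `bond_current` holds the per-bond averages)
#' @export
simulate_open <- function(N, bc, t_max = 1e3, seed, burn_in = 0.2,
                          n_batches = 50, init = NULL) {
  stopifnot(N >= 3, !missing(seed))
  set.seed(seed)
  br <- boundary_rates(bc)
  gam <- bc$rates$gamma
  occ <- if (is.null(init)) {
    as.integer(stats::runif(N) < (bc$rhoL + bc$rhoR) / 2)
  } else as.integer(init)
  bond_rate <- function(b) {
    # bond b = 0..N, stored at index b+1
    if (b == 0L) {
      if (occ[1L] == 0L) br$alpha[occ[2L] + 1L] else 0
    } else if (b == N) {
      if (occ[N] == 1L) br$beta[occ[N - 1L] + 1L] else 0
    } else if (occ[b] == 1L && occ[b + 1L] == 0L) {
      if (b == 1L) br$gL[occ[3L] + 1L]
      else if (b == N - 1L) br$gR[occ[N - 2L] + 1L]
      else gam[occ[b - 1L] + 1L, occ[b + 2L] + 1L]
    } else 0
  }
  rate <- vapply(0:N, bond_rate, 0)
  kmc_run(occ, rate, t_max, burn_in, n_batches, seed,
          jump = function(bidx) {
            b <- bidx - 1L       # bond number
            if (b == 0L) occ[1L] <<- 1L
            else if (b == N) occ[N] <<- 0L
            else { occ[b] <<- 0L; occ[b + 1L] <<- 1L }
            for (j in max(0L, b - 2L):min(N, b + 2L))
              rate[j + 1L] <<- bond_rate(j)
            bidx
          },
          get_occ = function() occ, get_rate = function() rate,
          n_bonds = N + 1L)
}

# shared continuous-time engine: `jump` applies event at catalogue index b,
# updates the closure-over variables, and returns the bond index to count.
kmc_run <- function(occ, rate, t_max, burn_in, n_batches, seed,
                    jump, get_occ, get_rate, n_bonds) {
  t <- 0
  t_start <- burn_in * t_max
  batch_len <- (t_max - t_start) / n_batches
  nsites <- length(occ)
  occ_acc <- numeric(nsites)
  phi_acc <- 0
  counts <- numeric(n_bonds)          # crossings since accumulation start
  batch_counts <- matrix(0, n_batches, n_bonds)
  batch_occ <- matrix(0, n_batches, nsites)
  batch_phi <- numeric(n_batches)
  n_events <- 0L
  ring <- n_bonds == nsites

  pair_sum <- function(o) {
    if (ring) sum(o * o[c(2:nsites, 1L)]) else sum(o[-nsites] * o[-1L])
  }

  accumulate <- function(t0, t1) {
    if (t1 <= t_start) return(invisible())
    lo <- max(t0, t_start)
    dt <- t1 - lo
    if (dt <= 0) return(invisible())
    o <- get_occ()
    occ_acc <<- occ_acc + dt * o
    phi_acc <<- phi_acc + dt * pair_sum(o)
    b0 <- min(n_batches, 1L + floor((lo - t_start) / batch_len))
    b1 <- min(n_batches, 1L + floor((t1 - t_start - 1e-12) / batch_len))
    ps <- pair_sum(o)
    for (bb in b0:b1) {
      s0 <- t_start + (bb - 1) * batch_len
      s1 <- s0 + batch_len
      d <- max(0, min(t1, s1) - max(lo, s0))
      batch_occ[bb, ] <<- batch_occ[bb, ] + d * o
      batch_phi[bb] <<- batch_phi[bb] + d * ps
    }
    invisible()
  }

  while (t < t_max) {
    rates_now <- get_rate()
    tot <- sum(rates_now)
    if (tot <= 0) {                   # absorbing (jammed ring, empty chain
      accumulate(t, t_max)            # with no injection, ...)
      t <- t_max
      break
    }
    dt <- stats::rexp(1, tot)
    t_new <- min(t + dt, t_max)
    accumulate(t, t_new)
    if (t + dt > t_max) { t <- t_max; break }
    t <- t_new
    b <- sample.int(length(rates_now), 1L, prob = rates_now)
    bcounted <- jump(b)
    n_events <- n_events + 1L
    if (t > t_start) {
      counts[bcounted] <- counts[bcounted] + 1
      bb <- min(n_batches, 1L + floor((t - t_start) / batch_len))
      batch_counts[bb, bcounted] <- batch_counts[bb, bcounted] + 1
    }
  }

  t_acc <- t_max - t_start
  dens <- occ_acc / t_acc
  batch_cur <- rowMeans(batch_counts) / batch_len   # per-bond mean current
  cur <- mean(counts) / t_acc
  cur_se <- stats::sd(batch_cur) / sqrt(n_batches)
  batch_dens <- batch_occ / batch_len
  dens_se <- apply(batch_dens, 2, stats::sd) / sqrt(n_batches)
  npairs <- if (ring) nsites else nsites - 1L
  structure(list(
    current = cur, current_se = cur_se,
    bond_current = counts / t_acc,
    density = dens, density_se = dens_se,
    phi = phi_acc / t_acc / npairs,
    phi_se = stats::sd(batch_phi / batch_len / npairs) / sqrt(n_batches),
    n_events = n_events, t_max = t_max, seed = seed),
    class = "kls_kmc")
}

#' @export
print.kls_kmc <- function(x, ...) {
  cat(sprintf(
    "KMC run: %d events, current = %.6g +- %.2g, mean density = %.4f\n",
    x$n_events, x$current, x$current_se, mean(x$density)))
  invisible(x)
}
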