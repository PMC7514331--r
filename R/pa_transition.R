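#' Locate the pair-approximation dynamical transition
#'
#' In the fast phase the relaxation rate is independent of the left
#' reservoir density, so its asymptotic value can be computed at rhoL = 1
#' (deep in the fast phase) by extrapolating lambda_1 over a sequence of
#' sizes with the Bulirsch-Stoer algorithm (the approach to the asymptote
#' is ~ N^-2 there).  The dynamical transition is then located as the rhoL
#' where the finite-size rate at the working size `N_big` first reaches
#' this plateau, coming from the slow phase where the rate grows from zero
#' at the LD/HD coexistence line.
#'
#' For an HD phase that extends to rhoL = 1 the plateau is anchored there;
#' for an HD phase bounded above by another coexistence line (the lower HD
#' phase of a double-humped diagram, whose fast phase is central), rhoL = 1
#' lies in a maximal-current phase where the rate is not defined, so the
#' plateau is anchored at the argmax of the finite-size rate inside the HD
#' range (the fast phase is where the rate is maximal).  Such a phase can
#' yield two crossings, one per flanking slow phase.
#'
#' @param rhoR right reservoir density (in an HD phase)
#' @param rates a `kls_rates`
#' @param N_big working size for the rhoL scan
#' @param N_seq sizes used to extrapolate the fast-phase plateau
#' @param rhoL_range scan interval; defaults to the HD phase extent
#'   (coexistence boundary, 1)
#' @param resolution bisection resolution in rhoL
#' @param omega BST exponent
#' @param coarse_step step of the bracketing scan
#' @return object of class `kls_pa_transition`: list with `rhoL_star`
#'   (numeric vector of crossings; empty if none found), `plateau`,
#'   `plateau_bst`, `N_big`, `scan` (the coarse scan table), `status`
#' @export
pa_transition_locator <- function(rhoR, rates, N_big = 200,
                                  N_seq = c(50, 100, 200),
                                  rhoL_range = NULL, resolution = 1e-3,
                                  omega = 2, coarse_step = 0.02) {
  if (is.null(rhoL_range)) rhoL_range <- hd_phase_rhoL_range(rhoR, rates)
  if (diff(rhoL_range) <= 0) {
    return(structure(list(rhoL_star = rhoL_range[1], plateau = NA_real_,
                          plateau_bst = NULL, N_big = N_big, scan = NULL,
                          status = "degenerate-range"),
                     class = "kls_pa_transition"))
  }
  lo <- rhoL_range[1] + resolution
  hi <- rhoL_range[2] - if (rhoL_range[2] < 1) resolution else 0
  grid <- unique(c(seq(lo, hi, by = coarse_step), hi))
  lam_big <- vapply(grid, function(rL) pa_lambda1(rL, rhoR, rates, N_big), 0)
  anchor <- if (rhoL_range[2] >= 1) 1 else grid[which.max(lam_big)]
  lam_plateau <- vapply(N_seq, function(N)
    pa_lambda1(anchor, rhoR, rates, N), 0)
  bst <- bst_extrapolate(lam_plateau, N_seq, omega)
  plateau <- bst$limit
  g <- lam_big - plateau
  scan <- data.frame(rhoL = grid, lambda1 = lam_big)
  idx <- which(g[-1] * g[-length(g)] < 0)
  if (length(idx) == 0) {
    return(structure(list(rhoL_star = numeric(0), plateau = plateau,
                          plateau_bst = bst, anchor = anchor, N_big = N_big,
                          scan = scan,
                          status = "no transition detected in range"),
                     class = "kls_pa_transition"))
  }
  roots <- vapply(idx, function(j) {
    a <- grid[j]; b <- grid[j + 1]
    fa <- g[j]
    while (b - a > resolution) {
      m <- (a + b) / 2
      fm <- pa_lambda1(m, rhoR, rates, N_big) - plateau
      if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
    }
    (a + b) / 2
  }, 0)
  structure(list(rhoL_star = roots, plateau = plateau, plateau_bst = bst,
                 anchor = anchor, N_big = N_big, scan = scan, status = "ok"),
            class = "kls_pa_transition")
}

#' @export
print.kls_pa_transition <- function(x, ...) {
  cat(sprintf("PA dynamical transition (N = %d): plateau lambda1 = %.8g\n",
              x$N_big, x$plateau))
  if (length(x$rhoL_star)) {
    cat("  crossings at rhoL* =",
        paste(sprintf("%.4f", x$rhoL_star), collapse = ", "), "\n")
  } else cat(" ", x$status, "\n")
  invisible(x)
}
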