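#' Cluster entropies and entropy cumulants
#'
#' Diagnostics for the pair-factorization assumption.  For a chain with
#' per-site 1-node marginals P_i[n], 2-node marginals P_i[n_i, n_{i+1}] and
#' (optionally) 3-node marginals, the cluster entropies are
#' \deqn{S_i = -\sum_n P_i[n]\ln P_i[n], \qquad
#'       S_{i,i+1} = -\sum_{n,m} P_i[n,m]\ln P_i[n,m]}
#' (natural logarithms, with 0 ln 0 = 0), the 2-node cumulant is
#' \eqn{\tilde S_{i,i+1} = S_{i,i+1} - S_i - S_{i+1}} (minus the mutual
#' information, hence always <= 0), and the 3-node cumulant is
#' \eqn{\tilde S_{i,i+1,i+2} = S_{i,i+1,i+2} - S_{i,i+1} - S_{i+1,i+2}
#' + S_{i+1}}.  Under exact pair factorization all 3-node (and higher)
#' cumulants vanish, which is the defining property of the bulk stationary
#' state of the KLS chain and the closure assumption of the pair
#' approximation.
#'
#' @param p1 list (or single vector) of 1-node marginals, each length 2
#'   (probabilities of occupation 0, 1)
#' @param p2 list (or single 2x2 matrix) of 2-node marginals,
#'   `p2[[i]][m+1, n+1]` = P(n_i = m, n_{i+1} = n)
#' @param p3 optional list of 2x2x2 arrays of 3-node marginals
#' @param tol normalization tolerance
#' @return list with vectors `s1`, `s2`, `c2` and, if `p3` given, `c3`
#' @export
entropy_cumulants <- function(p1, p2, p3 = NULL, tol = 1e-10) {
  if (is.numeric(p1)) p1 <- list(p1)
  if (is.matrix(p2)) p2 <- list(p2)
  if (!is.null(p3) && is.array(p3) && length(dim(p3)) == 3) p3 <- list(p3)
  check_table <- function(p, what) {
    if (any(unlist(p) < 0)) stop("negative probability in ", what)
    bad <- vapply(p, function(t) abs(sum(t) - 1) > tol, TRUE)
    if (any(bad)) stop(what, " not normalized to within ", tol)
  }
  check_table(p1, "1-node marginals")
  check_table(p2, "2-node marginals")
  if (!is.null(p3)) check_table(p3, "3-node marginals")
  s1 <- vapply(p1, shannon_nats, 0)
  s2 <- vapply(p2, shannon_nats, 0)
  n2 <- length(s2)
  if (length(s1) < n2 + 1)
    stop("need one more 1-node marginal than 2-node marginals")
  c2 <- s2 - s1[seq_len(n2)] - s1[seq_len(n2) + 1]
  out <- list(s1 = s1, s2 = s2, c2 = c2)
  if (!is.null(p3)) {
    s3 <- vapply(p3, shannon_nats, 0)
    n3 <- length(s3)
    if (n2 < n3 + 1)
      stop("need one more 2-node marginal than 3-node marginals")
    out$c3 <- s3 - s2[seq_len(n3)] - s2[seq_len(n3) + 1] + s1[seq_len(n3) + 1]
  }
  out
}

shannon_nats <- function(p) {
  p <- as.numeric(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Pair-factorized 3-node marginal
#'
#' Builds the 3-node marginal implied by pair factorization,
#' \eqn{P[n_1 n_2 n_3] = P_{12}[n_1 n_2] P_{23}[n_2 n_3] / P_2[n_2]},
#' e.g. from a bulk state.  Its 3-node entropy cumulant is exactly zero.
#'
#' @param p2a,p2b 2x2 pair marginals of the two bonds
#' @param p1mid length-2 single-site marginal of the shared middle site
#' @return 2x2x2 array, dimensions ordered (n1, n2, n3)
#' @export
factorized_3site <- function(p2a, p2b, p1mid) {
  out <- array(0, c(2, 2, 2))
  for (m in 1:2) for (l in 1:2) for (r in 1:2) {
    den <- p1mid[m]
    out[l, m, r] <- if (den > 0) p2a[l, m] * p2b[m, r] / den else 0
  }
  out
}

#' @rdname factorized_3site
#' @param bulk a `kls_bulk` state
#' @return for `bulk_pair_matrix`: the 2x2 pair marginal of a bulk state
#' @export
bulk_pair_matrix <- function(bulk) {
  matrix(c(bulk$p00, bulk$p10, bulk$p01, bulk$p11), 2, 2,
         dimnames = list(n1 = c("0", "1"), n2 = c("0", "1")))
}
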