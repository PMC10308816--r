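# Maximum-likelihood estimation of the regional canonical partition
# functions Omega_A(k), Omega_B(k) from a pooled count matrix.
#
# The likelihood of the counts factorizes over frames with per-frame
# probability Omega_A(k) Omega_B(N - k) / Z_N, Z_N = sum_k Omega_A(k)
# Omega_B(N - k).  Eliminating the per-N normalization multipliers
# analytically yields the coupled self-consistent updates
#
#   Omega_A(k) <- A_k / sum_N L_N Omega_B(N - k) / Z_N
#   Omega_B(k) <- B_k / sum_N L_N Omega_A(N - k) / Z_N
#
# iterated with Z_N refreshed every sweep and the gauge Omega_A(0) =
# Omega_B(0) = 1 re-fixed after each sweep.  A residual lambda^k tilt
# freedom remains; it is harmless because the chemical potential is always
# re-calibrated from a buffer concentration, which makes every
# concentration-indexed observable gauge invariant (tested, not assumed).

#' Solve for the regional canonical partition functions
#'
#' Fixed-point iteration for the maximum-likelihood estimates of
#' `Omega_A(k)` and `Omega_B(k)` given pooled frame counts from
#' constant-N trajectories.  Occupancies never observed in a region
#' (`A[k] == 0` or `B[k] == 0`) have their `Omega` pinned to zero and are
#' excluded from the update denominators.  Fractional (real-valued) counts,
#' as produced by Dirichlet-weighted bootstrap resampling, are accepted
#' unchanged.
#'
#' @param counts A `count_matrix` (see [build_count_matrix()]); `t` may be
#'   real-valued.
#' @param tol Convergence tolerance on the maximum relative change of any
#'   nonzero `Omega` entry between sweeps.
#' @param max_iter Maximum number of sweeps; exceeding it flags
#'   non-convergence (never silent).
#' @param init Optional list with components `omega_A`, `omega_B` used as a
#'   warm start (e.g. the point estimate when bootstrapping).
#' @param likelihood_trace Record the log-likelihood at every sweep (the
#'   monotonicity monitor).  Disable inside tight bootstrap loops.
#'
#' @return An object of class `partition_functions` with components
#'   `omega_A`, `omega_B` (length `N_max + 1`, index `k + 1`), `Z_N`,
#'   `gauge` (`"omega0"`), `iterations`, `residual`, `converged`, and
#'   `log_lik_trace` (log-likelihood per sweep; non-decreasing).
#' @seealso [log_likelihood()], [gc_distribution()]
#' @export
solve_partition_functions <- function(counts, tol = 1e-10, max_iter = 100000L,
                                      init = NULL, likelihood_trace = TRUE) {
  stopifnot(inherits(counts, "count_matrix"), tol > 0)
  if (sum(counts$L) <= 0) stop("count matrix has no frames")
  N_max <- counts$N_max
  K <- N_max + 1L                       # k = 0..N_max at index k+1
  A <- counts$A; B <- counts$B; L <- counts$L
  if (A[1] <= 0 || B[1] <= 0)
    stop("gauge fixing requires observed frames with k = 0 in each region ",
         "(A_0 > 0 and B_0 > 0)")

  supp_A <- A > 0
  supp_B <- B > 0
  omega_A <- if (is.null(init)) as.numeric(supp_A) else as.numeric(init$omega_A)
  omega_B <- if (is.null(init)) as.numeric(supp_B) else as.numeric(init$omega_B)
  omega_A[!supp_A] <- 0
  omega_B[!supp_B] <- 0
  omega_A <- omega_A / omega_A[1]
  omega_B <- omega_B / omega_B[1]

  active_N <- which(L > 0)
  # Z_N = sum_k omega_A(k) omega_B(N-k)
  z_of <- function(oA, oB) {
    vapply(seq_len(N_max), function(N) {
      k <- 0:N
      sum(oA[k + 1L] * oB[N - k + 1L])
    }, numeric(1))
  }

  ll_trace <- numeric(0)
  iter <- 0L
  resid <- Inf
  repeat {
    iter <- iter + 1L
    Z <- z_of(omega_A, omega_B)
    if (likelihood_trace)
      ll_trace <- c(ll_trace, .ll_counts(counts, omega_A, omega_B, Z))

    # denominators D_A(k) = sum_N L_N omega_B(N-k)/Z_N  (N >= k)
    new_A <- numeric(K); new_B <- numeric(K)
    for (kk in which(supp_A)) {
      k <- kk - 1L
      Ns <- active_N[active_N >= k]
      den <- sum(L[Ns] * omega_B[Ns - k + 1L] / Z[Ns])
      new_A[kk] <- A[kk] / den
    }
    for (kk in which(supp_B)) {
      k <- kk - 1L
      Ns <- active_N[active_N >= k]
      den <- sum(L[Ns] * omega_A[Ns - k + 1L] / Z[Ns])
      new_B[kk] <- B[kk] / den
    }
    new_A <- new_A / new_A[1]
    new_B <- new_B / new_B[1]

    rel <- c(abs(new_A[supp_A] / omega_A[supp_A] - 1),
             abs(new_B[supp_B] / omega_B[supp_B] - 1))
    resid <- max(rel)
    omega_A <- new_A; omega_B <- new_B
    if (resid < tol || iter >= max_iter) break
  }
  Z <- z_of(omega_A, omega_B)
  converged <- resid < tol
  if (!converged)
    warning(sprintf("partition-function solver did not converge: residual %.3e after %d sweeps",
                    resid, iter))
  names(omega_A) <- names(omega_B) <- 0:N_max
  structure(list(omega_A = omega_A, omega_B = omega_B, Z_N = Z,
                 gauge = "omega0", iterations = iter, residual = resid,
                 converged = converged, log_lik_trace = ll_trace,
                 N_max = N_max),
            class = "partition_functions")
}

#' @export
print.partition_functions <- function(x, ...) {
  cat(sprintf("partition_functions: N_max = %d, gauge = %s, %d sweeps, residual %.2e%s\n",
              x$N_max, x$gauge, x$iterations, x$residual,
              if (x$converged) "" else " (NOT converged)"))
  cat("omega_A:", format(x$omega_A, digits = 4), "\n")
  cat("omega_B:", format(x$omega_B, digits = 4), "\n")
  invisible(x)
}

# internal: log-likelihood given precomputed Z
.ll_counts <- function(counts, omega_A, omega_B, Z) {
  ll <- 0
  for (N in which(counts$L > 0)) {
    k <- 0:N
    tk <- counts$t[N, k + 1L]
    pos <- tk > 0
    if (!any(pos)) next
    prod_ab <- omega_A[k + 1L][pos] * omega_B[N - k + 1L][pos]
    if (any(prod_ab <= 0))
      stop("counts observed at occupancies outside the model support (N = ", N, ")")
    ll <- ll + sum(tk[pos] * (log(prod_ab) - log(Z[N])))
  }
  ll
}

#' Align the residual gauge tilt against a reference
#'
#' The likelihood is flat along the `lambda^k` tilt direction, so the
#' solver's fixed point carries an arbitrary tilt.  For direct comparison
#' with reference partition functions (e.g. the exact lattice ones) this
#' helper estimates `log lambda` by least squares on the region-B log
#' ratios and removes the tilt from both regions.  Observables never need
#' this: they are gauge invariant once the chemical potential is
#' calibrated from a concentration.
#'
#' @param pf A `partition_functions` object.
#' @param omega_B_ref Reference region-B partition function (length
#'   `N_max + 1`).
#' @return `pf` with both `omega` vectors rescaled by `lambda^-k`.
#' @export
gauge_align <- function(pf, omega_B_ref) {
  k <- 0:pf$N_max
  sup <- pf$omega_B > 0 & omega_B_ref > 0 & k > 0
  if (!any(sup)) stop("no common support to estimate the gauge tilt")
  d <- log(pf$omega_B[sup] / omega_B_ref[sup])
  log_lambda <- sum(k[sup] * d) / sum(k[sup]^2)
  pf$omega_A <- pf$omega_A * exp(-log_lambda * k)
  pf$omega_B <- pf$omega_B * exp(-log_lambda * k)
  pf$Z_N <- vapply(seq_len(pf$N_max), function(N) {
    kk <- 0:N
    sum(pf$omega_A[kk + 1L] * pf$omega_B[N - kk + 1L])
  }, numeric(1))
  pf
}

#' Log-likelihood of a count matrix under given partition functions
#'
#' Computes `sum_{N,k} t[N,k] log(Omega_A(k) Omega_B(N-k) / Z_N)`.  The
#' value is invariant under the `lambda^k` gauge rescaling of both
#' `Omega` vectors; the solver uses it as its monotonicity monitor.
#'
#' @param counts A `count_matrix`.
#' @param pf A `partition_functions` object, or any list with `omega_A`,
#'   `omega_B` vectors of length `N_max + 1`.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(counts, pf) {
  stopifnot(inherits(counts, "count_matrix"))
  omega_A <- pf$omega_A; omega_B <- pf$omega_B
  if (any(omega_A < 0) || any(omega_B < 0))
    stop("partition-function entries must be nonnegative")
  N_max <- counts$N_max
  Z <- vapply(seq_len(N_max), function(N) {
    k <- 0:N
    sum(omega_A[k + 1L] * omega_B[N - k + 1L])
  }, numeric(1))
  if (any(Z[counts$L > 0] <= 0))
    stop("Z_N must be positive for every trajectory with frames")
  .ll_counts(counts, omega_A, omega_B, Z)
}
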