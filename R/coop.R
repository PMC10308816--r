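# Concentration-dependent reactivities, power-law exponents, pairwise
# free-energy couplings, Bayesian-bootstrap uncertainties and
# Benjamini-Hochberg selection.

#' Concentration-dependent reactivity profile
#'
#' For every concentration on the grid: calibrate the chemical potential
#' against the buffer, compute per-frame grand-canonical weights, and
#' return the weighted frequency with which each nucleotide is observed in
#' a bound state.  Because the weights vary smoothly with the chemical
#' potential, the resulting curves are smooth functions of concentration.
#'
#' @param binding A `binding_table` whose frames align with the occupancy
#'   stream used to solve `pf`.
#' @param pf `partition_functions` solved from the occupancies in
#'   `binding` (if `NULL`, solved here).
#' @param V_B Buffer volume in nm^3.
#' @param concentrations Strictly increasing grid of molarities.
#' @param temperature Kelvin (default 300).
#' @return Data frame of class `reactivity_curves` with columns
#'   `nucleotide`, `concentration_M`, `R`.
#' @export
reactivity_profile <- function(binding, pf = NULL, V_B, concentrations,
                               temperature = 300) {
  stopifnot(all(diff(concentrations) > 0), all(concentrations > 0))
  occ <- occupancies_from_binding(binding)
  counts <- build_count_matrix(occ,
                               N_max = max(as.integer(names(occ))))
  if (is.null(pf)) pf <- solve_partition_functions(counts)
  ceiling_conc <- concentration_ceiling(pf, V_B)
  if (any(concentrations >= ceiling_conc))
    stop(sprintf("grid concentrations at or above the attainable ceiling %.6g M",
                 ceiling_conc))
  df <- binding[order(binding$trajectory_N, binding$frame), ]
  nucs <- .bt_nucleotides(df)
  bound <- as.matrix(df[, nucs, drop = FALSE])
  out <- lapply(concentrations, function(C) {
    bm <- mu_from_concentration(pf, buffer_spec(V_B, C, temperature))
    w <- frame_weights(pf, bm, counts, occ)
    R <- as.numeric(crossprod(bound, w$weight))
    data.frame(nucleotide = nucs, concentration_M = C, R = R)
  })
  res <- do.call(rbind, out)
  class(res) <- c("reactivity_curves", "data.frame")
  res
}

#' Fit a power law to a reactivity curve
#'
#' Ordinary least squares of `log R` on `log C` over a concentration
#' window: `R = alpha * C^beta`, `beta` the slope and `alpha` the
#' extrapolated reactivity at 1 M.
#'
#' @param concentration_M Molarity grid.
#' @param R Reactivities (must be positive inside the window).
#' @param c_min,c_max Fitting window bounds in mol/L (defaults 1e-3 and
#'   1e-2, the range where higher-order concentration dependence emerges).
#' @return List with `alpha`, `beta`, `se_alpha`, `se_beta` (OLS standard
#'   errors; `NA` with fewer than 3 points), `n_points`, and the window.
#' @export
fit_power_law <- function(concentration_M, R, c_min = 1e-3, c_max = 1e-2) {
  sel <- concentration_M >= c_min & concentration_M <= c_max
  if (sum(sel) < 2L)
    stop("need at least two grid points inside the fitting window")
  C <- concentration_M[sel]; Rw <- R[sel]
  if (any(Rw <= 0))
    stop("nonpositive reactivities inside the fitting window")
  fit <- stats::lm(log(Rw) ~ log(C))
  co <- stats::coef(fit)
  # suppressWarnings: noise-free curves trip lm's perfect-fit warning
  se <- if (length(Rw) > 2L) suppressWarnings(sqrt(diag(stats::vcov(fit))))
        else c(NA_real_, NA_real_)
  alpha <- exp(unname(co[1]))
  list(alpha = alpha, beta = unname(co[2]),
       se_alpha = alpha * unname(se[1]), se_beta = unname(se[2]),
       n_points = length(Rw), c_min = c_min, c_max = c_max)
}

#' Weighted pairwise binding-state frequencies
#'
#' @param binding A `binding_table` (frames in trajectory/frame order).
#' @param weights A `frame_weight_table` aligned with `binding`.
#' @param i,j Nucleotide ids.
#' @return Named numeric `(p00, p01, p10, p11)` summing to 1.
#' @export
pair_state_frequencies <- function(binding, weights, i, j) {
  nucs <- .bt_nucleotides(binding)
  if (!(i %in% nucs) || !(j %in% nucs))
    stop("unknown nucleotide id(s): ",
         paste(setdiff(c(i, j), nucs), collapse = ", "))
  ord <- order(binding$trajectory_N, binding$frame, method = "radix")
  bi <- binding[[i]][ord] > 0
  bj <- binding[[j]][ord] > 0
  w <- weights$weight
  if (length(bi) != length(w)) stop("binding table and weights misaligned")
  p <- c(p00 = sum(w[!bi & !bj]), p01 = sum(w[!bi & bj]),
         p10 = sum(w[bi & !bj]), p11 = sum(w[bi & bj]))
  p / sum(p)
}

#' Pairwise free-energy coupling from state frequencies
#'
#' `DDG_ij = -kT ln[(p11 p00) / (p10 p01)]`, reported in k_B T units by
#' default; negative values mean cooperative binding (site i binds more
#' favourably when j is bound), positive anticooperative.  Pairs with any
#' zero cell are flagged undefined rather than returned infinite.
#'
#' @param p Named frequencies `(p00, p01, p10, p11)`, normalized.
#' @param temperature Kelvin; only used when `units = "kcal/mol"`.
#' @param units `"kT"` (default) or `"kcal/mol"`.
#' @return Scalar coupling, or `NA` when undefined.
#' @export
coupling_free_energy <- function(p, temperature = 300, units = c("kT", "kcal/mol")) {
  units <- match.arg(units)
  if (abs(sum(p) - 1) > 1e-8) stop("pair-state frequencies must sum to 1")
  if (any(p <= 0)) return(NA_real_)
  ddg <- -log((p[["p11"]] * p[["p00"]]) / (p[["p10"]] * p[["p01"]]))
  if (units == "kcal/mol") ddg <- ddg * 0.0019872041 * temperature
  unname(ddg)
}

#' Free-energy coupling matrix over all nucleotide pairs
#'
#' Computes the weighted pair-state frequencies and the coupling for every
#' unordered nucleotide pair at one reagent concentration.
#'
#' @param binding A `binding_table`.
#' @param weights A `frame_weight_table` for the concentration of
#'   interest.
#' @param temperature Kelvin.
#' @param units `"kT"` or `"kcal/mol"`.
#' @return Object of class `coupling_matrix`: symmetric matrix with `NA`
#'   diagonal and `NA` for undefined pairs; attribute `pairs` holds a long
#'   data frame with the frequencies.
#' @export
coupling_matrix <- function(binding, weights, temperature = 300,
                            units = c("kT", "kcal/mol")) {
  units <- match.arg(units)
  nucs <- .bt_nucleotides(binding)
  m <- matrix(NA_real_, length(nucs), length(nucs),
              dimnames = list(nucs, nucs))
  pairs <- list()
  for (a in seq_along(nucs)) for (b in seq_along(nucs)) {
    if (b <= a) next
    p <- pair_state_frequencies(binding, weights, nucs[a], nucs[b])
    ddg <- coupling_free_energy(p, temperature, units)
    m[a, b] <- m[b, a] <- ddg
    pairs[[length(pairs) + 1L]] <-
      data.frame(i = nucs[a], j = nucs[b], t(p), ddg = ddg,
                 defined = !is.na(ddg))
  }
  structure(m, pairs = do.call(rbind, pairs), units = units,
            class = c("coupling_matrix", class(m)))
}

#' Bayesian bootstrap over trajectories
#'
#' Treats each constant-N trajectory as a single data point.  Per
#' iteration, trajectory weights are drawn from a flat Dirichlet
#' distribution; the analysis closure receives them (scaled so they
#' average 1) and is expected to rescale each trajectory's frame counts by
#' its weight, re-solve the partition functions, re-calibrate the chemical
#' potential, and recompute the observable.
#'
#' @param analysis `function(traj_weights)` returning a numeric vector of
#'   fixed length; `traj_weights` is named by trajectory N and sums to
#'   `n_trajectories`.
#' @param trajectory_Ns Integer vector of trajectory particle numbers
#'   (>= 2 trajectories).
#' @param n_iter Bootstrap iterations (default 10000).
#' @param seed Optional integer seed.
#' @return Matrix `n_iter x length(output)` of bootstrap replicates.
#' @export
bayesian_bootstrap <- function(analysis, trajectory_Ns, n_iter = 10000L,
                               seed = NULL) {
  if (length(trajectory_Ns) < 2L)
    stop("Bayesian bootstrap needs at least two trajectories")
  if (!is.null(seed)) set.seed(seed)
  n <- length(trajectory_Ns)
  out <- NULL
  for (it in seq_len(n_iter)) {
    g <- stats::rgamma(n, shape = 1)        # flat Dirichlet via normalized Exp(1)
    w <- g / sum(g) * n
    names(w) <- trajectory_Ns
    val <- analysis(w)
    if (is.null(out)) out <- matrix(NA_real_, n_iter, length(val),
                                    dimnames = list(NULL, names(val)))
    out[it, ] <- val
  }
  out
}

#' Reweight a count matrix by trajectory weights
#'
#' Multiplies each trajectory's row of frame counts by its Dirichlet
#' weight, producing the fractional count matrix consumed by
#' [solve_partition_functions()] during bootstrap iterations.
#'
#' @param counts A `count_matrix`.
#' @param traj_weights Named numeric vector (names = trajectory N).
#' @return A `count_matrix` with real-valued counts.
#' @export
reweight_counts <- function(counts, traj_weights) {
  t_mat <- counts$t
  for (nm in names(traj_weights)) {
    N <- as.integer(nm)
    t_mat[N, ] <- t_mat[N, ] * traj_weights[[nm]]
  }
  new_count_matrix(t_mat)
}

#' Benjamini-Hochberg selection of significant couplings
#'
#' Standard step-up FDR control on per-pair empirical bootstrap p-values
#' (fraction of iterations whose coupling contradicts the point-estimate
#' sign, with the `(r + 1)/(B + 1)` finite-sample correction applied by
#' the caller).  Pairs with undefined couplings must be excluded before
#' calling.
#'
#' @param p_values Numeric vector of p-values, one per tested pair.
#' @param alpha FDR level (default 0.01).
#' @param m Number of hypotheses; must equal `length(p_values)`.
#' @return Logical vector: `TRUE` where the pair is selected.
#' @export
bh_select <- function(p_values, alpha = 0.01, m = length(p_values)) {
  if (m != length(p_values))
    stop(sprintf("m = %d does not match the %d supplied p-values",
                 m, length(p_values)))
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH") <= alpha
}

#' Empirical bootstrap p-value with finite-sample correction
#'
#' `(r + 1) / (B + 1)` where `r` counts bootstrap replicates whose sign
#' contradicts the point estimate; avoids exact zeros at finite `B`.
#'
#' @param replicates Numeric vector of bootstrap replicates of the
#'   statistic.
#' @param point_estimate Sign reference.
#' @return Scalar p-value.
#' @export
bootstrap_sign_pvalue <- function(replicates, point_estimate) {
  if (point_estimate == 0) return(1)
  r <- sum(sign(replicates) != sign(point_estimate), na.rm = TRUE)
  (r + 1) / (sum(!is.na(replicates)) + 1)
}

#' Number of unordered pairs among analyzed nucleotides
#'
#' @param n_nucleotides Number of analyzed nucleotides.
#' @return `choose(n, 2)` simultaneous pair hypotheses.
#' @export
n_pair_hypotheses <- function(n_nucleotides) {
  as.integer(choose(n_nucleotides, 2))
}
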